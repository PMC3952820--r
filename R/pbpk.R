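#' Compound parameter set
#'
#' Physicochemical and kinetic parameters of one compound: molecular weight,
#' lipophilicity, fraction unbound, the passive-exchange interface list, a
#' compound-specific lipid affinity constant (for the steatosis model), and
#' the metabolization parameters. Each interface `(a, b)` carries a
#' dimensionless partition coefficient `K_ab` (exchange vanishes when
#' `c_a = K_ab c_b`) and a volume-normalized permeability-exchange
#' coefficient `P_ab` (1/min). The default topology is the serial chain
#' rbc-pls, pls-int, int-cell; a fourth interface slot may be added.
#'
#' @param name compound name.
#' @param MW molecular weight (g/mol).
#' @param logP lipophilicity (dimensionless).
#' @param fu fraction unbound in plasma, in `[0, 1]`.
#' @param interfaces data.frame with columns `a`, `b` (subspace names among
#'   rbc, pls, int, cell), `K` (`> 0`), `P` (1/min, `>= 0`).
#' @param k_lip lipid affinity constant of the steatosis model (`>= 0`).
#' @param metabolism a [metabolism_params()].
#' @export
compound_params <- function(name, MW, logP, fu,
                            interfaces, k_lip = 0,
                            metabolism = metabolism_params("none")) {
  subs <- c("rbc", "pls", "int", "cell")
  stopifnot(is.data.frame(interfaces),
    all(c("a", "b", "K", "P") %in% names(interfaces)))
  if (!all(interfaces$a %in% subs) || !all(interfaces$b %in% subs))
    stop("interfaces must connect subspaces among rbc, pls, int, cell")
  if (any(interfaces$a == interfaces$b))
    stop("interfaces must connect distinct subspaces")
  if (any(interfaces$K <= 0)) stop("partition coefficients must be positive")
  if (any(interfaces$P < 0)) stop("permeabilities must be nonnegative")
  if (fu < 0 || fu > 1) stop("fraction unbound must be in [0, 1]")
  if (k_lip < 0) stop("k_lip must be nonnegative")
  if (nrow(interfaces) > 4) stop("at most four passive interfaces")
  structure(list(name = name, MW = MW, logP = logP, fu = fu,
    interfaces = interfaces, k_lip = k_lip, metabolism = metabolism),
  class = "compound_params")
}

#' Metabolization parameters
#'
#' Metabolization acts on the cellular concentration only and is a pure sink
#' (no metabolite tracking): first-order linear mass action
#' (`r = k_met c_cell`) or Michaelis-Menten (`r = V_max c_cell / (K_m + c_cell)`).
#'
#' @param mode `"none"`, `"linear"` or `"michaelis_menten"`.
#' @param k_met first-order rate (1/min), linear mode.
#' @param V_max maximum rate (umol/L/min), MM mode.
#' @param K_m half-saturation concentration (umol/L), MM mode.
#' @export
metabolism_params <- function(mode = c("none", "linear", "michaelis_menten"),
                              k_met = NULL, V_max = NULL, K_m = NULL) {
  mode <- match.arg(mode)
  if (mode == "linear" && (is.null(k_met) || k_met <= 0))
    stop("linear metabolization needs k_met > 0")
  if (mode == "michaelis_menten" &&
    (is.null(V_max) || V_max <= 0 || is.null(K_m) || K_m <= 0))
    stop("Michaelis-Menten metabolization needs V_max > 0 and K_m > 0")
  structure(list(mode = mode, k_met = k_met, V_max = V_max, K_m = K_m),
    class = "metabolism_params")
}

#' Metabolization rate
#'
#' @param c_cell cellular concentration(s), umol/L, `>= 0`.
#' @param params a [metabolism_params()].
#' @return rate(s) in umol/L/min, `>= 0` (subtracted from `dc_cell/dt`).
#' @export
metabolization_rate <- function(c_cell, params) {
  if (any(c_cell < 0)) stop("c_cell must be nonnegative")
  switch(params$mode,
    none = rep(0, length(c_cell)),
    linear = params$k_met * c_cell,
    michaelis_menten = params$V_max * c_cell / (params$K_m + c_cell)
  )
}

#' Passive exchange right-hand side
#'
#' Gradient-driven exchange across the compound's interfaces: for each
#' interface `(a, b)` with deviation `J = c_a - K_ab c_b`,
#' `dc_a/dt -= (P_ab / f_a) J` and `dc_b/dt += (P_ab / f_b) J`, so the total
#' mass `sum_i f_i c_i` is conserved exactly and the right-hand side
#' vanishes at the interface equilibria. Linear in `c`. Vectorized over grid
#' nodes: `c` may be an `n x 4` matrix, `f` an `n x 4` (or length-4) matrix
#' of volume fractions, and per-node `K`/`P` overrides may be supplied.
#'
#' @param c concentrations, length-4 vector `(rbc, pls, int, cell)` or
#'   `n x 4` matrix (umol/L).
#' @param params a [compound_params()].
#' @param f volume fractions, length >= 4 named vector or `n x 4+` matrix.
#' @param K_override,P_override optional list keyed `"a:b"` of per-node
#'   vectors replacing an interface's `K` or `P` (e.g. a steatotic
#'   `K_cell` field, or zeroed permeability in necrotic voxels).
#' @return `dc/dt` with the shape of `c`, in umol/L/min.
#' @export
exchange_rhs <- function(c, params, f, K_override = NULL, P_override = NULL) {
  subs <- c("rbc", "pls", "int", "cell")
  vec <- is.null(dim(c))
  cm <- if (vec) matrix(c, 1, 4) else c
  fm <- if (is.null(dim(f))) {
    matrix(f[subs], nrow(cm), 4, byrow = TRUE, dimnames = list(NULL, subs))
  } else f[, subs, drop = FALSE]
  colnames(cm) <- subs
  out <- matrix(0, nrow(cm), 4, dimnames = list(NULL, subs))
  ifc <- params$interfaces
  for (r in seq_len(nrow(ifc))) {
    a <- ifc$a[r]; b <- ifc$b[r]
    key <- paste(a, b, sep = ":")
    K <- if (!is.null(K_override[[key]])) K_override[[key]] else ifc$K[r]
    P <- if (!is.null(P_override[[key]])) P_override[[key]] else ifc$P[r]
    fa <- fm[, a]; fb <- fm[, b]
    if (any(fa == 0 & P > 0) || any(fb == 0 & P > 0))
      stop(sprintf("zero volume fraction on active interface %s", key))
    J <- P * (cm[, a] - K * cm[, b])
    out[, a] <- out[, a] - J / pmax(fa, .Machine$double.xmin)
    out[, b] <- out[, b] + J / pmax(fb, .Machine$double.xmin)
  }
  if (vec) drop(out) else out
}

#' Adaptive Runge-Kutta-Fehlberg 4(5) integration
#'
#' Classical Fehlberg tableau with automatic step-size control: the embedded
#' 5th-order solution estimates the local error of the accepted 4th-order
#' step; steps are retried with `h <- 0.9 h (tol/err)^(1/5)` (clipped to
#' [0.2, 5] fold change) until the scaled error is `<= 1`. Works on states
#' of any shape (vector or matrix; grid-node-vectorized states share the
#' adaptive step, whose acceptance bound then holds at every node).
#'
#' @param rhs function `(t, y) -> dy/dt` (same shape as `y`).
#' @param y0 initial state.
#' @param t_span length-2 numeric `(t0, t1)`.
#' @param tol absolute and relative local error tolerance per step.
#' @param h0 initial step; default `min(0.1 span, span)`.
#' @param max_steps safety bound on accepted + rejected steps.
#' @return list `y` (state at `t1`), `steps` (accepted), `rejected`.
#' @export
rkf45_integrate <- function(rhs, y0, t_span, tol = 1e-8, h0 = NULL,
                            max_steps = 100000L) {
  if (tol <= 0) stop("tol must be positive")
  t <- t_span[1]
  tend <- t_span[2]
  span <- tend - t
  if (span <= 0) stop("t_span must be increasing")
  h <- if (is.null(h0)) 0.1 * span else min(h0, span)
  y <- y0
  steps <- 0L
  rejected <- 0L
  total <- 0L
  while (t < tend - 1e-14 * abs(span)) {
    h <- min(h, tend - t)
    if (h < 1e-12 * span)
      stop(sprintf("RKF45 step size underflow at t = %g (|y|_max = %g)",
        t, max(abs(y))))
    k1 <- rhs(t, y)
    k2 <- rhs(t + h / 4, y + h * k1 / 4)
    k3 <- rhs(t + 3 * h / 8, y + h * (3 * k1 + 9 * k2) / 32)
    k4 <- rhs(t + 12 * h / 13,
      y + h * (1932 * k1 - 7200 * k2 + 7296 * k3) / 2197)
    k5 <- rhs(t + h, y + h * (439 / 216 * k1 - 8 * k2 + 3680 / 513 * k3 -
      845 / 4104 * k4))
    k6 <- rhs(t + h / 2, y + h * (-8 / 27 * k1 + 2 * k2 - 3544 / 2565 * k3 +
      1859 / 4104 * k4 - 11 / 40 * k5))
    y4 <- y + h * (25 / 216 * k1 + 1408 / 2565 * k3 + 2197 / 4104 * k4 -
      1 / 5 * k5)
    y5 <- y + h * (16 / 135 * k1 + 6656 / 12825 * k3 + 28561 / 56430 * k4 -
      9 / 50 * k5 + 2 / 55 * k6)
    scale <- tol * (1 + pmax(abs(y), abs(y4)))
    ratio <- max(abs(y5 - y4) / scale)
    total <- total + 1L
    if (total > max_steps) stop("RKF45 exceeded max_steps")
    if (is.na(ratio) || ratio > 1) {
      rejected <- rejected + 1L
      fac <- if (is.na(ratio)) 0.2 else max(0.2, 0.9 * ratio^(-0.2))
      h <- h * fac
      next
    }
    y <- y4
    t <- t + h
    steps <- steps + 1L
    fac <- if (ratio < 1e-12) 5 else min(5, max(0.2, 0.9 * ratio^(-0.2)))
    h <- h * fac
  }
  list(y = y, steps = steps, rejected = rejected)
}

#' One PBPK reaction step on a subspace field
#'
#' Integrates the pointwise exchange + metabolization ODEs over `dt` seconds
#' at every foreground voxel (vectorized, shared adaptive RKF45 step).
#' Returns the updated field and the metabolized mass, measured exactly as
#' the drop of `sum_i f_i c_i` (exchange conserves it; metabolization is the
#' only sink).
#'
#' @param field a [subspace_field()].
#' @param params a [compound_params()].
#' @param dt step in seconds.
#' @param tol RKF45 tolerance.
#' @param K_override,P_override per-voxel interface overrides (see
#'   [exchange_rhs()]).
#' @param met_scale per-voxel multiplier on the metabolization rate (0 in
#'   necrotic voxels), default 1.
#' @return list `field`, `metabolized` (umol).
#' @export
pbpk_step <- function(field, params, dt, tol = 1e-8,
                      K_override = NULL, P_override = NULL, met_scale = 1) {
  f <- field$frac[, 1:4, drop = FALSE]
  met <- params$metabolism
  rhs <- function(t, cm) {
    cm[cm < 0] <- 0
    d <- exchange_rhs(cm, params, f, K_override, P_override)
    if (met$mode != "none") {
      r <- met_scale * metabolization_rate(cm[, 4], met)
      d[, 4] <- d[, 4] - r
    }
    d
  }
  h3 <- field$mask$spacing^3
  mass_before <- sum(field$conc * f) * h3 * L_PER_MM3
  # integrate in minutes (kinetic rates are 1/min)
  out <- rkf45_integrate(rhs, field$conc, c(0, dt / 60), tol = tol)
  cm <- out$y
  cm[cm < 0] <- 0
  field$conc <- cm
  mass_after <- sum(field$conc * f) * h3 * L_PER_MM3
  list(field = field, metabolized = mass_before - mass_after)
}

#' Well-stirred liver compartment reference model
#'
#' The classical perfusion-limited counterpart of the spatial model: one
#' well-stirred compartment per subspace with the same volume fractions,
#' exchange and metabolization kinetics, fed and drained at the total
#' perfusion `Q_liv`. The sinusoidal phases obey
#' `dC_ph/dt = Q_ph / (f_ph V) (c_in_ph(t) - C_ph) + exchange`, interstitial
#' and cellular concentrations follow exchange (+ metabolization sink).
#'
#' @param params a [compound_params()].
#' @param fractions length-5 named volume fractions.
#' @param V_liv liver volume (mm^3).
#' @param Q_liv total perfusion (mm^3/s).
#' @param inflow function `t -> c(rbc, pls)` inflow concentrations (umol/L).
#' @param times output time grid (s), starting at 0.
#' @param tol RKF45 tolerance.
#' @return data.frame `time`, `c_out` (whole-blood outflow umol/L), `c_rbc`,
#'   `c_pls`, `c_int`, `c_cell`, `metabolized` (cumulative umol).
#' @export
wellstirred_reference <- function(params, fractions, V_liv, Q_liv, inflow,
                                  times, tol = 1e-8) {
  f <- fractions[c("rbc", "pls", "int", "cell")]
  f_sin <- f[["rbc"]] + f[["pls"]]
  wph <- c(f[["rbc"]], f[["pls"]]) / f_sin
  Qph <- Q_liv * wph
  met <- params$metabolism
  # state: C_rbc, C_pls, C_int, C_cell, cumulative metabolized mass (umol)
  rhs <- function(t, y) {
    cc <- pmax(y[1:4], 0)
    d <- exchange_rhs(cc, params, f) / 60 # 1/min -> 1/s
    cin <- inflow(t)
    d[1] <- d[1] + Qph[1] * (cin[1] - cc[1]) / (f[["rbc"]] * V_liv)
    d[2] <- d[2] + Qph[2] * (cin[2] - cc[2]) / (f[["pls"]] * V_liv)
    rmet <- if (met$mode == "none") 0 else metabolization_rate(cc[4], met) / 60
    d[4] <- d[4] - rmet
    c(d, rmet * f[["cell"]] * V_liv * L_PER_MM3)
  }
  y <- numeric(5)
  out <- data.frame(time = times, c_out = 0, c_rbc = 0, c_pls = 0,
    c_int = 0, c_cell = 0, metabolized = 0)
  for (i in seq_along(times)[-1]) {
    y <- rkf45_integrate(rhs, y, c(times[i - 1], times[i]), tol = tol)$y
    out[i, 2:7] <- c(sum(y[1:2] * wph), y[1:4], y[5])
  }
  out$c_out <- out$c_rbc * wph[1] + out$c_pls * wph[2]
  out
}
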