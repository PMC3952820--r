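#' Radius-dependent effective blood viscosity (Fåhræus–Lindqvist effect)
#'
#' In vessels below roughly 0.5 mm diameter the apparent viscosity of blood
#' drops markedly. We use the empirical in-vitro law of Pries, Neuhaus &
#' Gaehtgens (Am J Physiol 263:H1770, 1992) for the relative apparent
#' viscosity as a function of tube diameter D (micrometer) and discharge
#' hematocrit H:
#'
#'   mu_45(D)  = 220 exp(-1.3 D) + 3.2 - 2.44 exp(-0.06 D^0.645)
#'   C(D)      = (0.8 + exp(-0.075 D)) (-1 + 1/(1 + 1e-11 D^12)) +
#'               1/(1 + 1e-11 D^12)
#'   mu(D, H)  = 1 + (mu_45 - 1) ((1 - H)^C - 1) / ((1 - 0.45)^C - 1)
#'
#' The large-vessel asymptote is mu_45 -> 3.2 at H = 0.45.
#'
#' @param hematocrit discharge hematocrit in (0, 1).
#' @return An object of class `viscosity_model`.
#' @export
viscosity_model <- function(hematocrit = 0.45) {
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must be in (0, 1)")
  structure(list(hematocrit = hematocrit), class = "viscosity_model")
}

#' Relative effective viscosity at a vessel radius
#'
#' @param radius vessel radius in mm, `> 0` (vectorized).
#' @param model a [viscosity_model()].
#' @return dimensionless relative viscosity, same length as `radius`.
#' @export
effective_viscosity <- function(radius, model = viscosity_model()) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("radius must be positive (mm)")
  D <- 2000 * radius # diameter in micrometer
  mu45 <- 220 * exp(-1.3 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
  H <- model$hematocrit
  if (abs(H - 0.45) < 1e-12) return(mu45)
  f <- 1 / (1 + 1e-11 * D^12)
  C <- (0.8 + exp(-0.075 * D)) * (-1 + f) + f
  1 + (mu45 - 1) * ((1 - H)^C - 1) / ((1 - 0.45)^C - 1)
}
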