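#' Terminal-edge line sources and sinks for the Darcy problem
#'
#' Every supplying terminal edge discharges its flow uniformly along its
#' centerline (positive volumetric source), every draining terminal edge
#' withdraws its flow (negative). With the equal-leaf-flow rule the strengths
#' are `+-Q_liv / N_leaves / L_e` per mm, and the net total is zero exactly
#' (closed organ).
#'
#' @param svs flow-assigned supplying [vascular_tree()].
#' @param dvs flow-assigned draining [vascular_tree()].
#' @return data.frame of segments: `x0`, `y0`, `z0`, `x1`, `y1`, `z1` (mm),
#'   `strength` (mm^3/s per mm), `length`, `edge` (edge id in its tree),
#'   `kind`.
#' @export
build_line_sources <- function(svs, dvs) {
  if (is.null(svs$edges$flow) || is.null(dvs$edges$flow))
    stop("both trees must be flow-assigned")
  qs <- sum(svs$edges$flow[svs$is_leaf])
  qd <- sum(dvs$edges$flow[dvs$is_leaf])
  if (abs(qs - qd) > 1e-9 * max(qs, qd, 1))
    stop("supplying and draining trees carry unequal total flows")
  seg <- function(tree, sign) {
    le <- tree_leaf_edges(tree)
    a <- tree$nodes[tree$edges$parent[le], , drop = FALSE]
    b <- tree$nodes[tree$edges$child[le], , drop = FALSE]
    L <- tree$edges$length[le]
    data.frame(
      x0 = a[, 1], y0 = a[, 2], z0 = a[, 3],
      x1 = b[, 1], y1 = b[, 2], z1 = b[, 3],
      strength = sign * tree$edges$flow[le] / L, length = L,
      edge = le, kind = tree$kind
    )
  }
  rbind(seg(svs, +1), seg(dvs, -1))
}

# 8x8 stiffness matrix of a trilinear hexahedral element with side h and unit
# coefficient, by 2x2x2 Gauss quadrature (exact for this integrand).
# Corner order: (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),(1,0,1),(0,1,1),(1,1,1).
#' @keywords internal
.hex_stiffness <- function(h) {
  gp <- c(-1, 1) / sqrt(3) / 2 + 0.5 # Gauss points on [0,1]
  corners <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
  K <- matrix(0, 8, 8)
  shape_grad <- function(xi, corner) {
    s <- function(t, c) if (c == 1) t else 1 - t
    ds <- function(c) if (c == 1) 1 else -1
    c(
      ds(corner[1]) * s(xi[2], corner[2]) * s(xi[3], corner[3]),
      s(xi[1], corner[1]) * ds(corner[2]) * s(xi[3], corner[3]),
      s(xi[1], corner[1]) * s(xi[2], corner[2]) * ds(corner[3])
    ) / h
  }
  for (gx in gp) for (gy in gp) for (gz in gp) {
    G <- t(vapply(seq_len(8), function(k) shape_grad(c(gx, gy, gz), corners[k, ]),
      numeric(3)))
    K <- K + (G %*% t(G)) * (h^3 / 8)
  }
  K
}

#' Assemble the trilinear finite-element Darcy system on a mask
#'
#' Nodes are the foreground voxel centers; elements are the hexahedral cells
#' whose eight corner voxels are all foreground. Returns the (singular,
#' pure-Neumann) stiffness matrix and the node bookkeeping.
#' @keywords internal
.assemble_darcy <- function(mask, K_eff = 1) {
  h <- mask$spacing
  d <- mask$dim
  occ <- mask$occupancy
  loc <- array(0L, d)
  loc[mask$fg] <- seq_along(mask$fg)
  # element base voxels: all 8 corners foreground
  ok <- occ[-d[1], -d[2], -d[3], drop = FALSE] &
    occ[-1, -d[2], -d[3], drop = FALSE] &
    occ[-d[1], -1, -d[3], drop = FALSE] &
    occ[-1, -1, -d[3], drop = FALSE] &
    occ[-d[1], -d[2], -1, drop = FALSE] &
    occ[-1, -d[2], -1, drop = FALSE] &
    occ[-d[1], -1, -1, drop = FALSE] &
    occ[-1, -1, -1, drop = FALSE]
  base <- which(ok)
  if (!length(base)) stop("mask foreground supports no finite element")
  bi <- arrayInd(base, d - 1L)
  corners <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
  cn <- vapply(seq_len(8), function(k) {
    loc[cbind(bi[, 1] + corners[k, 1], bi[, 2] + corners[k, 2],
      bi[, 3] + corners[k, 3])]
  }, integer(nrow(bi)))
  cn <- matrix(cn, ncol = 8)
  Ke <- .hex_stiffness(h) * K_eff
  nel <- nrow(cn)
  ii <- jj <- integer(64 * nel)
  xx <- numeric(64 * nel)
  k <- 0L
  for (a in 1:8) for (b in 1:8) {
    idx <- k + seq_len(nel)
    ii[idx] <- cn[, a]
    jj[idx] <- cn[, b]
    xx[idx] <- Ke[a, b]
    k <- k + nel
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
    dims = c(length(mask$fg), length(mask$fg)))
  # nodes supported by at least one element; unsupported foreground voxels
  # (isolated surface corners) carry no pressure DOF and no flux
  active <- logical(length(mask$fg))
  active[unique(as.vector(cn))] <- TRUE
  loc_active <- loc
  loc_active[mask$fg[!active]] <- 0L
  list(A = A, loc = loc, loc_active = loc_active, active = active,
    n = length(mask$fg))
}

# exact line integrals of the trilinear nodal basis along a segment:
# subdivide at element-face crossings, 3-point Gauss per piece
#' @keywords internal
.line_load <- function(mask, loc, x0, x1, strength) {
  h <- mask$spacing
  d <- mask$dim
  L <- sqrt(sum((x1 - x0)^2))
  if (L == 0) return(NULL)
  # element coordinate: element base index along a dim is floor(x/h + 0.5)
  ts <- c(0, 1)
  for (dim in 1:3) {
    a <- x0[dim]; b <- x1[dim]
    if (abs(b - a) < 1e-14) next
    ks <- seq(floor(min(a, b) / h - 0.5), ceiling(max(a, b) / h + 0.5))
    cross <- ((ks + 0.5) * h - a) / (b - a)
    ts <- c(ts, cross[cross > 0 & cross < 1])
  }
  ts <- sort(unique(ts))
  gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)) / 2 + 0.5
  gw <- c(5, 8, 5) / 18
  nodes <- integer(0)
  vals <- numeric(0)
  for (s in seq_len(length(ts) - 1)) {
    t0 <- ts[s]; t1 <- ts[s + 1]
    seg_len <- (t1 - t0) * L
    if (seg_len <= 0) next
    for (g in seq_along(gp)) {
      t <- t0 + gp[g] * (t1 - t0)
      x <- x0 + t * (x1 - x0)
      bix <- pmin(pmax(floor(x / h + 0.5), 1), d - 1L)
      xi <- x / h + 0.5 - bix # in [0,1] within the element
      wts <- c(
        (1 - xi[1]) * (1 - xi[2]) * (1 - xi[3]), xi[1] * (1 - xi[2]) * (1 - xi[3]),
        (1 - xi[1]) * xi[2] * (1 - xi[3]), xi[1] * xi[2] * (1 - xi[3]),
        (1 - xi[1]) * (1 - xi[2]) * xi[3], xi[1] * (1 - xi[2]) * xi[3],
        (1 - xi[1]) * xi[2] * xi[3], xi[1] * xi[2] * xi[3]
      )
      corners <- as.matrix(expand.grid(a = 0:1, b = 0:1, c = 0:1))
      cs <- loc[cbind(bix[1] + corners[, 1], bix[2] + corners[, 2],
        bix[3] + corners[, 3])]
      contrib <- strength * seg_len * gw[g] * wts
      keep <- cs > 0L
      if (!all(keep)) {
        # corner outside foreground: reassign its share to present corners
        lost <- sum(contrib[!keep])
        contrib <- contrib[keep]
        if (length(contrib)) contrib <- contrib + lost / length(contrib)
        cs <- cs[keep]
      }
      nodes <- c(nodes, cs)
      vals <- c(vals, contrib)
    }
  }
  list(nodes = nodes, vals = vals)
}

#' Solve the steady Darcy pressure equation on the organ mask
#'
#' Solves `-div(K_eff grad p) = q` weakly on the foreground with zero-flux
#' (pure Neumann) boundary conditions, the right-hand side assembled by exact
#' line integrals of the trilinear basis along each source segment. The
#' nullspace is fixed by a mean-zero Lagrange multiplier; the returned `p` is
#' a relative pressure only.
#'
#' @param mask an [organ_mask()].
#' @param sources a [build_line_sources()] data.frame.
#' @param K_eff effective permeability (permeability over dynamic viscosity);
#'   unity by convention, it only rescales `p`.
#' @param tol compatibility tolerance: `|sum(q)|` relative to `sum(|q|)`.
#' @return object of class `pressure_field`: `p` (one value per foreground
#'   voxel, mean zero), `mask`, `K_eff`.
#' @export
solve_pressure <- function(mask, sources, K_eff = 1, tol = 1e-8) {
  sys <- .assemble_darcy(mask, K_eff)
  f <- numeric(sys$n)
  if (nrow(sources)) {
    tot <- sum(sources$strength * sources$length)
    scale <- max(sum(abs(sources$strength) * sources$length), .Machine$double.xmin)
    if (abs(tot) > tol * scale)
      stop("incompatible sources: net inflow does not vanish")
    for (i in seq_len(nrow(sources))) {
      ld <- .line_load(mask, sys$loc_active,
        c(sources$x0[i], sources$y0[i], sources$z0[i]),
        c(sources$x1[i], sources$y1[i], sources$z1[i]),
        sources$strength[i])
      if (!is.null(ld)) {
        agg <- rowsum(ld$vals, ld$nodes)
        f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg[, 1]
      }
    }
  }
  act <- which(sys$active)
  na <- length(act)
  fa <- f[act]
  fa <- fa - mean(fa) # enforce discrete compatibility exactly
  # pure-Neumann nullspace: the compatible system is solved with one pinned
  # node (grounding the constant mode), then re-centered to zero mean
  Aa <- Matrix::forceSymmetric(sys$A[act, act, drop = FALSE])
  pa <- numeric(na)
  pa[-1] <- as.numeric(Matrix::solve(Aa[-1, -1, drop = FALSE], fa[-1]))
  p <- numeric(sys$n)
  p[act] <- pa - mean(pa)
  structure(list(p = p, mask = mask, K_eff = K_eff, active = sys$active),
    class = "pressure_field")
}

#' Darcy velocity field from a pressure field
#'
#' Face volumetric fluxes between adjacent foreground voxels are computed
#' from difference quotients, `F = -K_eff (p_j - p_i) / h * h^2` (mm^3/s);
#' faces between foreground and background carry zero flux, which enforces
#' the vanishing normal velocity at the organ boundary at the discrete
#' level. The per-voxel velocity `v = -(K_eff / phi_sin) grad p` (mm/s) is
#' the face-flux average over each voxel divided by the sinusoidal porosity.
#'
#' @param pressure a [solve_pressure()] result.
#' @param phi_sin sinusoidal porosity (volume fraction of the perfused
#'   blood subspaces), `> 0`.
#' @return object of class `velocity_field`: `faces` (list per axis with
#'   local foreground indices `from`, `to` and flux `F`), `v` (`n_fg x 3`,
#'   mm/s), `phi_sin`, `mask`, and `outflux` (per-voxel total volumetric
#'   outflow used for Courant bounds).
#' @export
velocity_from_pressure <- function(pressure, phi_sin) {
  if (phi_sin <= 0) stop("phi_sin must be positive")
  mask <- pressure$mask
  h <- mask$spacing
  d <- mask$dim
  loc <- array(0L, d)
  loc[mask$fg] <- seq_along(mask$fg)
  p <- pressure$p
  faces <- vector("list", 3)
  n <- length(mask$fg)
  outflux <- numeric(n)
  vsum <- matrix(0, n, 3)
  nfaces <- matrix(0L, n, 3)
  stride <- c(1L, d[1], d[1] * d[2])
  idx <- arrayInd(mask$fg, d)
  for (ax in 1:3) {
    havenb <- idx[, ax] < d[ax]
    from_glob <- mask$fg[havenb]
    to_glob <- from_glob + stride[ax]
    to_loc <- loc[to_glob]
    keep <- to_loc > 0L
    from <- loc[from_glob][keep]
    to <- to_loc[keep]
    Fv <- -pressure$K_eff * (p[to] - p[from]) / h * h^2
    if (!is.null(pressure$active)) {
      # no flux across faces of element-unsupported voxels
      Fv[!pressure$active[from] | !pressure$active[to]] <- 0
    }
    faces[[ax]] <- list(from = from, to = to, F = Fv)
    pos <- Fv > 0
    outflux[from[pos]] <- outflux[from[pos]] + Fv[pos]
    outflux[to[!pos]] <- outflux[to[!pos]] - Fv[!pos]
    add <- Fv / (h^2 * phi_sin) # face velocity (mm/s)
    vsum[from, ax] <- vsum[from, ax] + add
    vsum[to, ax] <- vsum[to, ax] + add
    nfaces[from, ax] <- nfaces[from, ax] + 1L
    nfaces[to, ax] <- nfaces[to, ax] + 1L
  }
  v <- vsum / pmax(nfaces, 1L)
  structure(list(faces = faces, v = v, phi_sin = phi_sin, mask = mask,
    outflux = outflux), class = "velocity_field")
}

#' Discrete divergence of the face fluxes per foreground voxel (mm^3/s)
#'
#' Positive where the field locally expands; nonzero only near the line
#' sources and sinks (and, mildly, from the finite-element/finite-volume
#' mismatch). Sums to zero over the domain because boundary faces carry no
#' flux.
#'
#' @param vel a [velocity_from_pressure()] result.
#' @export
velocity_divergence <- function(vel) {
  n <- nrow(vel$v)
  div <- numeric(n)
  for (ax in 1:3) {
    fc <- vel$faces[[ax]]
    div[fc$from] <- div[fc$from] - fc$F
    div[fc$to] <- div[fc$to] + fc$F
  }
  -div
}
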