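#' Per-voxel subspace concentrations and volume fractions
#'
#' Holds, for every foreground voxel, the molar concentrations (umol/L,
#' each relative to its own subspace volume) of the four compound-carrying
#' subspaces rbc, pls, int, cell, and the five volume fractions (including
#' `rest`, which carries no compound). Fractions must be nonnegative and sum
#' to one at every voxel within 1e-12. The sinusoidal (perfused) fraction is
#' `f_sin = f_rbc + f_pls`.
#'
#' @param mask an [organ_mask()].
#' @param fractions either a named numeric vector
#'   `c(rbc=, pls=, int=, cell=, rest=)` applied globally, or an
#'   `n_fg x 5` matrix for per-voxel fractions (after pathology edits).
#' @param conc optional `n_fg x 4` start concentrations (default zero).
#' @return object of class `subspace_field`.
#' @export
subspace_field <- function(mask, fractions, conc = NULL) {
  n <- length(mask$fg)
  subs <- c("rbc", "pls", "int", "cell")
  if (is.null(dim(fractions))) {
    fractions <- matrix(fractions[c(subs, "rest")], n, 5, byrow = TRUE,
      dimnames = list(NULL, c(subs, "rest")))
  }
  if (nrow(fractions) != n || ncol(fractions) != 5)
    stop("fractions must be length-5 or n_fg x 5")
  colnames(fractions) <- c(subs, "rest")
  if (any(fractions < 0)) stop("volume fractions must be nonnegative")
  if (any(abs(rowSums(fractions) - 1) > 1e-12))
    stop("volume fractions must sum to 1 at every voxel")
  if (is.null(conc)) conc <- matrix(0, n, 4, dimnames = list(NULL, subs))
  conc <- matrix(conc, n, 4, dimnames = list(NULL, subs))
  if (any(conc < 0)) stop("concentrations must be nonnegative")
  structure(list(mask = mask, conc = conc, frac = fractions),
    class = "subspace_field")
}

#' Per-subspace total amounts in the field (umol)
#' @param field a [subspace_field()].
#' @export
hhs_stored_mass <- function(field) {
  h3 <- field$mask$spacing^3
  colSums(field$conc * field$frac[, 1:4, drop = FALSE]) * h3 * L_PER_MM3
}

#' Per-voxel total tissue concentration
#'
#' The imaging-comparable observable: the volume-fraction-weighted average
#' `c_total = sum_i f_i c_i` over rbc, pls, int, cell (umol per L of total
#' tissue; the rest subspace carries no compound).
#'
#' @param field a [subspace_field()].
#' @return numeric vector, one value per foreground voxel.
#' @export
total_concentration <- function(field) {
  rowSums(field$conc * field$frac[, 1:4, drop = FALSE])
}

# normalized voxel weights of a rasterized centerline segment (foreground
# voxels only; points falling on background snap to the nearest foreground
# voxel among their 26-neighborhood, else to the globally nearest)
#' @keywords internal
.line_voxel_weights <- function(mask, x0, x1, step = mask$spacing / 4) {
  L <- sqrt(sum((x1 - x0)^2))
  nseg <- max(2L, ceiling(L / step))
  t <- (seq_len(nseg) - 0.5) / nseg
  pts <- cbind(x0[1] + t * (x1[1] - x0[1]), x0[2] + t * (x1[2] - x0[2]),
    x0[3] + t * (x1[3] - x0[3]))
  vox <- .point_to_voxel(mask, pts)
  loc <- match(vox, mask$fg)
  if (anyNA(loc)) {
    centers <- mask_voxel_centers(mask)
    for (i in which(is.na(loc))) {
      loc[i] <- which.min(rowSums(sweep(centers, 2, pts[i, ])^2))
    }
  }
  agg <- rowsum(rep(1 / nseg, nseg), loc)
  list(idx = as.integer(rownames(agg)), w = as.numeric(agg[, 1]))
}

#' Volume-weighted neighborhood average around a terminal edge
#'
#' Averages the sinusoidal-phase concentrations over the foreground voxels
#' whose centers lie within `radius` of the edge's centerline, weighting by
#' each voxel's phase volume. This is the value a draining terminal edge
#' drains from its vicinity.
#'
#' @param field a [subspace_field()].
#' @param tree the [vascular_tree()] owning the edge.
#' @param edge terminal edge index.
#' @param radius neighborhood radius (mm), default twice the grid spacing.
#' @return named numeric `c(rbc=, pls=)` (umol/L).
#' @export
neighborhood_average <- function(field, tree, edge,
                                 radius = 2 * field$mask$spacing) {
  if (radius <= 0) stop("radius must be positive")
  centers <- mask_voxel_centers(field$mask)
  a <- tree$nodes[tree$edges$parent[edge], ]
  b <- tree$nodes[tree$edges$child[edge], ]
  idx <- which(.point_segment_dist2(centers, a, b) <= radius^2)
  if (!length(idx))
    stop(sprintf("empty neighborhood around terminal edge %d", edge))
  .nb_avg(field, idx)
}

#' @keywords internal
.nb_avg <- function(field, idx) {
  w_rbc <- field$frac[idx, "rbc"]
  w_pls <- field$frac[idx, "pls"]
  c(
    rbc = sum(field$conc[idx, "rbc"] * w_rbc) / sum(w_rbc),
    pls = sum(field$conc[idx, "pls"] * w_pls) / sum(w_pls)
  )
}

#' Precompute the vascular-HHS coupling geometry
#'
#' For every supplying terminal edge: the rasterized centerline voxel
#' weights used to inject its outflow. For every draining terminal edge: the
#' neighborhood voxel set (for averaging) and the centerline weights (for
#' posting the matching sink).
#'
#' @param mask an [organ_mask()].
#' @param svs,dvs flow-assigned trees.
#' @param radius neighborhood radius (mm) for the draining average.
#' @return list with `src` (per SVS terminal: `idx`, `w`, `Q`) and `snk`
#'   (per DVS terminal: `idx`, `w`, `nb`, `Q`).
#' @export
hhs_coupling <- function(mask, svs, dvs, radius = 2 * mask$spacing) {
  centers <- mask_voxel_centers(mask)
  per_leaf <- function(tree, with_nb) {
    le <- tree_leaf_edges(tree)
    lapply(seq_along(le), function(k) {
      e <- le[k]
      a <- tree$nodes[tree$edges$parent[e], ]
      b <- tree$nodes[tree$edges$child[e], ]
      lw <- .line_voxel_weights(mask, a, b)
      out <- list(edge = e, idx = lw$idx, w = lw$w, Q = tree$edges$flow[e])
      if (with_nb) {
        nb <- which(.point_segment_dist2(centers, a, b) <= radius^2)
        if (!length(nb))
          stop(sprintf("empty neighborhood around draining terminal edge %d", e))
        out$nb <- nb
      }
      out
    })
  }
  list(src = per_leaf(svs, FALSE), snk = per_leaf(dvs, TRUE), radius = radius)
}

#' Advect the sinusoidal phases through the HHS for one macro step
#'
#' Conservative explicit upwind finite-volume transport of `c_rbc` and
#' `c_pls` on the Darcy face fluxes (`c_int`, `c_cell` are untouched), with
#' Courant-limited sub-stepping. Terminal-edge mass sources are injected
#' along their rasterized centerlines; draining sinks withdraw the
#' neighborhood-average concentration at each terminal's flow rate,
#' distributed along its centerline and capped at the locally available mass
#' (cap events are counted in the ledger). Because the normal velocity
#' vanishes at the organ boundary no explicit boundary handling is needed,
#' and the ledger closes exactly: mass change = injected - removed.
#'
#' @param field a [subspace_field()].
#' @param vel a [velocity_from_pressure()] result on the same mask.
#' @param dt macro step (s).
#' @param coupling a [hhs_coupling()] structure (or `NULL` for no
#'   source/sink terms).
#' @param src_mass matrix `n_src x 2` of masses (umol per phase) to inject
#'   over the step (typically the supplying tree's terminal outflow).
#' @param phase_weights blood volume split `c(rbc, pls)` between the phases
#'   (used to split each terminal's flow).
#' @return list: `field`, `injected` (`n_src x 2`, umol), `removed`
#'   (`n_snk x 2`, umol), `outflow_conc` (`n_snk x 2`, the flow-consistent
#'   draining inflow concentrations `removed / (Q_ph dt)`), `n_substeps`,
#'   `cap_events`.
#' @export
hhs_advect_step <- function(field, vel, dt, coupling = NULL, src_mass = NULL,
                            phase_weights = c(0.5, 0.5)) {
  if (dt <= 0) stop("dt must be positive")
  if (!identical(vel$mask$dim, field$mask$dim))
    stop("velocity field grid mismatch")
  h3 <- field$mask$spacing^3
  n <- nrow(field$conc)
  f_sin <- field$frac[, "rbc"] + field$frac[, "pls"]
  # transfer operator: (T c)_i = sum of upwind face fluxes (mm^3/s weighted)
  T <- .hhs_transfer_operator(vel, n)
  rate <- vel$outflux / (f_sin * h3)
  nsub <- max(1L, as.integer(ceiling(dt * max(rate) / 0.95)))
  dts <- dt / nsub
  vol_rbc <- field$frac[, "rbc"] * h3 * L_PER_MM3 # L per voxel, rbc space
  vol_pls <- field$frac[, "pls"] * h3 * L_PER_MM3
  crbc <- field$conc[, "rbc"]
  cpls <- field$conc[, "pls"]
  nsrc <- if (is.null(coupling)) 0L else length(coupling$src)
  nsnk <- if (is.null(coupling)) 0L else length(coupling$snk)
  injected <- matrix(0, max(nsrc, 1L), 2)
  removed <- matrix(0, max(nsnk, 1L), 2)
  cap_events <- 0L
  fs3 <- f_sin * h3
  for (s in seq_len(nsub)) {
    dc <- as.numeric(T %*% crbc) * (dts / fs3)
    crbc <- crbc + dc
    dc <- as.numeric(T %*% cpls) * (dts / fs3)
    cpls <- cpls + dc
    if (nsrc > 0 && !is.null(src_mass)) {
      for (k in seq_len(nsrc)) {
        sp <- coupling$src[[k]]
        add <- src_mass[k, ] / nsub
        crbc[sp$idx] <- crbc[sp$idx] + add[1] * sp$w / vol_rbc[sp$idx]
        cpls[sp$idx] <- cpls[sp$idx] + add[2] * sp$w / vol_pls[sp$idx]
        injected[k, ] <- injected[k, ] + add
      }
    }
    if (nsnk > 0) {
      for (k in seq_len(nsnk)) {
        sk <- coupling$snk[[k]]
        nb <- sk$nb
        wr <- field$frac[nb, "rbc"]
        wp <- field$frac[nb, "pls"]
        cav <- c(sum(crbc[nb] * wr) / sum(wr), sum(cpls[nb] * wp) / sum(wp))
        want <- sk$Q * phase_weights * cav * dts * L_PER_MM3 # umol
        for (ph in 1:2) {
          if (want[ph] <= 0) next
          idx <- sk$idx
          volx <- if (ph == 1) vol_rbc[idx] else vol_pls[idx]
          cx <- if (ph == 1) crbc[idx] else cpls[idx]
          take <- want[ph] * sk$w
          avail <- cx * volx
          over <- take > avail
          if (any(over)) {
            cap_events <- cap_events + 1L
            take <- pmin(take, avail)
          }
          if (ph == 1) crbc[idx] <- crbc[idx] - take / volx
          else cpls[idx] <- cpls[idx] - take / volx
          removed[k, ph] <- removed[k, ph] + sum(take)
        }
      }
    }
  }
  field$conc[, "rbc"] <- crbc
  field$conc[, "pls"] <- cpls
  outflow_conc <- if (nsnk > 0) {
    Q <- vapply(coupling$snk, `[[`, numeric(1), "Q")
    removed / (outer(Q, phase_weights) * dt * L_PER_MM3)
  } else NULL
  list(field = field, injected = injected[seq_len(max(nsrc, 0L)), , drop = FALSE],
    removed = removed[seq_len(max(nsnk, 0L)), , drop = FALSE],
    outflow_conc = outflow_conc, n_substeps = nsub, cap_events = cap_events)
}

#' @keywords internal
.hhs_transfer_operator <- function(vel, n) {
  if (!is.null(vel$.T) && nrow(vel$.T) == n) return(vel$.T)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (ax in 1:3) {
    fc <- vel$faces[[ax]]
    donor <- ifelse(fc$F > 0, fc$from, fc$to)
    recv <- ifelse(fc$F > 0, fc$to, fc$from)
    aF <- abs(fc$F)
    keep <- aF > 0
    ii <- c(ii, donor[keep], recv[keep])
    jj <- c(jj, donor[keep], donor[keep])
    xx <- c(xx, -aF[keep], aF[keep])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Attach the cached transfer operator to a velocity field
#'
#' Precomputes the sparse upwind transfer operator so repeated
#' [hhs_advect_step()] calls do not rebuild it.
#' @param vel a [velocity_from_pressure()] result.
#' @param n number of foreground voxels.
#' @export
cache_transfer_operator <- function(vel, n) {
  vel$.T <- .hhs_transfer_operator(vel, n)
  vel
}
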