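#' Steatosis lipid volume-ratio field
#'
#' Per-voxel lipid accumulation ratio `rho(x)` in `[0, 1)`. In
#' `heterogeneous` mode, i.i.d. uniform draws within the enclosing lobe's
#' `[lo, hi]` range are generated on a grid `coarsening` times coarser than
#' the computational resolution and interpolated multilinearly onto the
#' voxel grid (avoiding unphysiologically large local variation). In
#' `homogeneous` mode the field is the single constant equal to the
#' volume-weighted mean of the per-lobe range midpoints, so both modes share
#' the same liver-wide mean lipid content.
#'
#' @param mask an [organ_mask()] with lobe labels.
#' @param ranges named list: for each lobe label (as character) a numeric
#'   `c(lo, hi)` with `0 <= lo <= hi < 1`.
#' @param mode `"homogeneous"` or `"heterogeneous"`.
#' @param coarsening integer `>= 1`, coarse-grid factor (default 4).
#' @param seed RNG seed (Mersenne-Twister, recorded in attributes).
#' @return numeric vector `rho`, one value per foreground voxel, with
#'   attributes `mode` and `seed`.
#' @export
make_steatosis_field <- function(mask, ranges,
                                 mode = c("heterogeneous", "homogeneous"),
                                 coarsening = 4L, seed = 1L) {
  mode <- match.arg(mode)
  if (coarsening < 1L) stop("coarsening must be >= 1")
  labels <- sort(unique(mask$lobe[mask$occupancy]))
  for (lb in labels) {
    r <- ranges[[as.character(lb)]]
    if (is.null(r)) stop(sprintf("no steatosis range for lobe %d", lb))
    if (r[1] < 0 || r[2] < r[1] || r[2] >= 1)
      stop("each range must satisfy 0 <= lo <= hi < 1")
  }
  lobe_fg <- mask$lobe[mask$fg]
  if (mode == "homogeneous") {
    mids <- vapply(labels, function(lb) mean(ranges[[as.character(lb)]]),
      numeric(1))
    counts <- tabulate(match(lobe_fg, labels), length(labels))
    rho <- rep(sum(mids * counts) / sum(counts), length(mask$fg))
  } else {
    h <- mask$spacing
    H <- coarsening * h
    d <- mask$dim
    # i.i.d. uniform [0, 1] draws on a grid `coarsening` times coarser than
    # the voxel grid (coarse node g sits at physical (g - 1) * H), covering
    # every voxel center
    ncoarse <- as.integer(ceiling(d * h / H)) + 1L
    centers <- mask_voxel_centers(mask)
    draw <- .with_seed(seed, array(stats::runif(prod(ncoarse)), ncoarse))
    # multilinear interpolation of the noise at the voxel centers, then
    # mapping through the voxel's own lobe range: keeps every value inside
    # its lobe's [lo, hi] and each lobe's mean at the range midpoint, with
    # no blending bias across lobe boundaries
    pos <- centers / H
    i0 <- floor(pos) + 1L
    for (k in 1:3) i0[, k] <- pmin(pmax(i0[, k], 1L), ncoarse[k] - 1L)
    xi <- pos - (i0 - 1L)
    u <- numeric(length(mask$fg))
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      w <- (if (a) xi[, 1] else 1 - xi[, 1]) *
        (if (b) xi[, 2] else 1 - xi[, 2]) *
        (if (cc) xi[, 3] else 1 - xi[, 3])
      u <- u + w * draw[cbind(i0[, 1] + a, i0[, 2] + b, i0[, 3] + cc)]
    }
    lo <- vapply(labels, function(lb) ranges[[as.character(lb)]][1], numeric(1))
    hi <- vapply(labels, function(lb) ranges[[as.character(lb)]][2], numeric(1))
    li <- match(lobe_fg, labels)
    rho <- lo[li] + u * (hi[li] - lo[li])
  }
  attr(rho, "mode") <- mode
  attr(rho, "seed") <- as.integer(seed)
  rho
}

#' Steatotic cellular partition coefficient
#'
#' The lipid accumulation modifies the cellular partition coefficient by
#' volume-weighted mixing of the aqueous (healthy) and lipid affinities,
#' `K_cell(rho) = K_cell_healthy (1 - rho) + k_lip rho`: anchored at the
#' healthy value for `rho = 0`, linear in `rho`, and monotonically
#' increasing whenever the compound's lipid affinity exceeds its healthy
#' cellular affinity (`k_lip > K_cell_healthy`, the lipophilic case). The
#' functional form is a pluggable strategy: pass any `form(K_h, rho, k_lip)`.
#'
#' @param K_cell_healthy healthy cellular partition coefficient (`> 0`).
#' @param rho lipid volume ratio(s) in `[0, 1)`.
#' @param k_lip compound lipid affinity constant (`>= 0`).
#' @param form the mixing rule; default as above.
#' @return per-voxel `K_cell`, same length as `rho`.
#' @export
steatotic_kcell <- function(K_cell_healthy, rho, k_lip,
                            form = function(K_h, rho, k_lip) {
                              K_h * (1 - rho) + k_lip * rho
                            }) {
  if (any(rho < 0) || any(rho >= 1)) stop("rho must be in [0, 1)")
  if (k_lip < 0) stop("k_lip must be nonnegative")
  form(K_cell_healthy, rho, k_lip)
}

#' Pericentral necrosis mask
#'
#' Selects the fraction `gamma` of the foreground closest to the draining
#' terminal-edge centerlines (exact point-to-segment distances), emulating
#' pericentral hepatocyte death.
#'
#' @param mask an [organ_mask()].
#' @param dvs draining [vascular_tree()].
#' @param gamma target necrotic volume fraction in `[0, 1]`.
#' @return logical vector over foreground voxels (`TRUE` = necrotic), with
#'   attribute `distance` (mm to the nearest draining terminal centerline).
#' @export
necrosis_mask <- function(mask, dvs, gamma) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  centers <- mask_voxel_centers(mask)
  le <- tree_leaf_edges(dvs)
  d2 <- rep(Inf, nrow(centers))
  for (e in le) {
    d2 <- pmin(d2, .point_segment_dist2(centers,
      dvs$nodes[dvs$edges$parent[e], ], dvs$nodes[dvs$edges$child[e], ]))
  }
  d <- sqrt(d2)
  k <- round(gamma * length(d))
  nec <- rep(FALSE, length(d))
  if (k > 0) nec[order(d)[seq_len(k)]] <- TRUE
  attr(nec, "distance") <- d
  nec
}

#' Apply pericentral necrosis to a subspace field
#'
#' In necrotic voxels the cellular space is replaced by interstitial space
#' (`f_int <- f_int + f_cell`, `f_cell <- 0`) and metabolization is forced
#' to zero; the volume-fraction sum is preserved at every voxel. Perfusion
#' is unchanged (the sinusoidal fractions are untouched).
#'
#' @param field a [subspace_field()].
#' @param necrotic logical vector from [necrosis_mask()] (or a `gamma` plus
#'   `mask`/`dvs` via that function).
#' @return list: `field` (edited fractions), `met_scale` (per-voxel
#'   metabolization multiplier, 0 in necrotic voxels), `P_override` (zeroed
#'   int:cell permeability in necrotic voxels, to be passed to
#'   [exchange_rhs()] / [pbpk_step()] together with the compound's healthy
#'   `P`).
#' @export
apply_necrosis <- function(field, necrotic) {
  stopifnot(length(necrotic) == nrow(field$frac))
  fr <- field$frac
  fr[necrotic, "int"] <- fr[necrotic, "int"] + fr[necrotic, "cell"]
  fr[necrotic, "cell"] <- 0
  field$frac <- fr
  list(field = field, met_scale = as.numeric(!necrotic),
    necrotic = necrotic)
}
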