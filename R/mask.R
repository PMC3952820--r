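#' Voxelized organ domain
#'
#' An `organ_mask` holds a binary occupancy volume at isotropic spacing `h`
#' (mm), a per-voxel lobe label (0 on background, positive integers on
#' foreground) and the derived organ volume `V_liv = count(foreground) * h^3`.
#' Physical coordinates are cell-centered: voxel `(i, j, k)` (0-based) sits at
#' `x = (i + 0.5) * h`.
#'
#' @param occupancy logical 3D array, `TRUE` on foreground.
#' @param spacing isotropic voxel spacing in mm, `> 0`.
#' @param lobe integer 3D array of the same shape; nonzero exactly on
#'   foreground. Defaults to a single lobe labelled 1.
#' @return An object of class `organ_mask` with fields `spacing`, `dim`,
#'   `occupancy`, `lobe`, `volume` (mm^3) and `fg` (linear foreground indices).
#' @export
organ_mask <- function(occupancy, spacing, lobe = NULL) {
  stopifnot(is.array(occupancy), length(dim(occupancy)) == 3L)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number (mm)")
  occupancy <- array(as.logical(occupancy), dim = dim(occupancy))
  if (!any(occupancy)) stop("mask has no foreground voxel")
  if (is.null(lobe)) {
    lobe <- array(0L, dim = dim(occupancy))
    lobe[occupancy] <- 1L
  }
  lobe <- array(as.integer(lobe), dim = dim(occupancy))
  if (any(lobe[occupancy] == 0L) || any(lobe[!occupancy] != 0L))
    stop("lobe labels must be nonzero exactly on the foreground")
  fg <- which(occupancy)
  structure(
    list(
      spacing = spacing,
      dim = dim(occupancy),
      occupancy = occupancy,
      lobe = lobe,
      volume = length(fg) * spacing^3,
      fg = fg
    ),
    class = "organ_mask"
  )
}

#' @export
print.organ_mask <- function(x, ...) {
  cat(sprintf(
    "<organ_mask> %d x %d x %d @ %.3g mm, V_liv = %.4g mm^3, %d lobe(s)\n",
    x$dim[1], x$dim[2], x$dim[3], x$spacing, x$volume,
    length(unique(x$lobe[x$occupancy]))
  ))
  invisible(x)
}

#' Physical centers of the foreground voxels
#'
#' @param mask an [organ_mask()].
#' @return matrix `n_fg x 3` of cell-centered coordinates (mm).
#' @export
mask_voxel_centers <- function(mask) {
  idx <- arrayInd(mask$fg, mask$dim)
  (idx - 0.5) * mask$spacing
}

#' Map physical points to voxel linear indices
#'
#' Points outside the array bounds get index `NA`.
#' @keywords internal
.point_to_voxel <- function(mask, pts) {
  pts <- matrix(pts, ncol = 3)
  ijk <- floor(pts / mask$spacing) + 1L
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= mask$dim[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= mask$dim[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= mask$dim[3]
  out <- rep(NA_integer_, nrow(pts))
  if (any(ok)) {
    out[ok] <- as.integer((ijk[ok, 3] - 1L) * mask$dim[1] * mask$dim[2] +
      (ijk[ok, 2] - 1L) * mask$dim[1] + ijk[ok, 1])
  }
  out
}

#' Test whether points lie in (or within `tol_voxels` of) the foreground
#'
#' @param mask an [organ_mask()].
#' @param pts numeric matrix `n x 3` (mm) or a length-3 vector.
#' @param tol_voxels nonnegative integer; a point counts as inside if any
#'   voxel within a cube of that many voxels around it is foreground.
#' @return logical vector.
#' @export
mask_contains <- function(mask, pts, tol_voxels = 0L) {
  pts <- matrix(pts, ncol = 3)
  base <- floor(pts / mask$spacing) + 1L
  res <- rep(FALSE, nrow(pts))
  offs <- as.matrix(expand.grid(
    di = -tol_voxels:tol_voxels, dj = -tol_voxels:tol_voxels,
    dk = -tol_voxels:tol_voxels
  ))
  for (r in seq_len(nrow(offs))) {
    ijk <- sweep(base, 2, offs[r, ], "+")
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= mask$dim[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= mask$dim[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= mask$dim[3]
    if (!any(ok)) next
    lin <- (ijk[ok, 3] - 1L) * mask$dim[1] * mask$dim[2] +
      (ijk[ok, 2] - 1L) * mask$dim[1] + ijk[ok, 1]
    res[ok] <- res[ok] | mask$occupancy[lin]
  }
  res
}

#' Generate a synthetic two-lobe ellipsoidal organ mask
#'
#' Stands in for a CT-derived liver segmentation: an axis-aligned ellipsoid
#' rasterized at isotropic spacing, split into two lobes by an axis-aligned
#' plane. Deterministic for fixed inputs (the seed is reserved for future
#' stochastic surface perturbations and recorded only).
#'
#' @param half_axes numeric length-3, ellipsoid half axes (mm), all `> 0`.
#' @param spacing voxel spacing (mm), `> 0`.
#' @param lobe_split_plane list with `axis` (1, 2 or 3) and `offset` (mm,
#'   relative to the ellipsoid center); voxels with center coordinate below
#'   the offset get lobe 1, the rest lobe 2.
#' @param seed integer, recorded in the result attributes.
#' @param margin_voxels voxels of background padding around the ellipsoid.
#' @return an [organ_mask()].
#' @export
generate_synthetic_mask <- function(half_axes, spacing,
                                    lobe_split_plane = list(axis = 1, offset = 0),
                                    seed = 1L, margin_voxels = 1L) {
  stopifnot(length(half_axes) == 3L)
  if (any(half_axes <= 0) || spacing <= 0)
    stop("half_axes and spacing must be positive")
  if (spacing > max(half_axes))
    stop("degenerate ellipsoid: spacing exceeds every half axis")
  n <- ceiling(2 * half_axes / spacing) + 2L * margin_voxels
  ctr <- n / 2 * spacing # ellipsoid center (mm)
  xs <- (seq_len(n[1]) - 0.5) * spacing
  ys <- (seq_len(n[2]) - 0.5) * spacing
  zs <- (seq_len(n[3]) - 0.5) * spacing
  dx2 <- ((xs - ctr[1]) / half_axes[1])^2
  dy2 <- ((ys - ctr[2]) / half_axes[2])^2
  dz2 <- ((zs - ctr[3]) / half_axes[3])^2
  occ <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  if (!any(occ)) stop("degenerate ellipsoid smaller than one voxel")
  ax <- lobe_split_plane$axis
  coord <- switch(ax, xs, ys, zs) - ctr[ax]
  lobe <- array(0L, dim = n)
  below <- coord < lobe_split_plane$offset
  sel <- array(below[slice.index(occ, ax)], dim = n)
  lobe[occ & sel] <- 1L
  lobe[occ & !sel] <- 2L
  m <- organ_mask(occ, spacing, lobe)
  attr(m, "seed") <- as.integer(seed)
  attr(m, "half_axes") <- half_axes
  m
}

#' Read / write masks as NIfTI rasters
#'
#' Requires isotropic spacing on read (errors otherwise). Lobe labels are
#' stored as the voxel values (0 background).
#'
#' @param mask an [organ_mask()].
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `read_mask_nifti` returns an [organ_mask()];
#'   `write_mask_nifti` returns `path` invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  img <- RNifti::asNifti(array(as.numeric(mask$lobe), dim = mask$dim))
  RNifti::pixdim(img) <- rep(mask$spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)[1:3]
  if (diff(range(pd)) > 1e-6 * mean(pd))
    stop("mask raster must have isotropic spacing")
  lobe <- array(as.integer(round(as.array(img))), dim = dim(img)[1:3])
  organ_mask(lobe != 0L, spacing = pd[1], lobe = lobe)
}

#' Export a per-foreground-voxel field as a NIfTI raster
#'
#' Writes values (e.g. a pressure field, velocity magnitude, or a
#' `c_total` snapshot) into the mask geometry, background zero.
#'
#' @param mask the [organ_mask()] the field lives on.
#' @param values numeric vector, one value per foreground voxel.
#' @param path output path (`.nii` / `.nii.gz`).
#' @export
write_field_nifti <- function(mask, values, path) {
  stopifnot(length(values) == length(mask$fg))
  arr <- array(0, dim = mask$dim)
  arr[mask$fg] <- values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(mask$spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
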