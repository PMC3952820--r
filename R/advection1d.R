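#' Per-edge 1D concentration field on a vascular tree
#'
#' Each edge carries a 1D finite-volume sub-grid (at least two cells, spacing
#' at most `dx_target`) of molar concentrations (umol/L) for each advected
#' phase (red blood cells and plasma by default). Cells are ordered along the
#' flow direction: root-to-leaf on a supplying tree, leaf-to-root (distal to
#' proximal within every edge) on a draining tree. Both phases advect with
#' the identical per-edge mean velocity.
#'
#' @param tree a flow-assigned [vascular_tree()] (see [assign_flows()]).
#' @param dx_target target sub-grid spacing (mm); per edge the spacing is
#'   `L_e / max(2, ceiling(L_e / dx_target))`.
#' @param phase_weights fraction of the blood volume occupied by each phase
#'   (sums to 1); used only in the mass ledger.
#' @param phases phase names.
#' @return object of class `edge_concentration_field` with a `conc` matrix
#'   (`n_cells x n_phases`, initialized to zero) and a precomputed advection
#'   plan.
#' @export
edge_concentration_field <- function(tree, dx_target = 1,
                                     phase_weights = c(rbc = 0.5, pls = 0.5),
                                     phases = names(phase_weights)) {
  if (is.null(tree$edges$flow)) stop("tree must be flow-assigned first")
  e <- tree$edges
  ncell <- pmax(2L, as.integer(ceiling(e$length / dx_target)))
  dx <- e$length / ncell
  offset <- c(0L, cumsum(ncell))
  n_tot <- offset[length(offset)]
  edge_of_cell <- rep(seq_len(nrow(e)), ncell)
  pos_in_edge <- sequence(ncell)
  first_cell <- offset[seq_len(nrow(e))] + 1L
  last_cell <- offset[-1]
  left_idx <- seq_len(n_tot) - 1L
  left_idx[pos_in_edge == 1L] <- NA_integer_
  # upstream mixing matrix: inflow concentration of edge i is M[i, ] %*% c_last
  ne <- nrow(e)
  if (tree$kind == "supplying") {
    has_up <- which(tree$parent_edge > 0L)
    M <- Matrix::sparseMatrix(
      i = has_up, j = tree$parent_edge[has_up], x = 1, dims = c(ne, ne))
    bc_edges <- which(tree$parent_edge == 0L) # root edge
  } else {
    # draining: flow child -> parent; upstream of an edge are its child edges,
    # mixed with flow-weight Q_child / Q_edge (instant mixing at junctions)
    has_up <- which(tree$parent_edge > 0L)
    M <- Matrix::sparseMatrix(
      i = tree$parent_edge[has_up], j = has_up,
      x = e$flow[has_up] / pmax(e$flow[tree$parent_edge[has_up]], .Machine$double.xmin),
      dims = c(ne, ne))
    bc_edges <- which(tree$is_leaf)
  }
  structure(list(
    kind = tree$kind,
    conc = matrix(0, n_tot, length(phases), dimnames = list(NULL, phases)),
    phases = phases, phase_weights = as.numeric(phase_weights),
    ncell = ncell, dx = dx, edge_of_cell = edge_of_cell,
    first_cell = first_cell, last_cell = last_cell, left_idx = left_idx,
    area = e$area, flow = e$flow, velocity = e$velocity,
    leaf_edges = which(tree$is_leaf),
    root_edge = which(tree$parent_edge == 0L),
    M = M, bc_edges = bc_edges,
    cell_vol = e$area[edge_of_cell] * dx[edge_of_cell] # mm^3 per cell
  ), class = "edge_concentration_field")
}

#' Total stored mass per phase in a vascular field (umol)
#' @param field an [edge_concentration_field()].
#' @export
field_stored_mass <- function(field) {
  colSums(field$conc * field$cell_vol) * field$phase_weights * L_PER_MM3
}

#' Advect concentrations through a vascular tree for one macro step
#'
#' Conservative explicit upwind finite-volume transport with internal
#' sub-stepping at Courant number `<= 1` on every edge (the sub-step is the
#' largest integer fraction of `dt` satisfying the bound). At supplying
#' junctions the concentration passes unchanged to all children; at draining
#' junctions the inflow is the flow-weighted average of the child outflows
#' (instant mixing). Mass is conserved to rounding: the returned ledger
#' satisfies `inflow - outflow = stored_after - stored_before`.
#'
#' @param tree the flow-assigned [vascular_tree()] the field was built on.
#' @param field an [edge_concentration_field()].
#' @param dt macro time step (s), `> 0`.
#' @param inflow for a supplying tree: a function `t -> c(rbc, pls)` (umol/L)
#'   or a constant numeric vector of per-phase root inflow concentrations;
#'   for a draining tree: a `n_leaf x n_phases` matrix of per-terminal inflow
#'   concentrations (see [dvs_leaf_inflow()]), constant over the step.
#' @param t0 macro step start time (s), passed to an inflow function.
#' @return list with elements `field` (updated), `inflow_mass` (umol, per
#'   phase), `outflow_mass` (per external outflow edge and phase: terminal
#'   edges of a supplying tree, the root edge of a draining tree),
#'   `outflow_conc` (flow-weighted mean outflow concentration over the step,
#'   per phase; draining trees only), `stored_before`, `stored_after`.
#' @export
tree_advect_step <- function(tree, field, dt, inflow, t0 = 0) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  nph <- length(field$phases)
  v <- field$velocity
  dx <- field$dx
  vmax_rate <- max(v / dx)
  nsub <- max(1L, as.integer(ceiling(dt * vmax_rate - 1e-12)))
  dts <- dt / nsub
  nu_edge <- v * dts / dx
  nu <- nu_edge[field$edge_of_cell]
  supplying <- field$kind == "supplying"
  if (supplying) {
    infun <- if (is.function(inflow)) inflow else function(t) inflow
    out_edges <- field$leaf_edges
  } else {
    bc_mat <- matrix(inflow, ncol = nph)
    if (nrow(bc_mat) != length(field$bc_edges))
      stop("per-terminal inflow count mismatch with terminal edges")
    if (any(bc_mat < 0)) stop("inflow concentrations must be nonnegative")
    out_edges <- field$root_edge
  }
  w <- field$phase_weights
  Qph <- outer(field$flow, w) # per-edge per-phase flow (mm^3/s)
  conc <- field$conc
  stored_before <- field_stored_mass(field)
  inflow_mass <- numeric(nph)
  outflow_mass <- matrix(0, length(out_edges), nph,
    dimnames = list(NULL, field$phases))
  first <- field$first_cell
  eid <- seq_along(field$flow)
  interior <- which(!is.na(field$left_idx))
  li <- field$left_idx[interior]
  for (s in seq_len(nsub)) {
    c_last <- conc[field$last_cell, , drop = FALSE]
    cin_edge <- as.matrix(field$M %*% c_last)
    if (supplying) {
      bc <- matrix(infun(t0 + (s - 0.5) * dts), nrow = length(field$bc_edges),
        ncol = nph, byrow = TRUE)
    } else {
      bc <- bc_mat
    }
    cin_edge[field$bc_edges, ] <- bc
    cin <- conc
    cin[interior, ] <- conc[li, , drop = FALSE]
    cin[first, ] <- cin_edge[eid, , drop = FALSE]
    conc <- conc - nu * (conc - cin)
    # external mass bookkeeping (upwind fluxes, consistent with the update)
    inflow_mass <- inflow_mass +
      colSums(Qph[field$bc_edges, , drop = FALSE] * bc) * dts * L_PER_MM3
    outflow_mass <- outflow_mass +
      Qph[out_edges, , drop = FALSE] * c_last[out_edges, , drop = FALSE] *
        dts * L_PER_MM3
  }
  field$conc <- conc
  res <- list(
    field = field, inflow_mass = inflow_mass, outflow_mass = outflow_mass,
    stored_before = stored_before, stored_after = field_stored_mass(field),
    n_substeps = nsub
  )
  if (!supplying) {
    res$outflow_conc <- colSums(outflow_mass) /
      (field$flow[field$root_edge] * w * dt * L_PER_MM3)
  }
  res
}

#' Distribute supplying terminal outflow as line sources
#'
#' The cross-section of a terminal edge is taken to shrink linearly to zero,
#' so the mass it discharges leaves uniformly along its centerline. Given the
#' instantaneous state, the line density of a terminal edge is
#' `Q_e * c_out / L_e` per phase.
#'
#' @param tree a flow-assigned supplying [vascular_tree()].
#' @param field its [edge_concentration_field()].
#' @return matrix `n_terminal x n_phases` of line densities
#'   (umol / (s mm), using outflow concentrations at the current state).
#' @export
terminal_outflow_to_hhs <- function(tree, field) {
  if (field$kind != "supplying") stop("line sources require a supplying tree")
  leaves <- field$leaf_edges
  c_out <- field$conc[field$last_cell[leaves], , drop = FALSE]
  w <- field$phase_weights
  L <- tree$edges$length[leaves]
  sweep(c_out * (field$flow[leaves] * L_PER_MM3 / L), 2, w, "*")
}

#' Boundary condition for draining-tree advection
#'
#' Validates per-terminal averaged concentrations (one row per terminal
#' edge, one column per phase) and returns them in the shape
#' [tree_advect_step()] expects for a draining tree.
#'
#' @param tree a draining [vascular_tree()].
#' @param values numeric matrix `n_terminal x n_phases` (or a vector for one
#'   phase), all `>= 0`.
#' @export
dvs_leaf_inflow <- function(tree, values) {
  if (tree$kind != "draining") stop("leaf inflow applies to draining trees")
  values <- as.matrix(values)
  if (nrow(values) != sum(tree$is_leaf))
    stop("inflow value count mismatch with terminal edges")
  if (any(values < 0)) stop("inflow concentrations must be nonnegative")
  values
}
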