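#' Directed bifurcative vascular tree
#'
#' Nodes carry 3D positions (mm); edges connect a parent node to a child node
#' and carry a constant radius (mm). Derived per-edge quantities: length `L`
#' (mm), cross-section area `A = pi r^2` (mm^2) and, after [assign_flows()],
#' volumetric flow `Q` (mm^3/s) and mean velocity `v = Q/A` (mm/s). A
#' supplying tree transports from the root towards the leaves; a draining
#' tree from the leaves towards the root (geometry is stored identically,
#' rooted at the trunk).
#'
#' @param kind `"supplying"` or `"draining"`.
#' @param nodes numeric matrix `n x 3` of positions (mm).
#' @param edges data.frame with integer columns `parent`, `child` (node ids)
#'   and numeric `radius` (mm).
#' @return object of class `vascular_tree`.
#' @export
vascular_tree <- function(kind, nodes, edges) {
  kind <- match.arg(kind, c("supplying", "draining"))
  nodes <- matrix(as.numeric(nodes), ncol = 3)
  edges <- data.frame(
    parent = as.integer(edges$parent), child = as.integer(edges$child),
    radius = as.numeric(edges$radius)
  )
  if (any(edges$radius <= 0)) stop("all edge radii must be positive")
  n <- nrow(nodes)
  if (any(edges$parent < 1 | edges$parent > n | edges$child < 1 | edges$child > n))
    stop("edge endpoints out of range")
  indeg <- tabulate(edges$child, n)
  if (any(indeg > 1)) stop("tree is not acyclic/single-parent")
  roots <- setdiff(unique(edges$parent), edges$child)
  used <- sort(unique(c(edges$parent, edges$child)))
  if (length(used) != n) stop("tree has unused nodes")
  if (length(roots) != 1L) stop("tree must have a single root node")
  tr <- structure(
    list(kind = kind, nodes = nodes, edges = edges, root_node = roots),
    class = "vascular_tree"
  )
  tr <- .tree_derive(tr)
  if (any(tr$edges$length <= 0)) stop("all edge lengths must be positive")
  if (nrow(edges) + 1L != n) stop("tree is not connected")
  tr
}

# lengths, areas, topological edge order (root -> leaves), leaf set
#' @keywords internal
.tree_derive <- function(tr) {
  e <- tr$edges
  d <- tr$nodes[e$child, , drop = FALSE] - tr$nodes[e$parent, , drop = FALSE]
  e$length <- sqrt(rowSums(d^2))
  e$area <- pi * e$radius^2
  tr$edges <- e
  # parent edge of each edge: the edge whose child is this edge's parent node
  edge_at_child <- integer(nrow(tr$nodes))
  edge_at_child[e$child] <- seq_len(nrow(e))
  tr$parent_edge <- ifelse(e$parent == tr$root_node, 0L, edge_at_child[e$parent])
  # topological order by walking from the root
  kids <- split(seq_len(nrow(e)), e$parent)
  ord <- integer(nrow(e))
  queue <- kids[[as.character(tr$root_node)]]
  k <- 0L
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    k <- k + 1L
    ord[k] <- cur
    nxt <- kids[[as.character(e$child[cur])]]
    if (!is.null(nxt)) queue <- c(queue, nxt)
  }
  if (k != nrow(e)) stop("tree is not connected")
  tr$topo <- ord
  tr$is_leaf <- !(e$child %in% e$parent)
  tr
}

#' @export
print.vascular_tree <- function(x, ...) {
  cat(sprintf(
    "<vascular_tree> %s: %d nodes, %d edges, %d leaves%s\n",
    x$kind, nrow(x$nodes), nrow(x$edges), sum(x$is_leaf),
    if (!is.null(x$edges$flow)) sprintf(", Q_root = %.4g mm^3/s",
      x$edges$flow[x$topo[1]]) else ""
  ))
  invisible(x)
}

#' Leaf (terminal) edge indices
#' @param tree a [vascular_tree()].
#' @export
tree_leaf_edges <- function(tree) which(tree$is_leaf)

#' Total intravascular volume `sum(pi r^2 L)` in mm^3
#' @param tree a [vascular_tree()].
#' @export
tree_volume <- function(tree) sum(tree$edges$area * tree$edges$length)

#' Assign flows by the equal-leaf-outflow rule
#'
#' Every terminal edge carries `Q_liv / N_leaves`; interior flows follow by
#' summation towards the root, so flow conservation at every junction is
#' exact by construction. Mean velocities are `v = Q / A`.
#'
#' @param tree a [vascular_tree()].
#' @param Q_liv total perfusion (mm^3/s), `> 0` (0 allowed for zeroing).
#' @return the tree with `flow` and `velocity` edge columns.
#' @export
assign_flows <- function(tree, Q_liv) {
  if (Q_liv < 0) stop("Q_liv must be nonnegative")
  if (any(tree$edges$radius <= 0)) stop("zero-radius edge")
  e <- tree$edges
  nl <- sum(tree$is_leaf)
  q <- numeric(nrow(e))
  q[tree$is_leaf] <- Q_liv / nl
  # accumulate child flows onto parents in reverse topological order
  for (i in rev(tree$topo)) {
    p <- tree$parent_edge[i]
    if (p > 0L) q[p] <- q[p] + q[i]
  }
  e$flow <- q
  e$velocity <- q / e$area
  tree$edges <- e
  tree
}

#' Murray-law radius assignment from a fixed terminal radius
#'
#' Each terminal edge gets radius `r_leaf`; at every junction the parent
#' radius satisfies `r_p^gamma = sum(r_child^gamma)` (Murray's power law,
#' default cube law `gamma = 3`). This is the radius rule used by the
#' constructive optimization; effective viscosity enters the hydraulic
#' resistance diagnostics (see [tree_resistance()]), not the radius
#' recursion.
#'
#' @param tree a [vascular_tree()].
#' @param r_leaf terminal radius (mm).
#' @param gamma Murray exponent.
#' @export
murray_radii <- function(tree, r_leaf, gamma = 3) {
  rg <- numeric(nrow(tree$edges))
  rg[tree$is_leaf] <- r_leaf^gamma
  for (i in rev(tree$topo)) {
    p <- tree$parent_edge[i]
    if (p > 0L) rg[p] <- rg[p] + rg[i]
  }
  tree$edges$radius <- rg^(1 / gamma)
  .tree_derive(tree)
}

#' Poiseuille resistance of every edge with radius-dependent viscosity
#'
#' `R_e = 8 mu_rel(r) L / (pi r^4)` in relative units (the constant plasma
#' viscosity scale drops out of all comparisons).
#'
#' @param tree a [vascular_tree()].
#' @param model a [viscosity_model()].
#' @export
tree_resistance <- function(tree, model = viscosity_model()) {
  e <- tree$edges
  8 * effective_viscosity(e$radius, model) * e$length / (pi * e$radius^4)
}

#' Prune short terminal edges and contract short interior edges
#'
#' Terminal edges shorter than `min_length` are removed; interior edges
#' shorter than `min_length` are contracted (their child node is merged into
#' the parent node, possibly creating multifurcations). Applied repeatedly
#' until no short edge remains; flows are re-assigned by the equal-leaf rule
#' afterwards if they were present.
#'
#' @param tree a [vascular_tree()].
#' @param min_length minimum edge length (mm), `>= 0`.
#' @export
prune_and_contract <- function(tree, min_length) {
  if (min_length < 0) stop("min_length must be nonnegative")
  had_flow <- !is.null(tree$edges$flow)
  Q <- if (had_flow) sum(tree$edges$flow[tree$is_leaf]) else NULL
  repeat {
    root_edge <- which(tree$parent_edge == 0L)
    short <- which(tree$edges$length < min_length)
    if (any(short == root_edge) && tree$is_leaf[root_edge])
      stop("pruning would remove the root edge")
    short <- setdiff(short, root_edge) # the trunk is never contracted
    if (!length(short)) break
    i <- short[1]
    e <- tree$edges
    if (tree$is_leaf[i]) {
      drop_node <- e$child[i]
      e <- e[-i, , drop = FALSE]
    } else {
      # contract: merge child node into parent node
      drop_node <- e$child[i]
      keep_node <- e$parent[i]
      e <- e[-i, , drop = FALSE]
      e$parent[e$parent == drop_node] <- keep_node
    }
    # compact node ids
    remap <- cumsum(seq_len(nrow(tree$nodes)) != drop_node) # old -> new
    remap[drop_node] <- NA_integer_
    nodes <- tree$nodes[-drop_node, , drop = FALSE]
    e$parent <- remap[e$parent]
    e$child <- remap[e$child]
    tree <- vascular_tree(tree$kind, nodes,
      data.frame(parent = e$parent, child = e$child, radius = e$radius))
  }
  if (had_flow) tree <- assign_flows(tree, Q)
  tree
}

#' Perfectly symmetric dyadic test tree
#'
#' A binary tree of the given depth with equal edge lengths, laid out along
#' `+x` with alternating `y`/`z` spread, radii by Murray's law from `r_leaf`.
#' Closed-form root-to-leaf path length `(depth + 1) * edge_length` makes
#' analytic transit times available for advection tests.
#'
#' @param depth bifurcation generations (`0` = a single edge).
#' @param edge_length per-edge length (mm).
#' @param r_leaf terminal radius (mm).
#' @param gamma Murray exponent.
#' @param kind `"supplying"` or `"draining"`.
#' @param origin root node position (mm).
#' @export
dyadic_test_tree <- function(depth, edge_length = 2, r_leaf = 0.1, gamma = 3,
                             kind = "supplying", origin = c(0, 0, 0)) {
  stopifnot(depth >= 0)
  nodes <- matrix(origin, ncol = 3)
  edges <- data.frame(parent = integer(), child = integer(), radius = numeric())
  # breadth-first construction; x advances each generation, lateral spread decays
  frontier <- data.frame(node = 1L, y = origin[2], z = origin[3])
  # root edge
  nodes <- rbind(nodes, c(origin[1] + edge_length, origin[2], origin[3]))
  edges <- rbind(edges, data.frame(parent = 1L, child = 2L, radius = 1))
  frontier <- data.frame(node = 2L, y = origin[2], z = origin[3])
  x <- origin[1] + edge_length
  spread <- 0.6 * edge_length # < edge_length so every edge has length edge_length
  for (g in seq_len(depth)) {
    nf <- nrow(frontier)
    newf <- frontier[0, ]
    lateral <- if (g %% 2 == 1) "y" else "z"
    for (r in seq_len(nf)) {
      for (s in c(-1, 1)) {
        y <- frontier$y[r] + if (lateral == "y") s * spread else 0
        z <- frontier$z[r] + if (lateral == "z") s * spread else 0
        dx <- sqrt(max(edge_length^2 - spread^2, (0.25 * edge_length)^2))
        nodes <- rbind(nodes, c(x + dx, y, z))
        id <- nrow(nodes)
        edges <- rbind(edges, data.frame(
          parent = frontier$node[r], child = id, radius = 1))
        newf <- rbind(newf, data.frame(node = id, y = y, z = z))
      }
    }
    frontier <- newf
    x <- x + sqrt(max(edge_length^2 - spread^2, (0.25 * edge_length)^2))
    spread <- spread / 2
  }
  tr <- vascular_tree(kind, nodes, edges)
  murray_radii(tr, r_leaf, gamma)
}

#' Serialize / deserialize a tree as JSON
#'
#' The document holds `kind`, node positions and edges
#' (`parent`, `child`, `radius`); derived quantities are recomputed on read.
#'
#' @param tree a [vascular_tree()].
#' @param path file path.
#' @export
write_tree_json <- function(tree, path) {
  doc <- list(
    kind = tree$kind,
    nodes = unname(apply(tree$nodes, 1, function(r) as.list(r), simplify = FALSE)),
    edges = lapply(seq_len(nrow(tree$edges)), function(i) list(
      parent = tree$edges$parent[i], child = tree$edges$child[i],
      radius = tree$edges$radius[i]
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  doc <- jsonlite::read_json(path)
  nodes <- do.call(rbind, lapply(doc$nodes, function(p) unlist(p)))
  edges <- do.call(rbind, lapply(doc$edges, function(e) {
    data.frame(parent = e$parent, child = e$child, radius = e$radius)
  }))
  vascular_tree(doc$kind, nodes, edges)
}

#' Export tree centerlines as legacy-ASCII VTK polydata
#'
#' One polyline per edge with a per-cell `radius` array, for inspection in
#' standard viewers.
#'
#' @param tree a [vascular_tree()].
#' @param path output `.vtk` path.
#' @export
write_tree_vtk <- function(tree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0", "vascular tree centerlines", "ASCII",
    "DATASET POLYDATA", sprintf("POINTS %d float", nrow(tree$nodes))
  ), con)
  write(t(tree$nodes), con, ncolumns = 3)
  ne <- nrow(tree$edges)
  writeLines(sprintf("LINES %d %d", ne, 3 * ne), con)
  write(t(cbind(2L, tree$edges$parent - 1L, tree$edges$child - 1L)), con,
    ncolumns = 3)
  writeLines(c(sprintf("CELL_DATA %d", ne), "SCALARS radius float 1",
    "LOOKUP_TABLE default"), con)
  write(tree$edges$radius, con, ncolumns = 1)
  invisible(path)
}

# squared distance from points (m x 3) to a segment [a, b]
#' @keywords internal
.point_segment_dist2 <- function(pts, a, b) {
  pts <- matrix(pts, ncol = 3)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(rowSums(sweep(pts, 2, a)^2))
  t <- pmin(1, pmax(0, (sweep(pts, 2, a) %*% ab) / len2))
  proj <- matrix(a, nrow(pts), 3, byrow = TRUE) + outer(as.numeric(t), ab)
  rowSums((pts - proj)^2)
}
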