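# shared fixtures (built once per session; standard_fixture caches internally)

box_mask <- function(n = 12L, spacing = 1) {
  organ_mask(array(TRUE, dim = c(n, n, n)), spacing)
}

single_tube <- function(L = 10, v = 2, Q = 2) {
  # radius chosen so that v = Q / (pi r^2)
  r <- sqrt(Q / (pi * v))
  tr <- vascular_tree("supplying", rbind(c(0.5, 0.5, 0.5), c(0.5 + L, 0.5, 0.5)),
    data.frame(parent = 1L, child = 2L, radius = r))
  assign_flows(tr, Q)
}

# random binary tree with random edge lengths and radii, for property tests
random_tree <- function(n_leaves, kind = "supplying", seed = 1) {
  set.seed(seed)
  nodes <- matrix(c(0, 0, 0), 1, 3)
  edges <- data.frame(parent = integer(), child = integer(), radius = numeric())
  nodes <- rbind(nodes, c(runif(1, 1, 3), 0, 0))
  edges <- rbind(edges, data.frame(parent = 1L, child = 2L, radius = runif(1, 0.25, 0.5)))
  leaves <- 2L
  while (length(leaves) < n_leaves) {
    split <- leaves[sample.int(length(leaves), 1L)]
    for (s in c(-1, 1)) {
      pos <- nodes[split, ] + c(runif(1, 0.5, 2), s * runif(1, 0.3, 1.5),
        runif(1, -1, 1))
      nodes <- rbind(nodes, pos)
      edges <- rbind(edges, data.frame(parent = split, child = nrow(nodes),
        radius = runif(1, 0.15, 0.4)))
    }
    leaves <- c(setdiff(leaves, split), nrow(nodes) - 1L, nrow(nodes))
  }
  assign_flows(vascular_tree(kind, nodes, edges), runif(1, 2, 10))
}

# small geometry for fast end-to-end runs (coarser grid, fewer leaves)
small_geometry <- function(seed = 7L) {
  key <- sprintf("small_geom_%d", seed)
  cache <- hepatoflow:::.fixture_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  mask <- generate_synthetic_mask(c(6, 4.5, 3), 0.75,
    lobe_split_plane = list(axis = 1, offset = -2), seed = seed)
  ctr <- mask$dim / 2 * 0.75
  mk <- function(kind, sgn) {
    tr <- vascular_tree(kind,
      rbind(c(ctr[1] + sgn * 4.8, ctr[2], ctr[3]),
        c(ctr[1] + sgn * 3.2, ctr[2], ctr[3])),
      data.frame(parent = 1L, child = 2L, radius = 0.4))
    cco_extend(tr, mask, 16L, seed = seed + (sgn > 0), r_leaf = 0.15)
  }
  svs <- assign_flows(mk("supplying", -1), 30)
  dvs <- assign_flows(mk("draining", +1), 30)
  g <- list(mask = mask, svs = svs, dvs = dvs)
  cache[[key]] <- g
  g
}

small_config <- function(compound = "tracer", duration = 40, ...) {
  g <- small_geometry()
  args <- list(Q_liv = 30, dt = 0.5, duration = duration, c_in = 50,
    injection_duration_s = 10, spacing = 0.75, n_leaves = 16L,
    compound = compound, geometry = g)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

# session-cached simulation runs keyed by label
run_cache <- local({
  env <- new.env(parent = emptyenv())
  function(key, expr) {
    if (is.null(env[[key]])) env[[key]] <- force(expr)
    env[[key]]
  }
})
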