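test_that("synthetic ellipsoid mask matches the analytic volume and is deterministic", {
  m <- generate_synthetic_mask(c(8, 6, 4), 0.5, list(axis = 1, offset = -2.5))
  expect_s3_class(m, "organ_mask")
  V_analytic <- 4 / 3 * pi * 8 * 6 * 4
  expect_lt(abs(m$volume - V_analytic) / V_analytic, 0.05)
  expect_equal(m$volume, length(m$fg) * 0.5^3)
  # lobe labels nonzero exactly on foreground, two lobes
  expect_true(all(m$lobe[m$occupancy] > 0))
  expect_true(all(m$lobe[!m$occupancy] == 0))
  expect_setequal(unique(m$lobe[m$occupancy]), c(1L, 2L))
  m2 <- generate_synthetic_mask(c(8, 6, 4), 0.5, list(axis = 1, offset = -2.5))
  expect_identical(m$occupancy, m2$occupancy)
  expect_identical(m$lobe, m2$lobe)
})

test_that("degenerate mask inputs error", {
  expect_error(generate_synthetic_mask(c(1, 1, 1), 2), "degenerate")
  expect_error(generate_synthetic_mask(c(0, 1, 1), 0.5), "positive")
  expect_error(organ_mask(array(FALSE, c(2, 2, 2)), 1), "foreground")
})

test_that("mask NIfTI round trip preserves occupancy, lobes and spacing", {
  m <- generate_synthetic_mask(c(3, 2, 2), 0.5, list(axis = 2, offset = 0))
  path <- tempfile(fileext = ".nii.gz")
  write_mask_nifti(m, path)
  m2 <- read_mask_nifti(path)
  expect_identical(m2$occupancy, m$occupancy)
  expect_identical(m2$lobe, m$lobe)
  expect_equal(m2$spacing, m$spacing)
})

test_that("per-voxel fields export as rasters and anisotropic input errors", {
  m <- generate_synthetic_mask(c(3, 2, 2), 0.5, list(axis = 2, offset = 0))
  vals <- seq_along(m$fg) / length(m$fg)
  path <- tempfile(fileext = ".nii.gz")
  write_field_nifti(m, vals, path)
  back <- RNifti::readNifti(path)
  expect_equal(as.array(back)[m$fg], vals, tolerance = 1e-6)
  # anisotropic rasters are rejected on read
  img <- RNifti::asNifti(array(1, c(4, 4, 4)))
  RNifti::pixdim(img) <- c(0.5, 0.5, 1)
  p2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, p2)
  expect_error(read_mask_nifti(p2), "isotropic")
})

test_that("effective viscosity follows the chosen in-vitro law", {
  # large-vessel asymptote of the law at H = 0.45 is 3.2
  expect_lt(abs(effective_viscosity(2) - 3.2) / 3.2, 0.01)
  # monotone decrease towards capillary radii
  expect_lt(effective_viscosity(0.010), effective_viscosity(0.500))
  rr <- c(0.01, 0.02, 0.05, 0.1, 0.3, 0.5)
  expect_true(all(diff(effective_viscosity(rr)) > 0))
  expect_error(effective_viscosity(0), "positive")
  expect_error(effective_viscosity(-1), "positive")
  # hematocrit dependence: thinner blood, lower viscosity
  expect_lt(effective_viscosity(1, viscosity_model(0.2)),
    effective_viscosity(1, viscosity_model(0.45)))
})

test_that("equal-leaf flow assignment conserves flow and scales linearly", {
  tr <- dyadic_test_tree(3)
  tr <- assign_flows(tr, 8)
  leaves <- tree_leaf_edges(tr)
  expect_equal(tr$edges$flow[leaves], rep(1, 8))
  root <- tr$topo[1]
  expect_equal(tr$edges$flow[root], 8)
  # junction conservation exact on every interior edge
  for (i in seq_len(nrow(tr$edges))) {
    kids <- which(tr$parent_edge == i)
    if (length(kids)) {
      expect_identical(sum(tr$edges$flow[kids]), tr$edges$flow[i])
    }
  }
  tr2 <- assign_flows(tr, 16)
  expect_equal(tr2$edges$velocity, 2 * tr$edges$velocity)
})

test_that("prune_and_contract removes short edges and preserves conservation", {
  tr <- dyadic_test_tree(2, edge_length = 2)
  tr <- assign_flows(tr, 4)
  expect_identical(prune_and_contract(tr, 0)$edges, tr$edges)
  # shrink one terminal edge below threshold
  le <- tree_leaf_edges(tr)[1]
  child <- tr$edges$child[le]
  parent <- tr$edges$parent[le]
  nodes <- tr$nodes
  nodes[child, ] <- nodes[parent, ] + 0.1 * (nodes[child, ] - nodes[parent, ]) /
    sqrt(sum((nodes[child, ] - nodes[parent, ])^2))
  tr2 <- assign_flows(vascular_tree("supplying", nodes,
    tr$edges[, c("parent", "child", "radius")]), 4)
  pruned <- prune_and_contract(tr2, 0.2)
  expect_equal(sum(pruned$is_leaf), 3)
  expect_equal(unique(pruned$edges$flow[tree_leaf_edges(pruned)]), 4 / 3)
  expect_true(all(pruned$edges$length >= 0.2))
  # interior contraction creates a multifurcation but conserves flow
  tr3 <- dyadic_test_tree(2, edge_length = 2)
  nodes <- tr3$nodes
  # shrink a first-generation interior edge (child of the trunk junction)
  e1 <- tr3$topo[1]
  ik <- which(tr3$parent_edge == e1)[1] # interior edge below the trunk
  nodes[tr3$edges$child[ik], ] <- nodes[tr3$edges$parent[ik], ] + c(0.05, 0.05, 0)
  tr3 <- assign_flows(vascular_tree("supplying", nodes,
    tr3$edges[, c("parent", "child", "radius")]), 4)
  con <- prune_and_contract(tr3, 0.2)
  expect_equal(sum(con$is_leaf), 4)
  expect_equal(con$edges$flow[con$topo[1]], 4)
  # a trifurcation now exists at the trunk junction
  expect_equal(max(table(con$edges$parent)), 3)
  expect_true(all(con$edges$length >= 0.2))
  # the protected trunk may stay short, but never disappears
  expect_equal(sum(con$parent_edge == 0L), 1)
})

test_that("pruning cannot remove the root edge", {
  tr <- assign_flows(single_tube(L = 0.1), 1)
  expect_error(prune_and_contract(tr, 0.5), "root")
})

test_that("dyadic test tree has closed-form depth properties", {
  expect_equal(nrow(dyadic_test_tree(0)$edges), 1)
  t3 <- dyadic_test_tree(3, edge_length = 2)
  expect_equal(sum(t3$is_leaf), 8)
  # Murray radii: parent^3 = sum child^3 at each junction
  for (i in seq_len(nrow(t3$edges))) {
    kids <- which(t3$parent_edge == i)
    if (length(kids)) {
      expect_equal(t3$edges$radius[i]^3, sum(t3$edges$radius[kids]^3),
        tolerance = 1e-12)
    }
  }
})

test_that("tree JSON round trip preserves the tree", {
  tr <- dyadic_test_tree(2)
  path <- tempfile(fileext = ".json")
  write_tree_json(tr, path)
  tr2 <- read_tree_json(path)
  expect_equal(tr2$nodes, tr$nodes)
  expect_equal(tr2$edges$radius, tr$edges$radius)
  expect_identical(tr2$kind, tr$kind)
})

test_that("VTK export writes valid polydata headers", {
  tr <- dyadic_test_tree(1)
  path <- tempfile(fileext = ".vtk")
  write_tree_vtk(tr, path)
  lines <- readLines(path)
  expect_match(lines[1], "vtk DataFile")
  expect_match(lines[4], "POLYDATA")
  expect_match(lines[5], sprintf("POINTS %d", nrow(tr$nodes)))
})
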