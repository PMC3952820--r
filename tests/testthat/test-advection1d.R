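test_that("advection of a spatially uniform field with matching inflow is exact", {
  tr <- assign_flows(dyadic_test_tree(2), 4)
  f <- edge_concentration_field(tr, dx_target = 0.5)
  f$conc[] <- 7
  st <- tree_advect_step(tr, f, 1, function(t) c(7, 7))
  expect_equal(st$field$conc, f$conc)
  # many steps, still unchanged
  for (k in 1:5) st <- tree_advect_step(tr, st$field, 1, function(t) c(7, 7))
  expect_equal(st$field$conc, f$conc)
})

test_that("plug front transits a single tube in L/v up to one sub-grid cell", {
  tr <- single_tube(L = 10, v = 2, Q = 2) # transit 5 s
  dx <- 0.25
  f <- edge_concentration_field(tr, dx_target = dx)
  dt <- 0.05
  tt <- 0
  crossing <- NA
  for (k in 1:240) {
    st <- tree_advect_step(tr, f, dt,
      function(t) if (t < 2) c(10, 10) else c(0, 0), t0 = tt)
    f <- st$field
    tt <- tt + dt
    c_out <- sum(st$outflow_mass) / (2 * dt * 1e-6) # mean outflow conc
    if (is.na(crossing) && c_out >= 5) crossing <- tt
  }
  cell_transit <- dx / 2
  expect_lt(abs(crossing - 5), 5 * cell_transit + dt)
})

test_that("draining junction mixes with exact flow weights", {
  # two children with flows 3 and 1 feeding one parent edge
  nodes <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 1, 0), c(4, -1, 0))
  edges <- data.frame(parent = c(1L, 2L, 2L), child = c(2L, 3L, 4L),
    radius = c(0.4, 0.35, 0.2))
  tr <- vascular_tree("draining", nodes, edges)
  # overwrite equal-split: set leaf flows 3:1 manually
  tr$edges$flow <- c(4, 3, 1)
  tr$edges$velocity <- tr$edges$flow / tr$edges$area
  f <- edge_concentration_field(tr, dx_target = 0.5)
  bc <- dvs_leaf_inflow(tr, matrix(c(4, 0, 4, 0), 2, 2)) # c=4 and c=0
  st <- tree_advect_step(tr, f, 20, bc) # settle to steady state
  st <- tree_advect_step(tr, st$field, 1, bc) # measure at steady state
  # steady state: root outflow = (3*4 + 1*0)/4 = 3
  expect_equal(unname(st$outflow_conc), c(3, 3), tolerance = 1e-6)
})

test_that("per-step mass ledger closes on random trees (property)", {
  worst <- 0
  for (s in 1:100) {
    kind <- if (s %% 2) "supplying" else "draining"
    tr <- random_tree(n_leaves = 3 + s %% 6, kind = kind, seed = s)
    f <- edge_concentration_field(tr, dx_target = 0.7)
    set.seed(s)
    f$conc[] <- runif(length(f$conc), 0, 5)
    inflow <- if (kind == "supplying") {
      cc <- runif(2, 0, 3)
      function(t) cc
    } else {
      matrix(runif(2 * sum(tr$is_leaf), 0, 3), ncol = 2)
    }
    st <- tree_advect_step(tr, f, 0.05, inflow)
    resid <- sum(st$inflow_mass) - sum(st$outflow_mass) -
      (sum(st$stored_after) - sum(st$stored_before))
    scale <- max(sum(st$inflow_mass), sum(st$stored_before), 1e-30)
    worst <- max(worst, abs(resid) / scale)
    expect_true(all(st$field$conc >= 0))
  }
  expect_lt(worst, 1e-10)
})

test_that("rbc and plasma stay proportional under proportional forcing", {
  tr <- assign_flows(dyadic_test_tree(2), 6)
  f <- edge_concentration_field(tr, dx_target = 0.5)
  f$conc[, 1] <- seq_len(nrow(f$conc)) %% 5
  f$conc[, 2] <- 2 * f$conc[, 1]
  for (k in 1:10) {
    st <- tree_advect_step(tr, f, 0.4, function(t) c(3, 6), t0 = (k - 1) * 0.4)
    f <- st$field
  }
  expect_equal(f$conc[, 2], 2 * f$conc[, 1], tolerance = 1e-12)
})

test_that("numerical front spreading shrinks with sub-grid refinement", {
  widths <- vapply(c(1, 0.5, 0.25), function(dx) {
    tr <- single_tube(L = 10, v = 2, Q = 2)
    f <- edge_concentration_field(tr, dx_target = dx)
    f$conc[] <- 0
    tt <- 0
    dt <- 0.05
    outs <- numeric(0)
    for (k in 1:160) {
      st <- tree_advect_step(tr, f, dt, function(t) c(10, 10), t0 = tt)
      f <- st$field
      tt <- tt + dt
      outs <- c(outs, sum(st$outflow_mass) / (2 * dt * 1e-6))
    }
    # width of the smeared step: time between 10% and 90% crossing
    t10 <- 0.05 * min(which(outs >= 1))
    t90 <- 0.05 * min(which(outs >= 9))
    t90 - t10
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("terminal line sources distribute outflow uniformly along edges", {
  tr <- single_tube(L = 4, v = 2, Q = 2)
  f <- edge_concentration_field(tr, dx_target = 0.5,
    phase_weights = c(rbc = 0.5, pls = 0.5))
  f$conc[] <- 2 # uniform concentration
  src <- terminal_outflow_to_hhs(tr, f)
  # per phase: Q_ph * c / L = (1 mm^3/s * 2 umol/L * 1e-6) / 4 mm
  expect_equal(unname(src[1, ]), rep(2 * 1 * 1e-6 / 4, 2))
  f$conc[] <- 0
  expect_equal(unname(terminal_outflow_to_hhs(tr, f)[1, ]), c(0, 0))
  # draining tree refuses
  trd <- assign_flows(vascular_tree("draining", tr$nodes,
    tr$edges[, c("parent", "child", "radius")]), 2)
  fd <- edge_concentration_field(trd, dx_target = 0.5)
  expect_error(terminal_outflow_to_hhs(trd, fd), "supplying")
})

test_that("steady-state terminal outflow balances the root inflow", {
  tr <- assign_flows(dyadic_test_tree(3, edge_length = 1.5), 8)
  f <- edge_concentration_field(tr, dx_target = 0.5)
  for (k in 1:120) {
    st <- tree_advect_step(tr, f, 0.5, function(t) c(5, 5), t0 = (k - 1) * 0.5)
    f <- st$field
  }
  # in steady state the summed terminal outflow rate equals Q_liv * c_in
  rate <- sum(st$outflow_mass) / 0.5 # umol/s
  expect_equal(rate, 8 * 5 * 1e-6, tolerance = 1e-6)
})

test_that("draining leaves fed a constant converge to it at the root", {
  tr <- assign_flows(dyadic_test_tree(3, edge_length = 1.5,
    kind = "draining"), 8)
  f <- edge_concentration_field(tr, dx_target = 0.5)
  nl <- sum(tr$is_leaf)
  bc <- dvs_leaf_inflow(tr, matrix(2.5, nl, 2))
  for (k in 1:120) {
    st <- tree_advect_step(tr, f, 0.5, bc)
    f <- st$field
  }
  expect_equal(unname(st$outflow_conc), c(2.5, 2.5), tolerance = 1e-9)
  # zero everywhere stays zero
  f0 <- edge_concentration_field(tr, dx_target = 0.5)
  st0 <- tree_advect_step(tr, f0, 1, dvs_leaf_inflow(tr, matrix(0, nl, 2)))
  expect_equal(unname(st0$outflow_conc), c(0, 0))
  # one leaf at c*, rest zero: converges to c* Q_leaf / Q_liv
  one <- matrix(0, nl, 2)
  one[1, ] <- 4
  f1 <- edge_concentration_field(tr, dx_target = 0.5)
  for (k in 1:120) {
    st1 <- tree_advect_step(tr, f1, 0.5, dvs_leaf_inflow(tr, one))
    f1 <- st1$field
  }
  expect_equal(unname(st1$outflow_conc), rep(4 / nl, 2), tolerance = 1e-9)
  # count mismatch errors
  expect_error(dvs_leaf_inflow(tr, matrix(1, nl - 1, 2)), "mismatch")
})
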