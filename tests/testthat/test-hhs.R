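# build a velocity field from an analytic pressure profile on a mask
vel_from_profile <- function(mask, pfun, phi = 0.16) {
  ctr <- mask_voxel_centers(mask)
  p <- structure(list(p = pfun(ctr), mask = mask, K_eff = 1,
    active = rep(TRUE, length(mask$fg))), class = "pressure_field")
  velocity_from_pressure(p, phi)
}

test_that("subspace field validates fractions and computes totals", {
  m <- box_mask(6, 1)
  fr <- default_fractions()
  f <- subspace_field(m, fr)
  expect_equal(unname(hhs_stored_mass(f)), rep(0, 4))
  bad <- fr
  bad["rest"] <- bad["rest"] + 0.01
  expect_error(subspace_field(m, bad), "sum to 1")
  f$conc[, "rbc"] <- 2
  expect_equal(sum(hhs_stored_mass(f)),
    2 * fr[["rbc"]] * m$volume * 1e-6)
})

test_that("total concentration is the volume-fraction weighted average", {
  m <- box_mask(4, 1)
  fr <- c(rbc = 0.1, pls = 0.2, int = 0.2, cell = 0.4, rest = 0.1)
  f <- subspace_field(m, fr)
  f$conc[] <- rep(c(1, 1, 0, 0), each = nrow(f$conc))
  expect_equal(total_concentration(f), rep(0.3, length(m$fg)))
  # all equal with no rest -> the common value
  fr2 <- c(rbc = 0.1, pls = 0.2, int = 0.2, cell = 0.5, rest = 0)
  f2 <- subspace_field(m, fr2)
  f2$conc[] <- 4
  expect_equal(total_concentration(f2), rep(4, length(m$fg)))
  expect_equal(total_concentration(subspace_field(m, fr)),
    rep(0, length(m$fg)))
})

test_that("zero velocity and no sources leave the field unchanged", {
  m <- box_mask(6, 1)
  vel <- vel_from_profile(m, function(x) rep(0, nrow(x)))
  f <- subspace_field(m, default_fractions())
  set.seed(1)
  f$conc[, "rbc"] <- runif(nrow(f$conc))
  f$conc[, "pls"] <- runif(nrow(f$conc))
  st <- hhs_advect_step(f, vel, dt = 1)
  expect_equal(st$field$conc, f$conc)
})

test_that("a blob translates at v dt per step under uniform velocity", {
  m <- box_mask(24, 1)
  phi <- 0.16
  a <- phi # p = -phi * x -> v = 1 mm/s along x
  vel <- vel_from_profile(m, function(x) -a * x[, 1], phi = phi)
  expect_equal(max(abs(vel$v[, 2:3])), 0)
  f <- subspace_field(m, default_fractions())
  ctr <- mask_voxel_centers(m)
  blob <- exp(-rowSums(sweep(ctr, 2, c(7, 12, 12))^2) / 4)
  f$conc[, "rbc"] <- blob
  f$conc[, "pls"] <- blob
  com0 <- sum(ctr[, 1] * blob) / sum(blob)
  dt <- 0.1
  for (k in 1:50) {
    st <- hhs_advect_step(f, vel, dt = dt)
    f <- st$field
  }
  com <- sum(ctr[, 1] * f$conc[, "rbc"]) / sum(f$conc[, "rbc"])
  expect_lt(abs(com - (com0 + 50 * dt * 1)), 1)
  expect_true(all(f$conc >= 0))
})

test_that("interior advection conserves mass exactly and stays proportional", {
  m <- box_mask(10, 1)
  vel <- vel_from_profile(m, function(x) -0.16 * (x[, 1] + 0.5 * x[, 2]))
  f <- subspace_field(m, default_fractions())
  set.seed(2)
  c0 <- runif(nrow(f$conc))
  f$conc[, "rbc"] <- c0
  f$conc[, "pls"] <- 3 * c0
  mass0 <- hhs_stored_mass(f)
  st <- hhs_advect_step(f, vel, dt = 0.5)
  mass1 <- hhs_stored_mass(st$field)
  expect_equal(sum(mass1[1:2]), sum(mass0[1:2]), tolerance = 1e-12)
  expect_equal(st$field$conc[, "pls"], 3 * st$field$conc[, "rbc"],
    tolerance = 1e-10)
  # int and cell untouched by advection
  expect_equal(st$field$conc[, "int"], f$conc[, "int"])
  expect_equal(st$field$conc[, "cell"], f$conc[, "cell"])
})

test_that("grid mismatch between field and velocity errors", {
  vel <- vel_from_profile(box_mask(6, 1), function(x) rep(0, nrow(x)))
  f <- subspace_field(box_mask(8, 1), default_fractions())
  expect_error(hhs_advect_step(f, vel, 1), "mismatch")
})

test_that("source injection grows total mass by exactly the injected amount", {
  g <- small_geometry()
  m <- g$mask
  vel <- vel_from_profile(m, function(x) rep(0, nrow(x)))
  coupling <- hhs_coupling(m, g$svs, g$dvs)
  f <- subspace_field(m, default_fractions())
  nsrc <- length(coupling$src)
  src_mass <- matrix(0.002, nsrc, 2)
  st <- hhs_advect_step(f, vel, dt = 1, coupling = coupling,
    src_mass = src_mass, phase_weights = c(0.388, 0.612))
  mass <- hhs_stored_mass(st$field)
  removed <- sum(st$removed)
  expect_equal(sum(mass[1:2]), sum(src_mass) - removed, tolerance = 1e-10)
  expect_equal(sum(st$injected), sum(src_mass))
})

test_that("neighborhood averages honor weights and limiting cases", {
  g <- small_geometry()
  m <- g$mask
  f <- subspace_field(m, default_fractions())
  f$conc[, "rbc"] <- 3.5
  f$conc[, "pls"] <- 1.5
  le <- tree_leaf_edges(g$dvs)[1]
  av <- neighborhood_average(f, g$dvs, le, radius = 2 * m$spacing)
  expect_equal(unname(av), c(3.5, 1.5))
  # half the neighborhood at c*, half at zero (uniform fractions) -> c*/2
  ctr <- mask_voxel_centers(m)
  a <- g$dvs$nodes[g$dvs$edges$parent[le], ]
  b <- g$dvs$nodes[g$dvs$edges$child[le], ]
  idx <- which(hepatoflow:::.point_segment_dist2(ctr, a, b) <= (2 * m$spacing)^2)
  half <- idx[seq_len(floor(length(idx) / 2))]
  f2 <- subspace_field(m, default_fractions())
  f2$conc[half, "rbc"] <- 2
  av2 <- neighborhood_average(f2, g$dvs, le, radius = 2 * m$spacing)
  expect_equal(unname(av2[1]), 2 * length(half) / length(idx))
  # radius shrunk to a single voxel returns that voxel's value
  f3 <- subspace_field(m, default_fractions())
  f3$conc[, "rbc"] <- seq_len(nrow(f3$conc))
  d2 <- hepatoflow:::.point_segment_dist2(ctr, a, b)
  rtiny <- sqrt(sort(d2)[1]) + 1e-9
  av3 <- neighborhood_average(f3, g$dvs, le, radius = rtiny)
  expect_equal(unname(av3[1]), which.min(d2))
  expect_error(neighborhood_average(f3, g$dvs, le, radius = -1), "positive")
})
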