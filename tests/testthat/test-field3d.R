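test_that("lattice construction honours margin, spacing and equivariance", {
  single <- conformer("C", matrix(0, 1, 3))
  lat <- build_lattice(single, spacing = 2, margin = 4)
  expect_true(all(lat$origin <= -4))
  pts <- lattice_points(lat)
  expect_true(all(apply(pts, 2, max) >= 4))
  expect_true(all(lat$dims >= 5))
  # translation equivariance
  moved <- single
  moved$atoms$x <- moved$atoms$x + 10
  lat2 <- build_lattice(moved, spacing = 2, margin = 4)
  expect_equal(lat2$origin, lat$origin + c(10, 0, 0))
  expect_equal(lat2$dims, lat$dims)
  # a 6 A-long molecule needs a box edge of at least 14 A on that axis
  rod <- conformer(c("C", "C"), rbind(c(-3, 0, 0), c(3, 0, 0)))
  lat3 <- build_lattice(rod, spacing = 1, margin = 4)
  expect_gte((lat3$dims[1] - 1) * lat3$spacing, 14)
  expect_error(build_lattice(list()), "at least one")
})

test_that("steric field follows the Lennard-Jones closed form and cutoff", {
  # single carbon at the origin; probe parameters are the defaults
  cf <- conformer("C", matrix(0, 1, 3))
  eps <- sqrt(0.107 * 0.107)
  rmin <- 1.70 + 1.52
  lat <- structure(list(origin = c(rmin, 0, 0), spacing = 1,
                        dims = c(1L, 1L, 1L)), class = "lattice")
  expect_equal(steric_field(cf, lat), -eps, tolerance = 1e-10)
  # far away the energy vanishes
  lat_far <- structure(list(origin = c(40, 0, 0), spacing = 1,
                            dims = c(1L, 1L, 1L)), class = "lattice")
  expect_lt(abs(steric_field(cf, lat_far)), 1e-6)
  # inside the core the raw energy exceeds the cutoff and is truncated
  lat_in <- structure(list(origin = c(rmin / 2, 0, 0), spacing = 1,
                           dims = c(1L, 1L, 1L)), class = "lattice")
  expect_equal(steric_field(cf, lat_in), 30)
  # a grid point on the nucleus also scores the cutoff
  lat_0 <- structure(list(origin = c(0, 0, 0), spacing = 1,
                          dims = c(1L, 1L, 1L)), class = "lattice")
  expect_equal(steric_field(cf, lat_0), 30)
})

test_that("electrostatic field follows Coulomb with eps(r) = r", {
  cf <- conformer("C", matrix(0, 1, 3), charge = 0.5)
  lat <- structure(list(origin = c(4, 0, 0), spacing = 1,
                        dims = c(1L, 1L, 1L)), class = "lattice")
  e <- electrostatic_field(cf, lat)
  expect_equal(as.numeric(e), 332.0636 * 0.5 / 16, tolerance = 1e-9)
  # neutral molecule gives identically zero field
  cf0 <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  lat2 <- build_lattice(cf0, spacing = 2)
  expect_true(all(electrostatic_field(cf0, lat2) == 0))
  # sign symmetry
  cfp <- conformer(c("N", "O"), rbind(c(0, 0, 0), c(2, 0, 0)),
                   charge = c(0.3, -0.2))
  cfm <- conformer(c("N", "O"), rbind(c(0, 0, 0), c(2, 0, 0)),
                   charge = c(-0.3, 0.2))
  ep <- electrostatic_field(cfp, lat2); em <- electrostatic_field(cfm, lat2)
  expect_equal(as.numeric(ep), -as.numeric(em), tolerance = 1e-12)
  # truncation bounds
  cfbig <- conformer("C", matrix(0, 1, 3), charge = 5)
  latnear <- structure(list(origin = c(0.5, 0, 0), spacing = 1,
                            dims = c(1L, 1L, 1L)), class = "lattice")
  expect_equal(as.numeric(electrostatic_field(cfbig, latnear)), 30)
})

test_that("field blocks respect bounds and rigid-motion invariance", {
  spec <- field_sim_spec(n_molecules = 6, seed = 2)
  sim <- simulate_field_dataset(spec)
  lat <- build_lattice(sim$conformers, spacing = 2)
  blk <- field_block(sim$conformers, lat)
  expect_equal(nrow(blk), 6L)
  fld <- attr(blk, "field")
  expect_true(all(unclass(blk)[, fld == "steric"] <= 30 + 1e-12))
  expect_true(all(abs(unclass(blk)[, fld == "electrostatic"]) <= 30 + 1e-12))
  # moving conformers and lattice rigidly together leaves the matrix
  # unchanged (the lattice type is axis-aligned, so the testable rigid
  # motions are translations; the fields depend on distances only)
  trans <- lapply(sim$conformers, function(cf) {
    cf$atoms$x <- cf$atoms$x + 3.3; cf$atoms$y <- cf$atoms$y - 1.1; cf
  })
  lat_t <- lat
  lat_t$origin <- lat$origin + c(3.3, -1.1, 0)
  blk_t <- field_block(trans, lat_t)
  expect_equal(unclass(blk_t), unclass(blk), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("column filtering equals a direct per-column sd oracle", {
  spec <- field_sim_spec(n_molecules = 8, seed = 5)
  sim <- simulate_field_dataset(spec)
  blk <- field_block(sim$conformers)
  flt <- column_filter(blk, sigma_min = 6)
  sds <- apply(unclass(blk), 2, sd)
  expect_equal(attr(flt, "retained"), which(sds >= 6))
  # a constant column can never survive
  expect_false(any(sds[setdiff(seq_len(ncol(blk)),
                               attr(flt, "retained"))] >= 6))
  # two-molecule toy: sd({0, 20}) > 6 is retained
  expect_gt(sd(c(0, 20)), 6)
  expect_error(column_filter(blk, sigma_min = 1e6), "lower sigma_min")
})

test_that("PLS at full rank equals OLS and contributions normalize", {
  set.seed(31)
  n <- 12; p <- 4
  X <- matrix(rnorm(n * p, sd = 8), n, p)
  colnames(X) <- paste0("S", 1:p)
  blk <- structure(X, class = c("field_block", "matrix"),
                   lattice = NULL,
                   field = rep(c("steric", "electrostatic"), each = p / 2),
                   point = rep(1:(p / 2), 2), retained = 1:p)
  y <- drop(X %*% c(0.5, -0.3, 0.2, 0.1)) + rnorm(n, sd = 0.1)
  m <- fit_pls(blk, y, n_components = p, block_scale = FALSE)
  ols <- lm(y ~ X)
  expect_equal(unname(m$fitted), unname(fitted(ols)), tolerance = 1e-6)
  expect_equal(sum(m$contributions), 1, tolerance = 1e-9)
  # single informative column with one component: perfect recall and all
  # contribution mass on its block
  y1 <- drop(X[, 1]) * 2 + 5
  m1 <- fit_pls(structure(X[, 1, drop = FALSE],
                          class = c("field_block", "matrix"),
                          field = "steric", point = 1, retained = 1),
                y1, 1, block_scale = FALSE)
  expect_equal(m1$r2, 1, tolerance = 1e-9)
  expect_equal(unname(m1$contributions["steric"]), 1)
  expect_error(fit_pls(blk, rep(1, n), 2), "zero-variance")
  expect_error(fit_pls(blk, y, n_components = 50), "exceeds")
})

test_that("PLS recall R2 is non-decreasing in the component count", {
  spec <- field_sim_spec(n_molecules = 12, seed = 9)
  sim <- simulate_field_dataset(spec)
  blk <- column_filter(field_block(sim$conformers), sigma_min = 0.05)
  r2s <- vapply(1:5, function(a) fit_pls(blk, sim$y, a)$r2, 1.0)
  expect_true(all(diff(r2s) >= -1e-8))
})

test_that("component selection maximizes LOO Q2 with smallest-tie rule", {
  # rank-one noiseless system: one component suffices exactly
  set.seed(41)
  t1 <- rnorm(10)
  X <- outer(t1, c(2, -1, 0.5, 3))
  blk <- structure(X, class = c("field_block", "matrix"),
                   field = rep("steric", 4), point = 1:4, retained = 1:4)
  y <- 2 * t1 + 3
  sel <- select_components(blk, y, max_components = 4, block_scale = FALSE)
  expect_equal(sel$n_components, 1L)
  expect_equal(sel$q2, 1, tolerance = 1e-6)
  # argmax contract
  expect_true(all(sel$q2 >= sel$q2_all - 1e-12, na.rm = TRUE))
})

test_that("synthetic latent-rank datasets select the planted rank", {
  # X of exact rank 3 with a rank-3 response: the LOO Q2 curve flattens at
  # three components, and the smallest-tie rule lands there
  hits <- 0L
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 24; p <- 30
    scores <- matrix(rnorm(n * 3), n, 3)
    X <- scores %*% matrix(rnorm(3 * p), 3, p)
    y <- drop(scores %*% c(2, -1.5, 1)) + rnorm(n, sd = 0.2)
    blk <- structure(X, class = c("field_block", "matrix"),
                     field = rep("steric", p), point = seq_len(p),
                     retained = seq_len(p))
    sel <- select_components(blk, y, max_components = 6,
                             block_scale = FALSE)
    if (sel$n_components == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("contour grids match a sort-based percentile oracle", {
  spec <- field_sim_spec(n_molecules = 10, seed = 3)
  sim <- simulate_field_dataset(spec)
  blk <- column_filter(field_block(sim$conformers), sigma_min = 0.5)
  m <- fit_pls(blk, sim$y, 2)
  grid <- contour_grid(m, blk, favored_level = 80, disfavored_level = 20)
  vals <- c(grid$steric, grid$electrostatic)
  # non-retained points are exactly zero
  np <- prod(grid$lattice$dims)
  expect_length(vals, 2 * np)
  # percentile oracle on the positive/negative steric distributions
  pos <- sort(grid$steric[grid$steric > 0])
  if (length(pos)) {
    oracle <- unname(quantile(pos, 0.80))
    expect_equal(unname(grid$levels$steric["favored"]), oracle,
                 tolerance = 1e-9)
  }
  neg <- sort(grid$electrostatic[grid$electrostatic < 0])
  if (length(neg)) {
    oracle <- unname(quantile(neg, 0.20))
    expect_equal(unname(grid$levels$electrostatic["disfavored"]), oracle,
                 tolerance = 1e-9)
  }
  # all-zero coefficients give an all-zero grid
  m0 <- m; m0$coefficients[] <- 0
  g0 <- contour_grid(m0, blk)
  expect_true(all(g0$steric == 0) && all(g0$electrostatic == 0))
  # OpenDX export round-trips the value count
  prefix <- withr::local_tempfile()
  paths <- write_contour_dx(grid, prefix)
  expect_true(all(file.exists(paths)))
  n_items <- sum(vapply(readLines(paths[1]), function(l)
    length(strsplit(trimws(l), " +")[[1]]) *
      grepl("^[ -]*[0-9]", l), 0))
  expect_gte(n_items, np)
})
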