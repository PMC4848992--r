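test_that("linear simulator is seeded, scaled and noise-faithful", {
  spec <- linear_sim_spec(seed = 77)
  a <- simulate_linear_dataset(spec)
  b <- simulate_linear_dataset(spec)
  expect_identical(a, b)                     # bit reproducible
  expect_equal(dim(a$X), c(31L, 10L))
  # zero noise realizes a perfect linear response
  s0 <- linear_sim_spec(noise_sd = 0, seed = 3)
  sim0 <- simulate_linear_dataset(s0)
  expect_equal(sim0$truth$realized_r2, 1, tolerance = 1e-12)
  m0 <- fit_ols(sim0$X[, 1:5], sim0$y)
  expect_equal(m0$r2, 1, tolerance = 1e-10)
  # all-zero coefficients: realized R2 bounded by the null fluctuation
  sz <- linear_sim_spec(n = 500L, support = 1L, beta = 0, noise_sd = 1,
                        seed = 5)
  simz <- simulate_linear_dataset(sz)
  expect_lt(abs(cor(simz$X[, 1], simz$y)^2), 3 / (500 - 1))
  # invalid specs are rejected
  expect_error(linear_sim_spec(noise_sd = -1))
  expect_error(linear_sim_spec(support = 11, beta = 1, p = 10))
})

test_that("the default linear regime emulates the modelled series", {
  # n = 31, five active descriptors, noise 0.2 -> training R2 near 0.93
  r2s <- vapply(1:10, function(s) {
    sim <- simulate_linear_dataset(linear_sim_spec(seed = s))
    fit_ols(sim$X[, 1:5], sim$y)$r2
  }, 1.0)
  expect_gt(mean(r2s), 0.85)
  expect_lt(mean(r2s), 0.99)
})

test_that("stepwise recovers the planted support in the study regime", {
  hits <- 0L
  for (s in 1:50) {
    sim <- simulate_linear_dataset(linear_sim_spec(seed = s))
    sw <- stepwise_select(sim$X, sim$y)
    if (all(1:5 %in% match(sw$selected, colnames(sim$X))))
      hits <- hits + 1L
  }
  expect_gte(hits, 45L)  # >= 90% of seeded replicates
})

test_that("field simulator is seeded and structurally local", {
  spec <- field_sim_spec(seed = 4)
  a <- simulate_field_dataset(spec)
  expect_identical(a, simulate_field_dataset(spec))
  expect_length(a$conformers, spec$n_molecules)
  # zero effects and zero noise give a constant response
  s0 <- field_sim_spec(effect_steric = 0, effect_electrostatic = 0,
                       noise_sd = 0, seed = 1)
  expect_equal(var(simulate_field_dataset(s0)$y), 0)
  # two molecules differing at one site differ only in columns within
  # reach of that site: build them explicitly
  base <- field_sim_spec(n_molecules = 2, seed = 8,
                         bulk_options = 1.7, charge_options = 0)
  sim <- simulate_field_dataset(base)     # identical molecules
  c1 <- sim$conformers[[1]]; c2 <- sim$conformers[[2]]
  site_row <- nrow(c1$atoms)              # last atom = second site
  c2$atoms$charge[site_row] <- 0.5        # perturb one site only
  lat <- build_lattice(list(c1, c2), spacing = 2)
  f1 <- electrostatic_field(c1, lat); f2 <- electrostatic_field(c2, lat)
  changed <- which(abs(as.numeric(f1) - as.numeric(f2)) > 1e-9)
  pts <- lattice_points(lat)
  site_xyz <- as.numeric(c1$atoms[site_row, c("x", "y", "z")])
  d_changed <- sqrt(rowSums(sweep(pts[changed, , drop = FALSE], 2,
                                  site_xyz)^2))
  d_unchanged <- sqrt(rowSums(sweep(pts[-changed, , drop = FALSE], 2,
                                    site_xyz)^2))
  # every unchanged point is farther from the perturbed site than the
  # nearest changed point (the effect is centred on the site)
  expect_lt(min(d_changed), min(d_unchanged))
})

test_that("steric-only effects keep the electrostatic contribution minor", {
  ok <- 0L
  for (s in 1:5) {
    spec <- field_sim_spec(n_molecules = 20, effect_electrostatic = 0,
                           effect_steric = 3, charge_options = c(-0.1, 0.1),
                           noise_sd = 0.05, seed = s)
    sim <- simulate_field_dataset(spec)
    blk <- column_filter(field_block(sim$conformers), sigma_min = 0.5)
    # fit without block scaling: block scaling deliberately equalizes the
    # two fields a priori, which would mask the energetic origin probed here
    m <- fit_pls(blk, sim$y, 2, block_scale = FALSE)
    if (m$contributions[["electrostatic"]] < 0.25) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("end-to-end field pipeline recovers planted effect signs", {
  hits <- 0L
  for (s in 1:10) {
    spec <- field_sim_spec(seed = 300 + s)
    sim <- simulate_field_dataset(spec)
    blk <- column_filter(field_block(sim$conformers), sigma_min = 0.5)
    sel <- select_components(blk, sim$y, max_components = 4)
    m <- fit_pls(blk, sim$y, sel$n_components)
    grid <- contour_grid(m, blk)
    # steric effect is positive: the steric contour mass around each
    # variable site must be positive (bulk-favored); electrostatic effect
    # positive means positive charge raises activity, i.e. a positive
    # (blue-like) electrostatic contour around the site
    pts <- lattice_points(attr(blk, "lattice"))
    near <- function(xyz, vals) {
      reg <- sqrt(rowSums(sweep(pts, 2, xyz)^2)) < 6
      sum(vals[reg])
    }
    s_ok <- e_ok <- TRUE
    for (r in seq_len(nrow(spec$sites))) {
      xyz <- as.numeric(spec$sites[r, c("x", "y", "z")])
      s_ok <- s_ok && near(xyz, grid$steric) > 0
      e_ok <- e_ok && near(xyz, grid$electrostatic) > 0
    }
    if (s_ok && e_ok) hits <- hits + 1L
  }
  expect_gte(hits, 9L)  # >= 90% of seeds
})
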