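test_that("the flux-form scheme conserves mass and leaves uniform fields unchanged", {
  set.seed(51)
  n <- 30
  vals <- matrix(runif(n^2, 0, 5), n, n)
  Dmap <- matrix(runif(n^2, 0.2, 1), n, n)   # heterogeneous diffusivity
  f <- scalar_field(vals, dx = 1, species = "oxygen", diffusivity = Dmap)
  g <- fd_step(f, dt = 1)
  expect_lt(abs(sum(g$values) - sum(vals)) / sum(vals), 1e-10)
  # repeated stepping keeps conserving
  for (i in 1:20) g <- fd_step(g, dt = 1)
  expect_lt(abs(sum(g$values) - sum(vals)) / sum(vals), 1e-10)
  u <- scalar_field(matrix(3, n, n), dx = 1, species = "oxygen",
                    diffusivity = Dmap)
  expect_equal(fd_step(u, dt = 5)$values, matrix(3, n, n))
})

test_that("a diffused point mass matches the 2-D heat kernel", {
  expect_lt(heat_kernel_error(81, dx = 1, D = 1, t = 10), 0.01)
})

test_that("halving the grid spacing reduces the heat-kernel error at second order", {
  e1 <- heat_kernel_error(81, dx = 1, D = 1, t = 16)
  e2 <- heat_kernel_error(161, dx = 0.5, D = 1, t = 16)
  expect_gt(e1 / e2, 3)
})

test_that("pure consumption decays exponentially and a 6 h half-life halves the drug", {
  n <- 15
  f <- scalar_field(matrix(7, n, n), dx = 0.004, species = "oxygen",
                    diffusivity = 2.5e-5)
  g <- fd_step(f, sink_rate = 0.02, dt = 60)        # phi_K = 0.02 /s, 60 s
  expect_equal(g$values[1, 1], 7 * exp(-0.02 * 60), tolerance = 1e-3)
  d <- scalar_field(matrix(2, n, n), dx = 0.004, species = "drug",
                    diffusivity = drug_diffusivity())
  eta <- decay_constant(6) / 3600                   # 6 h half-life, per s
  d2 <- fd_step(d, sink_rate = eta, dt = 6 * 3600)
  expect_equal(d2$values[3, 3], 1, tolerance = 1e-3)   # exactly half of 2
})

test_that("derived drug constants match their closed forms", {
  # five printed significant figures
  expect_equal(round(drug_diffusivity(2.5e-5) / 2.5e-5, 5), 0.27851)
  expect_equal(drug_diffusivity(2.5e-5), 6.963e-6, tolerance = 1e-4)
  expect_equal(decay_constant(6), log(2) / 6)
  expect_equal(decay_constant(6), 0.11552, tolerance = 1e-4)
  expect_equal(decay_constant(Inf), 0)
})

test_that("oxygen scaling maps the maximum to h and recomputes per evaluation", {
  expect_equal(scale_oxygen(matrix(c(1, 4, 2, 4), 2), h = 100),
               matrix(c(25, 100, 50, 100), 2))
  expect_true(all(scale_oxygen(matrix(3, 4, 4), h = 100) == 100))
  expect_warning(z <- scale_oxygen(matrix(0, 3, 3)), "all-zero")
  expect_true(all(z == 0))
})

test_that("supplied-and-consumed oxygen is lowest in the colony core", {
  p <- model_params()
  occ <- matrix(0L, 31, 31)
  occ[12:20, 12:20] <- 1L
  K <- steady_oxygen(occ, p, spacing = 0.004)
  core <- K$values[16, 16]
  rim <- K$values[12, 16]
  outside <- K$values[2, 16]
  expect_lt(core, rim)
  expect_lt(rim, outside)
  # explicit relaxation agrees with the direct steady solve
  K2 <- relax_field(K, source = p$r_k * boundary_mask(occ),
                    sink_rate = p$phi_k * (occ != 0L), tol = 1e-9,
                    max_steps = 500)
  expect_equal(K2$values, K$values, tolerance = 1e-4)
  # an empty lattice has no steady state but rises uniformly under supply
  e <- scalar_field(matrix(1, 11, 11), dx = 0.004, species = "oxygen",
                    diffusivity = p$d_oxygen)
  e2 <- oxygen_step(e, matrix(0L, 11, 11), p, dt = 10)
  expect_true(all(e2$values > e$values))
  expect_lt(diff(range(e2$values)), 1e-12)
})

test_that("stronger supply never yields lower concentrations anywhere", {
  set.seed(61)
  n <- 20
  vals <- matrix(runif(n^2), n, n)
  src_a <- matrix(runif(n^2, 0, 0.5), n, n)
  src_b <- src_a + matrix(runif(n^2, 0, 0.5), n, n)
  f <- scalar_field(vals, dx = 1, species = "drug", diffusivity = 0.3)
  a <- fd_step(f, source = src_a, sink_rate = 0.05, dt = 4)
  b <- fd_step(f, source = src_b, sink_rate = 0.05, dt = 4)
  expect_true(all(b$values >= a$values))
})

test_that("drug pulses enter from outside the tumour and decay at the reported half-life", {
  p <- model_params()
  dose <- dose_descriptor("spheroid_daily", dose_mgkg = 25, n_doses = 1)
  occ <- matrix(0L, 31, 31)
  occ[13:19, 13:19] <- 1L
  f <- scalar_field(matrix(0, 31, 31), dx = 0.004, species = "drug",
                    diffusivity = drug_diffusivity())
  # zero dose: the field stays identically zero
  z <- drug_step(f, occ, dose_descriptor("spheroid_daily", dose_mgkg = 0),
                 p, dt = 3600, now = 0.5)
  expect_true(all(z$values == 0))
  # during the administration window the core sees less drug than the rim
  f <- drug_step(f, occ, dose, p, dt = 3600, now = 0)
  expect_gt(max(f$values), 0)
  expect_lt(f$values[16, 16], f$values[13, 16])
  expect_lt(f$values[13, 16], f$values[2, 16])
  # post-pulse, total drug falls with the 6 h half-life (uniform sink +
  # no-flux boundaries make total mass decay exactly first-order)
  m0 <- sum(f$values)
  f <- drug_step(f, occ, dose, p, dt = 6 * 3600, now = 2)
  expect_equal(sum(f$values) / m0, 0.5, tolerance = 1e-3)
})
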