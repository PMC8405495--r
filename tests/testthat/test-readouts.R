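test_that("the gammaH2AX fraction counts unrepaired damage over the chosen denominator", {
  expect_equal(gammah2ax_fraction(c("G1", "S", "G2M")), 0)
  expect_equal(gammah2ax_fraction(rep("DS", 4)), 100)
  expect_equal(gammah2ax_fraction(c("DS", rep("G1", 7), "DS", "DS", "S", "G2M")),
               25)  # 3 damaged of 12
  # repair-failed agents keep the marker until death; dead agents lose it
  st <- c("DS", "LETHAL_PENDING", "G1", "DEAD")
  expect_equal(gammah2ax_fraction(st, "viable"), 100 * 2 / 3)
  expect_equal(gammah2ax_fraction(st, "all"), 50)
  expect_warning(v <- gammah2ax_fraction(character(0)), "empty")
  expect_true(is.na(v))
})

test_that("disc-to-spheroid extrapolation reports the volume of the equal-area sphere", {
  expect_equal(spheroid_volume(0, dx = 0.004), 0)
  # a rasterised disc of radius 25 sites at 40 um spacing is a 0.1 cm sphere
  g <- expand.grid(i = 1:60, j = 1:60)
  n_occ <- sum((g$i - 30)^2 + (g$j - 30)^2 <= 25^2)
  expect_equal(spheroid_volume(n_occ, dx = 0.004), 4 / 3 * pi * 0.1^3,
               tolerance = 0.02)
  # closed form and monotonicity in the occupied count
  counts <- c(10, 50, 400, 2000)
  v <- vapply(counts, spheroid_volume, numeric(1), dx = 0.004)
  expect_equal(v, 4 / 3 * pi * sqrt(counts * 0.004^2 / pi)^3)
  expect_true(all(diff(v) > 0))
})

test_that("rmse matches hand-computed cases and its invariances", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 1), c(0, 2)), 1)
  expect_equal(rmse(3, 0), 3)
  expect_error(rmse(1:3, 1:2), "equal length")
  set.seed(71)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(rmse(a + 5, b + 5), rmse(a, b))        # shift invariance
  expect_equal(rmse(3 * a, 3 * b), 3 * rmse(a, b))    # linear scaling
})

test_that("time series survive a CSV round trip", {
  x <- data.frame(time = 0:3, n_total = c(10L, 12L, 15L, 18L),
                  gammah2ax_pct = c(0, 2.5, 3.75, 3.125))
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(x, path, dose = "1 uM", replicate = 2)
  y <- read_timeseries(path)
  expect_setequal(unique(y$metric), c("n_total", "gammah2ax_pct"))
  back <- y[y$metric == "gammah2ax_pct", ]
  expect_equal(back$value, x$gammah2ax_pct)
  expect_true(all(y$replicate == 2))
  expect_error(read_timeseries(system.file("extdata",
                                           "synthetic_invitro_monolayer.csv",
                                           package = "ddrabm")),
               "missing column")
})

test_that("fixture tables are validated on load", {
  path <- system.file("extdata", "synthetic_invitro_monolayer.csv",
                      package = "ddrabm")
  fx <- load_fixture(path)
  expect_s3_class(fx, "abm_fixture")
  expect_true(all(fx$dispersion >= 0))
  bad <- fx
  bad$time[2] <- -5   # breaks strict monotonicity within a series
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_fixture(tmp), "strictly increasing")
  nod <- fx[, setdiff(names(fx), "dispersion")]
  write.csv(nod, tmp, row.names = FALSE)
  expect_error(load_fixture(tmp), "dispersion")
})

test_that("fixture comparison interpolates the simulated means and reports RMSE per series", {
  summ <- data.frame(time = rep(seq(0, 72, by = 1), 2),
                     metric = rep(c("gammah2ax_pct", "n_total"), each = 73),
                     mean = c(seq(0, 36, by = 0.5), seq(1000, 8200, by = 100)),
                     sd = 0)
  fake_exp <- structure(list(summary = summ), class = "abm_experiment")
  fx <- data.frame(source = "invitro_monolayer", dose = 1,
                   metric = c("gammah2ax_pct", "gammah2ax_pct", "total"),
                   time = c(24, 48, 24), mean = c(10, 26, 3600),
                   dispersion = 1)
  class(fx) <- c("abm_fixture", "data.frame")
  out <- compare_to_fixture(fake_exp, fx)
  # sim at 24/48 h is 12/24 for gammaH2AX and 3400 cells at 24 h
  expect_equal(out$rmse[out$metric == "gammah2ax_pct"],
               sqrt(((12 - 10)^2 + (24 - 26)^2) / 2))
  expect_equal(out$rmse[out$metric == "total"], 200)
  fx_bad <- fx; fx_bad$time[1] <- 100
  expect_error(compare_to_fixture(fake_exp, fx_bad), "outside")
})

test_that("cell maps are written as readable VTK image data", {
  states <- matrix(0L, 4, 4); states[2, 2] <- 1L; states[3, 3] <- 6L
  oxy <- matrix(seq(0, 1, length.out = 16), 4, 4)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_cellmap_vtk(path, states, fields = list(oxygen = oxy), dx = 0.004)
  txt <- readLines(path)
  expect_true(any(grepl("DATASET STRUCTURED_POINTS", txt)))
  expect_true(any(grepl("DIMENSIONS 4 4 1", txt)))
  expect_true(any(grepl("SCALARS cell_state int", txt)))
  expect_true(any(grepl("SCALARS oxygen float", txt)))
  ints <- as.integer(strsplit(txt[which(grepl("LOOKUP_TABLE", txt))[1] + 1],
                              " ")[[1]])
  expect_equal(sum(ints != 0), 2)
  expect_equal(length(ints), 16)
})

test_that("YAML configurations rebuild the config and parameter objects", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("config:",
               "  mode: monolayer",
               "  treatment_trigger: 500",
               "  total_time: 24",
               "  n_replicates: 3",
               "  seed: 9",
               "  dose:",
               "    mode: monolayer_step",
               "    concentration: 1.5",
               "params:",
               "  sigma: 0.4"), tmp)
  got <- read_config(tmp)
  expect_s3_class(got$config, "abm_config")
  expect_equal(got$config$treatment_trigger, 500)
  expect_equal(got$config$dose$concentration, 1.5)
  expect_equal(got$params$sigma, 0.4)
  expect_equal(got$params$mu, 24)   # untouched defaults
})
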