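test_that("doubling times reproduce the calibrated distribution and stay positive", {
  set.seed(101)
  tau <- sample_doubling_time(1e5, 24, 0.5)
  expect_true(all(tau > 0))
  # 3-standard-error bands on the sample moments
  expect_lt(abs(mean(tau) - 24), 3 * 0.5 / sqrt(1e5))
  expect_lt(abs(sd(tau) - 0.5), 3 * 0.5 / sqrt(2 * 1e5))
  expect_identical(sample_doubling_time(5, 24, 0), rep(24, 5))
})

test_that("G1 delay factor follows its three branches and joins continuously", {
  expect_equal(g1_delay_factor(50), 1)
  expect_equal(g1_delay_factor(0.5), 2)
  expect_equal(g1_delay_factor(1.0), 0.9209 + 0.82 / (-0.2389 + 1.0),
               tolerance = 1e-12)
  expect_equal(g1_delay_factor(1.0), 1.9983, tolerance = 1e-4)
  expect_equal(g1_delay_factor(10.5), 1.0008, tolerance = 1e-4)
  # near-continuity at both breakpoints
  expect_lt(abs(g1_delay_factor(1) - g1_delay_factor(1 - 1e-9)), 2e-3)
  expect_lt(abs(g1_delay_factor(10.5) - g1_delay_factor(10.5 + 1e-9)), 2e-3)
  expect_true(all(g1_delay_factor(seq(10.6, 100, by = 0.1)) == 1))
  expect_error(g1_delay_factor(-1), "oxygen")
})

test_that("phase durations are the calibrated doubling-time fractions", {
  p <- model_params()
  expect_equal(phase_duration("G1", 24), 11)
  expect_equal(phase_duration("G1", 24, oxygen_pct = 0.5), 22)
  expect_equal(phase_duration("DS", 24), 0.72)
  expect_equal(phase_duration("S", 24), 8)
  expect_equal(phase_duration("G2M", 24), 5)
  # a full damage-routed cycle: D-S time is additional to S
  expect_equal(sum(phase_duration(c("G1", "DS", "S", "G2M"), 24)), 24.72)
  expect_error(phase_duration("G0", 24), "cycling states")
})

test_that("G1 exits fork to the damaged state at the calibrated probability", {
  p <- model_params()
  set.seed(202)
  n <- 1e4
  # n agents poised at G1 completion; one vectorised step resolves the fork
  adv <- ddrabm:::.advance_clocks(rep(1L, n), rep(24, n),
                                  rep(10.95, n), numeric(n), dt = 0.1,
                                  drug = numeric(n), oxy = rep(100, n),
                                  space = rep(TRUE, n), params = p)
  frac_ds <- mean(adv$state == 3L)
  expect_true(all(adv$state %in% c(2L, 3L)))
  expect_lt(abs(frac_ds - 0.75), 3 * sqrt(0.75 * 0.25 / n))
  # pi_ds = 0: every exit goes straight to S
  adv0 <- ddrabm:::.advance_clocks(rep(1L, 100), rep(24, 100),
                                   rep(10.95, 100), numeric(100), dt = 0.1,
                                   drug = numeric(100), oxy = rep(100, 100),
                                   space = rep(TRUE, 100),
                                   params = model_params(pi_ds = 0))
  expect_true(all(adv0$state == 2L))
})

test_that("repair is certain without drug, half-maximal at EC50, impossible at saturation", {
  p <- model_params()
  set.seed(303)
  expect_true(all(attempt_repair(rep(0, 1000), p)))
  expect_false(any(attempt_repair(rep(1e9, 1000), p)))
  rep_frac <- mean(attempt_repair(rep(p$ec50, 1e4), p))
  expect_lt(abs(rep_frac - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("a drug-free damage-routed agent completes its cycle in (1 + theta_ds) tau", {
  p <- model_params(pi_ds = 1)  # deterministic routing through D-S
  set.seed(404)
  a <- new_agent(tau = 24)
  t <- 0; dt <- 0.01
  repeat {
    res <- advance_agent(a, dt, local_drug = 0, params = p)
    a <- res$agent
    t <- t + dt
    if (res$event == "divides") break
    if (t > 30) stop("agent never divided")
  }
  expect_equal(t, 24.72, tolerance = 2 * dt / 24.72)
  expect_true(res$event == "divides")
})

test_that("state transitions stay on the cycle graph and death is irreversible", {
  p <- model_params()
  # G0 resumption happens at the start of a step, so a resumed agent whose
  # clock is already full may reach S or D-S within the same step
  allowed <- list(G1 = c("G1", "G0", "S", "DS"),
                  S = c("S", "G2M"),
                  DS = c("DS", "S", "LETHAL_PENDING"),
                  G2M = "G2M",          # division is signalled, not applied
                  G0 = c("G0", "G1", "S", "DS"),
                  LETHAL_PENDING = c("LETHAL_PENDING", "DEAD"))
  set.seed(505)
  for (i in 1:400) {
    from <- sample(names(allowed), 1)
    a <- new_agent(state = from, tau = runif(1, 20, 28),
                   clock = runif(1, 0, 12), death_clock = runif(1, 0, 30))
    res <- advance_agent(a, dt = runif(1, 0.05, 2),
                         local_drug = sample(c(0, 1, 100), 1),
                         space_available = sample(c(TRUE, FALSE), 1),
                         params = p)
    expect_true(res$agent$state %in% allowed[[from]],
                label = sprintf("%s -> %s", from, res$agent$state))
  }
  # a lethal-pending agent can never divide or rejoin the cycle
  a <- new_agent(state = "LETHAL_PENDING", tau = 24, death_clock = 0)
  for (i in 1:300) {
    res <- advance_agent(a, dt = 0.1, local_drug = 0, params = p)
    a <- res$agent
    expect_true(a$state %in% c("LETHAL_PENDING", "DEAD"))
    if (a$state == "DEAD") break
  }
  expect_identical(a$state, "DEAD")   # death_clock reached tau
  expect_error(advance_agent(a, 0.1, params = p), "DEAD")
})

test_that("quiescent agents freeze their clock and resume where they left off", {
  p <- model_params()
  a <- new_agent(state = "G1", tau = 24, clock = 5)
  res <- advance_agent(a, 0.1, space_available = FALSE, params = p)
  expect_identical(res$agent$state, "G0")
  expect_identical(res$event, "entered_G0")
  clock_at_exit <- res$agent$clock
  res2 <- advance_agent(res$agent, 0.1, space_available = FALSE, params = p)
  expect_equal(res2$agent$clock, clock_at_exit)  # frozen in G0
  res3 <- advance_agent(res2$agent, 0.1, space_available = TRUE, params = p)
  expect_identical(res3$agent$state, "G1")       # resumes, not restarts
  expect_equal(res3$agent$clock, clock_at_exit + 0.1)
})
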