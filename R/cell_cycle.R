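#' Sample individual doubling times
#'
#' Draws agent doubling times from a normal distribution with mean `mu` and
#' standard deviation `sigma`, redrawing any non-positive value (with the
#' default 24 h +/- 0.5 h the rejection probability is negligible and the
#' moments are unaffected).
#'
#' @param n Number of draws.
#' @param mu Mean doubling time (hours), > 0.
#' @param sigma Standard deviation (hours), >= 0.
#' @return A vector of `n` strictly positive doubling times.
#' @examples
#' set.seed(1); summary(sample_doubling_time(1000, 24, 0.5))
#' @export
sample_doubling_time <- function(n = 1, mu = 24, sigma = 0.5) {
  stopifnot(mu > 0, sigma >= 0)
  tau <- rnorm(n, mu, sigma)
  while (any(bad <- tau <= 0)) tau[bad] <- rnorm(sum(bad), mu, sigma)
  tau
}

#' G1 delay factor under hypoxia
#'
#' Multiplicative elongation of the G1 phase as a function of the scaled local
#' oxygen level: 2 below 1 percent, `a1 + a2 / (a3 + oxygen)` between 1 and
#' 10.5 percent, and 1 otherwise. With the default coefficients the three
#' branches join continuously to within 2e-3.
#'
#' @param oxygen_pct Scaled oxygen level in percent (0-100), vectorised.
#' @param a1,a2,a3 Coefficients of the middle branch.
#' @return Delay factor >= 1 (up to the small branch-joining error).
#' @examples
#' g1_delay_factor(c(0.5, 1, 10.5, 50))
#' @export
g1_delay_factor <- function(oxygen_pct, a1 = 0.9209, a2 = 0.8200,
                            a3 = -0.2389) {
  if (any(oxygen_pct < 0 | oxygen_pct > 100))
    stop("oxygen_pct must lie in [0, 100]")
  out <- rep(1, length(oxygen_pct))
  lo <- oxygen_pct < 1
  mid <- !lo & oxygen_pct <= 10.5
  out[lo] <- 2
  out[mid] <- a1 + a2 / (a3 + oxygen_pct[mid])
  out
}

#' Phase duration of an agent
#'
#' Time an agent with doubling time `tau` spends in a given cell-cycle state:
#' the state's fraction of the doubling time, with the G1 fraction scaled by
#' the G1 delay factor at the current local oxygen level. D-S time is
#' additional to S, so a drug-free cell completes G1 + D-S + S + G2/M in
#' `(1 + pi_ds-routed theta_ds) * tau`.
#'
#' @param state One of `"G1"`, `"S"`, `"DS"`, `"G2M"` (or its integer code).
#' @param tau Individual doubling time (hours).
#' @param oxygen_pct Scaled local oxygen (percent); 100 (normoxia) in
#'   monolayer mode.
#' @param params An [model_params()] object.
#' @return Duration in hours.
#' @examples
#' phase_duration("G1", 24)             # 11 h under normoxia
#' phase_duration("G1", 24, oxygen_pct = 0.5)  # 22 h under severe hypoxia
#' @export
phase_duration <- function(state, tau, oxygen_pct = 100,
                           params = model_params()) {
  code <- .state_code(state)
  if (any(!code %in% 1:4))
    stop("phase_duration is defined for cycling states G1, S, DS, G2M only")
  n <- max(length(code), length(tau), length(oxygen_pct))
  code <- rep_len(code, n)
  tau <- rep_len(tau, n)
  oxy <- rep_len(oxygen_pct, n)
  frac <- c(params$theta_g1, params$theta_s, params$theta_ds,
            params$theta_g2m)[code]
  g1 <- code == .STATES[["G1"]]
  frac[g1] <- frac[g1] * g1_delay_factor(oxy[g1], params$g1df_a1,
                                         params$g1df_a2, params$g1df_a3)
  frac * tau
}

#' Attempt DNA damage repair
#'
#' Bernoulli repair decision for agents completing the damaged-S state: each
#' succeeds with probability `1 - E(C)` where `E` is the sigmoid Emax effect
#' of the local drug concentration. Failure marks the lethal event: the agent
#' leaves the cycle and dies after a further `tau` hours.
#'
#' @param C Local drug concentration(s), micromolar.
#' @param params An [model_params()] object.
#' @param n Number of independent decisions (defaults to `length(C)`).
#' @return Logical vector: TRUE where repair succeeded.
#' @examples
#' set.seed(1); mean(attempt_repair(1, n = 1e4))  # about 0.5 at C = EC50
#' @export
attempt_repair <- function(C, params = model_params(), n = length(C)) {
  runif(n) < repair_probability(C, params)
}

# Vectorised one-step update of the cell-cycle state machine. All arguments
# are parallel vectors over agents; returns updated vectors plus event
# indices. Placement of daughters (and hence completion of mitosis) is the
# engine's job: agents whose G2/M clock is full raise `wants_divide` and keep
# their clock pinned until space is found.
.advance_clocks <- function(state, tau, clock, death_clock, dt,
                            drug, oxy, space, params) {
  S <- .STATES
  # quiescence bookkeeping: G1 agents without reachable space exit to G0,
  # G0 agents with space resume G1 with their clock preserved
  to_g0 <- state == S[["G1"]] & !space
  to_g1 <- state == S[["G0"]] & space
  state[to_g0] <- S[["G0"]]
  state[to_g1] <- S[["G1"]]

  st0 <- state
  # clock accumulation; hypoxia slows G1 accumulation by 1/G1DF so that a
  # cell moving through varying oxygen experiences a path-dependent G1
  in_g1 <- st0 == S[["G1"]]
  if (any(in_g1)) {
    g1df <- g1_delay_factor(oxy[in_g1], params$g1df_a1, params$g1df_a2,
                            params$g1df_a3)
    clock[in_g1] <- clock[in_g1] + dt / g1df
  }
  cyc <- st0 == S[["S"]] | st0 == S[["DS"]] | st0 == S[["G2M"]]
  clock[cyc] <- clock[cyc] + dt
  lp <- st0 == S[["LETHAL_PENDING"]]
  death_clock[lp] <- death_clock[lp] + dt

  # D-S completion: repair back to S or suffer the lethal event
  ds_done <- which(st0 == S[["DS"]] & clock >= params$theta_ds * tau)
  if (length(ds_done)) {
    over <- clock[ds_done] - params$theta_ds * tau[ds_done]
    rep_ok <- attempt_repair(drug[ds_done], params, n = length(ds_done))
    ok <- ds_done[rep_ok]; fail <- ds_done[!rep_ok]
    state[ok] <- S[["S"]];  clock[ok] <- over[rep_ok]
    state[fail] <- S[["LETHAL_PENDING"]]
    clock[fail] <- 0; death_clock[fail] <- over[!rep_ok]
  }
  # G1 completion: fork to D-S with probability pi_ds, else S
  g1_done <- which(st0 == S[["G1"]] & state == S[["G1"]] &
                     clock >= params$theta_g1 * tau)
  if (length(g1_done)) {
    over <- clock[g1_done] - params$theta_g1 * tau[g1_done]
    to_ds <- runif(length(g1_done)) < params$pi_ds
    state[g1_done] <- ifelse(to_ds, S[["DS"]], S[["S"]])
    clock[g1_done] <- over
  }
  # S completion
  s_done <- which(st0 == S[["S"]] & clock >= params$theta_s * tau)
  if (length(s_done)) {
    clock[s_done] <- clock[s_done] - params$theta_s * tau[s_done]
    state[s_done] <- S[["G2M"]]
  }
  # G2/M completion: request division (resolved by the engine)
  thr_g2m <- params$theta_g2m * tau
  wants_divide <- which(st0 == S[["G2M"]] & clock >= thr_g2m)
  clock[wants_divide] <- pmin(clock[wants_divide], thr_g2m[wants_divide])
  # timed death T_{L->D} = tau_i after the lethal event
  died <- which(lp & death_clock >= tau)
  state[died] <- S[["DEAD"]]

  list(state = state, clock = clock, death_clock = death_clock,
       wants_divide = wants_divide, died = died)
}

#' Advance a single agent by one time step
#'
#' Single-agent view of the state machine used by the simulation engine:
#' accumulates `dt` on the phase clock (scaled by the G1 delay factor in G1),
#' applies quiescence entry/exit, forks G1 exits between S and D-S, decides
#' repair at D-S completion, signals division at G2/M completion and timed
#' death after a failed repair. Division itself (daughter placement) is
#' resolved by the engine; `advance_agent` reports the request as a
#' `"divides"` event.
#'
#' @param agent A list with `state` (name or code), `tau`, `clock` and
#'   `death_clock` fields, e.g. from [new_agent()].
#' @param dt Time step (hours).
#' @param local_drug Drug concentration at the agent's site (micromolar).
#' @param local_oxygen Scaled oxygen at the agent's site (percent).
#' @param space_available Is lattice space reachable for proliferation?
#' @param params An [model_params()] object.
#' @return A list with the updated `agent` and an `event` string: one of
#'   `"none"`, `"entered_S"`, `"entered_DS"`, `"entered_G2M"`,
#'   `"entered_G0"`, `"reentered_G1"`, `"repaired"`, `"lethal"`,
#'   `"divides"`, `"died"`.
#' @examples
#' a <- new_agent(tau = 24)
#' advance_agent(a, dt = 0.1, params = model_params())$event
#' @export
advance_agent <- function(agent, dt, local_drug = 0, local_oxygen = 100,
                          space_available = TRUE, params = model_params()) {
  code <- .state_code(agent$state)
  if (code == .STATES[["DEAD"]]) stop("cannot advance a DEAD agent")
  res <- .advance_clocks(code, agent$tau, agent$clock, agent$death_clock,
                         dt, local_drug, local_oxygen, space_available,
                         params)
  new_code <- res$state
  event <- "none"
  if (length(res$wants_divide)) event <- "divides"
  else if (length(res$died)) event <- "died"
  else if (new_code != code) {
    event <- switch(.state_name(new_code),
                    S = if (code == .STATES[["DS"]]) "repaired" else "entered_S",
                    DS = "entered_DS", G2M = "entered_G2M",
                    G0 = "entered_G0", G1 = "reentered_G1",
                    LETHAL_PENDING = "lethal", DEAD = "died")
  }
  agent$state <- .state_name(new_code)
  agent$clock <- res$clock
  agent$death_clock <- res$death_clock
  list(agent = agent, event = event)
}

#' Create an agent
#'
#' @param state Initial state (default `"G1"`: every cell commences its life
#'   in G1 with a zero clock).
#' @param tau Individual doubling time (hours).
#' @param clock Phase clock (hours already spent in `state`).
#' @param death_clock Time since the lethal event (hours).
#' @return A list representing one agent.
#' @export
new_agent <- function(state = "G1", tau = 24, clock = 0, death_clock = 0) {
  stopifnot(tau > 0, clock >= 0)
  list(state = state, tau = tau, clock = clock, death_clock = death_clock)
}
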