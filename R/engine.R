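# Simulation engine: couples the cell-cycle state machine to the lattice and
# (in spheroid mode) to the oxygen/drug reaction-diffusion fields, handles
# the treatment trigger and dosing clock, and records readouts.

.new_pop <- function(cap = 256L) {
  p <- new.env(parent = emptyenv())
  p$n <- 0L
  p$state <- integer(cap)
  p$tau <- numeric(cap)
  p$clock <- numeric(cap)
  p$death_clock <- numeric(cap)
  p$row <- integer(cap)
  p$col <- integer(cap)
  p
}

.pop_grow <- function(p) {
  for (f in c("state", "row", "col"))
    p[[f]] <- c(p[[f]], integer(length(p[[f]])))
  for (f in c("tau", "clock", "death_clock"))
    p[[f]] <- c(p[[f]], numeric(length(p[[f]])))
  invisible(p)
}

.pop_add <- function(p, state, tau, row, col, clock = 0) {
  if (p$n == length(p$state)) .pop_grow(p)
  i <- p$n + 1L
  p$state[i] <- state
  p$tau[i] <- tau
  p$clock[i] <- clock
  p$death_clock[i] <- 0
  p$row[i] <- row
  p$col[i] <- col
  p$n <- i
  i
}

#' Run one simulation replicate
#'
#' Places a single agent at the centre of the lattice, grows the population
#' under the mode's proliferation and quiescence rules, starts treatment when
#' the trigger (cell count or extrapolated volume) is reached, and records
#' readouts at the configured cadence. In spheroid mode the oxygen field is
#' kept at its quasi-steady profile, the drug field is co-integrated in real
#' time with daily supply pulses and first-order decay, and dead agents are
#' removed from the lattice; in monolayer mode the drug concentration is a
#' homogeneous step at the treatment time and dead cells persist on the
#' lattice. Deterministic given `(config, params, seed)`.
#'
#' @param config An [simulation_config()] object.
#' @param params An [model_params()] object.
#' @param seed Integer RNG seed (defaults to the config's master seed).
#' @return A data frame of class `abm_readouts`: one row per output time
#'   (hours relative to treatment start) with state-resolved counts
#'   (`n_g1`, `n_s`, `n_ds`, `n_g2m`, `n_g0`, `n_lethal`, `n_dead`,
#'   `n_total`), `gammah2ax_pct`, `drug_conc` (applied concentration in
#'   monolayer mode, lattice maximum in spheroid mode) and `volume_cm3`
#'   (spheroid mode). Attributes: `t0` (absolute trigger time), `seed`,
#'   `dose`, `counters` (divisions, lethal events, deaths, removals) and
#'   `final_state` (occupancy, agent vectors, and fields in spheroid mode).
#' @examples
#' cfg <- simulation_config("monolayer", treatment_trigger = 30,
#'                          total_time = 5, lattice_size = 30)
#' run_replicate(cfg, model_params(), seed = 1)[1:3, ]
#' @export
run_replicate <- function(config, params = model_params(),
                          seed = config$seed) {
  stopifnot(inherits(config, "abm_config"), inherits(params, "abm_params"))
  set.seed(seed)
  mono <- config$mode == "monolayer"
  n_side <- config$lattice_size
  dt <- config$dt
  nu <- if (!is.na(config$nu)) config$nu
        else if (mono) params$nu_monolayer else params$nu_spheroid
  rec_every <- as.integer(round(config$record_dt / dt))
  dose <- config$dose
  S <- .STATES

  occ <- matrix(0L, n_side, n_side)
  pop <- .new_pop()
  ctr <- c(ceiling(n_side / 2), ceiling(n_side / 2))
  .pop_add(pop, S[["G1"]], sample_doubling_time(1, params$mu, params$sigma),
           ctr[1], ctr[2])
  occ[ctr[1], ctr[2]] <- 1L

  use_fields <- !mono
  if (use_fields) {
    K <- steady_oxygen(occ, params, spacing = config$lattice_spacing)
    Cmat <- matrix(0, n_side, n_side)
    drug_field <- scalar_field(Cmat, dx = config$lattice_spacing,
                               species = "drug", diffusivity = 1)
  }
  khat <- NULL

  t <- 0; step <- 0L; t0 <- NA_real_; step0 <- NA_integer_
  divisions <- 0L; lethal_events <- 0L; deaths <- 0L; removals <- 0L
  rows <- list(); snaps <- list()

  count_states <- function() {
    idx <- seq_len(pop$n)
    st <- pop$state[idx]
    onlat <- if (mono) idx else idx[st != S[["DEAD"]]]
    tabulate(pop$state[onlat], nbins = 7L)
  }

  record <- function(t_abs) {
    cnt <- count_states()
    st <- pop$state[seq_len(pop$n)]
    if (!mono) st <- st[st != S[["DEAD"]]]
    row <- data.frame(
      time = t_abs,
      n_g1 = cnt[1], n_s = cnt[2], n_ds = cnt[3], n_g2m = cnt[4],
      n_g0 = cnt[5], n_lethal = cnt[6], n_dead = cnt[7],
      n_total = sum(cnt),
      gammah2ax_pct = gammah2ax_fraction(st, config$gammah2ax_denominator),
      drug_conc = if (is.na(t0)) 0
                  else if (mono) monolayer_concentration(dose, t_abs, t0)
                  else max(Cmat),
      volume_cm3 = if (mono) NA_real_
                   else spheroid_volume(sum(occ != 0L),
                                        config$lattice_spacing))
    rows[[length(rows) + 1L]] <<- row
    if (config$record_fields && use_fields)
      snaps[[length(snaps) + 1L]] <<-
        list(time = t_abs, oxygen = khat, drug = Cmat, occ = occ)
  }

  trigger_met <- function() {
    if (mono) {
      cnt <- if (pop$n >= config$treatment_trigger) pop$n else 0L
      cnt >= config$treatment_trigger
    } else {
      spheroid_volume(sum(occ != 0L), config$lattice_spacing) >=
        config$treatment_trigger
    }
  }

  if (config$record_growth) record(0)

  repeat {
    idx <- seq_len(pop$n)

    # --- fields at the start of the step -------------------------------
    if (use_fields) {
      viable <- occ != 0L
      if (step %% config$oxygen_every == 0L) {
        if (step %% config$steady_solve_every == 0L) {
          K <- steady_oxygen(occ, params, viable = viable,
                             spacing = config$lattice_spacing)
        } else {
          K$diffusivity <- .diffusivity_map(params$d_oxygen, viable,
                                            params$intracellular_slowdown)
          K <- relax_field(K, source = params$r_k * .boundary_mask(occ),
                           sink_rate = params$phi_k * viable,
                           tol = 1e-6, max_steps = config$field_substeps)
        }
      }
      khat <- scale_oxygen(K, params$h)
      treatment_started <- !is.na(t0)
      if (treatment_started || max(Cmat) > 0) {
        drug_field$values <- Cmat
        drug_field <- drug_step(drug_field, occ, dose, params,
                                dt = dt * 3600,
                                now = if (treatment_started) t - t0 else -1,
                                viable = viable)
        Cmat <- drug_field$values
      }
    }

    # --- per-agent local conditions ------------------------------------
    at <- cbind(pop$row[idx], pop$col[idx])
    if (mono) {
      Cnow <- if (is.na(t0)) 0 else monolayer_concentration(dose, t, t0)
      drug_at <- rep(Cnow, pop$n)
      oxy_at <- rep(100, pop$n)
    } else {
      drug_at <- Cmat[at]
      oxy_at <- pmin(khat[at], 100)
    }
    if (is.finite(nu)) {
      smap <- .space_map(occ, as.integer(nu))
      space_at <- smap[at]
    } else {
      space_at <- rep(any(occ == 0L), pop$n)
    }

    # --- advance the state machine -------------------------------------
    adv <- .advance_clocks(pop$state[idx], pop$tau[idx], pop$clock[idx],
                           pop$death_clock[idx], dt, drug_at, oxy_at,
                           space_at, params)
    lethal_events <- lethal_events +
      sum(adv$state == S[["LETHAL_PENDING"]] &
            pop$state[idx] != S[["LETHAL_PENDING"]])
    pop$state[idx] <- adv$state
    pop$clock[idx] <- adv$clock
    pop$death_clock[idx] <- adv$death_clock

    # --- deaths (timed removal after the lethal event) ------------------
    if (length(adv$died)) {
      deaths <- deaths + length(adv$died)
      if (!mono) {
        occ[cbind(pop$row[adv$died], pop$col[adv$died])] <- 0L
        removals <- removals + length(adv$died)
      }
    }

    # --- divisions, in randomly permuted order --------------------------
    div <- adv$wants_divide
    if (length(div)) {
      for (i in div[sample.int(length(div))]) {
        shape <- if (runif(1) < 0.5) 0L else 1L
        mo <- if (is.finite(nu)) as.integer(nu) else n_side
        site <- .place_daughter_cpp(occ, pop$row[i], pop$col[i], shape, mo)
        if (anyNA(site)) {
          if (mono && !is.finite(nu))
            stop("lattice overflow: no free site for a mandatory daughter ",
                 "placement at step ", step, " (population ", pop$n, ")")
          next  # bounded neighbourhood full: parent waits at the end of
                # G2/M and retries once space frees up
        }
        j <- .pop_add(pop, S[["G1"]],
                      sample_doubling_time(1, params$mu, params$sigma),
                      site[1], site[2])
        occ[site[1], site[2]] <- j
        pop$state[i] <- S[["G1"]]
        pop$clock[i] <- 0
        divisions <- divisions + 1L
      }
    }

    step <- step + 1L
    t <- step * dt

    if (is.na(t0) && trigger_met()) {
      t0 <- t
      step0 <- step
      dose$t0 <- t0
    }

    if (!is.na(t0)) {
      if ((step - step0) %% rec_every == 0L) record(t)
      if (t - t0 >= config$total_time - 1e-9) break
    } else {
      if (config$record_growth && step %% rec_every == 0L) record(t)
      if (t > config$max_growth_time)
        stop("treatment trigger not reached within max_growth_time = ",
             config$max_growth_time, " h")
    }
  }

  out <- do.call(rbind, rows)
  out$time <- round(out$time - t0, 9)   # clear float dust off the time grid
  if (length(snaps))
    snaps <- lapply(snaps, function(s) { s$time <- round(s$time - t0, 9); s })
  if (!config$record_growth) out <- out[out$time >= -1e-9, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("abm_readouts", "data.frame")
  attr(out, "t0") <- t0
  attr(out, "seed") <- seed
  attr(out, "dose") <- dose
  attr(out, "counters") <- list(divisions = divisions,
                                lethal_events = lethal_events,
                                deaths = deaths, removals = removals)
  fin <- list(occ = occ,
              state = pop$state[seq_len(pop$n)],
              tau = pop$tau[seq_len(pop$n)],
              row = pop$row[seq_len(pop$n)],
              col = pop$col[seq_len(pop$n)])
  if (use_fields) {
    fin$oxygen_pct <- khat
    fin$drug <- Cmat
  }
  attr(out, "final_state") <- fin
  if (config$record_fields) attr(out, "snapshots") <- snaps
  out
}

#' Run a replicated in silico experiment
#'
#' Runs `n_replicates` independent replicates (replicate `i` is seeded with
#' `seed + i - 1`) and aggregates each readout into per-time-point means and
#' standard deviations, the convention used to report results that mitigate
#' intrinsic model stochasticity.
#'
#' @inheritParams run_replicate
#' @return An object of class `abm_experiment`: a list with `summary` (long
#'   data frame: `time`, `metric`, `mean`, `sd`), `replicates` (list of
#'   `abm_readouts`), `config` and `params`.
#' @examples
#' cfg <- simulation_config("monolayer", treatment_trigger = 30,
#'                          total_time = 4, lattice_size = 30,
#'                          n_replicates = 2, seed = 7)
#' ex <- run_experiment(cfg, model_params())
#' head(ex$summary)
#' @export
run_experiment <- function(config, params = model_params()) {
  reps <- lapply(seq_len(config$n_replicates), function(i) {
    run_replicate(config, params, seed = config$seed + i - 1L)
  })
  metrics <- setdiff(names(reps[[1]]), "time")
  times <- reps[[1]]$time
  summ <- do.call(rbind, lapply(metrics, function(m) {
    vals <- vapply(reps, function(r) r[[m]], numeric(length(times)))
    vals <- matrix(vals, nrow = length(times))
    data.frame(time = times, metric = m,
               mean = rowMeans(vals),
               sd = apply(vals, 1, sd))
  }))
  summ$sd[is.na(summ$sd)] <- 0   # single replicate: s.d. defined as 0
  structure(list(summary = summ, replicates = reps, config = config,
                 params = params),
            class = "abm_experiment")
}

#' @export
print.abm_experiment <- function(x, ...) {
  cat(sprintf("ABM experiment: %s, %d replicate(s), dose %s\n",
              x$config$mode, length(x$replicates), format(x$config$dose)))
  cat(sprintf("  %d output times in [%g, %g] h relative to treatment\n",
              length(unique(x$summary$time)), min(x$summary$time),
              max(x$summary$time)))
  invisible(x)
}
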