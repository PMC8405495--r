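#' Calibrated model parameters
#'
#' Container for all constants of the cell-cycle state machine, the oxygen and
#' drug transport equations and the Emax drug-response model. Defaults are the
#' in vitro calibrated values for LoVo cells treated with the ATR inhibitor
#' AZD6738, plus the oxygen-model coefficients used for spheroid simulations.
#'
#' @param mu Mean doubling time (hours). Default 24.
#' @param sigma Standard deviation of the doubling-time distribution (hours).
#'   Default 0.5; small values produce strongly cycle-synchronised populations.
#' @param pi_ds Probability that a cell leaving G1 enters the damaged-S (D-S)
#'   state rather than S. Default 0.75.
#' @param theta_g1,theta_s,theta_g2m Fractions of the doubling time spent in
#'   G1, S and G2/M; must sum to 1. Defaults 11/24, 8/24, 5/24.
#' @param theta_ds Fraction of the doubling time spent in the D-S state
#'   (additional to S). Default 0.03.
#' @param ec50 Drug concentration achieving half the maximal effect
#'   (micromolar). Default 1.
#' @param gamma Hill exponent of the sigmoid Emax model. Default 2.
#' @param emax Maximal drug effect in (0, 1]; 1 means complete repair
#'   inhibition at saturating concentration. Default 1.
#' @param d_oxygen Oxygen diffusion coefficient (cm^2/s). Default 2.5e-5.
#' @param intracellular_slowdown Factor by which diffusivity is divided at
#'   cell-occupied sites. Default 1.5.
#' @param r_k Oxygen supply coefficient at boundary-mask sites
#'   (concentration units per second). The scaled oxygen field is invariant to
#'   its absolute value. Default 1.
#' @param phi_k Oxygen consumption rate at viable-cell sites (1/s).
#'   Default 0.02, giving a consumption length sqrt((d_oxygen /
#'   intracellular_slowdown) / phi_k) of roughly 290 micrometres.
#' @param h Oxygen scaling factor: the maximum site maps to `h` percent.
#'   Default 100.
#' @param hypoxia_threshold Scaled-oxygen level (percent) at or below which a
#'   cell is classified as hypoxic. Default 10.
#' @param g1df_a1,g1df_a2,g1df_a3 Coefficients of the middle branch of the G1
#'   delay factor. Defaults 0.9209, 0.8200, -0.2389.
#' @param drug_half_life In vivo drug half-life (hours). Default 6.
#' @param dose_to_supply Linear coefficient mapping a daily dose label in
#'   mg/kg to the supply amplitude applied at boundary-mask sites during the
#'   administration window (micromolar per hour per mg/kg). This is the
#'   bioavailability calibration knob of the spheroid model. Default 0.15.
#' @param nu_monolayer Maximum daughter-placement neighbourhood order in
#'   monolayer mode. Default `Inf` (clipped at the lattice edge).
#' @param nu_spheroid Maximum daughter-placement neighbourhood order in
#'   spheroid mode. Default 3.
#' @param slow_drug_in_cells Should the intracellular slowdown factor also be
#'   applied to the drug diffusivity? Default TRUE.
#'
#' @return An object of class `abm_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$theta_g1 * p$mu   # hours a tau = 24 h cell spends in G1 under normoxia
#' @export
model_params <- function(mu = 24, sigma = 0.5, pi_ds = 0.75,
                         theta_g1 = 11 / 24, theta_s = 8 / 24,
                         theta_g2m = 5 / 24, theta_ds = 0.03,
                         ec50 = 1, gamma = 2, emax = 1,
                         d_oxygen = 2.5e-5, intracellular_slowdown = 1.5,
                         r_k = 1, phi_k = 0.02, h = 100,
                         hypoxia_threshold = 10,
                         g1df_a1 = 0.9209, g1df_a2 = 0.8200,
                         g1df_a3 = -0.2389,
                         drug_half_life = 6, dose_to_supply = 0.15,
                         nu_monolayer = Inf, nu_spheroid = 3,
                         slow_drug_in_cells = TRUE) {
  p <- as.list(environment())
  stopifnot(mu > 0, sigma >= 0, ec50 > 0, gamma > 0,
            theta_ds >= 0, phi_k >= 0, r_k >= 0, d_oxygen > 0,
            intracellular_slowdown >= 1, drug_half_life > 0,
            hypoxia_threshold >= 0, nu_spheroid >= 1, dose_to_supply >= 0)
  if (pi_ds < 0 || pi_ds > 1) stop("pi_ds must be a probability in [0, 1]")
  if (emax <= 0 || emax > 1) stop("emax must lie in (0, 1]")
  if (abs(theta_g1 + theta_s + theta_g2m - 1) > 1e-9)
    stop("theta_g1 + theta_s + theta_g2m must equal 1 (D-S time is additional)")
  class(p) <- "abm_params"
  p
}

#' @export
print.abm_params <- function(x, ...) {
  cat("Model parameters (in vitro-calibrated defaults)\n")
  cat(sprintf("  doubling time: N(mu = %g h, sigma = %g h); Pi_DS = %g\n",
              x$mu, x$sigma, x$pi_ds))
  cat(sprintf("  phase fractions: G1 %.4f, S %.4f, G2/M %.4f, D-S %.3f\n",
              x$theta_g1, x$theta_s, x$theta_g2m, x$theta_ds))
  cat(sprintf("  Emax model: EC50 = %g uM, gamma = %g, Emax = %g\n",
              x$ec50, x$gamma, x$emax))
  cat(sprintf("  oxygen: D = %g cm^2/s (/%g in cells), phi_K = %g /s, h = %g\n",
              x$d_oxygen, x$intracellular_slowdown, x$phi_k, x$h))
  cat(sprintf("  drug: D = %g cm^2/s, half-life %g h\n",
              drug_diffusivity(x$d_oxygen), x$drug_half_life))
  invisible(x)
}

#' Simulation configuration
#'
#' Assembles and validates the run-level settings of an in silico experiment:
#' lattice geometry, time discretisation, treatment trigger, dosing, output
#' cadence and replicate count. Monolayer mode models one cell per agent on a
#' homogeneous, well-oxygenated lattice with no field dynamics; spheroid mode
#' models cell groups on a physically spaced lattice with oxygen and drug
#' reaction-diffusion, quiescence, hypoxic G1 delay and dead-agent removal.
#'
#' @param mode `"monolayer"` or `"spheroid"`.
#' @param lattice_size Number of lattice points per side. Defaults: 100
#'   (monolayer), 1000 (spheroid).
#' @param lattice_spacing Lattice spacing in cm. Monolayer mode is unitless
#'   (one cell diameter) and ignores this; spheroid default is 40 micrometres
#'   (0.004 cm).
#' @param dt Agent time step in hours. Default 0.1, resolving the shortest
#'   phase (theta_ds * mu, about 0.72 h).
#' @param total_time Simulated time (hours) after the treatment trigger fires.
#'   Defaults: 72 (monolayer), 336 (spheroid, 14 days).
#' @param treatment_trigger Population size (cell count, monolayer; default
#'   1000) or extrapolated volume (cm^3, spheroid; default 0.25, the midpoint
#'   of the 0.2-0.3 cm^3 in vivo treatment-start range) at which treatment
#'   starts.
#' @param dose A [dose_descriptor()]; defaults to an untreated control of the
#'   matching mode.
#' @param n_replicates Replicates per experiment. Default 100.
#' @param seed Master seed; replicate i runs with `seed + i - 1`.
#' @param record_dt Output cadence in hours. Defaults: 1 (monolayer),
#'   6 (spheroid).
#' @param record_growth Record the pre-treatment growth phase (at the same
#'   cadence, negative times relative to treatment)? Default FALSE.
#' @param record_fields Keep oxygen/drug field snapshots at output times
#'   (spheroid mode)? Default FALSE.
#' @param nu Override for the daughter-placement neighbourhood order
#'   (default: `nu_monolayer` or `nu_spheroid` from the parameters).
#' @param max_growth_time Abort if the trigger has not fired after this many
#'   hours. Default 2000.
#' @param field_substeps Maximum explicit relaxation substeps applied to the
#'   oxygen field per agent step. Default 30.
#' @param oxygen_every Relax the oxygen field every this many agent steps.
#'   Default 1.
#' @param steady_solve_every Re-anchor the oxygen field with a direct solve of
#'   the discrete steady state every this many agent steps. Default 50.
#' @param gammah2ax_denominator `"viable"` (default: dead cells are excluded
#'   from the denominator, as in assays that gate on intact cells) or `"all"`
#'   (dead cells remain in the denominator).
#'
#' @return An object of class `abm_config`.
#' @examples
#' cfg <- simulation_config("monolayer", dose = dose_descriptor(concentration = 1),
#'                          n_replicates = 5, seed = 1)
#' cfg$treatment_trigger
#' @export
simulation_config <- function(mode = c("monolayer", "spheroid"),
                              lattice_size = NULL, lattice_spacing = NULL,
                              dt = 0.1, total_time = NULL,
                              treatment_trigger = NULL, dose = NULL,
                              n_replicates = 100, seed = 1,
                              record_dt = NULL, record_growth = FALSE,
                              record_fields = FALSE, nu = NULL,
                              max_growth_time = 2000,
                              field_substeps = 30, oxygen_every = 1,
                              steady_solve_every = 50,
                              gammah2ax_denominator = c("viable", "all")) {
  mode <- match.arg(mode)
  mono <- mode == "monolayer"
  if (is.null(lattice_size)) lattice_size <- if (mono) 100 else 1000
  if (is.null(lattice_spacing)) lattice_spacing <- if (mono) NA_real_ else 0.004
  if (is.null(total_time)) total_time <- if (mono) 72 else 336
  if (is.null(treatment_trigger)) treatment_trigger <- if (mono) 1000 else 0.25
  if (is.null(record_dt)) record_dt <- if (mono) 1 else 6
  if (is.null(dose))
    dose <- dose_descriptor(if (mono) "monolayer_step" else "spheroid_daily")
  if (is.null(nu)) nu <- NA_real_
  stopifnot(lattice_size > 0, dt > 0, total_time >= 0, n_replicates >= 1,
            treatment_trigger > 0, record_dt > 0, max_growth_time > 0,
            field_substeps >= 1, oxygen_every >= 1)
  if (!mono && (!is.finite(lattice_spacing) || lattice_spacing <= 0))
    stop("spheroid mode requires a positive lattice_spacing in cm")
  if (mono && !identical(dose$mode, "monolayer_step"))
    stop("monolayer mode requires a monolayer_step dose descriptor")
  if (!mono && !identical(dose$mode, "spheroid_daily"))
    stop("spheroid mode requires a spheroid_daily dose descriptor")
  if (abs(record_dt / dt - round(record_dt / dt)) > 1e-8)
    stop("record_dt must be an integer multiple of dt")
  cfg <- list(mode = mode, lattice_size = as.integer(lattice_size),
              lattice_spacing = lattice_spacing, dt = dt,
              total_time = total_time, treatment_trigger = treatment_trigger,
              dose = dose, n_replicates = as.integer(n_replicates),
              seed = as.integer(seed), record_dt = record_dt,
              record_growth = isTRUE(record_growth),
              record_fields = isTRUE(record_fields), nu = nu,
              max_growth_time = max_growth_time,
              field_substeps = as.integer(field_substeps),
              oxygen_every = as.integer(oxygen_every),
              steady_solve_every = as.integer(steady_solve_every),
              gammah2ax_denominator = match.arg(gammah2ax_denominator))
  class(cfg) <- "abm_config"
  cfg
}

#' @export
print.abm_config <- function(x, ...) {
  cat(sprintf("Simulation config: %s, %d x %d lattice", x$mode,
              x$lattice_size, x$lattice_size))
  if (!is.na(x$lattice_spacing))
    cat(sprintf(" (dx = %g cm)", x$lattice_spacing))
  cat(sprintf("\n  dt = %g h, %g h after trigger (%g %s), record every %g h\n",
              x$dt, x$total_time, x$treatment_trigger,
              if (x$mode == "monolayer") "cells" else "cm^3", x$record_dt))
  cat(sprintf("  dose: %s; %d replicate(s), master seed %d\n",
              format(x$dose), x$n_replicates, x$seed))
  invisible(x)
}

#' Dose descriptor
#'
#' Describes the drug exposure of an in silico experiment. In monolayer mode
#' the drug appears instantaneously and homogeneously at the treatment time at
#' the applied concentration and never decays. In spheroid mode a daily dose
#' is supplied at lattice points outside the tumour during a short
#' administration window and is eliminated with first-order kinetics.
#'
#' @param mode `"monolayer_step"` or `"spheroid_daily"`.
#' @param concentration Applied concentration (micromolar), monolayer mode.
#' @param dose_mgkg Daily dose label (mg/kg), spheroid mode; mapped to a
#'   supply amplitude by the `dose_to_supply` parameter.
#' @param n_doses Number of daily doses (spheroid). Default 14.
#' @param interval Dosing interval in hours. Default 24.
#' @param window Administration window length in hours. Default 1.
#' @return An object of class `abm_dose`.
#' @examples
#' dose_descriptor(concentration = 1)          # monolayer, 1 uM at treatment
#' dose_descriptor("spheroid_daily", dose_mgkg = 25)
#' @export
dose_descriptor <- function(mode = c("monolayer_step", "spheroid_daily"),
                            concentration = 0, dose_mgkg = 0,
                            n_doses = 14, interval = 24, window = 1) {
  mode <- match.arg(mode)
  stopifnot(concentration >= 0, dose_mgkg >= 0, n_doses >= 0,
            interval > 0, window > 0, window <= interval)
  d <- list(mode = mode, concentration = concentration,
            dose_mgkg = dose_mgkg, n_doses = as.integer(n_doses),
            interval = interval, window = window, t0 = NA_real_)
  class(d) <- "abm_dose"
  d
}

#' @export
format.abm_dose <- function(x, ...) {
  if (x$mode == "monolayer_step")
    sprintf("%g uM step at treatment", x$concentration)
  else
    sprintf("%g mg/kg daily x %d (%g h window)", x$dose_mgkg, x$n_doses,
            x$window)
}

#' @export
print.abm_dose <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
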