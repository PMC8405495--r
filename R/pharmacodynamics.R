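#' Monolayer drug concentration
#'
#' Step-function drug exposure of the monolayer model: zero everywhere before
#' the treatment time, the applied concentration everywhere at and after it.
#' There is no decay or elimination (the in vitro half-life exceeds the time
#' course of the experiment).
#'
#' @param dose A `monolayer_step` [dose_descriptor()].
#' @param t Time (hours), vectorised.
#' @param t0 Treatment time. Defaults to the `t0` recorded in `dose` (set by
#'   the engine when the treatment trigger fires).
#' @return Drug concentration (micromolar) at every lattice site at time `t`.
#' @examples
#' d <- dose_descriptor(concentration = 2)
#' monolayer_concentration(d, c(-1, 0, 72), t0 = 0)
#' @export
monolayer_concentration <- function(dose, t, t0 = dose$t0) {
  stopifnot(inherits(dose, "abm_dose"), identical(dose$mode, "monolayer_step"))
  if (is.na(t0)) stop("treatment time t0 is not set")
  ifelse(t < t0, 0, dose$concentration)
}

#' Sigmoid Emax drug effect
#'
#' Hill-type dose-effect relation `E = emax * C^gamma / (ec50^gamma +
#' C^gamma)`: zero at zero concentration, half-maximal at `C = ec50`, and
#' saturating at `emax`.
#'
#' @param C Drug concentration (micromolar), vectorised, non-negative.
#' @param ec50 Half-maximal concentration (> 0).
#' @param gamma Hill exponent (> 0).
#' @param emax Maximal effect in (0, 1].
#' @return Effect in `[0, emax]`.
#' @examples
#' emax_effect(c(0, 1, 3), ec50 = 1, gamma = 2)  # 0, 0.5, 0.9
#' @export
emax_effect <- function(C, ec50 = 1, gamma = 2, emax = 1) {
  stopifnot(ec50 > 0, gamma > 0, emax > 0, emax <= 1)
  if (any(C < 0)) stop("drug concentration must be non-negative")
  cg <- C^gamma
  out <- emax * cg / (ec50^gamma + cg)
  out[is.infinite(cg)] <- emax
  out
}

#' Repair probability under ATR inhibition
#'
#' Probability that a cell completing the damaged-S (D-S) state repairs its
#' replication-stress damage and resumes the cycle: `1 - E(C)` with `E` the
#' sigmoid Emax effect. Without drug the repair probability is 1; at
#' saturating concentration with `emax = 1` repair is completely inhibited.
#'
#' @param C Local drug concentration (micromolar), vectorised.
#' @param params An [model_params()] object (uses `ec50`, `gamma`, `emax`).
#' @return Repair probability in `[1 - emax, 1]`, non-increasing in `C`.
#' @examples
#' repair_probability(c(0, 1), model_params())  # 1, 0.5
#' @export
repair_probability <- function(C, params = model_params()) {
  1 - emax_effect(C, params$ec50, params$gamma, params$emax)
}
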