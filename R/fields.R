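#' Create a scalar concentration field
#'
#' Oxygen or drug concentration on the lattice, with a site-dependent
#' diffusivity map (diffusion is slowed by the intracellular slowdown factor
#' where a cell is present).
#'
#' @param values Matrix of concentrations (non-negative).
#' @param dx Lattice spacing in cm.
#' @param species `"oxygen"` or `"drug"`.
#' @param diffusivity Either a scalar (cm^2/s) or a matrix of the field
#'   dimensions.
#' @return An object of class `abm_field`.
#' @examples
#' f <- scalar_field(matrix(1, 11, 11), dx = 0.004, species = "oxygen",
#'                   diffusivity = 2.5e-5)
#' @export
scalar_field <- function(values, dx, species = c("oxygen", "drug"),
                         diffusivity) {
  species <- match.arg(species)
  stopifnot(is.matrix(values), nrow(values) == ncol(values), dx > 0)
  if (any(values < 0)) stop("field values must be non-negative")
  if (length(diffusivity) == 1)
    diffusivity <- matrix(diffusivity, nrow(values), ncol(values))
  if (any(diffusivity <= 0)) stop("diffusivity must be positive everywhere")
  structure(list(values = values, diffusivity = diffusivity, dx = dx,
                 species = species),
            class = "abm_field")
}

#' @export
print.abm_field <- function(x, ...) {
  cat(sprintf("%s field %d x %d (dx = %g cm), range [%g, %g]\n", x$species,
              nrow(x$values), ncol(x$values), x$dx, min(x$values),
              max(x$values)))
  invisible(x)
}

.as_grid <- function(x, n) {
  if (length(x) == 1) matrix(x, n, n) else x
}

#' One explicit finite-difference step
#'
#' Advances `dK/dt = div(D grad K) + source - sink_rate * K` by `dt` seconds
#' using a conservative flux-form update with harmonic-mean interface
#' diffusivities and zero-flux (mirror) boundaries. The step is internally
#' sub-divided to satisfy the diffusion stability bound `dx^2 / (4 max D)`
#' (0.9 safety factor) and a sink accuracy cap `sink * dt_sub <= 1e-3`.
#' Without source and sink the scheme conserves total mass to rounding error.
#'
#' @param field An [scalar_field()] object.
#' @param source Supply term (concentration per second), scalar or matrix.
#' @param sink_rate First-order removal rate (1/s), scalar or matrix.
#' @param dt Time to advance, in seconds.
#' @return The updated `abm_field`.
#' @export
fd_step <- function(field, source = 0, sink_rate = 0, dt) {
  stopifnot(inherits(field, "abm_field"), dt > 0)
  n <- nrow(field$values)
  res <- .fd_substeps_cpp(field$values, field$diffusivity,
                          .as_grid(source, n), .as_grid(sink_rate, n),
                          field$dx, dt, FALSE, 0, 0L)
  field$values <- res$values
  field
}

#' Relax a field towards its quasi-steady state
#'
#' Repeats explicit substeps at the stability limit until the per-substep
#' change falls below `tol` relative to the field maximum, or `max_steps` is
#' reached. Used to keep the oxygen field tracking its quasi-steady profile
#' between agent steps (oxygen transport is orders of magnitude faster than
#' cell dynamics).
#'
#' @inheritParams fd_step
#' @param tol Relative per-substep change at which to stop. Default 1e-6.
#' @param max_steps Substep budget.
#' @return The updated `abm_field`, with attributes `steps` and `converged`.
#' @export
relax_field <- function(field, source = 0, sink_rate = 0, tol = 1e-6,
                        max_steps = 1000L) {
  stopifnot(inherits(field, "abm_field"), max_steps >= 1)
  n <- nrow(field$values)
  res <- .fd_substeps_cpp(field$values, field$diffusivity,
                          .as_grid(source, n), .as_grid(sink_rate, n),
                          field$dx, 0, TRUE, tol, as.integer(max_steps))
  field$values <- res$values
  attr(field, "steps") <- res$steps
  attr(field, "converged") <- res$converged
  field
}

# Diffusivity map for a species given occupancy: D everywhere, divided by the
# intracellular slowdown factor at cell-occupied sites.
.diffusivity_map <- function(d_free, cellmask, slowdown) {
  d <- matrix(d_free, nrow(cellmask), ncol(cellmask))
  d[cellmask] <- d_free / slowdown
  d
}

#' Advance the oxygen field by one step
#'
#' Explicit update of the oxygen reaction-diffusion equation: supply `r_k` at
#' boundary-mask sites (outside the colony), consumption `phi_k * K` at
#' viable-cell sites, diffusion slowed inside the colony.
#'
#' @param field An oxygen [scalar_field()].
#' @param lattice An [new_lattice()] object (or occupancy matrix) from which
#'   the boundary mask and viable-cell mask are derived.
#' @param params An [model_params()] object.
#' @param dt Time to advance, in seconds.
#' @param viable Optional logical matrix marking viable (non-dead) cells;
#'   defaults to all occupied sites.
#' @return The updated `abm_field`.
#' @export
oxygen_step <- function(field, lattice, params, dt, viable = NULL) {
  occ <- if (inherits(lattice, "abm_lattice")) lattice$occ else lattice
  if (is.null(viable)) viable <- occ != 0L
  field$diffusivity <- .diffusivity_map(params$d_oxygen, viable,
                                        params$intracellular_slowdown)
  fd_step(field, source = params$r_k * .boundary_mask(occ),
          sink_rate = params$phi_k * viable, dt = dt)
}

#' Directly solve the quasi-steady oxygen profile
#'
#' Solves the steady state of the discrete oxygen equation (the same
#' harmonic-mean flux stencil and zero-flux boundaries as the explicit
#' stepper, with its time derivative set to zero) as a sparse linear system.
#' Requires at least one consuming cell, otherwise no steady state exists
#' under constant supply.
#'
#' @inheritParams oxygen_step
#' @param spacing Lattice spacing in cm; defaults to the lattice's own
#'   spacing (or 0.004 cm for a bare occupancy matrix).
#' @return An oxygen [scalar_field()] holding the steady profile.
#' @export
steady_oxygen <- function(lattice, params, viable = NULL, spacing = NULL) {
  occ <- if (inherits(lattice, "abm_lattice")) lattice$occ else lattice
  if (is.null(spacing))
    spacing <- if (inherits(lattice, "abm_lattice")) lattice$spacing else
      NA_real_
  if (is.na(spacing)) spacing <- 0.004
  if (is.null(viable)) viable <- occ != 0L
  if (!any(viable))
    stop("steady oxygen profile requires at least one viable cell")
  n <- nrow(occ)
  D <- .diffusivity_map(params$d_oxygen, viable, params$intracellular_slowdown)
  idx <- function(r, c) (c - 1L) * n + r
  hm <- function(a, b) 2 * a * b / (a + b)
  inv_dx2 <- 1 / spacing^2
  # face conductances: vertical (rows r, r+1) and horizontal (cols c, c+1)
  Dv <- hm(D[-n, , drop = FALSE], D[-1, , drop = FALSE]) * inv_dx2
  Dh <- hm(D[, -n, drop = FALSE], D[, -1, drop = FALSE]) * inv_dx2
  rv <- rep(seq_len(n - 1), n); cv <- rep(seq_len(n), each = n - 1)
  rh <- rep(seq_len(n), n - 1); ch <- rep(seq_len(n - 1), each = n)
  i <- c(idx(rv, cv), idx(rh, ch))
  j <- c(idx(rv + 1L, cv), idx(rh, ch + 1L))
  wt <- c(as.numeric(Dv), as.numeric(Dh))
  diag_mat <- matrix(params$phi_k * as.numeric(viable), n, n)
  diag_mat[-n, ] <- diag_mat[-n, ] + Dv
  diag_mat[-1, ] <- diag_mat[-1, ] + Dv
  diag_mat[, -n] <- diag_mat[, -n] + Dh
  diag_mat[, -1] <- diag_mat[, -1] + Dh
  # -div(D grad) + diag(phi cell): symmetric positive definite given at
  # least one consuming site; stored as upper triangle
  A <- Matrix::sparseMatrix(i = c(i, seq_len(n * n)),
                            j = c(j, seq_len(n * n)),
                            x = c(-wt, as.numeric(diag_mat)),
                            dims = c(n * n, n * n), symmetric = TRUE)
  b <- params$r_k * as.numeric(.boundary_mask(occ))
  K <- as.numeric(Matrix::solve(A, b))
  K[K < 0] <- 0
  scalar_field(matrix(K, n, n), dx = spacing, species = "oxygen",
               diffusivity = D)
}

#' Scale oxygen to percentages
#'
#' Divides the field by its current global maximum and multiplies by the
#' scaling factor `h`, so the best-oxygenated site maps to `h` percent. The
#' scaling is recomputed at every evaluation time.
#'
#' @param field An [scalar_field()] object or bare matrix.
#' @param h Scaling factor (default 100).
#' @return A matrix of scaled oxygen percentages.
#' @examples
#' scale_oxygen(matrix(c(1, 4, 2, 4), 2), h = 100)
#' @export
scale_oxygen <- function(field, h = 100) {
  K <- if (inherits(field, "abm_field")) field$values else field
  mx <- max(K)
  if (mx <= 0) {
    warning("all-zero oxygen field; scaled oxygen defined as 0")
    return(K * 0)
  }
  K / mx * h
}

#' Drug diffusion coefficient from the oxygen one
#'
#' Diffusivity scales with the inverse square root of molecular weight, so
#' the drug (412.512 g/mol) diffuses at `sqrt(31.998 / 412.512)` (about
#' 0.27851) times the oxygen rate (31.998 g/mol).
#'
#' @param d_oxygen Oxygen diffusion coefficient (cm^2/s).
#' @return Drug diffusion coefficient (cm^2/s).
#' @examples
#' drug_diffusivity(2.5e-5)
#' @export
drug_diffusivity <- function(d_oxygen = 2.5e-5) {
  stopifnot(d_oxygen > 0)
  d_oxygen * sqrt(31.998 / 412.512)
}

#' First-order decay constant from a half-life
#'
#' @param half_life Half-life (any time unit), > 0; `Inf` gives 0.
#' @return Decay rate `ln(2) / half_life` in the reciprocal unit.
#' @examples
#' decay_constant(6)   # per hour, for a 6 h half-life
#' @export
decay_constant <- function(half_life) {
  stopifnot(half_life > 0)
  log(2) / half_life
}

# Is `now` (hours since treatment start) inside a daily administration
# window? Dose k runs over [k * interval, k * interval + window).
.dosing_active <- function(dose, now) {
  if (dose$n_doses < 1 || now < 0) return(FALSE)
  k <- floor(now / dose$interval)
  k < dose$n_doses && (now - k * dose$interval) < dose$window
}

#' Advance the drug field by one step
#'
#' Explicit update of the drug reaction-diffusion equation: during an
#' administration window the supply amplitude is applied at boundary-mask
#' sites (outside the tumour); the drug decays everywhere with the rate
#' implied by its half-life and diffuses with the weight-scaled diffusivity
#' (slowed inside cells when `slow_drug_in_cells` is set).
#'
#' @param field A drug [scalar_field()].
#' @param lattice An [new_lattice()] object or occupancy matrix.
#' @param dosing A `spheroid_daily` [dose_descriptor()].
#' @param params An [model_params()] object.
#' @param dt Time to advance, in seconds.
#' @param now Hours since treatment start (dosing clock); negative before
#'   treatment.
#' @param viable Optional logical matrix of viable cells.
#' @return The updated `abm_field`.
#' @export
drug_step <- function(field, lattice, dosing, params, dt, now,
                      viable = NULL) {
  stopifnot(inherits(dosing, "abm_dose"),
            identical(dosing$mode, "spheroid_daily"))
  occ <- if (inherits(lattice, "abm_lattice")) lattice$occ else lattice
  if (is.null(viable)) viable <- occ != 0L
  slow <- if (isTRUE(params$slow_drug_in_cells))
    params$intracellular_slowdown else 1
  field$diffusivity <- .diffusivity_map(drug_diffusivity(params$d_oxygen),
                                        viable, slow)
  amp <- if (.dosing_active(dosing, now))
    dosing$dose_mgkg * params$dose_to_supply / 3600 else 0  # uM/s
  eta <- decay_constant(params$drug_half_life) / 3600       # 1/s
  fd_step(field, source = amp * .boundary_mask(occ), sink_rate = eta,
          dt = dt)
}
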