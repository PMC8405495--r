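#' Create an empty occupancy lattice
#'
#' Square lattice whose points are either empty (0) or hold one agent id.
#' Coordinates are 1-based `(row, col)` pairs; Moore neighbourhoods use
#' Chebyshev distance, von Neumann neighbourhoods Manhattan distance.
#'
#' @param size Number of lattice points per side.
#' @param spacing Lattice spacing in cm (`NA` for the unitless monolayer
#'   lattice, where a site is one cell diameter).
#' @param mode `"monolayer"` or `"spheroid"`.
#' @return An object of class `abm_lattice`.
#' @examples
#' lat <- new_lattice(9)
#' lat$occ[5, 5] <- 1L
#' space_available(lat, c(5, 5), 3)
#' @export
new_lattice <- function(size, spacing = NA_real_,
                        mode = c("monolayer", "spheroid")) {
  mode <- match.arg(mode)
  stopifnot(size >= 1)
  structure(list(size = as.integer(size), spacing = spacing, mode = mode,
                 occ = matrix(0L, size, size)),
            class = "abm_lattice")
}

#' @export
print.abm_lattice <- function(x, ...) {
  cat(sprintf("%s lattice %d x %d, %d occupied site(s)\n", x$mode, x$size,
              x$size, sum(x$occ != 0L)))
  invisible(x)
}

#' Sites of a neighbourhood ring
#'
#' Enumerates the lattice sites at exactly order `order` from `center`: the
#' Moore ring (Chebyshev distance = order, 8k sites in the interior) or the
#' von Neumann ring (Manhattan distance = order, 4k sites in the interior),
#' clipped at the lattice edges.
#'
#' @param center `(row, col)` coordinate, 1-based.
#' @param order Ring order, >= 1.
#' @param shape `"moore"` or `"von_neumann"`.
#' @param size Lattice side length used for edge clipping.
#' @return A two-column matrix of `(row, col)` coordinates.
#' @examples
#' nrow(neighbourhood_sites(c(5, 5), 1, "moore", 9))        # 8
#' nrow(neighbourhood_sites(c(1, 1), 1, "moore", 9))        # 3 (corner)
#' @export
neighbourhood_sites <- function(center, order, shape = c("moore", "von_neumann"),
                                size) {
  shape <- match.arg(shape)
  stopifnot(order >= 1, length(center) == 2)
  if (center[1] < 1 || center[1] > size || center[2] < 1 || center[2] > size)
    stop("center is off-lattice")
  k <- as.integer(order)
  if (shape == "moore") {
    dr <- c(rep(-k, 2 * k + 1), rep(k, 2 * k + 1), seq(-k + 1, k - 1),
            seq(-k + 1, k - 1))
    dc <- c(seq(-k, k), seq(-k, k), rep(-k, max(0, 2 * k - 1)),
            rep(k, max(0, 2 * k - 1)))
  } else {
    d <- seq(-k, k)
    w <- k - abs(d)
    dr <- c(d, d[w > 0])
    dc <- c(w, -w[w > 0])
  }
  r <- center[1] + dr
  c <- center[2] + dc
  keep <- r >= 1 & r <= size & c >= 1 & c <= size
  cbind(row = r[keep], col = c[keep])
}

#' Place a daughter agent near its parent
#'
#' Draws the neighbourhood shape for this division (Moore or von Neumann,
#' fair coin) unless given, then scans ring orders outward from the parent;
#' at the first order holding at least one free site a free site is chosen
#' uniformly at random. Lower orders are always exhausted first, which
#' produces compact, approximately circular colonies.
#'
#' @param lattice An [new_lattice()] object (or bare integer occupancy
#'   matrix).
#' @param parent `(row, col)` of the (occupied) parent.
#' @param max_order Largest ring order to scan; `Inf` scans the whole lattice
#'   (placement is still clipped at the lattice edge).
#' @param shape Optional `"moore"` or `"von_neumann"` override.
#' @return `(row, col)` of the chosen free site, or `NULL` if every ring up
#'   to `max_order` is fully occupied.
#' @examples
#' lat <- new_lattice(9); lat$occ[5, 5] <- 1L
#' set.seed(1); place_daughter(lat, c(5, 5), 3)
#' @export
place_daughter <- function(lattice, parent, max_order = Inf, shape = NULL) {
  occ <- if (inherits(lattice, "abm_lattice")) lattice$occ else lattice
  if (occ[parent[1], parent[2]] == 0L)
    stop("parent site is not occupied")
  if (is.null(shape))
    shape_code <- if (runif(1) < 0.5) 0L else 1L
  else
    shape_code <- switch(match.arg(shape, c("moore", "von_neumann")),
                         moore = 0L, von_neumann = 1L)
  mo <- if (is.finite(max_order)) as.integer(max_order) else nrow(occ)
  site <- .place_daughter_cpp(occ, parent[1], parent[2], shape_code, mo)
  if (anyNA(site)) NULL else c(row = site[1], col = site[2])
}

# TRUE at sites with at least one empty site within Chebyshev distance `order`
# (excluding the site itself is irrelevant for the query: an occupied agent's
# own site is never empty). Two-pass separable dilation of the empty mask.
.space_map <- function(occ, order) {
  empty <- occ == 0L
  n <- nrow(occ)
  f <- empty
  for (k in seq_len(order)) {
    f[seq_len(n - k), ] <- f[seq_len(n - k), ] | empty[k + seq_len(n - k), ]
    f[k + seq_len(n - k), ] <- f[k + seq_len(n - k), ] | empty[seq_len(n - k), ]
  }
  g <- f
  for (k in seq_len(order)) {
    g[, seq_len(n - k)] <- g[, seq_len(n - k)] | f[, k + seq_len(n - k)]
    g[, k + seq_len(n - k)] <- g[, k + seq_len(n - k)] | f[, seq_len(n - k)]
  }
  g
}

#' Is proliferation space reachable from a site?
#'
#' TRUE if any site within the union of order 1..`max_order` Moore and von
#' Neumann neighbourhoods of `coord` is empty. The union over orders equals
#' the Chebyshev ball of radius `max_order`, the most permissive reading of
#' the quiescence scan. G1 agents without reachable space exit to G0.
#'
#' @param lattice An [new_lattice()] object or occupancy matrix.
#' @param coord `(row, col)` of the (occupied) agent.
#' @param max_order Neighbourhood order bound; `Inf` means any empty site on
#'   the lattice counts.
#' @return Logical scalar.
#' @export
space_available <- function(lattice, coord, max_order = 3) {
  occ <- if (inherits(lattice, "abm_lattice")) lattice$occ else lattice
  if (occ[coord[1], coord[2]] == 0L) stop("agent site is not occupied")
  if (!is.finite(max_order)) return(any(occ == 0L))
  n <- nrow(occ)
  rs <- max(1, coord[1] - max_order):min(n, coord[1] + max_order)
  cs <- max(1, coord[2] - max_order):min(n, coord[2] + max_order)
  any(occ[rs, cs] == 0L)
}

# Boundary mask m(x, t): 1 exactly at empty sites with at least one empty
# first-order Moore neighbour; lattice-edge sites treat the off-lattice side
# as empty. Oxygen and drug are supplied where m = 1 ("outside the spheroid").
.boundary_mask <- function(occ) {
  n <- nrow(occ)
  empty <- occ == 0L
  pad <- matrix(TRUE, n + 2, n + 2)
  pad[2:(n + 1), 2:(n + 1)] <- empty
  nb <- matrix(FALSE, n, n)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb | pad[2:(n + 1) + dr, 2:(n + 1) + dc]
  }
  empty & nb
}

#' Boundary mask of a lattice
#'
#' Binary field that is 1 at lattice points neither occupied by an agent nor
#' completely surrounded by agents (first-order Moore adjacency; off-lattice
#' neighbours of edge sites count as empty), i.e. outside the colony
#' boundary. This is where oxygen and drug are supplied in spheroid mode.
#'
#' @param lattice An [new_lattice()] object or occupancy matrix.
#' @return A 0/1 integer matrix of the lattice dimensions.
#' @examples
#' all(boundary_mask(new_lattice(5)) == 1)
#' @export
boundary_mask <- function(lattice) {
  occ <- if (inherits(lattice, "abm_lattice")) lattice$occ else lattice
  m <- .boundary_mask(occ)
  matrix(as.integer(m), nrow(occ), ncol(occ))
}

#' Resolve timed deaths
#'
#' Agents whose post-lethal-event clock has reached their own doubling time
#' `tau` are declared dead. In spheroid mode dead agents are removed from the
#' lattice (their site is freed); in monolayer mode a dead cell keeps
#' occupying its site for the remainder of the experiment.
#'
#' @param state Integer state codes or state names, vectorised over agents.
#' @param death_clock Hours since each agent's lethal event.
#' @param tau Individual doubling times.
#' @param mode `"monolayer"` or `"spheroid"`.
#' @return A list: `state` (updated codes), `newly_dead` (indices) and
#'   `free_site` (logical: should the agent's lattice site be emptied?).
#' @export
resolve_deaths <- function(state, death_clock, tau,
                           mode = c("monolayer", "spheroid")) {
  mode <- match.arg(mode)
  code <- .state_code(state)
  idx <- which(code == .STATES[["LETHAL_PENDING"]] & death_clock >= tau)
  code[idx] <- .STATES[["DEAD"]]
  list(state = code, newly_dead = idx, free_site = mode == "spheroid")
}
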