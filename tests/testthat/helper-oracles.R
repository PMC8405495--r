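# Brute-force oracles used to cross-check lattice operations.

# All sites at exactly Chebyshev (moore) or Manhattan (von_neumann) distance
# `order` from `center`, by exhaustive enumeration with edge clipping.
brute_ring <- function(center, order, shape, size) {
  g <- expand.grid(row = seq_len(size), col = seq_len(size))
  dr <- abs(g$row - center[1])
  dc <- abs(g$col - center[2])
  d <- if (shape == "moore") pmax(dr, dc) else dr + dc
  g[d == order, , drop = FALSE]
}

# Relative L2 error of a diffused point mass against the 2-D heat kernel.
heat_kernel_error <- function(n, dx, D, t) {
  f <- scalar_field(matrix(0, n, n), dx = dx, species = "oxygen",
                    diffusivity = D)
  c0 <- (n + 1) / 2
  f$values[c0, c0] <- 1 / dx^2
  f <- fd_step(f, dt = t)
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  r2 <- ((g$i - c0) * dx)^2 + ((g$j - c0) * dx)^2
  ana <- matrix(exp(-r2 / (4 * D * t)) / (4 * pi * D * t), n, n)
  sqrt(sum((f$values - ana)^2) / sum(ana^2))
}

# Isoperimetric ratio 4*pi*A/P^2 of the occupied region, with A the occupied
# site count and P the Euclidean perimeter of the convex hull of occupied
# sites. A rasterised disc scores close to 1; ragged or dendritic colonies
# (area far below their hull) score low. Lattice-step perimeters are not
# usable here: under taxicab perimeter the square, not the disc, maximises
# the ratio.
colony_circularity <- function(occ) {
  pts <- which(occ != 0L, arr.ind = TRUE)
  A <- nrow(pts)
  h <- grDevices::chull(pts)
  hull <- pts[c(h, h[1]), , drop = FALSE]
  P <- sum(sqrt(rowSums(diff(hull)^2)))
  4 * pi * A / P^2
}
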