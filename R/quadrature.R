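# Cumulative quadrature of a function on a uniform grid.
#
# Per-interval Simpson with midpoint evaluation: over each grid cell
# [a_k, a_{k+1}] the increment is h/6 (f(a_k) + 4 f(mid) + f(a_{k+1})),
# giving O(h^4) global accuracy while keeping the running sum O(n). Used for
# the cumulative hazards in the closed-form cohort solution and the
# nondifferential prevalence formula.
cumint <- function(f, grid) {
  a <- grid[-length(grid)]
  b <- grid[-1L]
  inc <- (b - a) / 6 * (f(a) + 4 * f((a + b) / 2) + f(b))
  c(0, cumsum(inc))
}

# Cumulative Simpson when the integrand is only known as values on a refined
# grid containing the midpoints (odd indices = coarse nodes). `v` has values
# on refine_grid(domain, 2L); returns the integral at the coarse nodes.
cumint_values <- function(v, h) {
  n2 <- length(v)
  stopifnot(n2 %% 2L == 1L)
  k <- (n2 - 1L) / 2L
  lo <- v[2L * seq_len(k) - 1L]
  mid <- v[2L * seq_len(k)]
  hi <- v[2L * seq_len(k) + 1L]
  c(0, cumsum(h / 6 * (lo + 4 * mid + hi)))
}

# Quadratic refinement of a grid argmax: fit a parabola through the maximal
# point and its neighbours, return the abscissa of its vertex. Falls back to
# the grid point at the boundary or for a degenerate (flat) triple.
refine_argmax <- function(x, y) {
  j <- which.max(y)
  if (j == 1L || j == length(y)) return(x[j])
  y0 <- y[j - 1L]; y1 <- y[j]; y2 <- y[j + 1L]
  den <- y0 - 2 * y1 + y2
  if (den >= 0 || abs(den) < .Machine$double.eps * max(abs(c(y0, y1, y2)), 1)) {
    return(x[j])
  }
  x[j] + (x[j + 1L] - x[j]) * 0.5 * (y0 - y2) / den
}
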