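#' Age domain for the illness-death model
#'
#' All solvers and hazard functions in previnc operate on a closed age
#' interval \eqn{[a_0, \omega]} discretised as a uniform grid. Ages are in
#' years; \eqn{\omega} is the (finite, user-supplied) upper age by which the
#' model population is considered fully observed.
#'
#' @param a0 Lower age bound in years, `a0 >= 0`.
#' @param omega Upper age bound \eqn{\omega} in years, `omega > a0`.
#' @param step Grid spacing in years, `step > 0`. `(omega - a0)` must be an
#'   integer multiple of `step` (to within rounding), so that the grid is the
#'   closed uniform partition of `[a0, omega]`.
#' @return An object of class `age_domain`: a list with elements `a0`,
#'   `omega`, `step` and the precomputed `grid`.
#' @examples
#' dom <- age_domain(30, 100, 0.1)
#' head(dom$grid)
#' @export
age_domain <- function(a0, omega, step = 0.1) {
  stopifnot(is.numeric(a0), length(a0) == 1L, is.finite(a0),
            is.numeric(omega), length(omega) == 1L, is.finite(omega),
            is.numeric(step), length(step) == 1L, is.finite(step))
  if (a0 < 0) stop("`a0` must be nonnegative (ages in years).", call. = FALSE)
  if (omega <= a0) stop("`omega` must exceed `a0`.", call. = FALSE)
  if (step <= 0) stop("`step` must be positive.", call. = FALSE)
  n <- (omega - a0) / step
  if (abs(n - round(n)) > 1e-8 * max(1, n)) {
    stop("`omega - a0` must be an integer multiple of `step`.", call. = FALSE)
  }
  n <- as.integer(round(n))
  grid <- a0 + step * seq.int(0L, n)
  grid[n + 1L] <- omega   # guard against accumulated rounding at the top end
  structure(list(a0 = a0, omega = omega, step = step, grid = grid),
            class = "age_domain")
}

#' @export
print.age_domain <- function(x, ...) {
  cat(sprintf("<age_domain> [%g, %g] years, step %g (%d grid points)\n",
              x$a0, x$omega, x$step, length(x$grid)))
  invisible(x)
}

is_age_domain <- function(x) inherits(x, "age_domain")

# Tolerance used when checking that an evaluation age lies inside a domain.
# Adaptive ODE steppers may query hazards a hair beyond the interval ends.
domain_eps <- function(domain) 1e-6 * max(1, abs(domain$omega))

assert_in_domain <- function(a, domain, what = "age") {
  eps <- domain_eps(domain)
  bad <- a < domain$a0 - eps | a > domain$omega + eps
  if (any(bad)) {
    stop(sprintf("%s %.6g outside the domain [%g, %g].",
                 what, a[which(bad)[1L]], domain$a0, domain$omega),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Refined grid with `k` subintervals per user step (k = 2 inserts midpoints).
refine_grid <- function(domain, k = 2L) {
  n <- length(domain$grid) - 1L
  h <- domain$step / k
  g <- domain$a0 + h * seq.int(0L, n * k)
  g[n * k + 1L] <- domain$omega
  g
}
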