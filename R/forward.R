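#' Construct a prevalence curve
#'
#' An age-specific prevalence curve is a tibble with columns `age` (years,
#' strictly increasing) and `p` (prevalence in `[0, 1]`), carrying class
#' `prevalence_curve`. Solvers return this type; use this constructor for
#' external (e.g. empirical) curves.
#'
#' @param age Numeric vector of ages, strictly increasing.
#' @param p Prevalence values in `[0, 1]`, same length as `age`.
#' @return A `prevalence_curve` tibble.
#' @examples
#' prevalence_curve(0:10, seq(0, 0.1, by = 0.01))
#' @export
prevalence_curve <- function(age, p) {
  stopifnot(is.numeric(age), is.numeric(p), length(age) == length(p))
  if (anyNA(age) || anyNA(p)) stop("Ages and prevalences must not be NA.", call. = FALSE)
  if (is.unsorted(age, strictly = TRUE)) {
    stop("Ages must be strictly increasing.", call. = FALSE)
  }
  if (any(p < 0 | p > 1)) {
    stop("Prevalence values must lie in [0, 1].", call. = FALSE)
  }
  new_prevalence_curve(tibble::tibble(age = as.numeric(age), p = as.numeric(p)))
}

new_prevalence_curve <- function(df, classification = NULL) {
  out <- tibble::new_tibble(df, class = "prevalence_curve")
  if (!is.null(classification)) attr(out, "classification") <- classification
  out
}

is_prevalence_curve <- function(x) inherits(x, "prevalence_curve")

new_cohort_trajectory <- function(df) {
  tibble::new_tibble(df, class = "cohort_trajectory")
}

#' Solve the cohort system by its closed form
#'
#' The two-compartment illness-death cohort system
#' \deqn{dS/da = -(i + m_0)\,S, \qquad dC/da = i\,S - m_1\,C}
#' is linear, so the trajectory of susceptibles \eqn{S} and cases \eqn{C} has
#' an explicit solution in terms of cumulative hazards:
#' \deqn{S(a) = S_0 \exp\{-\textstyle\int_{a_0}^a (i + m_0)\},\qquad
#'       C(a) = e^{-\int_{a_0}^a m_1}\Big(C_0 +
#'              \int_{a_0}^a i(\tau) S(\tau)\, e^{\int_{a_0}^\tau m_1} d\tau\Big).}
#' All integrals are evaluated by per-interval Simpson quadrature with
#' midpoint evaluation on the solution grid (O(step^4) accuracy, O(n) cost:
#' the nested integral reuses the running cumulative hazards).
#'
#' @param incidence,m0,m1 `rate_fn` hazards: disease incidence among the
#'   nondiseased, and mortality of the nondiseased / diseased.
#' @param S0,C0 Initial counts at age `a0`, both `>= 0` with `S0 + C0 > 0`.
#' @param domain An [age_domain()].
#' @return A `cohort_trajectory` tibble with columns `age`, `S`, `C`, `N`
#'   (`N = S + C`, the living population).
#' @examples
#' dom <- age_domain(30, 100, 0.5)
#' tr <- solve_cohort_closed_form(
#'   incidence = function_rate(function(a) pmax(0, a - 30) / 2000, dom),
#'   m0 = gompertz_rate(-10.7, 0.1, dom),
#'   m1 = gompertz_rate(-10.0, 0.1, dom),
#'   S0 = 1e5, C0 = 0, domain = dom)
#' tail(tr)
#' @seealso [solve_cohort_ode()] for the adaptive numerical route,
#'   [prevalence_of()] to reduce a trajectory to its prevalence.
#' @export
solve_cohort_closed_form <- function(incidence, m0, m1, S0, C0, domain) {
  check_cohort_inputs(incidence, m0, m1, S0, C0, domain)
  g2 <- refine_grid(domain, 2L)           # user grid + midpoints
  h2 <- domain$step / 2
  # cumulative hazards on the refined grid (their own midpoints are step/4)
  H_im0 <- cumint(function(a) incidence$f(a) + m0$f(a), g2)
  H_m1 <- cumint(m1$f, g2)
  S2 <- S0 * exp(-H_im0)
  integrand <- incidence$f(g2) * S2 * exp(H_m1)
  inner <- cumint_values(integrand, domain$step)
  idx <- seq(1L, length(g2), by = 2L)     # coarse nodes inside g2
  S <- S2[idx]
  C <- exp(-H_m1[idx]) * (C0 + inner)
  S <- pmax(S, 0)
  C <- pmax(C, 0)
  new_cohort_trajectory(tibble::tibble(age = domain$grid, S = S, C = C, N = S + C))
}

#' Solve the cohort system by adaptive numerical integration
#'
#' Integrates the linear two-compartment system directly with an adaptive
#' Runge-Kutta 4(5) scheme (relative tolerance `rtol`, absolute `atol`),
#' sampling the solution on the domain grid. Serves as an independent check
#' of [solve_cohort_closed_form()] and vice versa.
#'
#' @inheritParams solve_cohort_closed_form
#' @param rtol,atol Solver tolerances.
#' @return A `cohort_trajectory` tibble (`age`, `S`, `C`, `N`).
#' @export
solve_cohort_ode <- function(incidence, m0, m1, S0, C0, domain,
                             rtol = 1e-8, atol = 1e-10) {
  check_cohort_inputs(incidence, m0, m1, S0, C0, domain)
  rhs <- function(a, y, parms) {
    i <- incidence$f(a); mu0 <- m0$f(a); mu1 <- m1$f(a)
    list(c(-(i + mu0) * y[1L], i * y[1L] - mu1 * y[2L]))
  }
  sol <- deSolve::ode(y = c(S = S0, C = C0), times = domain$grid, func = rhs,
                      parms = NULL, method = "ode45", rtol = rtol, atol = atol)
  if (nrow(sol) < length(domain$grid) || anyNA(sol)) {
    stop("Cohort ODE integration failed before reaching omega.", call. = FALSE)
  }
  S <- pmax(as.numeric(sol[, "S"]), 0)
  C <- pmax(as.numeric(sol[, "C"]), 0)
  new_cohort_trajectory(tibble::tibble(age = domain$grid, S = S, C = C, N = S + C))
}

check_cohort_inputs <- function(incidence, m0, m1, S0, C0, domain) {
  stopifnot(is_rate_fn(incidence), is_rate_fn(m0), is_rate_fn(m1),
            is_age_domain(domain),
            is.numeric(S0), length(S0) == 1L, is.finite(S0),
            is.numeric(C0), length(C0) == 1L, is.finite(C0))
  if (S0 < 0 || C0 < 0) stop("Initial counts must be nonnegative.", call. = FALSE)
  if (S0 + C0 <= 0) stop("`S0 + C0` must be positive.", call. = FALSE)
  invisible(TRUE)
}

#' Age-specific prevalence of a cohort trajectory
#'
#' Reduces a `cohort_trajectory` to its prevalence \eqn{p = C/N} where
#' `N > 0`, with the convention `p = 0` where `N = 0` (the prevalence of an
#' extinct cohort is defined as zero).
#'
#' @param traj A `cohort_trajectory` from [solve_cohort_ode()] or
#'   [solve_cohort_closed_form()].
#' @return A `prevalence_curve` tibble.
#' @export
prevalence_of <- function(traj) {
  stopifnot(inherits(traj, "cohort_trajectory") ||
              all(c("age", "C", "N") %in% names(traj)))
  p <- ifelse(traj$N > 0, traj$C / pmax(traj$N, .Machine$double.xmin), 0)
  p <- pmin(pmax(p, 0), 1)   # roundoff guard; C <= N up to machine precision
  new_prevalence_curve(tibble::tibble(age = traj$age, p = p))
}

# Right-hand side of the scalar prevalence ODE for each mortality tag.
# The M_M1 row has a removable (1-p) factor; the simplified algebraic form
# (1-p) i - p (m1 - m) avoids 0/0 as p -> 1.
prevalence_rhs <- function(incidence, mort) {
  i <- incidence$f
  switch(mort$tag,
    M_M0  = function(a, p) (1 - p) * (i(a) - (mort$m$f(a) - mort$m0$f(a))),
    M_M1  = function(a, p) (1 - p) * i(a) - p * (mort$m1$f(a) - mort$m$f(a)),
    M0_M1 = function(a, p) (1 - p) * (i(a) - p * (mort$m1$f(a) - mort$m0$f(a))),
    M0_R  = function(a, p) (1 - p) * (i(a) - p * mort$m0$f(a) * (mort$R$f(a) - 1)),
    M1_R  = function(a, p) (1 - p) * (i(a) - p * mort$m1$f(a) * (mort$R$f(a) - 1) / mort$R$f(a)),
    M_R   = function(a, p) {
      Ra <- mort$R$f(a)
      (1 - p) * (i(a) - mort$m$f(a) * p * (Ra - 1) / (p * (Ra - 1) + 1))
    })
}

#' Solve the scalar prevalence ODE
#'
#' Integrates the initial value problem for the age-specific prevalence
#' \deqn{dp/da = (1 - p)\,\{i(a) - p\,(m_1(a) - m_0(a))\},\qquad p(a_0)=p_0,}
#' or the algebraically equivalent right-hand side selected by the mortality
#' tag (see [mortality_input()]): with `m` and `m0` or `m` and `m1` the ODE
#' is linear, with `m0`/`m1`/relative-risk pairs it is of Riccati type, and
#' with `m` and `R` (the population-attributable-fraction form) it is
#' Abelian. Integration uses adaptive Runge-Kutta 4(5) sampled on the domain
#' grid.
#'
#' Solutions of a consistent problem stay in `[0, 1]`; excursions below
#' `1e-9` (roundoff) are clamped silently, larger ones raise an error since
#' they indicate inconsistent inputs (e.g. negative excess mortality
#' `m1 < m0`, for which the bound is only warned about).
#'
#' @param incidence A `rate_fn`: disease incidence per person-year.
#' @param mortality A [mortality_input()].
#' @param p0 Initial prevalence at `a0`, in `[0, 1]`.
#' @param domain An [age_domain()].
#' @param rtol,atol Solver tolerances.
#' @return A `prevalence_curve` tibble (`age`, `p`) with attribute
#'   `classification` (`"linear"`, `"riccati"` or `"abelian"`).
#' @examples
#' dom <- age_domain(30, 100, 0.1)
#' mi <- mortality_input("M0_M1",
#'                       m0 = gompertz_rate(-10.7, 0.1, dom),
#'                       m1 = gompertz_rate(-10.0, 0.1, dom))
#' i <- function_rate(function(a) pmax(0, a - 30) / 2000, dom)
#' pc <- solve_prevalence_ode(i, mi, p0 = 0, domain = dom)
#' peak_age(pc)   # local maximum near age 80
#' @export
solve_prevalence_ode <- function(incidence, mortality, p0, domain,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(is_rate_fn(incidence), is_mortality_input(mortality),
            is_age_domain(domain), is.numeric(p0), length(p0) == 1L)
  if (!is.finite(p0) || p0 < 0 || p0 > 1) {
    stop("Initial prevalence `p0` must lie in [0, 1].", call. = FALSE)
  }
  rhs <- prevalence_rhs(incidence, mortality)
  f <- function(a, y, parms) list(rhs(a, y[1L]))
  sol <- deSolve::ode(y = c(p = p0), times = domain$grid, func = f,
                      parms = NULL, method = "ode45", rtol = rtol, atol = atol)
  if (nrow(sol) < length(domain$grid) || anyNA(sol)) {
    a_fail <- domain$grid[nrow(sol) + 1L]
    stop(sprintf("Prevalence ODE integration failed near age %g.", a_fail),
         call. = FALSE)
  }
  p <- as.numeric(sol[, "p"])
  lenient <- has_negative_excess(mortality, domain$grid)
  if (lenient) {
    warning("Negative excess mortality (m1 < m0 somewhere): prevalence may ",
            "leave [0, 1]; bound enforcement downgraded to a warning.",
            call. = FALSE)
  }
  excess <- max(0, max(-p), max(p - 1))
  if (excess > 1e-9) {
    msg <- sprintf("Prevalence leaves [0, 1] by %.3g near age %g; inputs are inconsistent.",
                   excess, domain$grid[which.max(pmax(-p, p - 1))])
    if (lenient) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)
  new_prevalence_curve(tibble::tibble(age = domain$grid, p = p),
                       classification = mortality$classification)
}

#' Closed-form prevalence under nondifferential mortality
#'
#' When diseased and nondiseased share the same mortality (`m0 = m1`, the
#' nondifferential case), mortality cancels from the prevalence dynamics and
#' \deqn{p(a) = 1 - (1 - p_0)\exp\{-\textstyle\int_{a_0}^a i\}.}
#' The cumulative incidence is evaluated by Simpson quadrature on the grid.
#'
#' @inheritParams solve_prevalence_ode
#' @return A `prevalence_curve` tibble.
#' @export
closed_form_nondifferential <- function(incidence, p0, domain) {
  stopifnot(is_rate_fn(incidence), is_age_domain(domain),
            is.numeric(p0), length(p0) == 1L)
  if (!is.finite(p0) || p0 < 0 || p0 > 1) {
    stop("Initial prevalence `p0` must lie in [0, 1].", call. = FALSE)
  }
  H <- cumint(incidence$f, domain$grid)
  p <- 1 - (1 - p0) * exp(-H)
  new_prevalence_curve(tibble::tibble(age = domain$grid, p = pmin(pmax(p, 0), 1)),
                       classification = "closed_form")
}

#' Survival curve of the living population
#'
#' Under the general mortality `m`, the living population satisfies
#' \eqn{dN/da = -m N}, so \eqn{N(a) = N_0 \exp\{-\int_{a_0}^a m\}}
#' (nonincreasing). Evaluated by Simpson quadrature of the cumulative
#' hazard.
#'
#' @param m A `rate_fn`: the general mortality.
#' @param N0 Initial population size, `> 0`.
#' @param domain An [age_domain()].
#' @return A tibble with columns `age` and `N`.
#' @export
survival_curve <- function(m, N0, domain) {
  stopifnot(is_rate_fn(m), is_age_domain(domain),
            is.numeric(N0), length(N0) == 1L)
  if (!is.finite(N0) || N0 <= 0) stop("`N0` must be positive.", call. = FALSE)
  H <- cumint(m$f, domain$grid)
  tibble::tibble(age = domain$grid, N = N0 * exp(-H))
}

#' General mortality induced by a prevalence solution
#'
#' Builds the population mortality \eqn{m(a) = p(a) m_1(a) + (1-p(a)) m_0(a)}
#' as a `rate_fn`, interpolating the prevalence curve by a cubic spline.
#' Useful for reconstructing the cohort system from a scalar prevalence
#' solution, or for constructing mutually consistent mortality inputs across
#' tags.
#'
#' @param curve A `prevalence_curve`.
#' @param m0,m1 `rate_fn` mortalities of the nondiseased / diseased.
#' @param domain Optional [age_domain()]; defaults to the domain of `m0`.
#' @return A `rate_fn` of kind `"function"`.
#' @export
general_mortality_rate <- function(curve, m0, m1, domain = NULL) {
  stopifnot(is_prevalence_curve(curve) || all(c("age", "p") %in% names(curve)),
            is_rate_fn(m0), is_rate_fn(m1))
  if (is.null(domain)) domain <- m0$domain
  ps <- stats::splinefun(curve$age, curve$p, method = "natural")
  f <- function(a) {
    p <- pmin(pmax(ps(a), 0), 1)
    p * m1$f(a) + (1 - p) * m0$f(a)
  }
  function_rate(f, domain)
}

#' Age of the (local) prevalence maximum
#'
#' Locates the grid maximiser of a prevalence curve and refines it by
#' quadratic interpolation through the maximal point and its two neighbours.
#' Many chronic diseases (dementia, diabetes, rheumatic diseases) show such
#' an interior maximum: prevalence rises while incidence dominates and falls
#' at old age when excess mortality removes cases faster than they accrue.
#'
#' @param curve A `prevalence_curve` (or any tibble with `age` and `p`).
#' @return The refined age of the maximum, in years.
#' @export
peak_age <- function(curve) {
  stopifnot(all(c("age", "p") %in% names(curve)))
  refine_argmax(curve$age, curve$p)
}
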