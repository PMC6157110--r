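#' Numerical derivative of a prevalence curve
#'
#' Differentiates an age-indexed curve on its grid. `method = "central"`
#' uses second-order central differences in the interior and second-order
#' one-sided differences at the two boundary points (exact for parabolas,
#' hence exact for linear curves everywhere). `method = "spline"` fits a
#' smoothing spline (smoothness chosen by generalized cross-validation when
#' `spar` is `NULL`) and differentiates it analytically — the right choice
#' for noisy empirical curves, where raw differences amplify noise.
#'
#' @param curve A `prevalence_curve` or any tibble with columns `age` and
#'   `p`, on a grid of at least 3 points.
#' @param method `"central"` or `"spline"`.
#' @param spar Smoothing parameter passed to [stats::smooth.spline()]
#'   (spline method only); `NULL` selects it by GCV.
#' @return A tibble with columns `age`, `dp` (per year) and `boundary`
#'   (`TRUE` at the two one-sided end points for the central method).
#' @examples
#' pc <- prevalence_curve(0:50, 0.001 * (0:50))
#' differentiate_curve(pc)$dp[1:3]   # exactly 0.001
#' @export
differentiate_curve <- function(curve, method = c("central", "spline"),
                                spar = NULL) {
  stopifnot(all(c("age", "p") %in% names(curve)))
  method <- match.arg(method)
  a <- curve$age
  p <- curve$p
  n <- length(a)
  if (n < 3L) stop("Differentiation needs at least 3 grid points.", call. = FALSE)
  if (!is.null(spar) && (!is.numeric(spar) || spar < 0)) {
    stop("`spar` must be a nonnegative number.", call. = FALSE)
  }
  boundary <- c(TRUE, rep(FALSE, n - 2L), TRUE)
  if (method == "central") {
    dp <- numeric(n)
    dp[2:(n - 1L)] <- (p[3:n] - p[1:(n - 2L)]) / (a[3:n] - a[1:(n - 2L)])
    h1 <- a[2L] - a[1L]
    dp[1L] <- (-3 * p[1L] + 4 * p[2L] - p[3L]) / (2 * h1)
    hn <- a[n] - a[n - 1L]
    dp[n] <- (3 * p[n] - 4 * p[n - 1L] + p[n - 2L]) / (2 * hn)
  } else {
    fit <- if (is.null(spar)) {
      stats::smooth.spline(a, p, cv = FALSE)       # GCV
    } else {
      stats::smooth.spline(a, p, spar = spar)
    }
    dp <- stats::predict(fit, a, deriv = 1)$y
    boundary <- rep(FALSE, n)
  }
  tibble::tibble(age = a, dp = dp, boundary = boundary)
}

# i(a) solved from the prevalence ODE right-hand side, per mortality tag.
# `p`, `dp` are vectors on `a`; rates are evaluated at `a`.
incidence_formula <- function(a, p, dp, mort) {
  base <- dp / (1 - p)
  switch(mort$tag,
    M_M0  = base + (mort$m$f(a) - mort$m0$f(a)),
    M_M1  = (dp + p * (mort$m1$f(a) - mort$m$f(a))) / (1 - p),
    M0_M1 = base + p * (mort$m1$f(a) - mort$m0$f(a)),
    M0_R  = base + p * mort$m0$f(a) * (mort$R$f(a) - 1),
    M1_R  = base + p * mort$m1$f(a) * (mort$R$f(a) - 1) / mort$R$f(a),
    M_R   = {
      Ra <- mort$R$f(a)
      base + mort$m$f(a) * p * (Ra - 1) / (p * (Ra - 1) + 1)
    })
}

#' Estimate age-specific incidence from prevalence (the inverse problem)
#'
#' Inverts the scalar prevalence ODE for the incidence: given the
#' age-specific prevalence `p(a)` and two pieces of mortality information,
#' \deqn{\hat i(a) = \frac{dp/da}{1 - p} + \text{mortality term},}
#' where the mortality term depends on the tag — e.g. `p (m1 - m0)` for the
#' `M0_M1` tag, or `m * PAF(p, R)` for the `M_R` tag used with vital
#' statistics plus a relative-risk assumption. This turns cross-sectional
#' prevalence data into incidence estimates without a follow-up study; the
#' price is an ill-posed inversion (see [illposedness_experiment()]), so the
#' derivative step dominates the error for noisy curves.
#'
#' Negative estimates are retained and flagged (they diagnose inconsistent
#' mortality assumptions) unless `clip_nonnegative = TRUE`. Ages where
#' `1 - p < 1e-3` are flagged `near_singular`; `p >= 1 - 1e-9` anywhere is
#' an error naming the offending age.
#'
#' @param curve A `prevalence_curve` (or tibble with `age`, `p`).
#' @param mortality A [mortality_input()].
#' @param method,spar Derivative options, see [differentiate_curve()].
#' @param clip_nonnegative If `TRUE`, negative estimates are set to 0 (the
#'   flag still records where).
#' @return An `incidence_estimate` tibble with columns `age`, `i_hat`,
#'   `flag_negative`, `flag_near_singular`, `boundary`, and attributes
#'   `derivative_method` / `spar`.
#' @examples
#' dom <- age_domain(0, 50, 0.1)
#' pc <- closed_form_nondifferential(constant_rate(0.01, dom), 0, dom)
#' mi <- mortality_input("M_R", m = constant_rate(0.01, dom), R = 1)
#' est <- estimate_incidence(pc, mi)
#' summary(est$i_hat)   # recovers 0.01
#' @export
estimate_incidence <- function(curve, mortality, method = c("central", "spline"),
                               spar = NULL, clip_nonnegative = FALSE) {
  stopifnot(all(c("age", "p") %in% names(curve)), is_mortality_input(mortality))
  method <- match.arg(method)
  p <- curve$p
  a <- curve$age
  sing <- p >= 1 - 1e-9
  if (any(sing)) {
    stop(sprintf("Prevalence reaches 1 (within 1e-9) at age %g; the inversion is singular there.",
                 a[which(sing)[1L]]), call. = FALSE)
  }
  d <- differentiate_curve(curve, method = method, spar = spar)
  i_hat <- incidence_formula(a, p, d$dp, mortality)
  flag_negative <- i_hat < 0
  if (clip_nonnegative) i_hat <- pmax(i_hat, 0)
  out <- tibble::new_tibble(
    tibble::tibble(age = a, i_hat = i_hat,
                   flag_negative = flag_negative,
                   flag_near_singular = (1 - p) < 1e-3,
                   boundary = d$boundary),
    class = "incidence_estimate")
  attr(out, "derivative_method") <- method
  attr(out, "spar") <- spar
  attr(out, "tag") <- mortality$tag
  out
}

#' Relative-risk scenario sweep for incidence estimation
#'
#' When the relative mortality risk `R` of the diseased is unknown, the
#' incidence can be bracketed by estimating it under extreme scenarios (the
#' *sandwich principle*): because the population-attributable-fraction term
#' is increasing in `R`, the estimate under the true `R` lies pointwise
#' between the estimates under a lower and an upper scenario wherever
#' `p > 0`. The classic sweep is `R = 0.5` (disease protective — one
#' extreme), `R = 1` (no differential mortality) and `R = 5` (strong risk
#' factor — the other extreme).
#'
#' @param curve A `prevalence_curve`.
#' @param m A `rate_fn`: the general (population) mortality, as available
#'   from vital statistics.
#' @param R_values Positive relative risks, one estimate per value; output
#'   rows keep the input order.
#' @inheritParams estimate_incidence
#' @return A tibble in long format: columns `R`, `age`, `i_hat`,
#'   `flag_negative`, `flag_near_singular`, `boundary`.
#' @export
scenario_sweep <- function(curve, m, R_values, method = c("central", "spline"),
                           spar = NULL, clip_nonnegative = FALSE) {
  stopifnot(is_rate_fn(m), is.numeric(R_values), length(R_values) >= 1L)
  if (any(R_values <= 0)) stop("All relative risks must be positive.", call. = FALSE)
  method <- match.arg(method)
  purrr::map_dfr(R_values, function(R) {
    est <- estimate_incidence(curve,
                              mortality_input("M_R", m = m, R = R),
                              method = method, spar = spar,
                              clip_nonnegative = clip_nonnegative)
    dplyr::bind_cols(tibble::tibble(R = R), tibble::as_tibble(est))
  })
}
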