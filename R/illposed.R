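#' Perturb a prevalence curve by a high-frequency sine
#'
#' Adds \eqn{\varepsilon \sin(n a)} to a prevalence curve. This is the
#' canonical perturbation family for demonstrating that the
#' incidence-from-prevalence inversion is ill-posed: the perturbation is
#' uniformly small (sup distance at most \eqn{\varepsilon}) but its
#' derivative carries a factor \eqn{\varepsilon n} that the inversion cannot
#' suppress.
#'
#' @param curve A `prevalence_curve`.
#' @param epsilon Amplitude \eqn{\varepsilon \ge 0} (dimensionless).
#' @param n Angular frequency (per year), `n > 0`. The grid must resolve the
#'   oscillation: `n * step < pi` (else the sine is aliased and the
#'   perturbation on the grid misrepresents the continuous construction).
#' @return A `prevalence_curve`; errors if the perturbed values leave
#'   `[0, 1]`.
#' @export
perturb_prevalence <- function(curve, epsilon, n) {
  stopifnot(all(c("age", "p") %in% names(curve)),
            is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon),
            is.numeric(n), length(n) == 1L, is.finite(n))
  if (epsilon < 0) stop("`epsilon` must be nonnegative.", call. = FALSE)
  if (n <= 0) stop("`n` must be positive.", call. = FALSE)
  step <- min(diff(curve$age))
  if (n * step >= pi) {
    stop(sprintf("Grid step %g cannot resolve frequency n = %g (need n * step < pi).",
                 step, n), call. = FALSE)
  }
  p_pert <- curve$p + epsilon * sin(n * curve$age)
  if (any(p_pert < 0 | p_pert > 1)) {
    stop("Perturbed prevalence leaves [0, 1]; reduce `epsilon`.", call. = FALSE)
  }
  new_prevalence_curve(tibble::tibble(age = curve$age, p = p_pert))
}

#' Demonstrate the ill-posedness of the incidence inversion
#'
#' For each frequency `n`, perturbs the input prevalence by
#' \eqn{\varepsilon_n \sin(n a)} with \eqn{\varepsilon_n = n^{-1/2}}, inverts
#' both the original and the perturbed curve for the incidence, and records
#' the sup-norm distance between the two estimates. Although the data
#' perturbation shrinks (\eqn{\varepsilon_n \to 0}), the inversion error
#' grows like \eqn{\sqrt{n}\,/\,(1 - p)}: the dominant term of the perturbed
#' estimate is \eqn{\varepsilon_n n \cos(n a)/(1 - p)}, which is unbounded
#' as \eqn{n \to \infty}. The inverse problem therefore lacks continuous
#' dependence on the data (ill-posedness in the sense of Hadamard) even
#' though the forward map is perfectly stable.
#'
#' In `mode = "analytic"` (default) the perturbation's derivative
#' \eqn{\varepsilon_n n \cos(n a)} enters in closed form while the base
#' curve is differentiated numerically — this isolates the continuum
#' mechanism from finite-difference aliasing, which matters because the
#' interesting frequencies exceed what any fixed grid can resolve. In
#' `mode = "numeric"` the perturbed curve is differentiated numerically like
#' any data curve (requires `n * step < pi`). The amplitudes
#' \eqn{\varepsilon_n} can be sizeable for small `n`, so the perturbed curve
#' is treated as a mathematical object and not range-validated; the
#' supremum is restricted to ages where the base prevalence is at most 0.99.
#'
#' @param curve A `prevalence_curve`, bounded away from 1.
#' @param mortality A [mortality_input()]; the mortality terms cancel in the
#'   estimate difference up to O(epsilon), so the nondifferential choice is
#'   typical.
#' @param n_values Increasing positive frequencies; default
#'   `c(10, 40, 160, 640)` (geometric with ratio 4, so the growth law
#'   predicts the error to double step over step).
#' @param mode `"analytic"` or `"numeric"`.
#' @param epsilon Optional fixed amplitude overriding the
#'   \eqn{\varepsilon_n = n^{-1/2}} coupling (e.g. `0` to verify the null
#'   case).
#' @return A tibble with columns `n`, `epsilon_n` and `sup_error` (per
#'   person-year).
#' @examples
#' dom <- age_domain(0, 100, 0.1)
#' pc <- closed_form_nondifferential(constant_rate(0.002, dom), 0, dom)
#' mi <- mortality_input("M0_M1", m0 = constant_rate(0.01, dom),
#'                       m1 = constant_rate(0.01, dom))
#' illposedness_experiment(pc, mi)
#' @export
illposedness_experiment <- function(curve, mortality,
                                    n_values = c(10, 40, 160, 640),
                                    mode = c("analytic", "numeric"),
                                    epsilon = NULL) {
  stopifnot(all(c("age", "p") %in% names(curve)), is_mortality_input(mortality),
            is.numeric(n_values), length(n_values) >= 1L)
  mode <- match.arg(mode)
  if (any(n_values <= 0)) stop("Frequencies must be positive.", call. = FALSE)
  if (is.unsorted(n_values, strictly = TRUE)) {
    stop("`n_values` must be increasing.", call. = FALSE)
  }
  a <- curve$age
  p <- curve$p
  if (max(p) >= 1 - 1e-9) {
    stop("The base prevalence must be bounded away from 1.", call. = FALSE)
  }
  step <- min(diff(a))
  keep <- p <= 0.99     # the supremum is taken where the inversion is regular
  d_base <- differentiate_curve(curve)$dp
  i_base <- incidence_formula(a, p, d_base, mortality)
  rows <- purrr::map_dfr(n_values, function(n) {
    eps <- if (is.null(epsilon)) n^(-0.5) else epsilon
    p_pert <- p + eps * sin(n * a)
    if (mode == "analytic") {
      d_pert <- d_base + eps * n * cos(n * a)
    } else {
      if (n * step >= pi) {
        stop(sprintf("Numeric mode cannot resolve n = %g on step %g (need n * step < pi).",
                     n, step), call. = FALSE)
      }
      d_pert <- differentiate_curve(new_prevalence_curve(
        tibble::tibble(age = a, p = pmin(pmax(p_pert, 0), 1))))$dp
    }
    ok <- keep & p_pert < 1 - 1e-9
    i_pert <- incidence_formula(a[ok], p_pert[ok], d_pert[ok], mortality)
    tibble::tibble(n = n, epsilon_n = eps,
                   sup_error = max(abs(i_pert - i_base[ok])))
  })
  rows
}

#' Forward-map stability (contrast to the ill-posed inverse)
#'
#' Solves the prevalence ODE for an incidence `i` and for a perturbed
#' incidence, and returns the sup-norm distance of the two prevalence
#' curves. For incidence perturbations of sup-distance \eqn{\delta} the
#' prevalence moves by at most \eqn{O(\delta)}: the direct problem is
#' well-behaved, which is exactly what the inverse problem is not.
#'
#' @param incidence,incidence_perturbed `rate_fn` incidences.
#' @inheritParams solve_prevalence_ode
#' @return A one-row tibble with `delta_incidence` (sup distance of the
#'   inputs on the grid) and `delta_prevalence` (sup distance of the
#'   outputs).
#' @export
forward_stability <- function(incidence, incidence_perturbed, mortality, p0,
                              domain) {
  p1 <- solve_prevalence_ode(incidence, mortality, p0, domain)
  p2 <- solve_prevalence_ode(incidence_perturbed, mortality, p0, domain)
  tibble::tibble(
    delta_incidence = max(abs(eval_rate(incidence, domain$grid) -
                                eval_rate(incidence_perturbed, domain$grid))),
    delta_prevalence = max(abs(p1$p - p2$p)))
}
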