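#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a prevalence curve
#'
#' Curves are already tidy tibbles; `tidy()` strips the class and
#' attributes, returning a plain tibble.
#'
#' @param x A `prevalence_curve`.
#' @param ... Unused.
#' @return A tibble with columns `age`, `p`.
#' @method tidy prevalence_curve
#' @export
tidy.prevalence_curve <- function(x, ...) {
  tibble::tibble(age = x$age, p = x$p)
}

#' @rdname tidy.prevalence_curve
#' @method glance prevalence_curve
#' @export
glance.prevalence_curve <- function(x, ...) {
  tibble::tibble(
    n_ages = nrow(x),
    a0 = min(x$age),
    omega = max(x$age),
    p_max = max(x$p),
    age_at_max = peak_age(x),
    classification = attr(x, "classification") %||% NA_character_)
}

#' Tidy an incidence estimate
#'
#' @param x An `incidence_estimate` from [estimate_incidence()].
#' @param ... Unused.
#' @return `tidy()`: the per-age tibble (`age`, `i_hat`, flags);
#'   `glance()`: a one-row summary with the derivative method, mortality
#'   tag, and flag counts.
#' @method tidy incidence_estimate
#' @export
tidy.incidence_estimate <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.incidence_estimate
#' @method glance incidence_estimate
#' @export
glance.incidence_estimate <- function(x, ...) {
  tibble::tibble(
    n_ages = nrow(x),
    tag = attr(x, "tag") %||% NA_character_,
    derivative_method = attr(x, "derivative_method") %||% NA_character_,
    n_negative = sum(x$flag_negative),
    n_near_singular = sum(x$flag_near_singular),
    i_hat_max = max(x$i_hat))
}

#' @rdname tidy.prevalence_curve
#' @method glance cohort_trajectory
#' @export
glance.cohort_trajectory <- function(x, ...) {
  tibble::tibble(
    n_ages = nrow(x),
    N0 = x$N[1L],
    N_omega = x$N[nrow(x)],
    survival_fraction = x$N[nrow(x)] / x$N[1L],
    p_omega = if (x$N[nrow(x)] > 0) x$C[nrow(x)] / x$N[nrow(x)] else 0)
}
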