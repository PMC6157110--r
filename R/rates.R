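#' Age-dependent hazard functions
#'
#' Incidence and mortality in the illness-death model are nonnegative
#' age-dependent hazards (per person-year). Three representations are
#' supported:
#'
#' * **Gompertz**: \eqn{\lambda(a) = \exp(\beta_0 + \beta_1 a)}, the standard
#'   parametric form for adult mortality ([gompertz_rate()]);
#' * **tabulated**: piecewise-linear interpolation between `(age, value)`
#'   knots, e.g. rates read from vital statistics ([tabulated_rate()]);
#' * **function**: an arbitrary vectorised R function of age
#'   ([function_rate()], with [constant_rate()] as the degenerate
#'   age-independent case).
#'
#' Every rate carries an [age_domain()]; evaluation outside it is an error,
#' and nonnegativity is checked on the domain grid at construction.
#'
#' @param beta0 Gompertz intercept (dimensionless, log rate at age 0).
#' @param beta1 Gompertz slope (per year).
#' @param domain An [age_domain()].
#' @return An object of class `rate_fn`.
#' @examples
#' dom <- age_domain(30, 100)
#' m0 <- gompertz_rate(-10.7, 0.1, dom)
#' eval_rate(m0, 50)
#' @seealso [eval_rate()], [mortality_input()]
#' @export
gompertz_rate <- function(beta0, beta1, domain) {
  stopifnot(is.numeric(beta0), length(beta0) == 1L, is.finite(beta0),
            is.numeric(beta1), length(beta1) == 1L, is.finite(beta1),
            is_age_domain(domain))
  new_rate_fn("gompertz", function(a) exp(beta0 + beta1 * a), domain,
              params = list(beta0 = beta0, beta1 = beta1))
}

#' Tabulated hazard from (age, value) knots
#'
#' @param knots A data frame with columns `age` and `value` (rate per
#'   person-year), ages strictly increasing, values nonnegative and finite.
#' @param domain An [age_domain()]; must be covered by the knot range, since
#'   extrapolation beyond the knots is an error rather than a constant
#'   extension.
#' @return A `rate_fn` evaluating by piecewise-linear interpolation.
#' @rdname gompertz_rate
#' @export
tabulated_rate <- function(knots, domain) {
  stopifnot(is.data.frame(knots), is_age_domain(domain))
  if (!all(c("age", "value") %in% names(knots))) {
    stop("`knots` needs columns `age` and `value`.", call. = FALSE)
  }
  age <- as.numeric(knots$age)
  value <- as.numeric(knots$value)
  if (anyNA(age) || anyNA(value) || any(!is.finite(age)) || any(!is.finite(value))) {
    stop("Knot ages and values must be finite numbers.", call. = FALSE)
  }
  if (is.unsorted(age, strictly = TRUE)) {
    stop("Knot ages must be strictly increasing.", call. = FALSE)
  }
  if (any(value < 0)) {
    stop("Tabulated rates must be nonnegative.", call. = FALSE)
  }
  eps <- domain_eps(domain)
  if (age[1L] > domain$a0 + eps || age[length(age)] < domain$omega - eps) {
    stop("Knots must cover the whole age domain; extrapolation is not allowed.",
         call. = FALSE)
  }
  f <- stats::approxfun(age, value, rule = 2)  # rule 2 only absorbs roundoff at ends
  new_rate_fn("tabulated", f, domain, params = list(knots = tibble::tibble(age = age, value = value)))
}

#' Hazard from an arbitrary function of age
#'
#' @param f A vectorised function of age returning rates per person-year.
#' @rdname gompertz_rate
#' @export
function_rate <- function(f, domain) {
  stopifnot(is.function(f), is_age_domain(domain))
  new_rate_fn("function", f, domain)
}

#' Constant (age-independent) hazard
#'
#' @param value Rate per person-year, `value >= 0`.
#' @rdname gompertz_rate
#' @export
constant_rate <- function(value, domain) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (value < 0) stop("A constant rate must be nonnegative.", call. = FALSE)
  force(value)
  new_rate_fn("constant", function(a) rep_len(value, length(a)), domain,
              params = list(value = value))
}

new_rate_fn <- function(kind, f, domain, params = list()) {
  # nonnegativity is validated by sampling on the domain grid at construction
  v <- f(domain$grid)
  if (anyNA(v) || any(!is.finite(v))) {
    stop("Rate evaluates to a non-finite value on the domain grid.", call. = FALSE)
  }
  if (any(v < 0)) {
    stop(sprintf("Rate is negative at age %g; hazards must be nonnegative.",
                 domain$grid[which(v < 0)[1L]]), call. = FALSE)
  }
  structure(list(kind = kind, f = f, domain = domain, params = params),
            class = "rate_fn")
}

is_rate_fn <- function(x) inherits(x, "rate_fn")

#' Evaluate a hazard at given ages
#'
#' @param rate A `rate_fn` (see [gompertz_rate()]).
#' @param a Numeric vector of ages (years); must lie within the rate's domain.
#' @return Numeric vector of rates per person-year.
#' @examples
#' dom <- age_domain(0, 100)
#' eval_rate(gompertz_rate(0, 0, dom), 50)   # exp(0) = 1
#' @export
eval_rate <- function(rate, a) {
  stopifnot(is_rate_fn(rate), is.numeric(a))
  assert_in_domain(a, rate$domain)
  rate$f(a)
}

#' @export
print.rate_fn <- function(x, ...) {
  cat(sprintf("<rate_fn> kind = %s on [%g, %g]\n",
              x$kind, x$domain$a0, x$domain$omega))
  if (x$kind == "gompertz") {
    cat(sprintf("  exp(%g + %g * age)\n", x$params$beta0, x$params$beta1))
  }
  invisible(x)
}

#' General (population) mortality as a prevalence-weighted mixture
#'
#' The overall mortality of a population is the convex combination of the
#' mortality of the nondiseased, `m0`, and of the diseased, `m1`, weighted by
#' the prevalence `p`: \eqn{m = p\,m_1 + (1-p)\,m_0}.
#'
#' @param p Prevalence value(s) in `[0, 1]`.
#' @param m0,m1 Nonnegative hazards (per person-year); vectors recycle.
#' @return The mixed hazard, lying between `min(m0, m1)` and `max(m0, m1)`.
#' @examples
#' general_mortality(0.5, 0.01, 0.03)  # 0.02
#' @export
general_mortality <- function(p, m0, m1) {
  stopifnot(is.numeric(p), is.numeric(m0), is.numeric(m1))
  if (any(p < 0 | p > 1, na.rm = FALSE)) {
    stop("Prevalence `p` must lie in [0, 1].", call. = FALSE)
  }
  if (any(m0 < 0) || any(m1 < 0)) {
    stop("Mortality rates must be nonnegative.", call. = FALSE)
  }
  p * m1 + (1 - p) * m0
}

#' Attributable fractions
#'
#' `eaf()` is the exposition attributable fraction \eqn{(R-1)/R} and `paf()`
#' the population attributable fraction \eqn{p(R-1)/(p(R-1)+1)}, where `R` is
#' the relative mortality risk of the diseased versus the nondiseased and `p`
#' the prevalence. A protective exposure (`R < 1`) gives negative fractions.
#'
#' @param R Relative risk, `R > 0`.
#' @param p Prevalence in `[0, 1]`.
#' @return Fraction(s); `paf(p, R) <= eaf(R)` whenever `R >= 1`, with
#'   equality at `p = 1`.
#' @examples
#' eaf(2)        # 0.5
#' paf(0.5, 2)   # 1/3
#' @export
eaf <- function(R) {
  stopifnot(is.numeric(R))
  if (any(R <= 0)) stop("Relative risk `R` must be positive.", call. = FALSE)
  (R - 1) / R
}

#' @rdname eaf
#' @export
paf <- function(p, R) {
  stopifnot(is.numeric(p), is.numeric(R))
  if (any(p < 0 | p > 1)) stop("Prevalence `p` must lie in [0, 1].", call. = FALSE)
  if (any(R <= 0)) stop("Relative risk `R` must be positive.", call. = FALSE)
  den <- p * (R - 1) + 1
  if (any(den <= 0)) {
    stop("PAF denominator p(R-1)+1 must be positive.", call. = FALSE)
  }
  p * (R - 1) / den
}

# ---- mortality information ------------------------------------------------

MORTALITY_TAGS <- c("M_M0", "M_M1", "M0_M1", "M0_R", "M1_R", "M_R")

ODE_CLASS <- c(M_M0 = "linear", M_M1 = "linear", M0_M1 = "riccati",
               M0_R = "riccati", M1_R = "riccati", M_R = "abelian")

#' Mortality information for the prevalence ODE
#'
#' Two pieces of mortality information determine the right-hand side of the
#' scalar prevalence ODE. Six combinations are supported, each selecting a
#' different algebraic form and ODE class:
#'
#' | tag     | given                  | ODE class |
#' |---------|------------------------|-----------|
#' | `M_M0`  | general `m` and `m0`   | linear    |
#' | `M_M1`  | general `m` and `m1`   | linear    |
#' | `M0_M1` | `m0` and `m1`          | Riccati   |
#' | `M0_R`  | `m0` and relative risk | Riccati   |
#' | `M1_R`  | `m1` and relative risk | Riccati   |
#' | `M_R`   | `m` and relative risk  | Abelian   |
#'
#' @param tag One of `"M_M0"`, `"M_M1"`, `"M0_M1"`, `"M0_R"`, `"M1_R"`,
#'   `"M_R"`.
#' @param m,m0,m1 `rate_fn` hazards as required by the tag: `m` is the
#'   general (population) mortality, `m0`/`m1` the mortality of the
#'   nondiseased/diseased.
#' @param R Relative risk \eqn{m_1/m_0}: a positive scalar (age-constant) or
#'   a `rate_fn`-like function of age with positive values.
#' @param domain Optional [age_domain()]; defaults to the domain of the first
#'   supplied rate.
#' @return An object of class `mortality_input` with the tag, the component
#'   functions, and the ODE classification.
#' @examples
#' dom <- age_domain(30, 100)
#' mi <- mortality_input("M0_M1",
#'                       m0 = gompertz_rate(-10.7, 0.1, dom),
#'                       m1 = gompertz_rate(-10.0, 0.1, dom))
#' mi$classification
#' @export
mortality_input <- function(tag, m = NULL, m0 = NULL, m1 = NULL, R = NULL,
                            domain = NULL) {
  tag <- match.arg(tag, MORTALITY_TAGS)
  need <- switch(tag,
                 M_M0  = c("m", "m0"),
                 M_M1  = c("m", "m1"),
                 M0_M1 = c("m0", "m1"),
                 M0_R  = c("m0", "R"),
                 M1_R  = c("m1", "R"),
                 M_R   = c("m", "R"))
  have <- list(m = m, m0 = m0, m1 = m1, R = R)
  for (nm in need) {
    if (is.null(have[[nm]])) {
      stop(sprintf("Tag %s requires component `%s`.", tag, nm), call. = FALSE)
    }
  }
  extra <- setdiff(names(have)[!vapply(have, is.null, logical(1))], need)
  if (length(extra)) {
    stop(sprintf("Tag %s does not use component(s): %s.",
                 tag, paste(extra, collapse = ", ")), call. = FALSE)
  }
  rates <- have[need]
  first_rate <- rates[[which(vapply(rates, is_rate_fn, logical(1)))[1L]]]
  if (is.null(domain)) domain <- first_rate$domain
  # constant R is represented as a degenerate age-independent function so all
  # six tags share the same evaluation contract
  if (!is.null(R)) {
    if (is.numeric(R) && length(R) == 1L) {
      if (!is.finite(R) || R <= 0) {
        stop("Relative risk `R` must be a positive number.", call. = FALSE)
      }
      Rv <- R
      R <- new_rate_fn("constant", function(a) rep_len(Rv, length(a)), domain,
                       params = list(value = Rv))
    } else if (is_rate_fn(R)) {
      if (any(eval_rate(R, domain$grid) <= 0)) {
        stop("Relative risk `R(a)` must be positive on the whole domain.",
             call. = FALSE)
      }
    } else {
      stop("`R` must be a positive scalar or a rate_fn.", call. = FALSE)
    }
  }
  for (nm in c("m", "m0", "m1")) {
    x <- get(nm)
    if (!is.null(x) && !is_rate_fn(x)) {
      stop(sprintf("`%s` must be a rate_fn.", nm), call. = FALSE)
    }
  }
  structure(list(tag = tag, m = m, m0 = m0, m1 = m1, R = R, domain = domain,
                 classification = unname(ODE_CLASS[tag])),
            class = "mortality_input")
}

is_mortality_input <- function(x) inherits(x, "mortality_input")

#' @export
print.mortality_input <- function(x, ...) {
  cat(sprintf("<mortality_input> tag %s (%s ODE)\n", x$tag, x$classification))
  invisible(x)
}

# True when the tag M0_M1 carries negative excess mortality somewhere; the
# chronic-disease theory assumes m1 >= m0, but the ODE remains integrable.
has_negative_excess <- function(mort, grid) {
  if (mort$tag != "M0_M1") return(FALSE)
  any(eval_rate(mort$m1, grid) < eval_rate(mort$m0, grid))
}
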