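#' Individual-level illness-death microsimulation
#'
#' Simulates `N0` individuals through the three-state illness-death model:
#' everyone enters nondiseased at age `a0`; the waiting time to the first
#' event is drawn from the combined hazard `i + m0` by inversion of the
#' cumulative hazard (tabulated on a fine grid and interpolated linearly —
#' deterministic cost, no rejection loops even for steep Gompertz tails);
#' at the event age the competing risks split with probability
#' `i/(i + m0)` into disease onset versus death; diseased individuals draw
#' their residual lifetime from `m1` by the same inversion. Individuals
#' still alive at `omega` are censored there.
#'
#' The generator consumes a fixed block of three uniforms per individual
#' from one root-seeded stream, so increasing `N0` reproduces the earlier
#' individuals bit-identically, and the same seed always yields the same
#' records.
#'
#' @param incidence,m0,m1 `rate_fn` hazards.
#' @param N0 Number of individuals, `>= 1`.
#' @param domain An [age_domain()].
#' @param seed Integer seed (mandatory: simulations are reproducible by
#'   contract).
#' @param hazard_step Tabulation step (years) for the cumulative-hazard
#'   inversion.
#' @return A tibble with one row per individual: `onset_age` (NA if never
#'   diseased), `death_age` (NA if alive at `omega`), and `final_state`
#'   (one of `"nondiseased"`, `"diseased"`, `"dead_nondiseased"`,
#'   `"dead_diseased"`).
#' @examples
#' dom <- age_domain(30, 100, 0.5)
#' rec <- simulate_cohort(constant_rate(0.01, dom),
#'                        gompertz_rate(-10.7, 0.1, dom),
#'                        gompertz_rate(-10.0, 0.1, dom),
#'                        N0 = 1000, domain = dom, seed = 1)
#' table(rec$final_state)
#' @export
simulate_cohort <- function(incidence, m0, m1, N0, domain, seed,
                            hazard_step = 0.01) {
  stopifnot(is_rate_fn(incidence), is_rate_fn(m0), is_rate_fn(m1),
            is_age_domain(domain),
            is.numeric(N0), length(N0) == 1L, N0 >= 1,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  N0 <- as.integer(N0)
  gf <- seq(domain$a0, domain$omega, by = hazard_step)
  if (gf[length(gf)] < domain$omega) gf <- c(gf, domain$omega)
  H0 <- cumint(function(a) incidence$f(a) + m0$f(a), gf)
  H1 <- cumint(m1$f, gf)
  if (any(!is.finite(H0)) || any(!is.finite(H1))) {
    stop("Non-finite cumulative hazard; check the rate functions.", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  u <- matrix(stats::runif(3L * N0), ncol = 3L, byrow = TRUE)

  inv_haz <- function(H, target) {
    # first age at which the cumulative hazard reaches `target`
    stats::approx(H, gf, xout = target, ties = min)$y
  }
  e1 <- -log(u[, 1L])
  has_event <- e1 < H0[length(H0)]
  t_event <- rep(NA_real_, N0)
  if (any(has_event)) t_event[has_event] <- inv_haz(H0, e1[has_event])

  onset_age <- rep(NA_real_, N0)
  death_age <- rep(NA_real_, N0)
  state <- rep("nondiseased", N0)

  if (any(has_event)) {
    te <- t_event[has_event]
    i_e <- incidence$f(te)
    tot <- i_e + m0$f(te)
    pr_disease <- ifelse(tot > 0, i_e / tot, 0)
    becomes_case <- u[has_event, 2L] < pr_disease
    idx <- which(has_event)
    case_idx <- idx[becomes_case]
    dead_idx <- idx[!becomes_case]
    death_age[dead_idx] <- t_event[dead_idx]
    state[dead_idx] <- "dead_nondiseased"
    if (length(case_idx)) {
      onset_age[case_idx] <- t_event[case_idx]
      # residual lifetime under the diseased mortality, conditional on onset
      tgt <- stats::approx(gf, H1, xout = t_event[case_idx], ties = min)$y -
        log(u[case_idx, 3L])
      dies <- tgt < H1[length(H1)]
      die_idx <- case_idx[dies]
      if (any(dies)) death_age[die_idx] <- inv_haz(H1, tgt[dies])
      state[die_idx] <- "dead_diseased"
      state[case_idx[!dies]] <- "diseased"
    }
  }
  tibble::tibble(
    onset_age = onset_age,
    death_age = death_age,
    final_state = factor(state, levels = c("nondiseased", "diseased",
                                           "dead_nondiseased", "dead_diseased")))
}

#' Empirical age-specific prevalence of simulated individuals
#'
#' At each grid age the numerator counts individuals alive and already
#' diseased, the denominator all individuals alive; the prevalence of an
#' empty risk set is 0 by convention. Wilson score intervals give 95%
#' binomial bounds.
#'
#' @param records A tibble from [simulate_cohort()].
#' @param age_grid Numeric vector of ages at which to evaluate.
#' @return A tibble with columns `age`, `p_hat`, `n_alive`, `ci_low`,
#'   `ci_high`.
#' @export
empirical_prevalence <- function(records, age_grid) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("onset_age", "death_age") %in% names(records)),
            is.numeric(age_grid))
  z <- stats::qnorm(0.975)
  res <- purrr::map_dfr(age_grid, function(a) {
    alive <- is.na(records$death_age) | records$death_age > a
    n <- sum(alive)
    k <- sum(alive & !is.na(records$onset_age) & records$onset_age <= a)
    if (n == 0L) {
      return(tibble::tibble(age = a, p_hat = 0, n_alive = 0L,
                            ci_low = 0, ci_high = 0))
    }
    ph <- k / n
    den <- 1 + z^2 / n
    centre <- (ph + z^2 / (2 * n)) / den
    half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
    tibble::tibble(age = a, p_hat = ph, n_alive = n,
                   ci_low = max(0, centre - half),
                   ci_high = min(1, centre + half))
  })
  res
}

# Deterministic t1d_like prevalence template: the qualitative age profile of
# a chronic disease of early onset — steep rise from birth to ~15, plateau
# around 15-20, second rise to 30, plateau by 35, peak prevalence a few per
# 1000. Synthetic: calibrated to shape only, not to any restricted dataset.
t1d_template_fun <- function() {
  knots_age <- c(0, 3, 6, 9, 12, 15, 17.5, 20, 23, 26, 30, 32.5, 35)
  knots_p <- c(0, 0.0004, 0.0009, 0.0014, 0.0019, 0.0023, 0.00245, 0.0025,
               0.0029, 0.0034, 0.0040, 0.00405, 0.0041)
  stats::splinefun(knots_age, knots_p, method = "monoH.FC")
}

#' Synthetic noisy prevalence fixture
#'
#' Generates an age-specific prevalence curve from a smooth deterministic
#' template plus binomial-scale sampling noise, for exercising the inverse
#' problem on data-like input. The `"t1d_like"` template emulates the
#' qualitative shape of type-1-diabetes prevalence in young women (steep
#' rise to about age 15, plateau to 20, second rise to 30, plateau by 35,
#' peak a few per 1000); it is entirely synthetic. A `"custom"` template
#' interpolates user-supplied knots monotonically.
#'
#' @param template `"t1d_like"` or `"custom"`.
#' @param knots For `"custom"`: data frame with columns `age`, `p`.
#' @param noise_sd_scale Multiplier on the binomial standard deviation
#'   `sqrt(p(1-p)/n_eff)`; `0` returns the deterministic template exactly.
#' @param n_eff Effective per-age sample size behind the noise model.
#' @param seed Integer seed (mandatory when `noise_sd_scale > 0`).
#' @param domain An [age_domain()]; default ages 0 to 35 by 0.5 years.
#' @return A `prevalence_curve` with attribute `p_template` holding the
#'   noiseless template values.
#' @examples
#' fx <- make_noisy_prevalence_fixture(seed = 1)
#' plot(fx$age, fx$p, type = "l")
#' @export
make_noisy_prevalence_fixture <- function(template = c("t1d_like", "custom"),
                                          knots = NULL, noise_sd_scale = 1,
                                          n_eff = 1e5, seed = NULL,
                                          domain = age_domain(0, 35, 0.5)) {
  template <- match.arg(template)
  stopifnot(is.numeric(noise_sd_scale), length(noise_sd_scale) == 1L,
            noise_sd_scale >= 0, is_age_domain(domain))
  f <- if (template == "t1d_like") {
    t1d_template_fun()
  } else {
    if (is.null(knots) || !all(c("age", "p") %in% names(knots))) {
      stop("Custom template needs `knots` with columns `age` and `p`.", call. = FALSE)
    }
    stats::splinefun(knots$age, knots$p, method = "monoH.FC")
  }
  p0 <- pmin(pmax(f(domain$grid), 0), 1)
  p <- p0
  if (noise_sd_scale > 0) {
    if (is.null(seed)) stop("A `seed` is required when noise is added.", call. = FALSE)
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
    sd <- noise_sd_scale * sqrt(p0 * (1 - p0) / n_eff)
    p <- pmin(pmax(p0 + stats::rnorm(length(p0), 0, sd), 0), 1)
  }
  out <- new_prevalence_curve(tibble::tibble(age = domain$grid, p = p))
  attr(out, "p_template") <- p0
  attr(out, "template") <- template
  out
}
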