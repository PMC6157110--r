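test_that("zero rates freeze the cohort and constant incidence decays S exponentially", {
  dom <- age_domain(0, 10, 0.1)
  z <- constant_rate(0, dom)
  tr <- solve_cohort_closed_form(z, z, z, S0 = 1000, C0 = 10, domain = dom)
  expect_equal(tr$S, rep(1000, nrow(tr)))
  expect_equal(tr$C, rep(10, nrow(tr)))
  tr2 <- solve_cohort_closed_form(constant_rate(0.02, dom), z, z,
                                  S0 = 1000, C0 = 0, domain = dom)
  expect_equal(tr2$S[nrow(tr2)], 1000 * exp(-0.2), tolerance = 1e-10)
  expect_error(solve_cohort_closed_form(z, z, z, 0, 0, dom), "positive")
})

test_that("closed-form and adaptive cohort solutions agree (mutual oracles)", {
  ex <- example1_setup()
  cf <- solve_cohort_closed_form(ex$incidence, ex$m0, ex$m1, 1e5, 0, ex$domain)
  od <- solve_cohort_ode(ex$incidence, ex$m0, ex$m1, 1e5, 0, ex$domain)
  expect_lt(sup_norm(cf$S, od$S) / max(od$S), 1e-6)
  expect_lt(sup_norm(cf$C, od$C) / max(od$C), 1e-6)
  expect_lt(sup_norm(cf$N, od$N) / max(od$N), 1e-6)
  # trajectory invariants: nonnegative, N = S + C, N nonincreasing
  for (tr in list(cf, od)) {
    expect_true(all(tr$S >= 0) && all(tr$C >= 0))
    expect_equal(tr$N, tr$S + tr$C, tolerance = 1e-9)
    expect_true(all(diff(tr$N) <= 1e-9 * max(tr$N)))
  }
})

test_that("equal constant mortalities give pure exponential population decay", {
  dom <- age_domain(0, 20, 0.1)
  mu <- constant_rate(0.03, dom)
  tr <- solve_cohort_ode(constant_rate(0, dom), mu, mu, 500, 500, dom)
  expect_equal(tr$N, 1000 * exp(-0.03 * (tr$age)), tolerance = 1e-8)
})

test_that("prevalence_of applies C/N with the empty-population convention", {
  tr <- tibble::tibble(age = 0:3, S = c(10, 5, 0, 0), C = c(0, 5, 4, 0))
  tr$N <- tr$S + tr$C
  p <- prevalence_of(tr)
  expect_equal(p$p, c(0, 0.5, 1, 0))   # p = 1 when S = 0, C > 0; p = 0 when N = 0
  ex <- example1_setup()
  tr2 <- solve_cohort_ode(ex$incidence, ex$m0, ex$m1, 1e5, 0, ex$domain)
  p2 <- prevalence_of(tr2)
  expect_true(all(p2$p >= 0 & p2$p <= 1))
})

test_that("the prevalence ODE reproduces the nondifferential closed form", {
  dom <- age_domain(0, 10, 0.1)
  nd <- mortality_input("M0_M1", m0 = constant_rate(0.01, dom),
                        m1 = constant_rate(0.01, dom))
  p0c <- solve_prevalence_ode(constant_rate(0, dom), nd, 0, dom)
  expect_equal(p0c$p, rep(0, nrow(p0c)))
  pc <- solve_prevalence_ode(constant_rate(0.01, dom), nd, 0, dom)
  expect_equal(pc$p[nrow(pc)], 1 - exp(-0.1), tolerance = 1e-8)
  expect_equal(attr(pc, "classification"), "riccati")
  expect_error(solve_prevalence_ode(constant_rate(0.01, dom), nd, 1.5, dom),
               "\\[0, 1\\]")
})

test_that("the worked example peaks near age 80", {
  ex <- example1_setup()
  pc <- solve_prevalence_ode(ex$incidence, ex$mortality, 0, ex$domain)
  pk <- peak_age(pc)
  expect_gt(pk, 75)
  expect_lt(pk, 85)
  # an interior local maximum: prevalence falls after the peak
  expect_lt(pc$p[nrow(pc)], max(pc$p))
})

test_that("closed_form_nondifferential handles the degenerate initial conditions", {
  dom <- age_domain(0, 10, 0.1)
  expect_equal(closed_form_nondifferential(constant_rate(0, dom), 0.3, dom)$p,
               rep(0.3, 101))
  expect_equal(closed_form_nondifferential(constant_rate(0.05, dom), 1, dom)$p,
               rep(1, 101))
  p <- closed_form_nondifferential(constant_rate(0.01, dom), 0, dom)
  expect_equal(p$p[101], 1 - exp(-0.1), tolerance = 1e-12)
})

test_that("survival_curve matches exponential decay and an ODE oracle", {
  dom <- age_domain(0, 10, 0.1)
  expect_equal(survival_curve(constant_rate(0, dom), 100, dom)$N, rep(100, 101))
  expect_equal(survival_curve(constant_rate(0.1, dom), 1, dom)$N[101], exp(-1),
               tolerance = 1e-10)
  dom2 <- age_domain(30, 100, 0.1)
  m <- gompertz_rate(-10.0, 0.1, dom2)
  sc <- survival_curve(m, 1e5, dom2)
  oracle <- deSolve::ode(y = c(N = 1e5), times = dom2$grid,
                         func = function(a, y, p) list(-m$f(a) * y),
                         parms = NULL, method = "ode45",
                         rtol = 1e-11, atol = 1e-12)
  expect_equal(sc$N, as.numeric(oracle[, "N"]), tolerance = 1e-8)
  expect_true(all(diff(sc$N) <= 0))
  expect_error(survival_curve(m, 0, dom2), "positive")
})

test_that("all six mortality-information variants produce the same prevalence", {
  ex <- example1_setup()
  ref <- solve_prevalence_ode(ex$incidence, ex$mortality, 0, ex$domain)
  m <- general_mortality_rate(ref, ex$m0, ex$m1)
  R <- exp(-10.0 - (-10.7))    # m1/m0 is age-constant for shared slope
  variants <- list(
    mortality_input("M_M0", m = m, m0 = ex$m0),
    mortality_input("M_M1", m = m, m1 = ex$m1),
    mortality_input("M0_R", m0 = ex$m0, R = R),
    mortality_input("M1_R", m1 = ex$m1, R = R),
    mortality_input("M_R", m = m, R = R))
  for (mi in variants) {
    p <- solve_prevalence_ode(ex$incidence, mi, 0, ex$domain)
    expect_lt(sup_norm(p$p, ref$p), 1e-6)
  }
})

test_that("correspondence holds in both directions for random smooth inputs", {
  set.seed(1)
  for (k in 1:4) {
    cfg <- random_config()
    S0 <- 1e5 * (1 - cfg$p0); C0 <- 1e5 * cfg$p0
    tr <- solve_cohort_ode(cfg$incidence, cfg$m0, cfg$m1, S0, C0, cfg$domain)
    # system -> scalar: prevalence of the trajectory solves the scalar ODE
    p_sys <- prevalence_of(tr)
    p_sca <- solve_prevalence_ode(cfg$incidence, cfg$mortality, cfg$p0, cfg$domain)
    expect_lt(sup_norm(p_sys$p, p_sca$p), 1e-6)
    # scalar -> system: S = (1-p) N and C = p N solve the cohort system
    m <- general_mortality_rate(p_sca, cfg$m0, cfg$m1)
    N <- survival_curve(m, 1e5, cfg$domain)$N
    expect_lt(sup_norm((1 - p_sca$p) * N, tr$S) / max(tr$S), 1e-5)
    expect_lt(sup_norm(p_sca$p * N, tr$C) / max(max(tr$C), 1), 1e-5)
  }
})

test_that("prevalence solutions stay in [0,1] for random nonnegative rates", {
  set.seed(2)
  for (k in 1:20) {
    cfg <- random_config()
    p <- solve_prevalence_ode(cfg$incidence, cfg$mortality, cfg$p0, cfg$domain)
    expect_true(all(p$p >= -1e-9 & p$p <= 1 + 1e-9))
  }
})

test_that("pointwise-larger incidence yields pointwise-larger prevalence", {
  dom <- age_domain(0, 60, 0.2)
  nd <- mortality_input("M0_M1", m0 = gompertz_rate(-10, 0.1, dom),
                        m1 = gompertz_rate(-10, 0.1, dom))
  set.seed(3)
  for (k in 1:5) {
    b <- runif(1, 0.001, 0.01)
    p_lo <- solve_prevalence_ode(constant_rate(b, dom), nd, 0, dom)
    p_hi <- solve_prevalence_ode(function_rate(function(a) b + 0.002 + 1e-4 * a, dom),
                                 nd, 0, dom)
    expect_true(all(p_hi$p - p_lo$p >= -1e-10))
  }
})

test_that("negative excess mortality is permitted with a warning", {
  dom <- age_domain(0, 50, 0.1)
  mi <- mortality_input("M0_M1", m0 = constant_rate(0.02, dom),
                        m1 = constant_rate(0.01, dom))
  expect_warning(solve_prevalence_ode(constant_rate(0.01, dom), mi, 0, dom),
                 "excess mortality")
})
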