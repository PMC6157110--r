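test_that("numerical differentiation is exact for linear curves and accurate for smooth ones", {
  pc <- prevalence_curve(seq(0, 50, by = 0.5), 0.001 * seq(0, 50, by = 0.5))
  d <- differentiate_curve(pc)
  expect_equal(d$dp, rep(0.001, nrow(d)), tolerance = 1e-12)
  pc2 <- prevalence_curve(0:20, rep(0.3, 21))
  expect_equal(differentiate_curve(pc2)$dp, rep(0, 21))
  a <- seq(0, 3, by = 0.01)
  pc3 <- prevalence_curve(a, (sin(a) + 1.5) / 10)
  d3 <- differentiate_curve(pc3)
  expect_lt(sup_norm(d3$dp, cos(a) / 10), 1e-4)
  expect_true(all(d3$boundary == c(TRUE, rep(FALSE, length(a) - 2), TRUE)))
  expect_error(differentiate_curve(prevalence_curve(0:1, c(0, 0.1))), "3 grid points")
})

test_that("estimate_incidence inverts the prevalence ODE formulas", {
  dom <- age_domain(0, 40, 0.1)
  # flat prevalence with nondifferential mortality: no incidence
  flat <- prevalence_curve(dom$grid, rep(0.2, length(dom$grid)))
  nd <- mortality_input("M0_M1", m0 = constant_rate(0.01, dom),
                        m1 = constant_rate(0.01, dom))
  est0 <- estimate_incidence(flat, nd)
  expect_equal(est0$i_hat, rep(0, nrow(est0)))
  # closed-form curve for constant incidence, inverted with R = 1
  pc <- closed_form_nondifferential(constant_rate(0.01, dom), 0, dom)
  mi <- mortality_input("M_R", m = constant_rate(0.01, dom), R = 1)
  est <- estimate_incidence(pc, mi)
  expect_lt(sup_norm(est$i_hat, rep(0.01, nrow(est))), 1e-4)
  expect_equal(attr(est, "derivative_method"), "central")
})

test_that("the inverse recovers the worked example's incidence (round trip)", {
  ex <- example1_setup()
  pc <- solve_prevalence_ode(ex$incidence, ex$mortality, 0, ex$domain)
  est <- estimate_incidence(pc, ex$mortality)
  inner <- est$age >= 31 & est$age <= 99
  i_true <- pmax(0, est$age - 30) / 2000
  expect_lt(sup_norm(est$i_hat[inner], i_true[inner]), 1e-4)
})

test_that("near-singular prevalence is flagged and p = 1 is an error", {
  dom <- age_domain(0, 10, 0.5)
  nd <- mortality_input("M0_M1", m0 = constant_rate(0, dom),
                        m1 = constant_rate(0, dom))
  hi <- prevalence_curve(dom$grid, seq(0.99905, 0.9995, length.out = length(dom$grid)))
  est <- estimate_incidence(hi, nd)
  expect_true(all(est$flag_near_singular))
  sing <- prevalence_curve(dom$grid, c(rep(0.5, length(dom$grid) - 1), 1))
  expect_error(estimate_incidence(sing, nd), "age 10")
})

test_that("negative estimates are flagged, and clipped only on request", {
  dom <- age_domain(0, 20, 0.5)
  nd <- mortality_input("M0_M1", m0 = constant_rate(0, dom),
                        m1 = constant_rate(0, dom))
  falling <- prevalence_curve(dom$grid, 0.3 - 0.01 * dom$grid)
  est <- estimate_incidence(falling, nd)
  expect_true(all(est$flag_negative))
  expect_true(all(est$i_hat < 0))
  clipped <- estimate_incidence(falling, nd, clip_nonnegative = TRUE)
  expect_true(all(clipped$i_hat == 0))
  expect_true(all(clipped$flag_negative))
})

test_that("all six mortality variants give identical incidence estimates when consistent", {
  ex <- example1_setup()
  pc <- solve_prevalence_ode(ex$incidence, ex$mortality, 0, ex$domain)
  m <- general_mortality_rate(pc, ex$m0, ex$m1)
  R <- exp(0.7)
  ref <- estimate_incidence(pc, ex$mortality)
  variants <- list(
    mortality_input("M_M0", m = m, m0 = ex$m0),
    mortality_input("M_M1", m = m, m1 = ex$m1),
    mortality_input("M0_R", m0 = ex$m0, R = R),
    mortality_input("M1_R", m1 = ex$m1, R = R),
    mortality_input("M_R", m = m, R = R))
  for (mi in variants) {
    expect_lt(sup_norm(estimate_incidence(pc, mi)$i_hat, ref$i_hat), 1e-8)
  }
})

test_that("round-trip error decreases as the grid is refined", {
  err_at <- function(step) {
    ex <- example1_setup(step)
    pc <- solve_prevalence_ode(ex$incidence, ex$mortality, 0, ex$domain)
    est <- estimate_incidence(pc, ex$mortality)
    inner <- est$age >= 31 & est$age <= 99
    sup_norm(est$i_hat[inner], pmax(0, est$age[inner] - 30) / 2000)
  }
  expect_lt(err_at(0.1), err_at(1.0))
})

test_that("scenario sweep obeys the sandwich principle and the R = 1 identity", {
  ex <- example1_setup()
  pc <- solve_prevalence_ode(ex$incidence, ex$mortality, 0, ex$domain)
  m <- general_mortality_rate(pc, ex$m0, ex$m1)
  sw <- scenario_sweep(pc, m, c(0.5, 2, 5))
  expect_equal(unique(sw$R), c(0.5, 2, 5))
  wide <- tidyr::pivot_wider(sw[, c("R", "age", "i_hat")],
                             names_from = "R", values_from = "i_hat")
  pos <- pc$p > 0
  # estimates are pointwise nondecreasing in R: the R = 2 curve is sandwiched
  expect_true(all(wide$`2`[pos] >= wide$`0.5`[pos] - 1e-12))
  expect_true(all(wide$`2`[pos] <= wide$`5`[pos] + 1e-12))
  # R = 1 removes the mortality correction entirely
  est1 <- scenario_sweep(pc, m, 1)
  d <- differentiate_curve(pc)
  expect_equal(est1$i_hat, d$dp / (1 - pc$p))
  # a zero-prevalence curve makes every scenario identical
  zero <- prevalence_curve(ex$domain$grid, rep(0, length(ex$domain$grid)))
  sw0 <- scenario_sweep(zero, m, c(0.5, 1, 5))
  w0 <- tidyr::pivot_wider(sw0[, c("R", "age", "i_hat")],
                           names_from = "R", values_from = "i_hat")
  expect_equal(w0$`0.5`, w0$`5`)
  expect_error(scenario_sweep(pc, m, c(1, -2)), "positive")
})

test_that("smoothing-spline inversion beats raw differences on noisy fixtures", {
  fx <- make_noisy_prevalence_fixture(seed = 7)
  template <- prevalence_curve(fx$age, attr(fx, "p_template"))
  dom <- age_domain(0, 35, 0.5)
  mi <- mortality_input("M_R", m = constant_rate(0.001, dom), R = 1)
  i_ref <- estimate_incidence(template, mi)$i_hat
  err_central <- sup_norm(estimate_incidence(fx, mi, method = "central")$i_hat, i_ref)
  err_spline <- sup_norm(estimate_incidence(fx, mi, method = "spline")$i_hat, i_ref)
  expect_lt(err_spline, err_central)
})

test_that("tidy and glance summarise estimates and curves", {
  ex <- example1_setup()
  pc <- solve_prevalence_ode(ex$incidence, ex$mortality, 0, ex$domain)
  g <- glance(pc)
  expect_equal(g$classification, "riccati")
  expect_equal(g$age_at_max, peak_age(pc))
  est <- estimate_incidence(pc, ex$mortality)
  ge <- glance(est)
  expect_equal(ge$tag, "M0_M1")
  expect_equal(ge$derivative_method, "central")
  expect_s3_class(tidy(est), "tbl_df")
  expect_false(inherits(tidy(pc), "prevalence_curve"))
})
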