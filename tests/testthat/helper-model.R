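# Shared model configurations for the test suite.

# The worked slope-field example: Gompertz mortalities, incidence ramping up
# linearly after age 30, cohort starting disease-free at 30.
example1_setup <- function(step = 0.1) {
  dom <- age_domain(30, 100, step)
  m0 <- gompertz_rate(-10.7, 0.1, dom)
  m1 <- gompertz_rate(-10.0, 0.1, dom)
  i <- function_rate(function(a) pmax(0, a - 30) / 2000, dom)
  list(domain = dom, m0 = m0, m1 = m1, incidence = i,
       mortality = mortality_input("M0_M1", m0 = m0, m1 = m1))
}

# Random smooth nonnegative rate configuration with nonnegative excess
# mortality (m1 = R * m0, R >= 1), for property-style checks. Uses Gompertz
# forms so all rates are smooth and the relative risk is age-constant.
random_config <- function(step = 0.25) {
  dom <- age_domain(30, 90, step)
  b0_i <- stats::runif(1, -7, -5)
  b1_i <- stats::runif(1, 0, 0.04)
  b0_m <- stats::runif(1, -11, -9)
  b1_m <- stats::runif(1, 0.08, 0.11)
  R <- stats::runif(1, 1, 3)
  m0 <- gompertz_rate(b0_m, b1_m, dom)
  m1 <- gompertz_rate(b0_m + log(R), b1_m, dom)
  list(domain = dom,
       incidence = gompertz_rate(b0_i, b1_i, dom),
       m0 = m0, m1 = m1, R = R,
       mortality = mortality_input("M0_M1", m0 = m0, m1 = m1),
       p0 = stats::runif(1, 0, 0.2))
}

sup_norm <- function(x, y) max(abs(x - y))
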