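test_that("gamma kernel: onset, zero at dosing, argmax at t_i + p*tau", {
  expect_equal(gamma_kernel(c(0, 4, 7.999), 8, 0.3, 15), c(0, 0, 0))
  expect_equal(gamma_kernel(8, 8, 0.3, 15), 0)    # power-law prefactor
  expect_equal(gamma_kernel(8, 8, 0, 15), 1)      # pure exponential kernel

  for (pars in list(c(0.3, 15), c(0.1, 2), c(0.8, 15))) {
    amax <- stats::optimize(function(t) -gamma_kernel(t, 8, pars[1], pars[2]),
                            c(8, 60))$minimum
    expect_equal(amax, 8 + pars[1] * pars[2], tolerance = 1e-5)
  }
})

test_that("normalization constant matches the incomplete-gamma closed form", {
  # single dose, horizon far beyond the kernel: tau^(p+1) Gamma(p+1)
  for (pars in list(c(0.3, 2), c(0.1, 1.5), c(0.8, 0.5), c(0, 1))) {
    p <- pars[1]; tau <- pars[2]
    sched <- administration_schedule(1, 1 + 60 * tau)
    expect_equal(normalization_constant(sched, p, tau),
                 tau^(p + 1) * gamma(p + 1), tolerance = 1e-8)
  }
  # truncated horizon: lower incomplete gamma oracle via pgamma
  sched <- administration_schedule(c(8, 10, 12, 14, 16), 17)
  oracle <- sum(15^(1.3) * gamma(1.3) *
                  stats::pgamma((17 - c(8, 10, 12, 14, 16)) / 15, 1.3))
  expect_equal(normalization_constant(sched, 0.3, 15), oracle,
               tolerance = 1e-10)
  # k identical untruncated windows scale linearly
  one <- normalization_constant(administration_schedule(0, 200), 0.3, 2)
  four <- normalization_constant(
    administration_schedule(c(0, 1, 2, 3) * 1e-9, 200), 0.3, 2)
  expect_equal(four, 4 * one, tolerance = 1e-8)
  expect_error(administration_schedule(numeric(0), 17), "empty")
})

test_that("normalized profiles release unit total drug over the horizon", {
  sched <- administration_schedule()
  for (pars in list(c(0.3, 15), c(0.1, 2), c(0.8, 15))) {
    prof <- normalize_profile(release_profile(pars[1], pars[2]), sched)
    total <- sum(vapply(sched$dose_times, function(ti) {
      stats::integrate(function(t) profile_value(prof, t, ti), ti,
                       sched$horizon, rel.tol = 1e-11)$value
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("profiles are invariant to the time unit after rate conversion", {
  rho <- 0.35
  sched_d <- administration_schedule(c(8, 10, 12, 14, 16), 17)
  sched_t <- administration_schedule(c(8, 10, 12, 14, 16) * rho, 17 * rho)
  prof_d <- normalize_profile(release_profile(0.3, 15), sched_d)
  prof_t <- normalize_profile(release_profile(0.3, 15 * rho), sched_t)
  for (t_day in c(9, 11.5, 14.2, 16.9)) {
    # a rate per unit dimensionless time converts to a rate per day by rho
    expect_equal(profile_value(prof_t, t_day * rho, 8 * rho) * rho,
                 profile_value(prof_d, t_day, 8), tolerance = 1e-10)
  }
})

test_that("vascular carrier concentration is a unit-step exponential", {
  expect_equal(vessel_concentration(7.9, 8, 15), 0)
  expect_equal(vessel_concentration(8, 8, 15), 1)
  expect_equal(vessel_concentration(8 + 15, 8, 15), exp(-1))
})

test_that("uptake needs vasculature and declines past the efficiency peak", {
  p <- lung
  expect_equal(uptake_rate(array(0, c(2, 2, 2)), 1, p),
               array(0, c(2, 2, 2)))
  expect_equal(uptake_rate(1, 1, p), 0.8 * exp(-0.25))
  # dense abnormal vasculature (m* = 1.97) delivers less than normal (m = 1)
  expect_lt(uptake_rate(1.9696, 1, p), uptake_rate(1, 1, p))
})

test_that("release rate sums profile-weighted carriers", {
  sched <- administration_schedule()
  prof <- normalize_profile(release_profile(0.3, 15), sched)
  z <- array(0, c(3, 3, 3)); one <- z + 1

  expect_equal(release_rate(5, list(), prof, sched), 0)   # before first dose
  expect_equal(release_rate(12, list(one), prof, sched),
               z + profile_value(prof, 12, 8))
  # two doses, distinct carriers: term-by-term hand evaluation at day 12
  hand <- 0.4 * profile_value(prof, 12, 8) + 1.5 * profile_value(prof, 12, 10)
  expect_equal(release_rate(12, list(0.4 * one, 1.5 * one), prof, sched),
               z + hand)
  # an absent agent contributes exactly zero
  expect_equal(release_rate(12, list(one, one), NULL, sched), z)
  expect_error(release_rate(12, rep(list(one), 6), prof, sched),
               "more carrier fields than scheduled doses")
  expect_error(profile_value(release_profile(0.3, 15), 12, 8),
               "not normalized")
})

test_that("free-drug reactions have the expected steady states", {
  p <- lung
  # pure decay without release
  expect_equal(rhs_c(2, 0, p), -p$nuC_t * 2)
  expect_equal(rhs_d(2, 0, 0, p), -p$nuD_t * 2)
  expect_equal(rhs_c(0, 1, p), 1300)
  # homogeneous steady states annihilate the reactions
  R <- 0.07
  c_star <- p$lambdaC_t * R / p$nuC_t
  expect_equal(rhs_c(c_star, R, p), 0)
  for (m in c(0, 0.5, 1, 1.97)) {
    d_star <- p$lambdaD_t * R / (p$mu_t * m + p$nuD_t)
    expect_equal(rhs_d(d_star, R, m, p), 0, tolerance = 1e-12)
  }
  # trapping: steady-state free chemo decreases strictly with vessel density
  d_star <- function(m) p$lambdaD_t * R / (p$mu_t * m + p$nuD_t)
  ms <- seq(0, 3, by = 0.1)
  expect_true(all(diff(d_star(ms)) < 0))
  # vascular collapse from m* = 1.97 to 1 roughly doubles retained drug
  expect_equal(d_star(1.97) / d_star(1), (0.1 + 8) / (0.1 + 8 * 1.97),
               tolerance = 1e-12)
})
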