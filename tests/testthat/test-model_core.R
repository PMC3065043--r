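test_that("reaction terms vanish at the known homogeneous states", {
  p <- lung
  z <- array(0, dim = c(4, 4, 4))
  one <- z + 1

  # extinction and carrying-capacity states of the tumour field
  expect_equal(rhs_n(z, z, z, p), z)
  expect_equal(rhs_n(one, 0 * one, 0 * one, p), 0 * one)

  # vessel-free, normal (m = 1) and unstable (m = 1/2) vasculature states,
  # uncoupled from the tumour
  p0 <- model_params(alpha2_t = 0, .defaults = p)
  expect_equal(rhs_m(z, z, z, p0), z)
  expect_equal(rhs_m(z, one, 0 * one, p0), 0 * one)
  expect_equal(max(abs(rhs_m(z, one / 2, 0 * one, p0))), 0)
})

test_that("coupled fixed points annihilate both reaction terms", {
  p <- lung
  roots <- vasculature_fixed_points(p)
  for (m_star in roots) {
    n_star <- tumor_fixed_point(m_star, p$alpha1_t)
    z <- array(0, dim = c(3, 3, 3))
    expect_lt(max(abs(rhs_n(z + n_star, z + m_star, z, p))), 1e-10)
    expect_lt(max(abs(rhs_m(z + n_star, z + m_star, z, p))), 1e-10)
  }
})

test_that("fixed points match the printed values and a polynomial oracle", {
  p <- lung  # alpha1 = 1.1, alpha2 = 0.9
  roots <- vasculature_fixed_points(p)
  # agreement with the printed pair (0.02, 1.97) to one unit in the last
  # printed digit (the exact lower root is 0.0254)
  expect_lt(max(abs(roots - c(0.02, 1.97))), 0.01)
  expect_equal(roots, c(0.02538568, 1.96961432), tolerance = 1e-7)

  # oracle: numeric roots of the literal steady-state polynomial
  # alpha + alpha2 + (beta + alpha1 alpha2) m + gamma m^2 = 0
  for (pars in list(c(1.1, 0.9), c(0.7, 0.95), c(1.05, 0.99))) {
    pp <- model_params(alpha1_t = pars[1], alpha2_t = pars[2],
                       .defaults = p)
    z <- polyroot(c(pp$alpha_t + pp$alpha2_t,
                    pp$beta_t + pp$alpha1_t * pp$alpha2_t, pp$gamma_t))
    oracle <- sort(Re(z))
    expect_equal(vasculature_fixed_points(pp), oracle, tolerance = 1e-10)
  }

  # a negative quadratic root (alpha2 > 1) is reported as the vessel-free
  # branch m = 0, which is itself a fixed point of the full dynamics
  strong <- model_params(alpha1_t = 1.5, alpha2_t = 1.2, .defaults = p)
  rs <- vasculature_fixed_points(strong)
  expect_equal(rs[1], 0)
  z <- array(0, dim = c(2, 2, 2))
  expect_equal(rhs_m(z + 1, z + rs[1], z, strong), z)

  # uncoupled cubic: nonzero stationary states at 1/2 and 1
  expect_equal(vasculature_fixed_points(model_params(alpha2_t = 0,
                                                     .defaults = p)),
               c(0.5, 1.0))
  # alpha2 = 1 collapses the discriminant's constant part: roots 0, (3+a1)/2
  expect_equal(vasculature_fixed_points(model_params(alpha2_t = 1,
                                                     .defaults = p)),
               c(0, 2.05))

  # non-canonical cubic coefficients route through the numeric solver
  pg <- model_params(alpha_t = -1.2, beta_t = 3.4, gamma_t = -2.2,
                     .defaults = p)
  rg <- vasculature_fixed_points(pg)
  resid <- pg$alpha_t + pg$alpha2_t +
    (pg$beta_t + pg$alpha1_t * pg$alpha2_t) * rg + pg$gamma_t * rg^2
  expect_lt(max(abs(resid)), 1e-10)

  # with nonnegative couplings and the canonical cubic the discriminant is
  # always positive; a vanishing quadratic coefficient (general cubic
  # route) can leave no real nontrivial state
  expect_error(
    vasculature_fixed_points(model_params(beta_t = 0.1, alpha2_t = 0,
                                          .defaults = p)),
    class = "nt_no_fixed_points")
})

test_that("tumour fixed point is the vasculature-shifted carrying capacity", {
  expect_equal(tumor_fixed_point(0, 1.1), 1)
  expect_equal(tumor_fixed_point(1.9696, 1.1), 3.16656)
  expect_equal(tumor_fixed_point(c(0.5, 2), 0), c(1, 1))
})

test_that("stability classification matches the uncoupled analysis", {
  st <- fixed_point_stability(model_params(alpha2_t = 0, .defaults = lung))
  # rows: m* = 0, 1/2, 1
  expect_equal(st$m_star, c(0, 0.5, 1))
  expect_equal(st$stable, c(TRUE, FALSE, TRUE))

  st2 <- fixed_point_stability(lung)
  expect_true(st2$stable[st2$m_star > 1])   # upper branch stable
  expect_false(st2$stable[abs(st2$m_star - 0.0254) < 1e-3])
})

test_that("delivery efficiency is unimodal with the documented maxima", {
  expect_equal(delivery_efficiency(0, 2), 0)
  expect_equal(delivery_efficiency(0, 2, "max_at_one"), 0)
  expect_equal(delivery_efficiency(1, 2), exp(-0.25))

  for (form in c("as_printed", "max_at_one")) {
    argmax <- stats::optimize(function(m) -delivery_efficiency(m, 2, form),
                              c(0, 6))$minimum
    expected <- if (form == "as_printed") 2 / sqrt(2) else 1
    expect_equal(argmax, expected, tolerance = 1e-5)
    # strictly increasing below the maximum, strictly decreasing above
    lo <- delivery_efficiency(seq(0, expected, length.out = 40), 2, form)
    hi <- delivery_efficiency(seq(expected, 8, length.out = 40), 2, form)
    expect_true(all(diff(lo) > 0))
    expect_true(all(diff(hi) < 0))
  }
})

test_that("field contracts are enforced", {
  z <- array(0, dim = c(3, 3, 3))
  expect_error(rhs_n(z, array(0, dim = c(2, 2, 2)), z, lung),
               "shape mismatch")
  expect_error(rhs_n(z - 1, z, z, lung), "negative")
  expect_error(model_params(mu_t = -1), "nonnegative")
  expect_error(model_params(m_lim = 0), "strictly positive")
})
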