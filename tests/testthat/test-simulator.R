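test_that("no-flux Laplacian is exact on quadratics and conserves mass", {
  g <- sim_grid(10, h = 0.25)
  np <- g$npts
  ax <- seq_len(np) * g$h
  f <- array(rep(ax^2, times = np * np), dim = c(np, np, np))  # f = x^2
  lap <- laplacian_noflux(f, g$h)
  expect_equal(lap[3:(np - 2), , ], array(2, dim = c(np - 4, np, np)))

  expect_equal(laplacian_noflux(array(3.7, c(6, 6, 6)), 0.5),
               array(0, c(6, 6, 6)))

  set.seed(42)
  r <- array(runif(np^3), dim = c(np, np, np))
  expect_lt(abs(sum(laplacian_noflux(r, g$h))),
            1e-10 * sqrt(sum(r^2)))
  expect_error(laplacian_noflux(matrix(1, 3, 3), 0.5), "3D")
})

test_that("initial state: deterministic seed, unit-peak seed, uniform vessels", {
  g <- smoke_grid()
  s1 <- initialize_state(g, lung, seed = 7)
  s2 <- initialize_state(g, lung, seed = 7)
  expect_identical(s1, s2)

  centre <- (g$npts + 1) / 2
  expect_equal(max(s1$n), 1)
  expect_equal(s1$n[13, 13, 13], 1)  # npts = 25: centre voxel
  expect_true(all(s1$n >= 0))
  expect_equal(max(s1$c), 0)
  expect_equal(length(s1$carriers), 0)

  # mean of 125,000 iid uniforms concentrates tightly around 1/2
  g50 <- sim_grid(50, h = 0.5)
  for (seed in 1:3) {
    m <- initialize_state(g50, lung, seed = seed)$m
    expect_lt(abs(mean(m) - 0.5), 0.005)
    expect_gte(min(m), 0); expect_lte(max(m), 1)
  }
})

test_that("a uniform coupled fixed point is stationary under stepping", {
  g <- tiny_grid()
  m_star <- vasculature_fixed_points(lung)[2]
  st <- uniform_state(g, tumor_fixed_point(m_star, lung$alpha1_t), m_star)
  arm <- build_arm("V")
  dt <- 0.002
  out <- step(st, dt, arm, lung, g)
  expect_lt(max(abs(out$n - st$n)), dt * 1e-10)
  expect_lt(max(abs(out$m - st$m)), dt * 1e-10)
  expect_equal(max(out$c), 0); expect_equal(max(out$d), 0)
})

test_that("one Euler step reproduces the hand-built update", {
  g <- tiny_grid()
  set.seed(11)
  np <- g$npts
  st <- initialize_state(g, lung, seed = 3)
  st$n <- array(runif(np^3, 0, 2), dim = dim(st$n))
  st$c <- array(runif(np^3, 0, 1), dim = dim(st$n))
  st$d <- array(runif(np^3, 0, 1), dim = dim(st$n))
  st$carriers <- list(array(runif(np^3), dim = dim(st$n)),
                      array(runif(np^3), dim = dim(st$n)))
  st$t <- days_to_dimensionless(12, unit_system(lung$rho, lung$D1))

  arm <- build_arm("NC_CD")
  dt <- 0.002
  out <- step(st, dt, arm, lung, g)

  day <- 12
  doses <- arm$schedule$dose_times[1:2]
  R_C <- release_rate(day, st$carriers, arm$profile_C, arm$schedule)
  R_D <- release_rate(day, st$carriers, arm$profile_D, arm$schedule)
  exp_n <- pmax(st$n + dt * (laplacian_noflux(st$n, g$h) +
    rhs_n(st$n, st$m, st$d, lung, chemo_active = TRUE)), 0)
  exp_m <- pmax(st$m + dt * (lung$D2_t * laplacian_noflux(st$m, g$h) +
    rhs_m(st$n, st$m, st$c, lung, anti_active = TRUE)), 0)
  exp_c <- pmax(st$c + dt * (lung$D3_t * laplacian_noflux(st$c, g$h) +
    rhs_c(st$c, R_C, lung)), 0)
  exp_d <- pmax(st$d + dt * (lung$D4_t * laplacian_noflux(st$d, g$h) +
    rhs_d(st$d, R_D, st$m, lung)), 0)
  exp_C1 <- st$carriers[[1]] + dt *
    uptake_rate(st$m, vessel_concentration(day, doses[1]), lung)

  expect_equal(out$n, exp_n, tolerance = 1e-13)
  expect_equal(out$m, exp_m, tolerance = 1e-13)
  expect_equal(out$c, exp_c, tolerance = 1e-13)
  expect_equal(out$d, exp_d, tolerance = 1e-13)
  expect_equal(out$carriers[[1]], exp_C1, tolerance = 1e-13)
})

test_that("an unsourced uniform drug field decays by the exact Euler factor", {
  g <- tiny_grid()
  st <- uniform_state(g, 0, 0)
  st$c <- st$c + 1
  dt <- 0.002
  out <- step(st, dt, build_arm("V"), lung, g)
  expect_equal(out$c, st$c * (1 - lung$nuC_t * dt), tolerance = 1e-15)
})

test_that("the stability bound is enforced", {
  g <- tiny_grid()
  st <- uniform_state(g, 0.5, 0.5)
  bad_dt <- stable_dt(g, lung) * 1.5
  expect_error(step(st, bad_dt, build_arm("V"), lung, g), "stability")
  expect_warning(step(st, bad_dt, build_arm("V"), lung, g,
                      override_stability = TRUE), "stability")
  expect_error(run_arm("V", lung, g, dt = bad_dt, t_end_days = 1),
               "stability")
})

test_that("tumour volume counts voxels above the detection threshold", {
  g <- sim_grid(10, h = 0.5)
  u <- unit_system(lung$rho, lung$D1)
  vox <- voxel_volume_mm3(g, u)
  expect_equal(tumor_volume(array(0, c(10, 10, 10)), 0.09, g, u), 0)
  expect_equal(tumor_volume(array(1, c(10, 10, 10)), 0.09, g, u),
               1000 * vox)
  half <- array(rep(c(0.1, 0.05), each = 500), c(10, 10, 10))
  expect_equal(tumor_volume(half, 0.09, g, u), 500 * vox)
})

test_that("crossing day interpolates linearly and handles non-crossing", {
  expect_true(is.na(crossing_day(data.frame(day = 0:5, volume_mm3 = 0), 50)))
  expect_equal(crossing_day(data.frame(day = c(0, 10),
                                       volume_mm3 = c(0, 100)), 50), 5)
  expect_equal(crossing_day(data.frame(day = c(0, 2),
                                       volume_mm3 = c(60, 100)), 50), 0)
})

test_that("control growth curves are reproducible and eventually monotone", {
  g <- tiny_grid()
  for (seed in 1:3) {
    cur <- run_arm("V", lung, g, seed = seed, t_end_days = 14,
                   record_every = 0.5)
    # once the travelling front is established the detectable volume can
    # only grow (the early dip, while the seed diffuses below threshold,
    # is a readout transient)
    est <- cur[cur$day >= 8, ]
    expect_true(all(diff(est$volume_mm3) >= 0))
    again <- run_arm("V", lung, g, seed = seed, t_end_days = 14,
                     record_every = 0.5)
    expect_identical(cur$volume_mm3, again$volume_mm3)
  }
})

test_that("tumour density respects the vasculature-set carrying capacity", {
  g <- tiny_grid()
  cur <- run_arm("NC_CD", lung, g, seed = 2, t_end_days = 17)
  expect_true(all(cur$volume_mm3 >= 0))
  man <- attr(cur, "manifest")
  expect_equal(man$arm$name, "NC_CD")
  expect_equal(man$h, g$h)
  # end-state check via step-wise integration is covered elsewhere; here we
  # assert the recorded curve is finite and bounded by the domain volume
  u <- unit_system(lung$rho, lung$D1)
  expect_true(all(cur$volume_mm3 <= g$npts^3 * voxel_volume_mm3(g, u)))
})

test_that("disabling delivery collapses every arm onto the control", {
  g <- tiny_grid()
  p0 <- model_params(delta_t = 0, .defaults = lung)
  ctrl <- run_arm("V", p0, g, seed = 5, t_end_days = 17)
  for (arm in c("L_C", "NC_CD")) {
    treated <- run_arm(arm, p0, g, seed = 5, t_end_days = 17)
    expect_identical(treated$volume_mm3, ctrl$volume_mm3)
  }
})

test_that("zero therapy strengths leave the tissue identical while drugs evolve", {
  g <- tiny_grid()
  p0 <- model_params(AC_t = 0, AD_t = 0, .defaults = lung)
  ctrl <- run_arm("V", p0, g, seed = 4, t_end_days = 17)
  treated <- run_arm("NC_CD", p0, g, seed = 4, t_end_days = 17)
  expect_identical(treated$volume_mm3, ctrl$volume_mm3)
})
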