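test_that("a single deposit builds a local bump, zero far away", {
  st <- abp_state(lo = -2, hi = 2, nbins = 80, c = 0.01, b = 0.9, alpha = 8)
  st <- abp_record(st, 0.3)
  centers <- seq(-2 + 0.025, 2 - 0.025, by = 0.05)
  i0 <- which.min(abs(centers - 0.3))
  expect_equal(which.max(st$bias), i0)
  expect_gt(st$bias[i0], 0)
  far <- abs(centers - 0.3) > 0.5
  expect_true(all(st$bias[far] == 0))
  expect_true(all(st$visits >= 0))
})

test_that("the bias cap is alpha*kT and is never exceeded", {
  st <- abp_state(lo = -1, hi = 1, nbins = 20, alpha = 8, temperature = 300,
                  stride = 1000L)
  expect_equal(abp_cap(st), 8 * 0.0083145 * 300)  # 19.95 kJ/mol at alpha = 8
  for (i in 1:4000) st <- abp_record(st, 0)
  # the cap is approached asymptotically (tempering shrinks deposits as the
  # bias nears it) and is never exceeded
  expect_true(all(st$bias <= abp_cap(st) + 1e-12))
  expect_gt(max(st$bias), 0.95 * abp_cap(st))
  gap1 <- abp_cap(st) - max(st$bias)
  for (i in 1:4000) st <- abp_record(st, 0)
  expect_lt(abp_cap(st) - max(st$bias), gap1)  # still converging upward
})

test_that("visit mass is monotone and deposits shrink near the cap", {
  st <- abp_state(lo = -1, hi = 1, nbins = 20, stride = 500L)
  prev <- st$visits
  increments <- numeric(20)
  for (i in 1:20) {
    st <- abp_record(st, 0)
    expect_true(all(st$visits >= prev))
    increments[i] <- sum(st$visits - prev)
    prev <- st$visits
  }
  expect_lt(increments[20], increments[1])  # tempering slows deposition
})

test_that("a fresh bias evaluates to zero energy and force", {
  st <- abp_state_angular(1, 72)
  b <- abp_bias(st, 0.5)
  expect_equal(b$energy, 0)
  expect_equal(b$gradient, 0)
})

test_that("a symmetric visit field has zero derivative at its center", {
  # deposits are sequential, so tempering breaks exact mirror symmetry at
  # the 1e-5 level; the derivative at the symmetry point stays ~0
  st <- abp_state(lo = -1, hi = 1, nbins = 41)
  for (dz in c(-0.3, -0.15, 0, 0.15, 0.3)) st <- abp_record(st, dz)
  expect_lt(abs(abp_bias(st, 0)$gradient), 1e-3 * max(abs(st$bias)))
})

test_that("periodic bias is continuous across the +/- pi seam", {
  st <- abp_state_angular(1, 72)
  for (i in 1:30) st <- abp_record(st, pi - 0.01 * i)
  # pi and -pi are the same wrapped point: identical energy to 1e-10
  expect_lt(abs(abp_bias(st, pi)$energy - abp_bias(st, -pi)$energy), 1e-10)
  # and approaching the seam from either side is continuous
  expect_lt(abs(abp_bias(st, pi - 1e-7)$energy -
                abp_bias(st, -pi + 1e-7)$energy), 1e-4)
})

test_that("off-grid deposits on non-periodic dimensions are rejected", {
  st <- abp_state(lo = -1, hi = 1, nbins = 20)
  expect_error(abp_record(st, 3), "outside")
})

test_that("checkpoints round-trip bitwise", {
  st <- abp_state_angular(1, 36, c = 0.02, b = 0.8, alpha = 6, stride = 5L)
  set.seed(1)
  for (z in runif(50, -pi, pi)) st <- abp_record(st, z)
  f <- tempfile()
  write_abp_checkpoint(st, f)
  back <- read_abp_checkpoint(f)
  expect_identical(back$visits, st$visits)
  expect_identical(back$bias, st$bias)
  expect_equal(back$c, st$c)
  expect_equal(back$alpha, st$alpha)
})

test_that("abp_fes masks unvisited cells separately from F = 0 cells", {
  st <- abp_state(lo = -2, hi = 2, nbins = 40)
  for (i in 1:50) st <- abp_record(st, -1)
  fes <- abp_fes(st)
  expect_true(any(is.na(fes$values)))       # untouched cells masked
  expect_equal(min(fes$values, na.rm = TRUE), 0)  # min-zero over visited
  expect_error(abp_fes(abp_state(lo = 0, hi = 1, nbins = 10)), "no deposits")
})

test_that("the bias recovers a small double-well free energy profile", {
  sys <- make_double_well(6, 2)
  bias <- abp_state(lo = -2, hi = 2, nbins = 80, stride = 10L, halfwidth = 3L)
  p <- integrator_params(dt = 0.01, temperature = 300, friction = 5,
                         n_steps = 1e6, record_stride = 10, seed = 13)
  tr <- langevin_run(sys, -1, p, cvs = list(coordinate_cv(1, name = "x")),
                     bias = bias)
  fes <- abp_fes(tr$bias)
  xc <- fes_centers(fes)[, 1]
  sel <- abs(xc) <= 1.3 & !is.na(fes$values)
  U <- 6 * (xc^2 - 1)^2
  expect_lt(max(abs((fes$values[sel] - min(fes$values[sel])) -
                    (U[sel] - min(U[sel])))), 1.5)
})
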