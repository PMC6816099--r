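test_that("uniform samples give a flat free-energy surface", {
  set.seed(1)
  z <- runif(2e5, -1, 1)
  fes <- histogram_fes(z, lo = -1, hi = 1, nbins = 20, temperature = 300)
  expect_lt(max(fes$values), 0.3)  # flat up to sampling noise
  expect_equal(min(fes$values), 0)
})

test_that("Boltzmann samples invert to the potential", {
  set.seed(2)
  # direct Boltzmann sampling from the double-well density (rejection)
  U <- function(x) 6 * (x^2 - 1)^2
  kT <- kB * 300
  x <- numeric(0)
  while (length(x) < 2e5) {
    cand <- runif(5e5, -1.8, 1.8)
    acc <- runif(5e5) < exp(-U(cand) / kT)
    x <- c(x, cand[acc])
  }
  fes <- histogram_fes(x, lo = -1.8, hi = 1.8, nbins = 36, temperature = 300)
  xc <- fes_centers(fes)[, 1]
  sel <- !is.na(fes$values) & fes$values < 10
  expect_lt(max(abs(fes$values[sel] - (U(xc)[sel] - min(U(xc)[sel])))), 1)
})

test_that("single-cell samples leave every other cell masked", {
  fes <- histogram_fes(rep(0.55, 100), lo = 0, hi = 1, nbins = 10)
  expect_equal(sum(!is.na(fes$values)), 1L)
  expect_equal(fes$values[6], 0)
  expect_error(histogram_fes(numeric(0), lo = 0, hi = 1, nbins = 10), "no samples")
})

test_that("delta_f follows its Boltzmann-weighted definition", {
  # two single cells at F = 0 and F = 5 -> +5 with A the higher cell
  fes <- fe_surface(list(c(0, 1, 2)), c(5, 0), temperature = 300)
  df <- delta_f(fes, function(z) z < 1, function(z) z > 1)
  expect_equal(df, 5)
  # a region compared with itself is exactly zero
  expect_identical(delta_f(fes, function(z) z > 1, function(z) z > 1), 0)
  # antisymmetry
  expect_identical(delta_f(fes, function(z) z < 1, function(z) z > 1),
                   -delta_f(fes, function(z) z > 1, function(z) z < 1))
  expect_error(delta_f(fes, function(z) z > 5, function(z) z > 1), "region A")
})

test_that("delta_f of mirror regions on a symmetric surface is ~0", {
  set.seed(3)
  sys <- make_double_well(6, 2)
  p <- integrator_params(dt = 0.01, temperature = 300, friction = 5,
                         n_steps = 3e6, record_stride = 10, seed = 19)
  tr <- langevin_run(sys, -1, p, cvs = list(coordinate_cv(1, name = "x")))
  fes <- histogram_fes(tr$cv_series[, 1], lo = -2, hi = 2, nbins = 40,
                       temperature = 300)
  df <- delta_f(fes, function(z) z < -0.5, function(z) z > 0.5)
  expect_lt(abs(df), 0.6)
})

test_that("barrier heights follow the minimal path, periodic arcs included", {
  # double-well-like 1-D surface
  xc <- seq(-1.95, 1.95, by = 0.1)
  U <- 15 * (xc^2 - 1)^2
  fes <- fe_surface(list(seq(-2, 2, by = 0.1)), U, temperature = 300)
  expect_equal(barrier(fes, -1, 1), 15, tolerance = 0.2)
  expect_equal(barrier(fes, 0.5, 0.5), 0)
  # periodic flat surface: zero either direction
  pf <- fe_surface(list(seq(-pi, pi, length.out = 37)), rep(1, 36),
                   periodic = TRUE, temperature = 300)
  expect_equal(barrier(pf, -2, 2), 0)
  # periodic surface takes the lower of the two arcs
  v <- rep(0, 36)
  v[10:14] <- 10   # bump on one arc only
  pf2 <- fe_surface(list(seq(-pi, pi, length.out = 37)), v, periodic = TRUE)
  expect_equal(barrier(pf2, -pi + 0.1, pi - 0.1), 0)
  # masked gap raises an error
  vm <- U
  vm[20] <- NA
  fm <- fe_surface(list(seq(-2, 2, by = 0.1)), vm)
  expect_error(barrier(fm, -1, 1), "masked")
})

test_that("FES TSV round-trips bitwise including masked cells", {
  set.seed(4)
  v <- runif(72, 0, 12)
  v[c(3, 40)] <- NA
  fes <- fe_surface(list(seq(-pi, pi, length.out = 73)), v, periodic = TRUE,
                    temperature = 285)
  f <- tempfile()
  write_fes(fes, f)
  back <- read_fes(f)
  expect_identical(back$values, fes$values)
  expect_identical(is.na(back$values), is.na(fes$values))
  expect_equal(back$temperature, 285)
  expect_equal(back$periodic, TRUE)
  # 2-D round trip
  v2 <- matrix(runif(36), 6, 6)
  fes2 <- fe_surface(list(seq(0, 1, length.out = 7), seq(0, 2, length.out = 7)),
                     as.numeric(v2))
  f2 <- tempfile()
  write_fes(fes2, f2)
  expect_identical(read_fes(f2)$values, fes2$values)
  # missing header rejected with a parse error
  writeLines(c("x\tF", "0.1\t2"), f)
  expect_error(read_fes(f), "parse error")
})

test_that("xi1 state regions partition paired from flipped", {
  reg <- xi1_regions()
  expect_true(reg$paired(0.2))
  expect_false(reg$paired(2))
  expect_true(reg$flipped(3))
  expect_true(reg$flipped(-2.9))
  expect_false(reg$flipped(1))
})
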