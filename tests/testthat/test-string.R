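test_that("string initialization interpolates linearly", {
  p <- init_string(0, 19, M = 20)
  expect_equal(as.numeric(p$images), 0:19)
  expect_warning(init_string(c(1, 1), c(1, 1), M = 3), "degenerate")
  expect_error(init_string(0, c(1, 2), M = 5), "dimension")
  expect_error(init_string(0, 1, M = 2), ">= 3")
})

test_that("reparametrization restores equal arc length exactly", {
  p <- init_string(0, 1, M = 3)
  p$images <- matrix(c(0, 0.1, 1), 3, 1)
  r <- reparametrize(p)
  expect_equal(as.numeric(r$images), c(0, 0.5, 1))
  # idempotence on an already uniform path
  q <- init_string(c(0, 0), c(3, 4), M = 11)
  q2 <- reparametrize(q)
  expect_equal(q2$images, q$images, tolerance = 1e-12)
  # consecutive gaps equalized on a bent path; length nearly preserved
  set.seed(5)
  w <- init_string(c(0, 0), c(1, 0), M = 12)
  w$images[2:11, 2] <- cumsum(rnorm(10, 0, 0.1))
  len0 <- max(baseflip:::arc_lengths(w$images))
  w2 <- reparametrize(w)
  gaps <- diff(baseflip:::arc_lengths(w2$images))
  expect_lt(diff(range(gaps)) / mean(gaps), 1e-6)
  # chordal resampling never lengthens the polyline; endpoints are exact
  expect_lte(max(baseflip:::arc_lengths(w2$images)), len0 + 1e-12)
  expect_equal(w2$images[1, ], w$images[1, ])
  expect_equal(w2$images[12, ], w$images[12, ])
})

test_that("string steps are orthogonal-projection updates with fixed endpoints", {
  p <- init_string(c(0, 0), c(1, 0), M = 5)
  # all-zero gradients: path unchanged
  p2 <- string_step(p, matrix(0, 5, 2))
  expect_equal(p2$images, p$images)
  # gradients parallel to the tangent: straight equidistant path unchanged
  g <- matrix(rep(c(1, 0), each = 5), 5, 2)
  p3 <- string_step(p, g, step_size = 0.05)
  expect_equal(p3$images, p$images, tolerance = 1e-12)
  # a zero central-difference tangent (images m-1 and m+1 coincide) errors
  pbad <- p
  pbad$images[4, ] <- pbad$images[2, ]
  expect_error(string_step(pbad, matrix(1, 5, 2)), "tangent")
})

test_that("repeated steps pull a bent string onto a quadratic valley floor", {
  # U = 0.5 x^2 + 25 y^2: valley floor is the line y = 0
  sys <- make_harmonic(c(1, 50))
  gradU <- function(z) system_gradient(sys, z)
  p <- init_string(c(-1, 0), c(1, 0), M = 15)
  p$images[, 2] <- 0.4 * sin(seq(0, pi, length.out = 15))  # bend it
  for (it in 1:800) {
    g <- t(apply(p$images, 1, gradU))
    p <- string_step(p, g, step_size = 0.005)
  }
  expect_lt(max(abs(p$images[, 2])), 1e-3)
})

test_that("mean-force estimates match the harmonic closed form", {
  kap <- 8; mu <- 0.3; k_im <- 25
  sys <- make_harmonic(kap, mu)
  p <- integrator_params(dt = 0.01, temperature = 300, friction = 5,
                         n_steps = 1e5, record_stride = 10, seed = 31)
  imf <- image_mean_force(sys, list(coordinate_cv(1, name = "x")), 1.2, k_im, p)
  expected <- k_im * kap * (1.2 - mu) / (k_im + kap)
  expect_lt(abs(imf$gradient - expected), 3 * imf$se)
  # z at the well center: zero mean force within noise
  imf0 <- image_mean_force(sys, list(coordinate_cv(1, name = "x")), mu, k_im, p)
  expect_lt(abs(imf0$gradient), 3 * imf0$se)
})

test_that("profiles integrate gradients: flat, signed, and path-independent", {
  p <- init_string(c(0, 0), c(1, 1), M = 8)
  expect_equal(string_profile(p, matrix(0, 8, 2)), rep(0, 8))
  # descending into a minimum gives negative increments (trapezoid contract)
  p1 <- init_string(2, 0, M = 5)
  g1 <- matrix(2 * p1$images[, 1], 5, 1)  # grad of U = x^2
  pr <- string_profile(p1, g1, method = "trapezoid")
  expect_true(all(diff(pr) < 0))
  # gradient theorem on a curved path (spline quadrature): endpoint
  # difference equals the potential difference, path-independent
  sys <- make_harmonic(c(2, 3), c(0.5, -0.5))
  pw <- init_string(c(-1, -1), c(1.5, 0.8), M = 20)
  pw$images[, 2] <- pw$images[, 2] + 0.5 * sin(seq(0, pi, length.out = 20))
  g <- t(apply(pw$images, 1, function(z) system_gradient(sys, z)))
  pr2 <- string_profile(pw, g)
  dU <- system_energy(sys, c(1.5, 0.8)) - system_energy(sys, c(-1, -1))
  expect_equal(pr2[20], dU, tolerance = 0.01)
  expect_error(string_profile(pw, g[1:3, ]), "per image")
})

test_that("run_string is deterministic and pins its endpoints", {
  mb <- make_muller_brown()
  o <- mb_oracle()
  cvs <- list(coordinate_cv(1, name = "x"), coordinate_cv(2, name = "y"))
  p <- integrator_params(dt = 8e-4, temperature = 0, friction = 30,
                         n_steps = 800, record_stride = 5, seed = 23)
  r1 <- run_string(mb, cvs, o$min1, o$min3, M = 10, n_iterations = 8,
                   k_image = 4000, steps_per_image = 800, params = p)
  r2 <- run_string(mb, cvs, o$min1, o$min3, M = 10, n_iterations = 8,
                   k_image = 4000, steps_per_image = 800, params = p)
  expect_identical(r1$profile_history, r2$profile_history)
  expect_identical(r1$path_history, r2$path_history)
  for (it in seq_len(r1$n_iterations)) {
    expect_equal(r1$path_history[[it]][1, ], o$min1)
    expect_equal(r1$path_history[[it]][10, ], o$min3)
  }
})

test_that("profile statistics give calibrated t confidence intervals", {
  ph <- matrix(rep(1:5, each = 20), 20, 5)
  res <- structure(list(profile_history = ph, n_iterations = 20),
                   class = "string_result")
  st <- profile_stats(res, 1:20)
  expect_equal(st$half_width, rep(0, 5))     # identical profiles
  expect_true(all(st$lower <= st$mean & st$mean <= st$upper))
  expect_error(profile_stats(res, 1), "at least 2")
  expect_error(profile_stats(res, 15:25), "history")
  # widening a stationary window shrinks the CI ~ 1/sqrt(n)
  set.seed(6)
  ph2 <- matrix(rnorm(200 * 5), 200, 5)
  res2 <- structure(list(profile_history = ph2, n_iterations = 200),
                    class = "string_result")
  w1 <- mean(profile_stats(res2, 1:50)$half_width)
  w2 <- mean(profile_stats(res2, 1:200)$half_width)
  expect_equal(w2 / w1, sqrt(50 / 200), tolerance = 0.25)
})

test_that("string results export as TSV with per-iteration rows", {
  ph <- list(matrix(1:6, 3, 2), matrix(2:7, 3, 2))
  res <- structure(list(path_history = ph,
                        profile_history = matrix(0, 2, 3),
                        n_iterations = 2,
                        final_path = init_string(c(0, 0), c(1, 1), M = 3)),
                   class = "string_result")
  f <- tempfile()
  write_string_tsv(res, f)
  d <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(d), 6)
  expect_equal(names(d), c("iteration", "image", "cv1", "cv2", "F"))
})
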