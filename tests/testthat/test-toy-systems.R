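test_that("double-well potential matches its closed form", {
  sys <- make_double_well(15, 2)
  expect_equal(system_energy(sys, 0), 15)
  expect_equal(system_energy(sys, 1), 0)
  expect_equal(system_energy(sys, -1), 0)
  expect_equal(system_energy(sys, 0.5), 15 * (0.25 - 1)^2)
  expect_equal(system_gradient(sys, 1), 0, tolerance = 1e-14)
  expect_equal(system_gradient(sys, -1), 0, tolerance = 1e-14)
  expect_error(make_double_well(-1, 2), "positive")
  expect_error(make_double_well(15, 0), "positive")
})

test_that("analytic gradients match finite differences on all systems", {
  systems <- list(make_double_well(15, 2), make_muller_brown(),
                  make_cos2d(6, 4), make_harmonic(c(3, 7), c(0.2, -0.5)))
  set.seed(1)
  for (sys in systems) {
    for (r in 1:25) {
      x <- runif(sys$dim, -1.4, 1.4)
      ga <- system_gradient(sys, x)
      gf <- fd_gradient(sys, x)
      expect_lt(max(abs(ga - gf)) / max(1, max(abs(gf))), 1e-5)
    }
  }
})

test_that("Muller-Brown has exactly three minima with the known energies", {
  mb <- make_muller_brown()
  U <- function(z) system_energy(mb, z)
  gU <- function(z) system_gradient(mb, z)
  # exhaustive descent from a coarse grid of starts
  starts <- expand.grid(x = seq(-1.7, 1.2, by = 0.15),
                        y = seq(-0.4, 2.2, by = 0.15))
  found <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), U, gU, method = "BFGS")
    if (o$value < -40) found <- rbind(found, round(c(o$par, o$value), 3))
  }
  found <- unique(found[order(found[, 3]), , drop = FALSE])
  # merge numerically-adjacent duplicates
  keep <- rep(TRUE, nrow(found))
  for (i in seq_len(nrow(found))) for (j in seq_len(i - 1)) {
    if (keep[j] && sum((found[i, 1:2] - found[j, 1:2])^2) < 1e-3) keep[i] <- FALSE
  }
  found <- found[keep, , drop = FALSE]
  expect_equal(nrow(found), 3)
  expect_equal(min(found[, 3]), -146.700, tolerance = 1e-3)
})

test_that("duplex spec validates sequences and the flipping residue", {
  expect_equal(length(parse_sequence("CCATG(5mC)GCTGAC")), 12)
  expect_equal(parse_sequence("A(5mC)G"), c("A", "5mC", "G"))
  expect_error(duplex_spec(sense = "CCATGCGCTGAC", antisense = "GTCAGCGCATGC"),
               "reverse-complementary")
  expect_error(duplex_spec(antisense = "GTCAGCGCATG"), "length")
  expect_error(duplex_spec(flip_index = 3L), "cytosine")
  expect_error(duplex_spec(flip_index = 40L), "range")
  spec <- duplex_spec()
  expect_equal(spec$flip_index, 5L)
  expect_equal(spec$sense[6], "5mC")
})

test_that("the coarse-grained duplex is a paired 72-bead local minimum", {
  spec <- duplex_spec()
  dup <- make_cg_duplex(spec)
  sys <- dup$system
  conf <- dup$conformation
  expect_equal(sys$n_particles, 72L)  # 12 bp x 2 strands x 3 beads
  # all 12 base-pair bead distances within the pairing cutoff
  m <- as.matrix(conf)
  for (r in 0:11) {
    i <- baseflip:::bead_index(spec, 0L, r, "B") + 1L
    j <- baseflip:::bead_index(spec, 1L, 11L - r, "B") + 1L
    expect_lt(sqrt(sum((m[i, ] - m[j, ])^2)), spec$pairing_cutoff)
  }
  # paired energy below any single-base-displaced variant
  E0 <- system_energy(sys, conf)
  set.seed(7)
  for (r in c(0, 5, 11)) {
    i <- baseflip:::bead_index(spec, 0L, r, "B") + 1L
    md <- m
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    md[i, ] <- md[i, ] + 2 * dir
    expect_lt(E0, system_energy(sys, conformation(md, sys)))
  }
  # minimization from the paired state barely moves it
  mn <- minimize(sys, conf, 2000)
  expect_lt(max(abs(mn$x - conf$x)), 0.1)
  # gradient consistency on a thermally perturbed configuration
  set.seed(8)
  x <- conf$x + rnorm(length(conf$x), 0, 0.05)
  ga <- system_gradient(sys, x)
  gf <- fd_gradient(sys, x)
  expect_lt(max(abs(ga - gf)) / max(abs(gf)), 1e-5)
})

test_that("the flipped reference is extrahelical, local and deterministic", {
  spec <- duplex_spec()
  dup <- make_cg_duplex(spec)
  flip <- make_flipped_reference(dup$system, dup$conformation, spec)
  xi1 <- duplex_xi1(spec)
  expect_gt(abs(pseudo_dihedral(flip, xi1)), 3 * pi / 4)
  # residues beyond the first shell of the flip site stay in place
  m0 <- as.matrix(dup$conformation)
  m1 <- as.matrix(flip)
  disp <- sqrt(rowSums((m1 - m0)^2))
  lab <- dup$system$labels
  far <- lab$strand == 1 | abs(lab$resi - spec$flip_index) > 1
  expect_lt(max(disp[far]), 0.5)
  # the flipped base itself moved far
  iB <- baseflip:::bead_index(spec, 0L, spec$flip_index, "B") + 1L
  expect_gt(disp[iB], 4)
  # determinism
  flip2 <- make_flipped_reference(dup$system, dup$conformation, spec)
  expect_identical(flip$x, flip2$x)
})

test_that("flip barrier grows with pairing strength (unbiased sampling)", {
  barriers <- vapply(c(2, 5), function(D) {
    spec <- duplex_spec(pairing_strength = D, stack_strength = 1)
    dup <- make_cg_duplex(spec)
    xi1 <- duplex_xi1(spec)
    p <- integrator_params(dt = 0.01, temperature = 300, friction = 5,
                           n_steps = 4e6, record_stride = 20, seed = 17)
    tr <- langevin_run(dup$system, dup$conformation, p, cvs = list(xi1))
    fes <- histogram_fes(tr$cv_series[, 1], lo = -pi, hi = pi, nbins = 36,
                         periodic = TRUE, temperature = 300)
    barrier(fes, 0, pi)
  }, 0.0)
  expect_lt(barriers[1], barriers[2])
})

test_that("duplex conformations write as XYZ and minimal PDB", {
  spec <- duplex_spec()
  dup <- make_cg_duplex(spec)
  xyz <- tempfile(fileext = ".xyz")
  write_xyz(dup$conformation, xyz, system = dup$system)
  lines <- readLines(xyz)
  expect_equal(as.integer(lines[1]), 72L)
  expect_equal(length(lines), 74L)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb_conformation(dup$conformation, dup$system, pdb)
  back <- read_structure(pdb, "toy")
  expect_equal(nrow(back), 72)
  expect_equal(unname(as.matrix(back[1, c("x", "y", "z")])[1, ]),
               as.matrix(dup$conformation)[1, ], tolerance = 1e-3,
               ignore_attr = TRUE)
})
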