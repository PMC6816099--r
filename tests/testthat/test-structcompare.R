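# All structures here are synthetic fixtures built in code (see
# helper-oracles.R); no experimental coordinates are used.

test_that("PDB reading preserves coordinates and applies the altloc policy", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, c(1.5, -2.25, 3.125)),
    pdb_atom_line(2, "CB", "ALA", "A", 1, c(0, 0, 1)),
    pdb_atom_line(3, "CA", "GLY", "A", 2, c(4, 5, 6)),
    "END"), f)
  s <- read_structure(f, "mini")
  expect_equal(nrow(s), 3)
  expect_equal(s$x[1], 1.5)
  expect_equal(s$y[1], -2.25)
  expect_equal(s$z[1], 3.125)
  expect_equal(s$resno, c(1, 1, 2))
  expect_true(all(s$is_protein))

  # altloc: keep highest occupancy; tie goes to A
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, c(0, 0, 0), occ = 0.4, altloc = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, c(9, 9, 9), occ = 0.6, altloc = "B"),
    pdb_atom_line(3, "CB", "ALA", "A", 1, c(1, 1, 1), occ = 0.5, altloc = "A"),
    pdb_atom_line(4, "CB", "ALA", "A", 1, c(8, 8, 8), occ = 0.5, altloc = "B"),
    "END"), f2)
  s2 <- read_structure(f2)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$x[s2$name == "CA"], 9)  # higher occupancy wins
  expect_equal(s2$x[s2$name == "CB"], 1)  # tie -> altloc A

  f3 <- tempfile(fileext = ".pdb")
  writeLines("END", f3)
  expect_error(read_structure(f3), "empty structure")

  f4 <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", "ALA", "A", 1, c(0, 0, 0)),
               "ATOM      2  CB ALA A   1        xx     1.0     1.0"), f4)
  expect_error(read_structure(f4), "line 2")
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(11)
  pts <- matrix(rnorm(30, sd = 4), 10, 3)
  # identity
  sp <- kabsch_superpose(pts, pts)
  expect_equal(sp$rmsd_all, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  # 90 degrees about z plus a shift
  R <- rotation_about_z(pi / 2)
  target <- sweep(pts %*% t(R), 2, c(3, -1, 7), "+")
  sp2 <- kabsch_superpose(pts, target)
  expect_lt(sp2$rmsd_all, 1e-9)
  expect_equal(sp2$rotation, R, tolerance = 1e-9)
  expect_equal(sp2$translation, c(3, -1, 7), tolerance = 1e-8)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-9)
  # degenerate collinear input rejected
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line + 0.1), "degenerate")
})

test_that("Kabsch matches a brute-force quaternion-grid oracle", {
  # 4-point asymmetric set vs a perturbed copy
  mobile <- matrix(c(0, 0, 0, 2, 0, 0, 0, 1.5, 0, 0.4, 0.3, 2.5), 4, 3,
                   byrow = TRUE)
  set.seed(12)
  target <- mobile %*% t(rotation_about_z(0.4)) +
    matrix(rnorm(12, 0, 0.15), 4, 3)
  sp <- kabsch_superpose(mobile, target)
  # oracle: exhaustive search over unit quaternions on a fine random grid
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  cm <- colMeans(mobile); ct <- colMeans(target)
  M <- sweep(mobile, 2, cm); T <- sweep(target, 2, ct)
  best <- Inf
  for (i in 1:200000) {
    R <- quat_rot(rnorm(4))
    r <- sqrt(mean(rowSums((M %*% t(R) - T)^2)))
    if (r < best) best <- r
  }
  expect_lte(sp$rmsd_all, best + 1e-9)      # optimality
  expect_equal(sp$rmsd_all, best, tolerance = 0.05)
})

test_that("Kabsch beats random proper rotations (optimality spot-check)", {
  set.seed(13)
  mobile <- matrix(rnorm(24, sd = 3), 8, 3)
  target <- mobile %*% t(rotation_about_z(1.1)) + matrix(rnorm(24, 0, 0.3), 8, 3)
  sp <- kabsch_superpose(mobile, target)
  cm <- colMeans(mobile); ct <- colMeans(target)
  M <- sweep(mobile, 2, cm); T <- sweep(target, 2, ct)
  for (i in 1:500) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3, 3, byrow = TRUE)
    expect_gte(sqrt(mean(rowSums((M %*% t(R) - T)^2))), sp$rmsd_all - 1e-12)
  }
})

test_that("iterative alignment rejects gross outliers and is monotone", {
  set.seed(14)
  mobile <- matrix(rnorm(60, sd = 5), 20, 3)
  target <- mobile  # exact match
  # clean data with a generous cutoff: identical to plain Kabsch
  sp0 <- align_iterative(mobile, target, cycles = 5, reject_cutoff = 10)
  expect_equal(sp0$rmsd_all, kabsch_superpose(mobile, target)$rmsd_all)
  expect_equal(sp0$n_rejected, 0L)
  # one gross outlier: rejected (the skewed first fit may drag a good
  # point past the cutoff too), RMSD returns to ~0 on the survivors
  target2 <- target
  target2[7, ] <- target2[7, ] + c(15, 0, 0)
  sp1 <- align_iterative(mobile, target2, cycles = 5, reject_cutoff = 2)
  expect_gte(sp1$n_rejected, 1L)
  expect_lt(sp1$rmsd_all, 1e-9)
  expect_equal(sp1$n_fitted + sp1$n_rejected, 20L)
  # rejection that leaves fewer than 3 pairs errors out
  target3 <- mobile[1:4, ]
  target3[3, ] <- target3[3, ] + c(50, 0, 0)
  target3[4, ] <- target3[4, ] + c(0, 50, 0)
  expect_error(align_iterative(mobile[1:4, ], target3,
                               reject_cutoff = 0.5), "survive")
})

test_that("pooled flipped-base RMSD matches hand-computed deviations", {
  dir <- tempfile(); dir.create(dir)
  ref <- file.path(dir, "ref.pdb")
  write_synthetic_complex(ref)
  # identical copy, arbitrarily rotated and shifted -> 0
  rot <- file.path(dir, "rot.pdb")
  write_synthetic_complex(rot, transform = rotation_about_z(1.2),
                          shift = c(10, -4, 2))
  structs <- list(ref = read_structure(ref, "ref"),
                  rot = read_structure(rot, "rot"))
  out <- flipped_base_rmsd(structs, "ref")
  expect_lt(out$rmsd, 2e-3)  # PDB fixtures carry 3-decimal coordinates
  # one atom displaced by exactly 1 A -> pooled RMSD sqrt(1/9)
  j1 <- matrix(0, 9, 3); j1[1, 1] <- 1
  d1 <- file.path(dir, "disp1.pdb")
  write_synthetic_complex(d1, base_jitter = j1)
  out1 <- flipped_base_rmsd(list(ref = structs$ref,
                                 d1 = read_structure(d1, "d1")), "ref")
  expect_equal(out1$rmsd, sqrt(1 / 9), tolerance = 1e-2)
  # two structures: one atom at 1 A, one exact -> sqrt(mean over 18 devs)
  out2 <- flipped_base_rmsd(list(ref = structs$ref, rot = structs$rot,
                                 d1 = read_structure(d1, "d1")), "ref")
  expect_equal(out2$rmsd, sqrt(1 / 18), tolerance = 1e-2)
  # per-structure mean variant
  out3 <- flipped_base_rmsd(list(ref = structs$ref, rot = structs$rot,
                                 d1 = read_structure(d1, "d1")), "ref",
                            pooled = FALSE)
  expect_equal(out3$rmsd, mean(c(0, sqrt(1 / 9))), tolerance = 1e-2)
  # missing shared atom warns and is excluded
  dm <- file.path(dir, "miss.pdb")
  write_synthetic_complex(dm, drop_atom = "C7")
  expect_warning(
    outm <- flipped_base_rmsd(list(ref = structs$ref,
                                   dm = read_structure(dm, "dm")), "ref"),
    "C7")
  expect_equal(outm$report$n_shared_atoms, 8)
  # report carries the per-structure fit columns
  expect_setequal(names(out2$report),
                  c("id", "n_fitted", "n_rejected", "rmsd_all", "rmsd_subset",
                    "n_shared_atoms"))
})

test_that("all RMSD outputs are invariant under a common rigid motion", {
  dir <- tempfile(); dir.create(dir)
  a <- file.path(dir, "a.pdb"); b <- file.path(dir, "b.pdb")
  write_synthetic_complex(a)
  j <- matrix(rnorm(27, 0, 0.3), 9, 3)
  write_synthetic_complex(b, base_jitter = j)
  s1 <- list(ref = read_structure(a, "ref"), b = read_structure(b, "b"))
  r1 <- flipped_base_rmsd(s1, "ref")
  # apply one common rigid motion to both structures
  sp <- structure(list(rotation = rotation_about_z(0.9),
                       translation = c(-3, 8, 1)), class = "superposition")
  s2 <- lapply(s1, apply_superposition, sp = sp)
  r2 <- flipped_base_rmsd(s2, "ref")
  expect_equal(r1$rmsd, r2$rmsd, tolerance = 1e-9)
})
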