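# Shared oracles and fixture builders, independent of the code paths they
# check: finite differences, Muller-Brown stationary points by root-finding
# on the analytic gradient, a fine-grid minimum-energy path, and synthetic
# PDB fixtures for the superposition module.

fd_gradient <- function(system, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (system_energy(system, xp) - system_energy(system, xm)) / (2 * h)
  }, 0.0)
}

mb_oracle <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    mb <- make_muller_brown()
    gradU <- function(z) system_gradient(mb, z)
    U <- function(z) system_energy(mb, z)
    min1 <- stats::optim(c(-0.5, 1.5), U, gradU, method = "BFGS")$par
    min2 <- stats::optim(c(0.0, 0.5), U, gradU, method = "BFGS")$par
    min3 <- stats::optim(c(0.6, 0.0), U, gradU, method = "BFGS")$par
    newton_saddle <- function(z0) {
      z <- z0
      for (i in 1:60) {
        g <- gradU(z)
        J <- pracma::jacobian(gradU, z)
        z <- z - solve(J, g)
        if (sqrt(sum(gradU(z)^2)) < 1e-10) break
      }
      z
    }
    s1 <- newton_saddle(c(-0.8, 0.6))
    s2 <- newton_saddle(c(0.2, 0.3))
    sd_path <- function(z0, h = 2e-4, nmax = 60000) {
      out <- matrix(NA_real_, nmax, 2)
      z <- z0
      for (i in 1:nmax) {
        out[i, ] <- z
        g <- gradU(z)
        ng <- sqrt(sum(g^2))
        if (ng < 2e-3) break
        z <- z - h * g / ng * min(ng, 50)
      }
      out[!is.na(out[, 1]), , drop = FALSE]
    }
    unstable <- function(s) {
      e <- eigen(pracma::jacobian(gradU, s))
      e$vectors[, which.min(e$values)]
    }
    branch <- function(s, v, target) {
      a <- sd_path(s + 1e-4 * v)
      b <- sd_path(s - 1e-4 * v)
      if (sum((a[nrow(a), ] - target)^2) < sum((b[nrow(b), ] - target)^2)) a else b
    }
    mep <- rbind(
      branch(s1, unstable(s1), min1)[rev(seq_len(nrow(branch(s1, unstable(s1), min1)))), ],
      s1,
      branch(s1, unstable(s1), min2),
      branch(s2, unstable(s2), min2)[rev(seq_len(nrow(branch(s2, unstable(s2), min2)))), ],
      s2,
      branch(s2, unstable(s2), min3))
    cache <<- list(min1 = min1, min2 = min2, min3 = min3,
                   s1 = s1, s2 = s2, mep = mep,
                   U = U, gradU = gradU)
    cache
  }
})

dist_to_polyline <- function(p, poly) {
  sqrt(min(rowSums((poly - matrix(p, nrow(poly), ncol(poly), byrow = TRUE))^2)))
}

# --- synthetic structure fixtures (labelled synthetic; built in code) -----

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          occ = 1.0, altloc = " ", element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0.0, element)
}

# a small synthetic SRA-like complex: a 12-residue CA/CB protein scaffold
# plus one flipped 5CM base with the full shared-atom set
synthetic_complex_coords <- function() {
  set.seed(4242)  # fixture geometry frozen once
  prot <- matrix(rnorm(24 * 3, sd = 6), 24, 3)
  base <- matrix(c(
    0.0, 0.0, 0.0,    # N1
    1.3, 0.4, 0.1,    # C2
    1.6, 1.6, 0.2,    # O2
    2.2, -0.6, 0.1,   # N3
    1.9, -1.9, 0.0,   # C4
    2.9, -2.8, 0.1,   # N4
    0.5, -2.3, -0.1,  # C5
    -0.4, -1.3, -0.1, # C6
    0.1, -3.7, -0.2), # C7
    9, 3, byrow = TRUE)
  list(prot = prot, base = base,
       base_names = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6", "C7"))
}

write_synthetic_complex <- function(path, transform = diag(3), shift = c(0, 0, 0),
                                    base_jitter = NULL, drop_atom = NULL) {
  cc <- synthetic_complex_coords()
  prot <- sweep(cc$prot %*% t(transform), 2, shift, "+")
  base <- cc$base
  if (!is.null(base_jitter)) base <- base + base_jitter
  base <- sweep(base %*% t(transform), 2, shift, "+")
  lines <- character(0)
  serial <- 1
  for (i in seq_len(12)) {
    lines <- c(lines, pdb_atom_line(serial, "CA", "ALA", "A", i, prot[2 * i - 1, ],
                                    element = "C"))
    serial <- serial + 1
    lines <- c(lines, pdb_atom_line(serial, "CB", "ALA", "A", i, prot[2 * i, ],
                                    element = "C"))
    serial <- serial + 1
  }
  keep <- cc$base_names
  if (!is.null(drop_atom)) keep <- setdiff(keep, drop_atom)
  for (j in seq_along(cc$base_names)) {
    if (!cc$base_names[j] %in% keep) next
    lines <- c(lines, pdb_atom_line(serial, cc$base_names[j], "5CM", "B", 101,
                                    base[j, ], element = substr(cc$base_names[j], 1, 1)))
    serial <- serial + 1
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}
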