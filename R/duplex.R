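# Coarse-grained bead-spring DNA duplex: three beads per nucleotide
# (phosphate P, sugar S, base B), harmonic backbone, breakable base-pair and
# stacking bonds, soft-core excluded volume. The central cytosine can rotate
# around the backbone between an intrahelical (paired) and an extrahelical
# (flipped) state.

#' Parse a nucleotide string with modification annotations
#'
#' `"CCATG(5mC)GCTGAC"` becomes the residue vector
#' `C C A T G 5mC G C T G A C`. Modified cytosines (`5mC`, `5hmC`) pair as
#' cytosine.
#'
#' @param s sequence string, 5' to 3', with parenthesised modifications
#' @return character vector of residue codes
#' @export
parse_sequence <- function(s) {
  out <- character(0)
  i <- 1
  chars <- strsplit(s, "")[[1]]
  while (i <= length(chars)) {
    if (chars[i] == "(") {
      j <- which(chars == ")" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("unbalanced parenthesis in sequence")
      out <- c(out, paste(chars[(i + 1):(j - 1)], collapse = ""))
      i <- j + 1
    } else {
      if (!chars[i] %in% c("A", "C", "G", "T"))
        stop("unknown nucleotide '", chars[i], "'")
      out <- c(out, chars[i])
      i <- i + 1
    }
  }
  out
}

base_identity <- function(res) ifelse(res %in% c("5mC", "5hmC"), "C", res)

complement_base <- function(res) {
  b <- base_identity(res)
  c(A = "T", T = "A", C = "G", G = "C")[b]
}

#' Specification of the coarse-grained duplex
#'
#' Defaults build a 12-bp duplex around the hemimethylated CpG sequence
#' sense `CCATG(5mC)GCTGAC` / antisense `GTCAGCGCATGG`, with the methylated
#' cytosine (0-based residue 5 on the sense strand) as the flipping base.
#' The modification is carried as a bead label only; it has no energetic
#' asymmetry.
#'
#' @param sense sense-strand sequence, 5' to 3', `(5mC)`-style annotations
#' @param antisense antisense-strand sequence, 5' to 3'
#' @param rise stacking distance between consecutive base pairs, Angstrom
#' @param pairing_strength well depth of the breakable cross-strand
#'   base-pair bond, kJ/mol
#' @param pairing_cutoff distance beyond which a base-pair bond is broken
#'   (zero force), Angstrom
#' @param backbone_k backbone bond spring constant, kJ/mol/A^2
#' @param angle_k backbone angle spring constant, kJ/mol/rad^2
#' @param base_angle_k spring constant of the P-S-B base-orientation angle
#'   on the non-flipping residues, kJ/mol/rad^2; the flipping residue's base
#'   rotates freely (that rotation is the collective variable)
#' @param stack_strength well depth of the breakable base-stacking bond,
#'   kJ/mol
#' @param stack2_strength optional well depth of a breakable
#'   second-neighbor stacking term B(r-1)-B(r+1), kJ/mol (default 0)
#' @param dock_strength well depth of the breakable base-backbone docking
#'   well B(r)-P(r) / B(r)-P(r+1), kJ/mol; inert in the paired helix (the
#'   base is too far from its phosphates) but captures an everted base
#'   against the flanking phosphates, giving the extrahelical state a
#'   defined docked pose with a distinctively distorted backbone -- the
#'   signature the backbone-restraint paradigms read out
#' @param flip_index 0-based sense-strand residue index of the flipping base
#' @return object of class `duplex_spec`
#' @export
duplex_spec <- function(sense = "CCATG(5mC)GCTGAC",
                        antisense = "GTCAGCGCATGG",
                        rise = 3.4,
                        pairing_strength = 10,
                        pairing_cutoff = 7.5,
                        backbone_k = 300,
                        angle_k = 25,
                        base_angle_k = 0,
                        stack_strength = 2,
                        stack2_strength = 0,
                        dock_strength = 0,
                        flip_index = NULL) {
  sr <- parse_sequence(sense)
  ar <- parse_sequence(antisense)
  if (length(sr) != length(ar))
    stop("sense and antisense sequences differ in length")
  rc <- rev(vapply(ar, complement_base, ""))
  if (!identical(unname(rc), unname(base_identity(sr))))
    stop("sequences are not reverse-complementary")
  if (is.null(flip_index)) {
    cand <- which(sr %in% c("5mC", "5hmC")) - 1L
    if (length(cand) == 0) cand <- which(base_identity(sr) == "C") - 1L
    flip_index <- cand[1]
  }
  flip_index <- as.integer(flip_index)
  if (flip_index < 0 || flip_index >= length(sr))
    stop("flip_index out of range")
  if (base_identity(sr[flip_index + 1]) != "C")
    stop("flip_index must address a cytosine on the sense strand")
  structure(list(sense = sr, antisense = ar, rise = rise,
                 pairing_strength = pairing_strength,
                 pairing_cutoff = pairing_cutoff,
                 backbone_k = backbone_k, angle_k = angle_k,
                 base_angle_k = base_angle_k,
                 stack_strength = stack_strength,
                 stack2_strength = stack2_strength,
                 dock_strength = dock_strength,
                 flip_index = flip_index),
            class = "duplex_spec")
}

# bead index (0-based) of (strand 0/1, residue, type P=0 S=1 B=2)
bead_index <- function(spec, strand, resi, type) {
  L <- length(spec$sense)
  type_i <- match(type, c("P", "S", "B")) - 1L
  as.integer(strand * 3L * L + 3L * resi + type_i)
}

# idealized ladder coordinates; strand A at x<0, strand B at x>0,
# antiparallel; antisense residue j pairs with sense residue L-1-j
duplex_geometry <- function(spec) {
  L <- length(spec$sense)
  n <- 6L * L
  xyz <- matrix(0, n, 3)
  lab <- data.frame(strand = integer(n), resi = integer(n),
                    type = character(n), residue = character(n),
                    stringsAsFactors = FALSE)
  fill <- function(strand, resi, type, pos, residue) {
    i <- bead_index(spec, strand, resi, type) + 1L
    xyz[i, ] <<- pos
    lab[i, ] <<- list(strand, resi, type, residue)
  }
  for (i in 0:(L - 1)) {
    z <- i * spec$rise
    fill(0L, i, "P", c(-8.2, 0.0, z - 0.5 * spec$rise), spec$sense[i + 1])
    fill(0L, i, "S", c(-6.0, 0.0, z), spec$sense[i + 1])
    fill(0L, i, "B", c(-2.5, 0.0, z), spec$sense[i + 1])
  }
  for (j in 0:(L - 1)) {
    z <- (L - 1 - j) * spec$rise
    fill(1L, j, "P", c(8.2, 0.0, z + 0.5 * spec$rise), spec$antisense[j + 1])
    fill(1L, j, "S", c(6.0, 0.0, z), spec$antisense[j + 1])
    fill(1L, j, "B", c(2.5, 0.0, z), spec$antisense[j + 1])
  }
  list(xyz = xyz, labels = lab)
}

#' Build the coarse-grained duplex system and its paired conformation
#'
#' Constructs a bead-spring ladder with three beads per nucleotide
#' (phosphate, sugar, base), harmonic backbone bonds and angles, breakable
#' flat-bottom base-pair bonds between partner bases, weak breakable
#' stacking bonds between consecutive bases of the same strand, a harmonic
#' base-orientation angle P-S-B, and soft-core excluded volume between
#' non-bonded beads. The returned conformation is the fully paired
#' B-form-like ladder, which is an exact minimum of the bonded terms.
#'
#' @param spec a [duplex_spec()]
#' @return list with elements `system` (a `toy_system`) and `conformation`
#'   (the paired ladder)
#' @export
make_cg_duplex <- function(spec = duplex_spec()) {
  if (!inherits(spec, "duplex_spec")) stop("spec must be a duplex_spec")
  L <- length(spec$sense)
  geo <- duplex_geometry(spec)
  xyz <- geo$xyz
  bi <- function(s, r, t) bead_index(spec, s, r, t)
  dist_ij <- function(i, j) sqrt(sum((xyz[i + 1, ] - xyz[j + 1, ])^2))
  ang_ijk <- function(i, j, k) {
    u <- xyz[i + 1, ] - xyz[j + 1, ]; v <- xyz[k + 1, ] - xyz[j + 1, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  bonds <- NULL; angles <- NULL; pairs <- NULL
  add_bond <- function(i, j, k) bonds <<- rbind(bonds, c(i, j, k, dist_ij(i, j)))
  add_angle <- function(i, j, k, kt) angles <<- rbind(angles, c(i, j, k, kt, ang_ijk(i, j, k)))
  for (s in 0:1) for (r in 0:(L - 1)) {
    add_bond(bi(s, r, "P"), bi(s, r, "S"), spec$backbone_k)
    add_bond(bi(s, r, "S"), bi(s, r, "B"), spec$backbone_k)
    if (r < L - 1) add_bond(bi(s, r, "S"), bi(s, r + 1, "P"), spec$backbone_k)
    if (r < L - 1) add_angle(bi(s, r, "P"), bi(s, r, "S"), bi(s, r + 1, "P"), spec$angle_k)
    if (r < L - 1) add_angle(bi(s, r, "S"), bi(s, r + 1, "P"), bi(s, r + 1, "S"), spec$angle_k)
    if (spec$base_angle_k > 0 && !(s == 0 && r == spec$flip_index))
      add_angle(bi(s, r, "P"), bi(s, r, "S"), bi(s, r, "B"), spec$base_angle_k)
  }
  # breakable base-pair bonds B(i, sense) - B(L-1-i, antisense)
  for (r in 0:(L - 1)) {
    i <- bi(0L, r, "B"); j <- bi(1L, L - 1L - r, "B")
    pairs <- rbind(pairs, c(i, j, spec$pairing_strength, dist_ij(i, j),
                            spec$pairing_cutoff))
  }
  # breakable stacking bonds B(r)-B(r+1), both strands
  for (s in 0:1) for (r in 0:(L - 2)) {
    i <- bi(s, r, "B"); j <- bi(s, r + 1, "B")
    pairs <- rbind(pairs, c(i, j, spec$stack_strength, dist_ij(i, j),
                            dist_ij(i, j) + 3.1))
  }
  # optional breakable second-neighbor stacking wells B(r-1)-B(r+1)
  if (spec$stack2_strength > 0) {
    for (s in 0:1) for (r in 0:(L - 3)) {
      i <- bi(s, r, "B"); j <- bi(s, r + 2, "B")
      pairs <- rbind(pairs, c(i, j, spec$stack2_strength, 3.6, 7.2))
    }
  }
  # base-backbone docking wells B(r)-P(r), B(r)-P(r+1): inert while the
  # base is intrahelical, they give an everted base a docked extrahelical
  # pose pressed against its flanking phosphates
  if (spec$dock_strength > 0) {
    for (s in 0:1) for (r in 0:(L - 1)) {
      pairs <- rbind(pairs, c(bi(s, r, "B"), bi(s, r, "P"),
                              spec$dock_strength, 2.5, 4.2))
      if (r < L - 1)
        pairs <- rbind(pairs, c(bi(s, r, "B"), bi(s, r + 1, "P"),
                                spec$dock_strength, 2.5, 4.2))
    }
  }
  # soft-core candidates: all pairs except 1-2 bonds, 1-3 angle pairs,
  # base-pair and stacking partners
  n <- 6L * L
  excluded <- new.env(hash = TRUE)
  mark <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE, excluded)
  apply(bonds, 1, function(b) mark(b[1], b[2]))
  apply(angles, 1, function(a) mark(a[1], a[3]))
  apply(pairs, 1, function(p) mark(p[1], p[2]))
  # base-phosphate contacts get a larger soft-core radius: an extrahelical
  # base presses the flanking phosphates outward, coupling base flipping to
  # backbone distortion (the handle the restraint paradigms grip)
  typ <- geo$labels$type
  sc <- NULL
  for (i in 0:(n - 2)) for (j in (i + 1):(n - 1)) {
    if (!exists(paste(i, j), excluded) && dist_ij(i, j) < 12) {
      bp <- (typ[i + 1] == "B" && typ[j + 1] == "P") ||
            (typ[i + 1] == "P" && typ[j + 1] == "B")
      sc <- rbind(sc, if (bp) c(i, j, 3.0, 100) else c(i, j, 1.8, 10))
    }
  }
  # hard cores between stacked base neighbors: the second-neighbor pull
  # must not crush an intact stack
  for (st in 0:1) for (r in 0:(L - 2)) {
    sc <- rbind(sc, c(bi(st, r, "B"), bi(st, r + 1, "B"), 3.0, 60))
  }
  masses <- c(P = 95, S = 83, B = 110)[geo$labels$type]
  cpp <- list(kind = "cg_duplex", dim = 3L * n, params = numeric(0),
              bonds = bonds, angles = angles, pairs = pairs,
              softcore_pairs = sc, sc_eps = 10, sc_rc = 1.8)
  sys <- new_toy_system("cg_duplex", 3L * n, n, masses, geo$labels, cpp,
                        spatial = TRUE)
  sys$duplex_spec <- spec
  # relax the ideal ladder onto the actual minimum of the full force field
  mn <- cpp_minimize(cpp, as.numeric(t(xyz)), 4000L, 0.02,
                     rep(FALSE, 3L * n), matrix(numeric(0), 0, 5), list())
  conf <- conformation(mn$x, sys, source = "initial")
  list(system = sys, conformation = conf)
}

# rotate the base bead (full angle) and sugar bead (partial angle,
# sugar_fraction) of the flip residue about the local backbone axis
# (through S, parallel to the P->P direction)
rotate_flip_base <- function(conf, spec, theta, sugar_fraction = 0) {
  m <- as.matrix(conf)
  fi <- spec$flip_index
  iS <- bead_index(spec, 0L, fi, "S") + 1L
  iB <- bead_index(spec, 0L, fi, "B") + 1L
  iP1 <- bead_index(spec, 0L, fi, "P") + 1L
  iP2 <- if (fi < length(spec$sense) - 1)
    bead_index(spec, 0L, fi + 1L, "P") + 1L else iP1
  axis <- m[iP2, ] - m[iP1, ]
  if (sum(axis^2) < 1e-12) axis <- c(0, 0, 1)
  axis <- axis / sqrt(sum(axis^2))
  rodrigues <- function(v, th)
    v * cos(th) + pracma_cross(axis, v) * sin(th) +
      axis * sum(axis * v) * (1 - cos(th))
  ctr <- m[iS, ]
  m[iB, ] <- ctr + rodrigues(m[iB, ] - ctr, theta)
  # sugar re-orientation: partial rotation about the backbone P-P axis
  pivot <- m[iP1, ]
  m[iS, ] <- pivot + rodrigues(m[iS, ] - pivot, sugar_fraction * theta)
  m
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct the extrahelical (flipped) reference conformation
#'
#' Rotates the base bead of the flipping residue about the local backbone
#' axis until the flip pseudodihedral `xi1` evaluates near `pi` (the
#' extrahelical state), then energy-minimizes the whole duplex with the
#' flipped base held fixed. All other residues relax only slightly; the
#' small backbone shifts near the flip site are what the restraint
#' paradigms latch onto.
#'
#' @param system,conf output of [make_cg_duplex()]
#' @param spec the [duplex_spec()] used to build the duplex
#' @param max_steps minimization step budget
#' @return the flipped `conformation`
#' @export
make_flipped_reference <- function(system, conf, spec = system$duplex_spec,
                                   max_steps = 6000, anchor_k = 25) {
  xi1 <- duplex_xi1(spec)
  target <- pi
  thetas <- seq(pi / 3, 5 * pi / 3, length.out = 961)
  best <- NULL; best_dev <- Inf
  for (th in thetas) {
    m <- rotate_flip_base(conf, spec, th)
    v <- cpp_cv_values(list(xi1$cpp), as.numeric(t(m)))
    dev <- abs(wrap_angle(v - target))
    if (dev < best_dev) { best_dev <- dev; best <- th }
  }
  m <- rotate_flip_base(conf, spec, best)
  fi <- spec$flip_index
  # hold the flipped base fixed; relax the flip residue and its flanking
  # phosphate freely; gently anchor the remainder of the helix at the
  # paired geometry so the flip stays a local rearrangement
  fixed <- rep(FALSE, system$dim)
  iB <- bead_index(spec, 0L, fi, "B")
  fixed[(3 * iB + 1):(3 * iB + 3)] <- TRUE
  m0 <- as.matrix(conf)
  # anchor only the terminal base pairs (fixes the global frame); the rest
  # of the backbone relaxes freely, so the accommodation of the everted
  # base stays local to the flip site
  L <- length(spec$sense)
  lab <- system$labels
  anchored <- which(lab$resi %in% c(0L, L - 1L)) - 1L
  pos <- cbind(anchored, m0[anchored + 1, , drop = FALSE], anchor_k)
  # the flip dihedral is held at the target while the backbone relaxes --
  # the analog of the protein-held bound pose of the extrahelical base
  cvr <- list(list(cv = xi1$cpp, target = target, k = 200))
  res <- cpp_minimize(system$cpp, as.numeric(t(m)), max_steps, 0.3, fixed,
                      pos, cvr)
  if (!is.finite(res$energy))
    stop("flip construction failed: minimization diverged")
  out <- conformation(res$x, system, source = "flipped-reference")
  v <- cpp_cv_values(list(xi1$cpp), out$x)
  if (abs(wrap_angle(v - pi)) > pi / 4)
    stop("flip construction failed: xi1 = ", round(v, 3), " not near pi")
  out
}
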