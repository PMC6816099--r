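# Collective variables: dihedral primitive, centroid pseudodihedrals with
# analytic gradients, Cartesian CVs, and the default base-flip CVs of the
# coarse-grained duplex.

#' Wrap an angle (or angular difference) into (-pi, pi]
#' @param a angle(s) in radians
#' @export
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Unwrap an angular time series (remove 2*pi jumps)
#' @param a angle series in radians
#' @return continuous series with the same increments modulo 2*pi
#' @export
unwrap_angle <- function(a) {
  if (length(a) < 2) return(a)
  d <- wrap_angle(diff(a))
  a[1] + c(0, cumsum(d))
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: the angle is positive when, looking down the
#' p2->p3 axis, the far bond p3->p4 is rotated clockwise from the near bond
#' p2->p1. Value in `(-pi, pi]`.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom)
#' @return angle in radians
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  cpp_dihedral(as.numeric(p1), as.numeric(p2), as.numeric(p3), as.numeric(p4))
}

new_cv <- function(name, cpp) {
  structure(list(name = name, cpp = cpp), class = "collective_variable")
}

#' @export
print.collective_variable <- function(x, ...) {
  cat("<collective_variable>", x$name, "(", x$cpp$type, ")\n")
  invisible(x)
}

#' Pseudodihedral collective variable over four particle groups
#'
#' The angle is the dihedral of the four group centroids; this is the
#' standard construction for base-flip coordinates, where single atoms are
#' replaced by rigid groups. Groups must be non-empty and pairwise
#' disjoint. `xi1` and `zeta1` refer to the same coordinate (both symbols
#' are used in the base-flipping literature); this package uses `xi1`.
#'
#' @param g1,g2,g3,g4 integer vectors of 1-based particle indices
#' @param name label for the CV
#' @return a `collective_variable`
#' @export
pseudo_dihedral_cv <- function(g1, g2, g3, g4, name = "custom") {
  gs <- list(g1, g2, g3, g4)
  if (any(vapply(gs, length, 1L) == 0)) stop("all four groups must be non-empty")
  all_idx <- unlist(gs)
  if (anyDuplicated(all_idx)) stop("groups must be pairwise disjoint")
  if (any(all_idx < 1)) stop("particle indices are 1-based")
  new_cv(name, list(type = "pdih",
                    g1 = as.integer(g1) - 1L, g2 = as.integer(g2) - 1L,
                    g3 = as.integer(g3) - 1L, g4 = as.integer(g4) - 1L))
}

#' Bare-coordinate collective variable
#'
#' Selects one degree of freedom of the system as the CV (e.g. `x` of a
#' one-particle analytic system). For angular coordinates set
#' `periodic = TRUE` so values wrap into `(-pi, pi]`.
#'
#' @param index 1-based degree-of-freedom index
#' @param periodic whether the coordinate is an angle
#' @param name label
#' @return a `collective_variable`
#' @export
coordinate_cv <- function(index, periodic = FALSE, name = paste0("q", index)) {
  new_cv(name, list(type = "coord", index = as.integer(index) - 1L,
                    periodic = periodic))
}

#' Cartesian collective variables of selected particles
#'
#' Expands to one coordinate CV per spatial component of each selected
#' particle (dimension `3 * length(particles)`), matching the use of raw
#' atomic coordinates as string-method CVs. Coordinates are restrained as
#' given, without prior rigid-body alignment.
#'
#' @param particles 1-based particle indices
#' @return list of `collective_variable`s
#' @export
cartesian_cv <- function(particles) {
  idx <- as.vector(t(outer((as.integer(particles) - 1L) * 3L, 0:2, "+"))) + 1L
  lapply(idx, function(i) coordinate_cv(i, FALSE, paste0("r", i)))
}

cv_list_cpp <- function(cvs) {
  if (inherits(cvs, "collective_variable")) cvs <- list(cvs)
  lapply(cvs, function(cv) cv$cpp)
}

#' Evaluate collective variables on a conformation
#' @param conf a `conformation` or coordinate vector
#' @param cvs one `collective_variable` or a list of them
#' @return numeric vector of CV values
#' @export
cv_values <- function(conf, cvs) {
  x <- if (inherits(conf, "conformation")) conf$x else as.numeric(conf)
  v <- cpp_cv_values(cv_list_cpp(cvs), x)
  names(v) <- vapply(if (inherits(cvs, "collective_variable")) list(cvs) else cvs,
                     function(cv) cv$name, "")
  v
}

#' Pseudodihedral of the four group centroids (single CV convenience)
#' @param conf a `conformation` or coordinate vector
#' @param cv a pseudodihedral `collective_variable`
#' @return angle in radians
#' @export
pseudo_dihedral <- function(conf, cv) unname(cv_values(conf, cv))

#' Analytic gradient of a collective variable
#'
#' Chain-rule gradient with respect to every degree of freedom; matches
#' central finite differences to relative error below 1e-5 and sums to zero
#' over particles (translation invariance).
#'
#' @inheritParams pseudo_dihedral
#' @return gradient vector, one entry per degree of freedom
#' @export
cv_gradient <- function(conf, cv) {
  x <- if (inherits(conf, "conformation")) conf$x else as.numeric(conf)
  cpp_cv_gradient(cv$cpp, x)
}

#' Default flip pseudodihedral xi1 of the coarse-grained duplex
#'
#' Centroid groups `S(i), P(i), P(i+1), B(i)` of the flipping residue `i`,
#' ordered so the paired ladder reads approximately 0 and the extrahelical
#' reference approximately pi. xi1 tracks rotation of the base around the
#' phosphate backbone.
#'
#' @param spec a [duplex_spec()]
#' @return a `collective_variable`
#' @export
duplex_xi1 <- function(spec) {
  fi <- spec$flip_index
  if (fi >= length(spec$sense) - 1)
    stop("flip_index must have a 3' neighbor for xi1")
  pseudo_dihedral_cv(
    bead_index(spec, 0L, fi, "S") + 1L,
    bead_index(spec, 0L, fi, "P") + 1L,
    bead_index(spec, 0L, fi + 1L, "P") + 1L,
    bead_index(spec, 0L, fi, "B") + 1L,
    name = "xi1")
}

#' Default base-rotation pseudodihedral xi2 of the coarse-grained duplex
#'
#' Centroid groups `B'(partner), P(i), S(i), B(i)`, ordered so the dihedral
#' axis is the backbone-sugar bond P(i)-S(i): xi2 tracks rotation of the
#' base around the sugar linkage relative to its pairing partner.
#'
#' @param spec a [duplex_spec()]
#' @return a `collective_variable`
#' @export
duplex_xi2 <- function(spec) {
  fi <- spec$flip_index
  L <- length(spec$sense)
  pseudo_dihedral_cv(
    bead_index(spec, 1L, L - 1L - fi, "B") + 1L,
    bead_index(spec, 0L, fi, "P") + 1L,
    bead_index(spec, 0L, fi, "S") + 1L,
    bead_index(spec, 0L, fi, "B") + 1L,
    name = "xi2")
}
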