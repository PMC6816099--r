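# Harmonic position and dihedral restraints, and the three graded
# backbone-restraint paradigms (none / flanking phosphates / all
# phosphates) used to emulate SRA-domain contact with the DNA backbone.

#' Build a restraint set
#'
#' @param positions data frame with columns `index` (1-based particle),
#'   `x`, `y`, `z` (reference position, Angstrom) and `k` (kJ/mol/A^2)
#' @param dihedrals list of `list(cv =, target =, k =)` entries with a
#'   pseudodihedral `collective_variable`, a target angle (radians) and a
#'   spring constant (kJ/mol/rad^2); angular differences are wrapped into
#'   `(-pi, pi]`
#' @return object of class `restraint_set`
#' @export
restraint_set <- function(positions = NULL, dihedrals = list()) {
  if (is.null(positions))
    positions <- data.frame(index = integer(0), x = numeric(0),
                            y = numeric(0), z = numeric(0), k = numeric(0))
  stopifnot(all(c("index", "x", "y", "z", "k") %in% names(positions)))
  if (any(positions$k < 0)) stop("restraint constants must be >= 0")
  if (nrow(positions) && !all(is.finite(as.matrix(positions[c("x","y","z")]))))
    stop("reference positions must be finite")
  for (d in dihedrals) {
    stopifnot(inherits(d$cv, "collective_variable"), is.finite(d$target), d$k >= 0)
  }
  structure(list(positions = positions, dihedrals = dihedrals),
            class = "restraint_set")
}

#' Number of restraints in a set
#' @param x a `restraint_set`
#' @export
length.restraint_set <- function(x) nrow(x$positions) + length(x$dihedrals)

restraints_pos_matrix <- function(rs, system) {
  p <- rs$positions
  if (nrow(p) && any(p$index < 1 | p$index > system$n_particles))
    stop("restraint particle index out of range")
  cbind(p$index - 1L, p$x, p$y, p$z, p$k)
}

restraints_cv_list <- function(rs) {
  lapply(rs$dihedrals, function(d)
    list(cv = d$cv$cpp, target = d$target, k = d$k))
}

#' Restraint energy and forces at a conformation
#'
#' Position terms are `0.5 k |x - x_ref|^2`; dihedral terms are
#' `0.5 k dphi^2` with `dphi` the wrapped angular difference. Forces are
#' the exact negative gradients.
#'
#' @param conf a `conformation`
#' @param restraints a [restraint_set()]
#' @param system the `toy_system` the conformation belongs to
#' @return list with `energy` (kJ/mol) and `forces` (vector per degree of
#'   freedom, kJ/mol/A)
#' @export
restraint_forces <- function(conf, restraints, system) {
  x <- if (inherits(conf, "conformation")) conf$x else as.numeric(conf)
  pos <- restraints_pos_matrix(restraints, system)
  g <- numeric(length(x))
  U <- 0
  if (nrow(pos)) {
    for (r in seq_len(nrow(pos))) {
      i <- 3 * pos[r, 1] + 1
      dx <- x[i:(i + 2)] - pos[r, 2:4]
      U <- U + 0.5 * pos[r, 5] * sum(dx^2)
      g[i:(i + 2)] <- g[i:(i + 2)] + pos[r, 5] * dx
    }
  }
  for (d in restraints$dihedrals) {
    v <- cv_values(x, d$cv)
    dphi <- wrap_angle(v - d$target)
    U <- U + 0.5 * d$k * dphi^2
    g <- g + d$k * dphi * cv_gradient(x, d$cv)
  }
  list(energy = unname(U), forces = -g)
}

#' Backbone-restraint paradigms for the duplex
#'
#' Three graded levels of backbone restraint emulating SRA-domain contact:
#' `"none"` (free DNA), `"flanking"` (position restraints on the two
#' phosphates flanking the flipping base, i.e. its 5' and 3' phosphates),
#' and `"all"` (position restraints on every backbone phosphate of both
#' strands). Reference positions are taken from the flipped (extrahelical)
#' reference conformation, so the restraints hold the backbone in its
#' flipped-accommodating geometry.
#'
#' @param paradigm `"none"`, `"flanking"` or `"all"`
#' @param system the duplex `toy_system`
#' @param flipped_ref `conformation` from [make_flipped_reference()]
#' @param k restraint constant, kJ/mol/A^2; the default is deliberately
#'   stiff -- the restraints emulate a protein clamping the backbone, and
#'   they must dominate the soft collective modes of the coarse-grained
#'   backbone for the clamp to be mechanically meaningful
#' @param spec the [duplex_spec()] (default: stored in the system)
#' @return a [restraint_set()]
#' @export
build_paradigm <- function(paradigm, system, flipped_ref, k = 600,
                           spec = system$duplex_spec) {
  paradigm <- match.arg(paradigm, c("none", "flanking", "all"))
  if (paradigm == "none") return(restraint_set())
  m <- as.matrix(flipped_ref)
  L <- length(spec$sense)
  fi <- spec$flip_index
  if (paradigm == "flanking") {
    if (fi >= L - 1) stop("flip_index must have a 3' phosphate")
    idx <- c(bead_index(spec, 0L, fi, "P"),
             bead_index(spec, 0L, fi + 1L, "P")) + 1L
  } else {
    idx <- unlist(lapply(0:1, function(s)
      vapply(0:(L - 1), function(r) bead_index(spec, s, r, "P"), 0L))) + 1L
  }
  restraint_set(data.frame(index = idx, x = m[idx, 1], y = m[idx, 2],
                           z = m[idx, 3], k = k))
}
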