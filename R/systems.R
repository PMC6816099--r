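# Analytic benchmark systems and the common toy_system / conformation classes.

new_toy_system <- function(kind, dim, n_particles, masses, labels, cpp, spatial = FALSE) {
  structure(
    list(kind = kind, dim = dim, n_particles = n_particles,
         masses = masses, labels = labels, cpp = cpp, spatial = spatial),
    class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat("<toy_system>", x$kind, "|", x$n_particles, "particle(s),",
      x$dim, "degrees of freedom\n")
  invisible(x)
}

#' Create a conformation for a toy system
#'
#' A conformation stores the full coordinate vector of a system
#' (`n_particles x 3` for spatial bead systems, or the bare coordinates of
#' an analytic low-dimensional system) together with a source tag.
#'
#' @param x numeric coordinate vector (Angstrom) or an `n x 3` matrix
#' @param system the `toy_system` the coordinates belong to
#' @param source free-text provenance tag (`"initial"`, `"flipped-reference"`,
#'   `"trajectory"`, ...)
#' @return an object of class `conformation`
#' @export
conformation <- function(x, system, source = "initial") {
  if (is.matrix(x)) x <- as.numeric(t(x))
  x <- as.numeric(x)
  if (length(x) != system$dim)
    stop("coordinate count does not match system dimension (",
         length(x), " vs ", system$dim, ")")
  if (!all(is.finite(x))) stop("non-finite coordinates")
  if (system$spatial) {
    m <- matrix(x, ncol = 3, byrow = TRUE)
    d <- as.matrix(stats::dist(m))
    diag(d) <- Inf
    if (min(d) <= 1e-6) stop("coincident particles (pairwise distance <= 1e-6 A)")
  }
  structure(list(x = x, n_particles = system$n_particles,
                 spatial = system$spatial, source = source),
            class = "conformation")
}

#' Coordinates of a conformation as an n x 3 matrix (spatial systems)
#' @param x a `conformation`
#' @param ... unused
#' @export
as.matrix.conformation <- function(x, ...) {
  if (!x$spatial) return(matrix(x$x, nrow = 1))
  matrix(x$x, ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation>", length(x$x), "coordinates, source:", x$source, "\n")
  invisible(x)
}

#' Potential energy of a configuration
#' @param system a `toy_system`
#' @param conf a `conformation` or bare coordinate vector
#' @return energy in kJ/mol
#' @export
system_energy <- function(system, conf) {
  x <- if (inherits(conf, "conformation")) conf$x else as.numeric(conf)
  cpp_force_energy(system$cpp, x)$energy
}

#' Potential-energy gradient of a configuration
#' @inheritParams system_energy
#' @return dU/dx, kJ/mol/Angstrom, one component per degree of freedom
#' @export
system_gradient <- function(system, conf) {
  x <- if (inherits(conf, "conformation")) conf$x else as.numeric(conf)
  cpp_force_energy(system$cpp, x)$gradient
}

mass_per_dof <- function(system) {
  if (system$spatial) rep(system$masses, each = 3) else
    rep_len(system$masses, system$dim)
}

#' Symmetric 1-D double-well benchmark potential
#'
#' `U(x) = barrier_height * ((x/a)^2 - 1)^2` with `a = well_separation/2`:
#' minima at `x = +/- a` with `U = 0` and a barrier of exactly
#' `barrier_height` at `x = 0`. Because the potential is one-dimensional the
#' free energy along `x` equals `U` exactly, which makes this the primary
#' oracle for the adaptive biasing potential.
#'
#' @param barrier_height barrier at the origin, kJ/mol (> 0)
#' @param well_separation distance between the two minima, Angstrom (> 0)
#' @param mass particle mass, amu
#' @return a `toy_system` with one particle in one dimension
#' @export
make_double_well <- function(barrier_height, well_separation, mass = 12) {
  if (!is.finite(barrier_height) || barrier_height <= 0)
    stop("barrier_height must be positive")
  if (!is.finite(well_separation) || well_separation <= 0)
    stop("well_separation must be positive")
  a <- well_separation / 2
  new_toy_system("double_well", 1L, 1L, mass, "particle",
                 list(kind = "double_well", dim = 1L,
                      params = c(barrier_height, a)))
}

#' Muller-Brown 2-D benchmark potential
#'
#' The canonical four-Gaussian Muller-Brown surface,
#' `U(x,y) = sum_k A_k exp(a_k (x-x0_k)^2 + b_k (x-x0_k)(y-y0_k) + c_k (y-y0_k)^2)`
#' with the standard constants
#' `A = (-200, -100, -170, 15)`, `a = (-1, -1, -6.5, 0.7)`,
#' `b = (0, 0, 11, 0.6)`, `c = (-10, -10, -6.5, 0.7)`,
#' `x0 = (1, 0, -0.5, -1)`, `y0 = (0, 0.5, 1.5, 1)`.
#' It has three minima connected through two saddle points and is the
#' standard benchmark for minimum-energy-path methods; energies are in the
#' surface's own units (treated as kJ/mol by the dynamics engine).
#'
#' @param mass particle mass, amu
#' @return a `toy_system` with one particle in two dimensions
#' @export
make_muller_brown <- function(mass = 40) {
  new_toy_system("muller_brown", 2L, 1L, mass, "particle",
                 list(kind = "muller_brown", dim = 2L, params = numeric(0)))
}

#' General harmonic well
#'
#' `U(x) = sum_i 0.5 * kappa_i * (x_i - mu_i)^2`. Used as the closed-form
#' oracle for restrained mean-force estimation and thermostat checks.
#'
#' @param kappa per-dimension spring constants, kJ/mol/A^2
#' @param mu per-dimension well centers, Angstrom
#' @param mass particle mass, amu
#' @return a `toy_system`
#' @export
make_harmonic <- function(kappa, mu = rep(0, length(kappa)), mass = 12) {
  if (length(kappa) != length(mu)) stop("kappa and mu lengths differ")
  if (any(kappa <= 0)) stop("kappa must be positive")
  d <- length(kappa)
  new_toy_system("harmonic", as.integer(d), 1L, mass, "particle",
                 list(kind = "harmonic", dim = as.integer(d),
                      params = c(d, kappa, mu)))
}

#' Separable periodic 2-D potential
#'
#' `U(xi1, xi2) = A (1 - cos xi1) + B (1 - cos xi2)` on the torus
#' `(-pi, pi]^2`. Its free energy surface equals `U` exactly, providing the
#' two-dimensional periodic oracle for the adaptive biasing potential.
#'
#' @param A,B well depths, kJ/mol
#' @param mass particle mass, amu
#' @return a `toy_system` with two periodic angular coordinates (radians)
#' @export
make_cos2d <- function(A = 6, B = 4, mass = 12) {
  if (A <= 0 || B <= 0) stop("A and B must be positive")
  new_toy_system("cos2d", 2L, 1L, mass, "particle",
                 list(kind = "cos2d", dim = 2L, params = c(A, B)))
}
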