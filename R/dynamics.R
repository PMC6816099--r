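# Langevin dynamics (BAOAB) and steepest-descent minimization, with
# pluggable bias and restraint forces. All randomness flows from the seed
# in integrator_params; identical inputs reproduce trajectories bitwise.

#' Integrator parameters
#'
#' @param dt time step, ps
#' @param temperature K (0 disables the thermal noise)
#' @param friction Langevin friction, 1/ps (0 gives ballistic,
#'   energy-conserving integration when the temperature is also 0)
#' @param n_steps number of steps
#' @param record_stride steps between recorded CV/energy samples
#' @param seed integer RNG seed
#' @return object of class `integrator_params`
#' @export
integrator_params <- function(dt = 0.01, temperature = 300, friction = 5,
                              n_steps = 1000L, record_stride = 10L,
                              seed = 1L) {
  stopifnot(dt > 0, friction >= 0, n_steps >= 1, record_stride >= 1,
            temperature >= 0)
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 n_steps = as.integer(n_steps),
                 record_stride = as.integer(record_stride),
                 seed = as.integer(seed)),
            class = "integrator_params")
}

#' Run Langevin dynamics
#'
#' BAOAB-split Langevin integration of a toy system. The total force is the
#' system force plus any adaptive bias (acting through the biased CVs), any
#' position/dihedral restraints, and any harmonic CV restraints. CV values
#' and system potential energy are recorded every `record_stride` steps.
#'
#' @param system a `toy_system`
#' @param start a `conformation` (or coordinate vector)
#' @param params an [integrator_params()]
#' @param cvs list of `collective_variable`s to record
#' @param bias optional [abp_state()]; deposits happen during the run and
#'   the updated state is returned in the trajectory
#' @param bias_cvs indices into `cvs` of the CVs the bias acts on
#'   (defaults to the first `ndim` recorders)
#' @param restraints optional [restraint_set()]
#' @param cv_restraints list of `list(cv =, target =, k =)` harmonic CV
#'   restraints (used by the string method)
#' @param frame_stride steps between stored frames (0 = none)
#' @return object of class `trajectory` with elements `cv_series` (matrix,
#'   one column per CV), `energies`, `final` conformation, `frames`,
#'   `params`, and `bias` (updated ABP state, if biased)
#' @export
langevin_run <- function(system, start, params, cvs = list(),
                         bias = NULL, bias_cvs = NULL,
                         restraints = NULL, cv_restraints = list(),
                         frame_stride = 0L) {
  x0 <- if (inherits(start, "conformation")) start$x else as.numeric(start)
  if (length(x0) != system$dim) stop("start does not match system dimension")
  cvs_cpp <- cv_list_cpp(cvs)
  abp_cpp <- NULL
  bias_idx <- integer(0)
  if (!is.null(bias)) {
    if (is.null(bias_cvs)) bias_cvs <- seq_len(bias$ndim)
    if (length(bias_cvs) != bias$ndim)
      stop("bias_cvs must name one recorder per bias dimension")
    abp_cpp <- bias
    bias_idx <- as.integer(bias_cvs) - 1L
  }
  pos <- matrix(numeric(0), 0, 5)
  cvr <- list()
  if (!is.null(restraints)) {
    pos <- restraints_pos_matrix(restraints, system)
    cvr <- restraints_cv_list(restraints)
  }
  for (r in cv_restraints)
    cvr <- c(cvr, list(list(cv = r$cv$cpp, target = r$target, k = r$k)))
  set.seed(params$seed)
  out <- cpp_langevin(system$cpp, x0, mass_per_dof(system),
                      params$dt, params$friction, params$temperature,
                      params$n_steps, params$record_stride,
                      cvs_cpp, abp_cpp, bias_idx, pos, cvr,
                      as.integer(frame_stride))
  colnames(out$cv_series) <- vapply(cvs, function(cv) cv$name, "")
  traj <- structure(
    list(cv_series = out$cv_series, energies = out$energies,
         final = conformation(out$final_x, system, source = "trajectory"),
         frames = if (frame_stride > 0) out$frames else NULL,
         params = params),
    class = "trajectory")
  if (!is.null(bias)) traj$bias <- structure(out$abp, class = "abp_state")
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", nrow(x$cv_series), "records,",
      ncol(x$cv_series), "CV(s),", x$params$n_steps, "steps\n")
  invisible(x)
}

#' Energy minimization by steepest descent with backtracking
#'
#' @param system a `toy_system`
#' @param start a `conformation` or coordinate vector
#' @param max_steps iteration budget; returns best-so-far when exhausted
#' @param ftol force-component convergence threshold, kJ/mol/A
#' @param fixed optional logical mask over degrees of freedom held fixed
#' @param restraints optional [restraint_set()]
#' @param cv_restraints list of `list(cv =, target =, k =)` harmonic CV
#'   restraints held during minimization
#' @return minimized `conformation` with attribute `energy`
#' @export
minimize <- function(system, start, max_steps = 2000L, ftol = 1e-4,
                     fixed = NULL, restraints = NULL, cv_restraints = list()) {
  x0 <- if (inherits(start, "conformation")) start$x else as.numeric(start)
  if (is.null(fixed)) fixed <- rep(FALSE, system$dim)
  pos <- if (is.null(restraints)) matrix(numeric(0), 0, 5) else
    restraints_pos_matrix(restraints, system)
  cvr <- lapply(cv_restraints, function(r)
    list(cv = r$cv$cpp, target = r$target, k = r$k))
  if (!is.null(restraints)) cvr <- c(cvr, restraints_cv_list(restraints))
  res <- cpp_minimize(system$cpp, x0, as.integer(max_steps), ftol,
                      fixed, pos, cvr)
  out <- conformation(res$x, system, source = "minimized")
  attr(out, "energy") <- res$energy
  out
}

#' Write a trajectory's CV series and energies as TSV
#'
#' Columns: `step`, one column per CV (radians or Angstrom), `energy`
#' (kJ/mol). Numbers are written with 17 significant digits so files
#' round-trip bitwise.
#'
#' @param traj a `trajectory`
#' @param path output file
#' @export
write_trajectory_tsv <- function(traj, path) {
  d <- data.frame(step = seq_len(nrow(traj$cv_series)) * traj$params$record_stride,
                  traj$cv_series, energy = traj$energies,
                  check.names = FALSE)
  write_tsv17(d, path)
}

write_tsv17 <- function(d, path) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) sprintf("%.17g", x))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write conformations or trajectory frames in XYZ format
#'
#' @param frames a `conformation`, a list of them, or a frame matrix from
#'   [langevin_run()]
#' @param path output file
#' @param labels per-particle element labels (defaults to bead type)
#' @param system the system (for labels), optional
#' @export
write_xyz <- function(frames, path, labels = NULL, system = NULL) {
  if (inherits(frames, "conformation")) frames <- list(frames)
  if (is.matrix(frames) && !inherits(frames, "conformation"))
    frames <- lapply(seq_len(nrow(frames)), function(i) frames[i, ])
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    x <- if (inherits(f, "conformation")) f$x else as.numeric(f)
    m <- matrix(x, ncol = 3, byrow = TRUE)
    if (is.null(labels)) {
      lab <- if (!is.null(system) && is.data.frame(system$labels))
        system$labels$type else rep("X", nrow(m))
    } else lab <- rep_len(labels, nrow(m))
    writeLines(as.character(nrow(m)), con)
    writeLines("baseflip frame", con)
    writeLines(sprintf("%s %.6f %.6f %.6f", lab, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Write a duplex conformation as a minimal PDB file
#'
#' One residue per nucleotide; bead names P, S, B; chains A (sense) and
#' B (antisense). PDB serial and residue numbers are 1-based.
#'
#' @param conf a `conformation` from [make_cg_duplex()]
#' @param system the duplex `toy_system`
#' @param path output file
#' @export
write_pdb_conformation <- function(conf, system, path) {
  m <- as.matrix(conf)
  lab <- system$labels
  lines <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    lines[i] <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      i, lab$type[i], substr(lab$residue[i], 1, 3),
      c("A", "B")[lab$strand[i] + 1], lab$resi[i] + 1,
      m[i, 1], m[i, 2], m[i, 3], 1.0, 0.0)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
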