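# Adaptive biasing potential over 1-2 collective variables: a gridded,
# history-dependent bias built from tempered mollified kernel deposits,
# with a hard cap at alpha*kT. The free-energy surface is read off as the
# negative of the accumulated bias.

#' Create an adaptive-bias state
#'
#' The bias lives on a regular grid over CV space. Each deposit spreads a
#' normalized raised-cosine kernel (half-width `halfwidth` bins) of mass
#' equal to `stride` (the number of dynamics steps it represents), scaled
#' by the tempering factor `1 - bias(z)/(alpha*kT)`, into the visit field;
#' the bias at each touched cell is then
#' `min(alpha*kT, (kT/b) * log(1 + b * c * visits))`.
#' With the default parameters `c = 0.01`, `b = 0.9`, `alpha = 8` the cap
#' is `8 * kT = 19.96` kJ/mol at 300 K, matching the energy scale of
#' base-pair rupture.
#'
#' @param lo,hi per-dimension grid bounds (radians or Angstrom)
#' @param nbins per-dimension bin counts (default 72 bins per 2*pi, i.e.
#'   5-degree resolution on angular grids)
#' @param periodic per-dimension periodic flags
#' @param c deposition-rate parameter (dimensionless)
#' @param b tempering/mollification parameter in (0, 1)
#' @param alpha bias cap in units of kT
#' @param temperature K
#' @param stride dynamics steps between deposits
#' @param halfwidth kernel half-width in grid cells
#' @return object of class `abp_state`
#' @export
abp_state <- function(lo, hi, nbins, periodic = rep(FALSE, length(lo)),
                      c = 0.01, b = 0.9, alpha = 8, temperature = 300,
                      stride = 10L, halfwidth = 3L) {
  ndim <- length(lo)
  stopifnot(ndim %in% 1:2, length(hi) == ndim, length(nbins) == ndim,
            all(hi > lo), all(nbins >= 2), c > 0, b > 0, b < 1, alpha > 0,
            temperature > 0, stride >= 1, halfwidth >= 1)
  ncell <- prod(nbins)
  structure(list(ndim = as.integer(ndim), nbins = as.integer(nbins),
                 lo = as.numeric(lo), hi = as.numeric(hi),
                 periodic = as.logical(periodic),
                 visits = numeric(ncell), bias = numeric(ncell),
                 c = c, b = b, alpha = alpha, temperature = temperature,
                 stride = as.integer(stride),
                 halfwidth = as.integer(halfwidth)),
            class = "abp_state")
}

#' Angular adaptive-bias state on (-pi, pi] per dimension
#' @param ndim 1 or 2
#' @param nbins bins per dimension (default 72 = 5 degrees)
#' @param ... passed to [abp_state()]
#' @export
abp_state_angular <- function(ndim = 1, nbins = 72, ...) {
  abp_state(lo = rep(-pi, ndim), hi = rep(pi, ndim),
            nbins = rep(nbins, ndim), periodic = rep(TRUE, ndim), ...)
}

#' @export
print.abp_state <- function(x, ...) {
  cat("<abp_state>", x$ndim, "D grid", paste(x$nbins, collapse = " x "),
      "| c =", x$c, "b =", x$b, "alpha =", x$alpha,
      "| cap =", round(abp_cap(x), 3), "kJ/mol\n")
  invisible(x)
}

#' Bias cap alpha*kT in kJ/mol
#' @param state an `abp_state`
#' @export
abp_cap <- function(state) state$alpha * kB * state$temperature

#' Record one deposit at a CV point
#'
#' Deposits a tempered mollified kernel centered at `z` and updates the
#' bias on the touched cells. Deposit mass is strictly positive while the
#' local bias is below the cap. Values on periodic dimensions wrap;
#' off-grid values on non-periodic dimensions are an error.
#'
#' @param state an [abp_state()]
#' @param z CV value(s), length `ndim`
#' @return the updated `abp_state`
#' @export
abp_record <- function(state, z) {
  out <- cpp_abp_deposit(unclass(state), as.numeric(z), state$stride)
  structure(out, class = "abp_state")
}

#' Bias energy and derivative at a CV point
#'
#' Energy by multilinear interpolation between cell centers; derivative by
#' interpolated central differences. Periodic dimensions wrap across the
#' +/- pi seam continuously.
#'
#' @param state an [abp_state()]
#' @param z CV value(s)
#' @return list with `energy` (kJ/mol) and `gradient` (dU/dz per dimension)
#' @export
abp_bias <- function(state, z) {
  v <- cpp_abp_eval(unclass(state), as.numeric(z))
  list(energy = v[1], gradient = v[-1])
}

#' Free-energy surface estimate from the accumulated bias
#'
#' Inverts the accumulated bias into a free-energy estimate, shifted so
#' the minimum over visited cells is zero; cells with zero visits are
#' masked (no data, as opposed to F = 0).
#'
#' Because deposits are tempered (the factor `1 - bias/cap`) and the bias
#' grows logarithmically in the visit mass, the raw bias under-represents
#' free-energy differences at stationarity; the unbiased estimator --
#' the exact inversion of the stationary growth-rate balance, analogous to
#' the well-tempered metadynamics scale factor -- is
#' `F = -(1+b) bias + kT log(1 - bias/cap)` (min-zero shifted).
#' Cells whose bias has reached the cap carry no further information;
#' they are flagged in the `capped` element of the returned surface.
#'
#' @param state an [abp_state()]
#' @return a [fe_surface] object with an extra logical element `capped`
#' @export
abp_fes <- function(state) {
  if (all(state$visits == 0)) stop("no deposits recorded")
  kT <- kB * state$temperature
  cap <- abp_cap(state)
  capped <- state$bias >= 0.999 * cap
  frac <- pmin(state$bias / cap, 0.999)
  vals <- -(1 + state$b) * state$bias + kT * log(1 - frac)
  vals[state$visits == 0] <- NA_real_
  fes <- fe_surface(edges_from_grid(state), vals, state$periodic,
                    state$temperature)
  fes$capped <- capped
  fes
}

edges_from_grid <- function(state) {
  lapply(seq_len(state$ndim), function(d)
    seq(state$lo[d], state$hi[d], length.out = state$nbins[d] + 1))
}

#' Write / read an adaptive-bias checkpoint (TSV)
#'
#' The checkpoint stores the grid definition, parameters, visits and bias
#' with 17 significant digits, enabling bitwise restart.
#'
#' @param state an `abp_state`
#' @param path file path
#' @export
write_abp_checkpoint <- function(state, path) {
  hdr <- c(
    paste0("# baseflip abp checkpoint"),
    paste0("# ndim\t", state$ndim),
    paste0("# nbins\t", paste(state$nbins, collapse = "\t")),
    paste0("# lo\t", paste(sprintf("%.17g", state$lo), collapse = "\t")),
    paste0("# hi\t", paste(sprintf("%.17g", state$hi), collapse = "\t")),
    paste0("# periodic\t", paste(as.integer(state$periodic), collapse = "\t")),
    paste0("# params\t", paste(sprintf("%.17g",
      c(state$c, state$b, state$alpha, state$temperature)), collapse = "\t")),
    paste0("# stride\t", state$stride),
    paste0("# halfwidth\t", state$halfwidth),
    "visits\tbias")
  body <- sprintf("%.17g\t%.17g", state$visits, state$bias)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_abp_checkpoint
#' @export
read_abp_checkpoint <- function(path) {
  lines <- readLines(path)
  if (!grepl("abp checkpoint", lines[1])) stop("not an abp checkpoint: ", path)
  gv <- function(tag) {
    l <- lines[grepl(paste0("^# ", tag, "\t"), lines)][1]
    strsplit(sub(paste0("^# ", tag, "\t"), "", l), "\t")[[1]]
  }
  ndim <- as.integer(gv("ndim"))
  nbins <- as.integer(gv("nbins"))
  lo <- as.numeric(gv("lo")); hi <- as.numeric(gv("hi"))
  periodic <- as.logical(as.integer(gv("periodic")))
  pars <- as.numeric(gv("params"))
  st <- abp_state(lo, hi, nbins, periodic, c = pars[1], b = pars[2],
                  alpha = pars[3], temperature = pars[4],
                  stride = as.integer(gv("stride")),
                  halfwidth = as.integer(gv("halfwidth")))
  dat <- utils::read.table(text = lines[(which(lines == "visits\tbias") + 1):length(lines)],
                           sep = "\t")
  st$visits <- dat[[1]]
  st$bias <- dat[[2]]
  st
}
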