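# Free-energy surfaces: construction from unbiased histograms (the
# Boltzmann-inversion oracle), state free-energy differences, barrier
# heights, and TSV round-trip I/O.

#' Free-energy surface on a regular 1-D or 2-D grid
#'
#' Values are in kJ/mol, shifted so the minimum over unmasked cells is
#' zero; cells without data are `NA` (masked). Values are stored cell-wise
#' with the first dimension varying fastest.
#'
#' @param edges list of per-dimension bin-edge vectors
#' @param values numeric vector of per-cell free energies (NA = masked)
#' @param periodic per-dimension periodic flags
#' @param temperature K
#' @return object of class `fe_surface`
#' @export
fe_surface <- function(edges, values, periodic = rep(FALSE, length(edges)),
                       temperature = 300) {
  ndim <- length(edges)
  stopifnot(ndim %in% 1:2)
  nbins <- vapply(edges, function(e) length(e) - 1L, 0L)
  stopifnot(length(values) == prod(nbins))
  if (all(is.na(values))) stop("surface has no unmasked cells")
  values <- values - min(values, na.rm = TRUE)
  structure(list(ndim = ndim, edges = edges, nbins = nbins,
                 values = values, periodic = as.logical(periodic),
                 temperature = temperature),
            class = "fe_surface")
}

#' @export
print.fe_surface <- function(x, ...) {
  cat("<fe_surface>", x$ndim, "D,", paste(x$nbins, collapse = " x "),
      "cells,", sum(is.na(x$values)), "masked, max F =",
      round(max(x$values, na.rm = TRUE), 2), "kJ/mol\n")
  invisible(x)
}

#' Cell-center coordinates of a surface
#' @param fes a `fe_surface`
#' @return matrix with one row per cell, one column per dimension
#' @export
fes_centers <- function(fes) {
  cs <- lapply(fes$edges, function(e) (e[-1] + e[-length(e)]) / 2)
  if (fes$ndim == 1) matrix(cs[[1]], ncol = 1) else
    as.matrix(expand.grid(cs[[1]], cs[[2]]))
}

#' Free-energy surface from unbiased CV samples
#'
#' Boltzmann inversion of the sampled CV density:
#' `F = -kT log(counts / max(counts))` per cell, empty cells masked,
#' shifted to min zero. This is the unbiased oracle against which the
#' adaptive-bias estimate is validated.
#'
#' @param cv_samples numeric vector (1-D) or matrix with one column per CV
#' @param lo,hi,nbins,periodic grid definition per dimension
#' @param temperature K
#' @return a [fe_surface]
#' @export
histogram_fes <- function(cv_samples, lo, hi, nbins,
                          periodic = rep(FALSE, length(lo)),
                          temperature = 300) {
  z <- if (is.matrix(cv_samples)) cv_samples else matrix(cv_samples, ncol = 1)
  if (nrow(z) == 0) stop("no samples")
  if (!all(is.finite(z))) stop("non-finite samples")
  ndim <- ncol(z)
  stopifnot(length(lo) == ndim, length(hi) == ndim, length(nbins) == ndim)
  idx <- matrix(0L, nrow(z), ndim)
  for (d in seq_len(ndim)) {
    dx <- (hi[d] - lo[d]) / nbins[d]
    u <- floor((z[, d] - lo[d]) / dx)
    if (periodic[d]) u <- ((u %% nbins[d]) + nbins[d]) %% nbins[d]
    else u[u == nbins[d] & z[, d] <= hi[d] + 1e-12] <- nbins[d] - 1
    idx[, d] <- u
  }
  keep <- rowSums(idx >= 0 & idx < matrix(nbins, nrow(z), ndim, byrow = TRUE)) == ndim
  idx <- idx[keep, , drop = FALSE]
  cell <- idx[, 1] + 1L + if (ndim == 2) nbins[1] * idx[, 2] else 0L
  counts <- tabulate(cell, nbins = prod(nbins))
  if (all(counts == 0)) stop("no samples fall on the grid")
  kT <- kB * temperature
  vals <- ifelse(counts > 0, -kT * log(counts / max(counts)), NA_real_)
  edges <- lapply(seq_len(ndim), function(d)
    seq(lo[d], hi[d], length.out = nbins[d] + 1))
  fe_surface(edges, vals, periodic, temperature)
}

#' Free-energy difference between two regions
#'
#' Boltzmann-weighted region free energies:
#' `delta_f = -kT log( sum_A exp(-F/kT) / sum_B exp(-F/kT) )`,
#' i.e. `F(A) - F(B)`. Regions are predicates over cell centers (functions
#' returning a logical per row of [fes_centers()]) or logical cell vectors.
#' Masked cells are excluded.
#'
#' @param fes a [fe_surface]
#' @param regionA,regionB region predicates or logical vectors
#' @return free-energy difference F(A) - F(B), kJ/mol
#' @export
delta_f <- function(fes, regionA, regionB) {
  centers <- fes_centers(fes)
  resolve <- function(r) {
    sel <- if (is.function(r)) {
      v <- apply(centers, 1, function(row) isTRUE(r(if (fes$ndim == 1) row[1] else row)))
      v
    } else as.logical(r)
    sel & !is.na(fes$values)
  }
  a <- resolve(regionA); b <- resolve(regionB)
  if (!any(a)) stop("region A contains no unmasked cells")
  if (!any(b)) stop("region B contains no unmasked cells")
  kT <- kB * fes$temperature
  fa <- -kT * log(sum(exp(-fes$values[a] / kT)))
  fb <- -kT * log(sum(exp(-fes$values[b] / kT)))
  fa - fb
}

#' Default xi1 state regions of the duplex
#'
#' Paired (intrahelical): `|xi1| < pi/3`; flipped (extrahelical):
#' `|xi1| > 2*pi/3`.
#'
#' @return list with predicate functions `paired` and `flipped`
#' @export
xi1_regions <- function() {
  list(paired = function(z) abs(wrap_angle(z)) < pi / 3,
       flipped = function(z) abs(wrap_angle(z)) > 2 * pi / 3)
}

#' Barrier height between two points on a 1-D surface
#'
#' Maximum free energy along the minimal path from `a` to `b` minus the
#' free energy at `a`. On periodic surfaces the lower of the two arcs is
#' taken. A masked cell between `a` and `b` (on both arcs, if periodic)
#' is an error.
#'
#' @param fes a 1-D [fe_surface]
#' @param a,b CV values
#' @return barrier height, kJ/mol
#' @export
barrier <- function(fes, a, b) {
  if (fes$ndim != 1) stop("barrier requires a 1-D surface")
  n <- fes$nbins[1]
  locate <- function(z) {
    e <- fes$edges[[1]]
    dx <- e[2] - e[1]
    i <- floor((z - e[1]) / dx)
    if (fes$periodic[1]) i <- ((i %% n) + n) %% n
    if (i < 0 || i >= n) stop("value outside surface range")
    as.integer(i) + 1L
  }
  ia <- locate(a); ib <- locate(b)
  if (is.na(fes$values[ia])) stop("point a lies in a masked cell")
  arc_max <- function(path) {
    v <- fes$values[path]
    if (anyNA(v)) NA_real_ else max(v)
  }
  if (ia == ib) return(0)
  fwd <- ia:ib
  if (fes$periodic[1]) {
    bwd <- if (ia < ib) c(ia:1, n:ib) else c(ia:n, 1:ib)
    ms <- c(arc_max(fwd), arc_max(bwd))
    if (all(is.na(ms))) stop("masked gap between a and b on both arcs")
    min(ms, na.rm = TRUE) - fes$values[ia]
  } else {
    m <- arc_max(fwd)
    if (is.na(m)) stop("masked gap between a and b")
    m - fes$values[ia]
  }
}

#' Write / read a free-energy surface as TSV
#'
#' Header comments carry the grid edges, periodicity and temperature;
#' masked cells are serialized as NaN. Writing then reading restores the
#' values bitwise.
#'
#' @param fes a [fe_surface]
#' @param path file path
#' @export
write_fes <- function(fes, path) {
  hdr <- c("# baseflip fes",
           paste0("# ndim\t", fes$ndim),
           paste0("# nbins\t", paste(fes$nbins, collapse = "\t")),
           paste0("# periodic\t", paste(as.integer(fes$periodic), collapse = "\t")),
           paste0("# temperature\t", sprintf("%.17g", fes$temperature)),
           vapply(seq_len(fes$ndim), function(d)
             paste0("# edges", d, "\t",
                    paste(sprintf("%.17g", fes$edges[[d]]), collapse = "\t")), ""))
  centers <- fes_centers(fes)
  vals <- ifelse(is.na(fes$values), "NaN", sprintf("%.17g", fes$values))
  cols <- apply(centers, 2, function(x) sprintf("%.17g", x))
  cols <- if (is.matrix(cols)) cols else matrix(cols, ncol = 1)
  body <- apply(cbind(cols, vals), 1, paste, collapse = "\t")
  writeLines(c(hdr, paste(c(paste0("cv", seq_len(fes$ndim)), "F"),
                          collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# baseflip fes", lines[1]))
    stop("parse error at line 1: missing fes header")
  gv <- function(tag) {
    hit <- grep(paste0("^# ", tag, "\t"), lines)
    if (!length(hit)) stop("parse error: missing header field '", tag, "'")
    strsplit(sub(paste0("^# ", tag, "\t"), "", lines[hit[1]]), "\t")[[1]]
  }
  ndim <- as.integer(gv("ndim"))
  periodic <- as.logical(as.integer(gv("periodic")))
  temperature <- as.numeric(gv("temperature"))
  edges <- lapply(seq_len(ndim), function(d) as.numeric(gv(paste0("edges", d))))
  first_data <- which(!startsWith(lines, "#"))[1] + 1L
  vals <- vapply(lines[first_data:length(lines)], function(l) {
    f <- strsplit(l, "\t")[[1]]
    as.numeric(f[length(f)])
  }, 0.0, USE.NAMES = FALSE)
  vals[is.nan(vals)] <- NA_real_
  fe_surface(edges, vals, periodic, temperature)
}
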