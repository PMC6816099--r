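# Structural meta-analysis of flipped-base complexes: PDB reading (via
# bio3d), Kabsch superposition, iterative outlier-rejecting alignment, and
# the pooled shared-atom RMSD of flipped modified cytosines across
# SRA-DNA costructures.

AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
         "MSE","SEC","PYL")

MODIFIED_CYTOSINES <- c("5CM", "5MC", "5HC", "5HM", "C49", "1CC")

#' Shared heavy atoms of 5-methyl- and 5-hydroxymethyl-cytosine
#'
#' Cytosine ring and exocyclic heavy atoms plus the C5 methyl(ene) carbon;
#' the hydroxymethyl oxygen is excluded because it has no 5mC counterpart.
#' @export
shared_5mc_atoms <- c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6", "C7")

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records through bio3d. Alternate locations are
#' resolved per atom by keeping the highest-occupancy conformer, ties
#' going to altloc `A`. PDB serial and residue numbers are 1-based and
#' preserved as printed.
#'
#' @param file PDB file path
#' @param source_id accession label attached to the structure
#' @return object of class `structure3d`: a data frame of atoms
#'   (`name`, `element`, `resname`, `resno`, `chain`, `x`, `y`, `z`,
#'   `occupancy`, `altloc`, `is_protein`) with attribute `source_id`
#' @export
read_structure <- function(file, source_id = tools::file_path_sans_ext(basename(file))) {
  if (!file.exists(file)) stop("no such file: ", file)
  lines <- readLines(file, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty structure: no ATOM/HETATM records in ", file)
  for (i in which(rec)) {
    coords <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46), substr(lines[i], 47, 54))))
    if (anyNA(coords))
      stop("parse error at line ", i, ": unreadable coordinates")
  }
  pdb <- bio3d::read.pdb(file, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  at <- data.frame(
    name = a$elety, element = a$elesy, resname = a$resid,
    resno = a$resno, chain = ifelse(is.na(a$chain), "", a$chain),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(at[c("x", "y", "z")]))))
    stop("non-finite coordinates in ", file)
  # altloc policy: highest occupancy, tie -> 'A'
  key <- paste(at$chain, at$resno, at$name)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- at$occupancy[idx]
    best <- idx[occ == max(occ)]
    if (length(best) > 1) {
      pa <- best[at$altloc[best] %in% c("A", "")]
      best <- if (length(pa)) pa[1] else best[1]
    }
    best[1]
  }))
  at <- at[sort(keep), , drop = FALSE]
  rownames(at) <- NULL
  at$is_protein <- at$resname %in% AA3
  structure(at, class = c("structure3d", "data.frame"), source_id = source_id)
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d>", attr(x, "source_id"), "|", nrow(x), "atoms,",
      sum(x$is_protein), "protein\n")
  invisible(x)
}

coords_of <- function(s) as.matrix(as.data.frame(s)[c("x", "y", "z")])

#' Optimal least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired coordinate sets; reflections are excluded by the determinant
#' correction. The transform maps `mobile` onto `target`:
#' `x' = x %*% t(rotation) + translation`.
#'
#' @param mobile,target n x 3 matrices of paired coordinates (n >= 3,
#'   non-collinear)
#' @return object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd_all`, `n_fitted`, `n_rejected`
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target)) stop("coordinate sets must be paired")
  if (nrow(mobile) < 3) stop("at least 3 point pairs required")
  cm <- colMeans(mobile); ct <- colMeans(target)
  M <- sweep(mobile, 2, cm); T <- sweep(target, 2, ct)
  if (svd(M)$d[2] < 1e-8 || svd(T)$d[2] < 1e-8)
    stop("degenerate geometry: collinear or coincident points")
  H <- t(M) %*% T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- M %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - T)^2)))
  structure(list(rotation = R, translation = as.numeric(ct - R %*% cm),
                 rmsd_all = rmsd, rmsd_subset = NA_real_,
                 n_fitted = nrow(mobile), n_rejected = 0L),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> RMSD", round(x$rmsd_all, 4), "A over", x$n_fitted,
      "atoms (", x$n_rejected, "rejected )\n")
  invisible(x)
}

#' Apply a superposition to coordinates or a structure
#' @param x n x 3 matrix or `structure3d`
#' @param sp a `superposition`
#' @return transformed object of the same type
#' @export
apply_superposition <- function(x, sp) {
  if (inherits(x, "structure3d")) {
    m <- coords_of(x) %*% t(sp$rotation)
    m <- sweep(m, 2, sp$translation, "+")
    x$x <- m[, 1]; x$y <- m[, 2]; x$z <- m[, 3]
    return(x)
  }
  sweep(as.matrix(x) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' Pair atoms of two structures by residue number and atom name
#'
#' Sequence-independent matching on (chain, residue number, atom name);
#' if the two structures share no chain identifiers, the chain is dropped
#' from the key.
#'
#' @param mobile,target `structure3d` objects
#' @param protein_only restrict to protein atoms
#' @return list of two index vectors (`mobile`, `target`)
#' @export
pair_atoms <- function(mobile, target, protein_only = TRUE) {
  sel_m <- if (protein_only) which(mobile$is_protein) else seq_len(nrow(mobile))
  sel_t <- if (protein_only) which(target$is_protein) else seq_len(nrow(target))
  use_chain <- length(intersect(unique(mobile$chain[sel_m]),
                                unique(target$chain[sel_t]))) > 0
  keyf <- function(s, idx) {
    if (use_chain) paste(s$chain[idx], s$resno[idx], s$name[idx])
    else paste(s$resno[idx], s$name[idx])
  }
  km <- keyf(mobile, sel_m); kt <- keyf(target, sel_t)
  common <- intersect(km, kt)
  list(mobile = sel_m[match(common, km)], target = sel_t[match(common, kt)])
}

#' Iterative superposition with outlier rejection
#'
#' Kabsch superposition followed by up to `cycles` rounds in which atom
#' pairs deviating by more than `reject_cutoff` are discarded and the fit
#' repeated — the behavior of standard structure-alignment tools. Defaults
#' (`cycles = 5`, `reject_cutoff = 2` Angstrom) mirror those tools.
#'
#' @param mobile,target `structure3d` objects or paired n x 3 matrices
#' @param cycles maximum rejection rounds
#' @param reject_cutoff per-atom deviation cutoff, Angstrom
#' @param protein_only pair only protein atoms (structures only)
#' @return a `superposition` with `n_rejected` filled in
#' @export
align_iterative <- function(mobile, target, cycles = 5, reject_cutoff = 2,
                            protein_only = TRUE) {
  if (inherits(mobile, "structure3d")) {
    pr <- pair_atoms(mobile, target, protein_only)
    if (length(pr$mobile) < 3) stop("fewer than 3 matched atom pairs")
    mm <- coords_of(mobile)[pr$mobile, , drop = FALSE]
    tt <- coords_of(target)[pr$target, , drop = FALSE]
  } else {
    mm <- as.matrix(mobile); tt <- as.matrix(target)
  }
  keep <- seq_len(nrow(mm))
  rejected <- 0L
  sp <- kabsch_superpose(mm, tt)
  for (cy in seq_len(cycles)) {
    fitted <- apply_superposition(mm[keep, , drop = FALSE], sp)
    dev <- sqrt(rowSums((fitted - tt[keep, , drop = FALSE])^2))
    bad <- dev > reject_cutoff
    if (!any(bad)) break
    if (sum(!bad) < 3) stop("fewer than 3 pairs survive rejection")
    keep <- keep[!bad]
    rejected <- rejected + sum(bad)
    sp <- kabsch_superpose(mm[keep, , drop = FALSE], tt[keep, , drop = FALSE])
  }
  sp$n_fitted <- length(keep)
  sp$n_rejected <- rejected
  sp
}

find_flipped_base <- function(s) {
  hit <- which(s$resname %in% MODIFIED_CYTOSINES)
  if (!length(hit)) stop("no modified cytosine residue found in ",
                         attr(s, "source_id"))
  first <- hit[1]
  which(s$chain == s$chain[first] & s$resno == s$resno[first] &
        s$resname == s$resname[first])
}

#' Pooled shared-atom RMSD of flipped modified bases
#'
#' Each structure is superposed onto the reference over all matched
#' protein atoms with [align_iterative()]; the named shared atoms of its
#' flipped modified cytosine are then compared with the reference's. The
#' pooled value is `sqrt(mean(squared deviations))` over every
#' (structure, atom) pair; `pooled = FALSE` instead averages per-structure
#' RMSDs.
#'
#' @param structures named list of `structure3d` objects (including the
#'   reference)
#' @param reference_id name of the reference structure in `structures`
#' @param shared_atom_names atom names compared (default
#'   [shared_5mc_atoms])
#' @param base_residues optional named list of `list(chain =, resno =)`
#'   overriding the automatic modified-cytosine detection
#' @param pooled pooled RMSD (default) or mean of per-structure RMSDs
#' @param cycles,reject_cutoff passed to [align_iterative()]
#' @return list with `rmsd` (Angstrom) and a per-structure `report` data
#'   frame (`id`, `n_fitted`, `n_rejected`, `rmsd_all`, `rmsd_subset`,
#'   `n_shared_atoms`)
#' @export
flipped_base_rmsd <- function(structures, reference_id,
                              shared_atom_names = shared_5mc_atoms,
                              base_residues = NULL, pooled = TRUE,
                              cycles = 5, reject_cutoff = 2) {
  if (!reference_id %in% names(structures))
    stop("reference_id not among structures")
  ref <- structures[[reference_id]]
  base_idx <- function(s, id) {
    if (!is.null(base_residues) && !is.null(base_residues[[id]])) {
      br <- base_residues[[id]]
      which(s$chain == br$chain & s$resno == br$resno)
    } else find_flipped_base(s)
  }
  ref_base <- as.data.frame(ref)[base_idx(ref, reference_id), ]
  ref_xyz <- function(atom) {
    r <- ref_base[ref_base$name == atom, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    as.numeric(r[1, c("x", "y", "z")])
  }
  sq_devs <- c(); per_struct <- numeric(0)
  report <- NULL
  for (id in setdiff(names(structures), reference_id)) {
    s <- structures[[id]]
    sp <- align_iterative(s, ref, cycles = cycles,
                          reject_cutoff = reject_cutoff)
    st <- apply_superposition(s, sp)
    base <- as.data.frame(st)[base_idx(st, id), ]
    missing <- character(0)
    devs <- c()
    for (atom in shared_atom_names) {
      rx <- ref_xyz(atom)
      b <- base[base$name == atom, , drop = FALSE]
      if (is.null(rx) || !nrow(b)) { missing <- c(missing, atom); next }
      devs <- c(devs, sum((as.numeric(b[1, c("x", "y", "z")]) - rx)^2))
    }
    if (length(missing))
      warning(id, ": missing shared atoms ", paste(missing, collapse = ", "))
    if (!length(devs)) stop(id, ": no shared atoms found on the flipped base")
    sq_devs <- c(sq_devs, devs)
    per_struct <- c(per_struct, sqrt(mean(devs)))
    report <- rbind(report, data.frame(
      id = id, n_fitted = sp$n_fitted, n_rejected = sp$n_rejected,
      rmsd_all = sp$rmsd_all, rmsd_subset = sqrt(mean(devs)),
      n_shared_atoms = length(devs)))
  }
  rmsd <- if (pooled) sqrt(mean(sq_devs)) else mean(per_struct)
  list(rmsd = rmsd, report = report)
}

#' Write a superposition report as TSV
#' @param result output of [flipped_base_rmsd()]
#' @param path output file
#' @export
write_structcompare_tsv <- function(result, path) {
  write_tsv17(result$report, path)
  invisible(path)
}
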