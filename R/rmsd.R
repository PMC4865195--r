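# Symmetry-corrected RMSD: chemically equivalent atoms (same element and
# AutoDock type) are interchangeable, so the naive index-matched RMSD
# overestimates the distance between two conformations whenever such atoms
# are permuted. The correction solves an optimal assignment within each
# (element, type) block -- cost = squared interatomic distance -- and takes
# the root mean square over the optimal mapping. Poses are compared in a
# common (receptor) frame; no superposition is performed, as in re-docking
# evaluation. Heavy atoms only.

atom_block_key <- function(atoms) paste(atoms$element, atoms$ad_type)

coords_and_types <- function(x) {
  if (inherits(x, "ligand_model")) {
    list(xyz = x$xyz, atoms = x$atoms)
  } else if (is.list(x) && !is.null(x$xyz) && !is.null(x$atoms)) {
    list(xyz = x$xyz, atoms = x$atoms)
  } else {
    stop("expected a ligand_model or list(xyz =, atoms =)", call. = FALSE)
  }
}

#' Symmetry-corrected RMSD via optimal atom assignment
#'
#' Minimizes the root-mean-square deviation between two conformations of
#' the same molecule over all atom mappings that pair atoms of identical
#' element and AutoDock type. Each within-type block is solved as a linear
#' assignment problem on squared distances (Hungarian method via
#' [clue::solve_LSAP()]). `probe_xyz` can override the probe coordinates,
#' e.g. to compare one model against many poses.
#'
#' @param ref,probe `ligand_model`s (or `list(xyz =, atoms =)`) with the
#'   same multiset of (element, type).
#' @param probe_xyz optional coordinate matrix replacing `probe`'s.
#' @return an `rmsd_result`: list with `rmsd` (Angstrom), `mapping`
#'   (permutation of the probe's heavy-atom indices, named by the
#'   reference's heavy-atom indices), and `naive_rmsd` (identity mapping).
#'   Always `rmsd <= naive_rmsd`.
#' @export
hungarian_rmsd <- function(ref, probe, probe_xyz = NULL) {
  a <- coords_and_types(ref)
  b <- coords_and_types(probe)
  if (!is.null(probe_xyz)) b$xyz <- probe_xyz
  ha <- which(a$atoms$is_heavy)
  hb <- which(b$atoms$is_heavy)
  if (length(ha) != length(hb)) {
    stop("heavy-atom counts differ (", length(ha), " vs ", length(hb), ")",
         call. = FALSE)
  }
  keys_a <- atom_block_key(a$atoms)[ha]
  keys_b <- atom_block_key(b$atoms)[hb]
  if (!identical(sort(keys_a), sort(keys_b))) {
    stop("atom type multisets differ between reference and probe",
         call. = FALSE)
  }
  xa <- a$xyz[ha, , drop = FALSE]
  xb <- b$xyz[hb, , drop = FALSE]
  mapping <- integer(length(ha))
  ss <- 0
  for (key in unique(keys_a)) {
    ia <- which(keys_a == key)
    ib <- which(keys_b == key)
    if (length(ia) == 1L) {
      mapping[ia] <- ib
      ss <- ss + sum((xa[ia, ] - xb[ib, ])^2)
      next
    }
    cost <- outer(seq_along(ia), seq_along(ib), function(p, q) {
      rowSums((xa[ia[p], , drop = FALSE] - xb[ib[q], , drop = FALSE])^2)
    })
    sol <- clue::solve_LSAP(cost)
    mapping[ia] <- ib[as.integer(sol)]
    ss <- ss + sum(cost[cbind(seq_along(ia), as.integer(sol))])
  }
  naive <- sqrt(mean(rowSums((xa - xb)^2)))
  structure(list(rmsd = sqrt(ss / length(ha)),
                 mapping = stats::setNames(hb[mapping], ha),
                 naive_rmsd = naive),
            class = "rmsd_result")
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat(sprintf("<rmsd_result> rmsd %.4f A (naive %.4f A)\n",
              x$rmsd, x$naive_rmsd))
  invisible(x)
}

#' Re-docking success test
#'
#' A pose reproduces the reference when its symmetry-corrected RMSD is
#' equal to, or less than, the threshold (2 A by convention).
#'
#' @param rmsd non-negative RMSD value(s), Angstrom.
#' @param threshold success threshold, Angstrom.
#' @return logical.
#' @export
docking_success <- function(rmsd, threshold = 2.0) {
  if (any(rmsd < 0)) stop("rmsd must be non-negative", call. = FALSE)
  rmsd <= threshold
}
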