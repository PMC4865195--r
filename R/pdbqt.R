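# AutoDock PDBQT i/o: atom records carry partial charge (columns after the
# coordinates) and an AutoDock atom type as the last token; ligand files add
# a torsion tree (ROOT/BRANCH/TORSDOF records). Hydrogens are parsed but
# excluded from all pair sums; polar hydrogens (type HD) only mark their
# heavy neighbor as an H-bond donor.

# AutoDock type -> chemical element. Aromatic carbon is type "A" as written
# in the file; no ring perception is attempted. Vanadium is typed as sulfur
# (the common preparation workaround for unsupported V).
AD_TYPE_ELEMENT <- c(
  C = "C", A = "C", N = "N", "NA" = "N", NS = "N", O = "O", OA = "O",
  OS = "O", S = "S", SA = "S", V = "S", H = "H", HD = "H", HS = "H",
  F = "F", Cl = "Cl", CL = "Cl", Br = "Br", BR = "Br", I = "I", P = "P",
  Mg = "Mg", MG = "Mg", Mn = "Mn", MN = "Mn", Zn = "Zn", ZN = "Zn",
  Ca = "Ca", CA = "Ca", Fe = "Fe", FE = "Fe", Cu = "Cu", CU = "Cu",
  Ni = "Ni", Co = "Co", Cd = "Cd", Hg = "Hg", K = "K", Li = "Li",
  Sr = "Sr", Cs = "Cs", Al = "Al"
)

METAL_ELEMENTS <- c("Mg", "Mn", "Zn", "Ca", "Fe", "Cu", "Ni", "Co", "Cd",
                    "Hg", "Na", "K", "Li", "Sr", "Cs", "Al")
HALOGEN_ELEMENTS <- c("F", "Cl", "Br", "I")

# single-bond covalent radii (Angstrom) for distance-based bond perception
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                    P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)

`%||%` <- function(a, b) if (is.null(a)) b else a

covalent_radius <- function(element) {
  r <- COVALENT_RADII[element]
  r[is.na(r)] <- 1.4  # metals and anything exotic: generous default
  unname(r)
}

ad_type_element <- function(ad_type) {
  el <- AD_TYPE_ELEMENT[ad_type]
  if (anyNA(el)) {
    stop("unknown AutoDock atom type token(s): ",
         paste(unique(ad_type[is.na(el)]), collapse = ", "), call. = FALSE)
  }
  unname(el)
}

# radius table key: aromatic carbon gets its own entry, metals share one
radius_class <- function(ad_type, element) {
  ifelse(ad_type == "A", "CA",
         ifelse(element %in% METAL_ELEMENTS, "Met", element))
}

#' Parse a PDBQT file or text
#'
#' Reads AutoDock PDBQT content. For `role = "receptor"` only ATOM/HETATM
#' records are used and the result is a rigid `receptor_model` with a
#' uniform-grid spatial index. For `role = "ligand"` the ROOT/BRANCH torsion
#' tree is required and reproduced as a rooted tree of rigid fragments, one
#' rotatable bond per BRANCH record.
#'
#' Atoms are typed on parse: element and radius class from the AutoDock type
#' token, interaction class from the type plus distance-perceived bonds (see
#' [classify_atoms()]). Multi-model files are read at `model = 1` by default;
#' use [parse_poses()] to read every MODEL block.
#'
#' @param x a file path, or PDBQT text (single string with newlines, or a
#'   character vector of lines).
#' @param role `"ligand"` or `"receptor"`.
#' @param model which MODEL block to read when the file has several.
#' @return A `ligand_model` (elements `atoms`, `xyz`, `torsions`,
#'   `fragments`, `n_rot`, `torsdof`, `bonds`, `intra_pairs`, `layout`) or a
#'   `receptor_model` (elements `atoms`, `xyz`, `index`).
#' @export
parse_pdbqt <- function(x, role = c("ligand", "receptor"), model = 1L) {
  role <- match.arg(role)
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }

  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0) {
    model_ends <- grep("^ENDMDL", lines)
    if (model > length(model_starts)) {
      stop("requested MODEL ", model, " but file has ",
           length(model_starts), call. = FALSE)
    }
    end <- if (model <= length(model_ends)) model_ends[model] else length(lines)
    lines <- lines[(model_starts[model] + 1L):(end - 1L)]
  }

  rec <- substr(lines, 1, 6)
  serial <- name <- ad_type <- character(0)
  coords <- matrix(numeric(0), ncol = 3)
  charge <- numeric(0)
  frag_of <- integer(0)
  layout <- list()

  frag_stack <- integer(0)
  frag_counter <- 0L
  frag_parent <- integer(0)
  torsions <- list()
  seen_root <- FALSE
  torsdof <- NA_integer_

  for (i in seq_along(lines)) {
    line <- lines[i]
    key <- trimws(rec[i])
    if (key %in% c("ATOM", "HETATM")) {
      xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                           substr(line, 39, 46),
                                           substr(line, 47, 54))))
      if (anyNA(xyz)) {
        stop("malformed coordinates at line ", i, ": ", line, call. = FALSE)
      }
      tail_toks <- strsplit(trimws(substr(line, 55, nchar(line))),
                            "[[:space:]]+")[[1]]
      if (length(tail_toks) == 0L) {
        stop("missing AutoDock type at line ", i, ": ", line, call. = FALSE)
      }
      typ <- tail_toks[length(tail_toks)]
      chg <- if (length(tail_toks) >= 2L) {
        suppressWarnings(as.numeric(tail_toks[length(tail_toks) - 1L]))
      } else NA_real_
      if (role == "ligand" && !seen_root) {
        stop("ligand atom outside ROOT at line ", i, call. = FALSE)
      }
      serial <- c(serial, trimws(substr(line, 7, 11)))
      name <- c(name, trimws(substr(line, 13, 16)))
      ad_type <- c(ad_type, typ)
      coords <- rbind(coords, xyz)
      charge <- c(charge, if (is.na(chg)) 0 else chg)
      frag_of <- c(frag_of, if (length(frag_stack)) frag_stack[length(frag_stack)] else 1L)
      layout[[length(layout) + 1L]] <- list(kind = "atom", idx = nrow(coords))
    } else if (role == "ligand" && key == "ROOT") {
      frag_counter <- 1L
      frag_stack <- 1L
      frag_parent <- 0L
      seen_root <- TRUE
      layout[[length(layout) + 1L]] <- list(kind = "text", text = "ROOT")
    } else if (role == "ligand" && key == "ENDROO") {
      layout[[length(layout) + 1L]] <- list(kind = "text", text = "ENDROOT")
    } else if (role == "ligand" && key == "BRANCH") {
      ab <- as.integer(strsplit(trimws(sub("^BRANCH", "", line)),
                                "[[:space:]]+")[[1]])
      if (length(ab) != 2L || anyNA(ab)) {
        stop("malformed BRANCH record at line ", i, ": ", line, call. = FALSE)
      }
      frag_counter <- frag_counter + 1L
      frag_parent <- c(frag_parent, frag_stack[length(frag_stack)])
      frag_stack <- c(frag_stack, frag_counter)
      torsions[[length(torsions) + 1L]] <- list(
        parent_serial = ab[1], child_serial = ab[2], frag = frag_counter)
      layout[[length(layout) + 1L]] <- list(kind = "text", text = trimws(line))
    } else if (role == "ligand" && key == "ENDBRA") {
      if (length(frag_stack) <= 1L) {
        stop("ENDBRANCH without matching BRANCH at line ", i, call. = FALSE)
      }
      frag_stack <- frag_stack[-length(frag_stack)]
      layout[[length(layout) + 1L]] <- list(kind = "text", text = trimws(line))
    } else if (role == "ligand" && key == "TORSDO") {
      torsdof <- as.integer(strsplit(trimws(line), "[[:space:]]+")[[1]][2])
      layout[[length(layout) + 1L]] <- list(kind = "text", text = trimws(line))
    }
    # REMARK and anything else: ignored
  }

  if (nrow(coords) == 0L) stop("no ATOM/HETATM records found", call. = FALSE)
  if (role == "ligand") {
    if (!seen_root) stop("ligand PDBQT requires a ROOT record", call. = FALSE)
    if (length(frag_stack) > 1L) {
      stop("unclosed BRANCH record (", length(frag_stack) - 1L,
           " still open at end of input)", call. = FALSE)
    }
  }

  element <- ad_type_element(ad_type)
  atoms <- data.frame(
    serial = as.integer(serial),
    name = name,
    element = element,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    charge = charge,
    ad_type = ad_type,
    radius_class = radius_class(ad_type, element),
    is_heavy = element != "H",
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL
  xyz <- unname(coords)

  bonds <- perceive_bonds(xyz, element)
  atoms$class <- classify_atoms(atoms, bonds)

  if (role == "receptor") {
    return(structure(list(atoms = atoms, xyz = xyz,
                          index = build_spatial_index(xyz)),
                     class = "receptor_model"))
  }

  # resolve torsion axis serials to row indices and moved-atom sets
  n_frag <- frag_counter
  children <- lapply(seq_len(n_frag), function(f) which(frag_parent == f))
  descendants <- function(f) {
    out <- f
    queue <- children[[f]]
    while (length(queue)) {
      out <- c(out, queue[1])
      queue <- c(queue[-1], children[[queue[1]]])
    }
    out
  }
  torsions <- lapply(torsions, function(tr) {
    a <- match(tr$parent_serial, atoms$serial)
    b <- match(tr$child_serial, atoms$serial)
    if (is.na(a) || is.na(b)) {
      stop("BRANCH axis serial ", tr$parent_serial, "-", tr$child_serial,
           " does not match any atom", call. = FALSE)
    }
    list(axis = c(a, b), frag = tr$frag,
         moved = which(frag_of %in% descendants(tr$frag)))
  })

  model <- structure(list(
    atoms = atoms, xyz = xyz, torsions = torsions, fragments = frag_of,
    n_rot = length(torsions), torsdof = torsdof, bonds = bonds,
    layout = layout
  ), class = "ligand_model")
  model$intra_pairs <- eligible_intra_pairs(model)
  model
}

#' @export
print.ligand_model <- function(x, ...) {
  cat("<ligand_model> ", nrow(x$atoms), " atoms (",
      sum(x$atoms$is_heavy), " heavy), ", x$n_rot, " rotatable bond(s)",
      if (!is.na(x$torsdof)) paste0(", TORSDOF ", x$torsdof), "\n", sep = "")
  invisible(x)
}

#' @export
print.receptor_model <- function(x, ...) {
  cat("<receptor_model>", nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Distance-based covalent bond perception
#'
#' Two atoms are bonded when their distance is below 1.2 times the sum of
#' their single-bond covalent radii (and above 0.4 A, to reject coincident
#' records). Used because PDBQT carries no connectivity.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param element chemical symbols, length n.
#' @return two-column integer matrix of bonded atom index pairs (i < j).
#' @export
perceive_bonds <- function(xyz, element) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  cov <- covalent_radius(element)
  max_bond <- 1.2 * 2 * max(cov)
  idx <- build_spatial_index(xyz, cell = max(max_bond, 1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- query_spatial_index(idx, xyz[i, ], max_bond)
    cand <- cand[cand > i]
    if (!length(cand)) next
    d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
    cut <- 1.2 * (cov[i] + cov[cand])
    keep <- cand[d < cut & d > 0.4]
    if (length(keep)) out[[i]] <- cbind(i, keep)
  }
  bonds <- do.call(rbind, out)
  if (is.null(bonds)) matrix(integer(0), ncol = 2) else unname(bonds)
}

#' Assign interaction classes to typed atoms
#'
#' Pure function of the AutoDock type and the bonded neighbors:
#' carbon bonded only to carbon/hydrogen is `hydrophobic`, carbon bonded to
#' any heteroatom is `polar_nonhb`; types NA/OA are acceptors; N/O with a
#' bonded polar hydrogen (type HD) are donors (`donor_acceptor` when both);
#' halogens are hydrophobic; metals are class `metal` and count as donors in
#' H-bond pairing; hydrogens are class `hydrogen`.
#'
#' @param atoms data frame with columns `element`, `ad_type` (as produced by
#'   [parse_pdbqt()]) plus coordinates `x`,`y`,`z` if `bonds` is `NULL`.
#' @param bonds two-column bond index matrix; perceived from coordinates
#'   when `NULL`.
#' @return character vector of interaction classes.
#' @export
classify_atoms <- function(atoms, bonds = NULL) {
  n <- nrow(atoms)
  if (is.null(bonds)) {
    bonds <- perceive_bonds(as.matrix(atoms[, c("x", "y", "z")]),
                            atoms$element)
  }
  nbrs <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      nbrs[[i]] <- c(nbrs[[i]], j)
      nbrs[[j]] <- c(nbrs[[j]], i)
    }
  }
  el <- atoms$element
  typ <- atoms$ad_type
  cls <- character(n)
  for (i in seq_len(n)) {
    e <- el[i]
    if (e == "H") {
      cls[i] <- "hydrogen"
    } else if (e %in% METAL_ELEMENTS) {
      cls[i] <- "metal"
    } else if (e %in% HALOGEN_ELEMENTS) {
      cls[i] <- "hydrophobic"
    } else if (e == "C") {
      het <- any(!el[nbrs[[i]]] %in% c("C", "H"))
      cls[i] <- if (het) "polar_nonhb" else "hydrophobic"
    } else {
      acceptor <- typ[i] %in% c("NA", "OA")
      donor <- e %in% c("N", "O") &&
        any(typ[nbrs[[i]]] == "HD")
      cls[i] <- if (acceptor && donor) "donor_acceptor"
      else if (acceptor) "acceptor"
      else if (donor) "donor"
      else "polar_nonhb"
    }
  }
  cls
}

#' Attach per-atom radii from a parameter set
#'
#' Scoring always resolves radii through the parameter set (the Vina and
#' Vinardo presets differ in their C/N/O radii); this helper materializes
#' the lookup as a `radius` column for inspection. Hydrogens get `NA`: they
#' carry no radius used in scoring.
#'
#' @param model a `ligand_model` or `receptor_model`.
#' @param params a `term_param_set`.
#' @return the model with `atoms$radius` filled in.
#' @export
assign_radii <- function(model, params) {
  model$atoms$radius <- atom_radii(model$atoms, params)
  model
}

atom_radii <- function(atoms, params) {
  r <- unname(params$radii[atoms$radius_class])
  missing <- atoms$is_heavy & is.na(r)
  if (any(missing)) {
    stop("no radius configured for class(es): ",
         paste(unique(atoms$radius_class[missing]), collapse = ", "),
         call. = FALSE)
  }
  r[!atoms$is_heavy] <- NA_real_
  r
}

format_pdbqt_atom <- function(i, atoms, xyz) {
  sprintf("ATOM  %5d %-4s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          atoms$serial[i], atoms$name[i], "LIG", "A", 1L,
          xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0,
          atoms$charge[i], atoms$ad_type[i])
}

#' Write ligand poses as multi-model PDBQT
#'
#' Each pose becomes one MODEL block carrying the ligand's full torsion-tree
#' records (so every block is itself parseable) and, when scores are given,
#' a `REMARK SCORE` line. Poses are written in the order supplied; sort by
#' score beforehand for ranked output.
#'
#' @param model a `ligand_model`.
#' @param poses list of n_atoms x 3 coordinate matrices (a single matrix is
#'   accepted).
#' @param scores optional numeric vector, one per pose.
#' @param path optional output file.
#' @return the PDBQT lines, invisibly when `path` is given.
#' @export
write_poses <- function(model, poses, scores = NULL, path = NULL) {
  stopifnot(inherits(model, "ligand_model"))
  if (is.matrix(poses)) poses <- list(poses)
  if (length(poses) == 0L) stop("empty pose list", call. = FALSE)
  n <- nrow(model$atoms)
  ok <- vapply(poses, function(p) is.matrix(p) && all(dim(p) == c(n, 3)),
               TRUE)
  if (!all(ok)) {
    stop("pose/atom count mismatch: each pose needs one coordinate triple ",
         "per atom (", n, " x 3)", call. = FALSE)
  }
  if (!is.null(scores) && length(scores) != length(poses)) {
    stop("scores length must match pose count", call. = FALSE)
  }
  out <- character(0)
  for (m in seq_along(poses)) {
    out <- c(out, sprintf("MODEL %8d", m))
    if (!is.null(scores)) {
      out <- c(out, sprintf("REMARK SCORE %.4f", scores[m]))
    }
    for (entry in model$layout) {
      out <- c(out, if (entry$kind == "atom") {
        format_pdbqt_atom(entry$idx, model$atoms, poses[[m]])
      } else entry$text)
    }
    out <- c(out, "ENDMDL")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read every MODEL block of a multi-model ligand PDBQT
#'
#' @param x file path or PDBQT text.
#' @return list with `model` (the `ligand_model` from the first block),
#'   `poses` (list of coordinate matrices) and `scores` (numeric, `NA` where
#'   no `REMARK SCORE` line was present).
#' @export
parse_poses <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else as.character(x)
  starts <- grep("^MODEL", lines)
  n_model <- max(length(starts), 1L)
  poses <- vector("list", n_model)
  scores <- rep(NA_real_, n_model)
  model <- parse_pdbqt(lines, role = "ligand", model = 1L)
  for (m in seq_len(n_model)) {
    mm <- parse_pdbqt(lines, role = "ligand", model = m)
    poses[[m]] <- mm$xyz
    if (length(starts)) {
      end <- c(starts, length(lines) + 1L)[m + 1L]
      blk <- lines[starts[m]:(end - 1L)]
      sc <- grep("^REMARK SCORE", blk, value = TRUE)
      if (length(sc)) {
        scores[m] <- as.numeric(strsplit(trimws(sc[1]), "[[:space:]]+")[[1]][3])
      }
    }
  }
  list(model = model, poses = poses, scores = scores)
}

#' Uniform-grid spatial index for cutoff queries
#'
#' Buckets atoms into cubic cells so that all atoms within a query radius of
#' a point can be collected by visiting the overlapping cells only. Queries
#' return exactly the brute-force distance filter.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param cell cell edge length in Angstrom.
#' @return a `spatial_index`.
#' @export
build_spatial_index <- function(xyz, cell = 4) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, cell > 0)
  ic <- floor(xyz / cell)
  key <- paste(ic[, 1], ic[, 2], ic[, 3], sep = ",")
  structure(list(cell = cell, map = split(seq_len(nrow(xyz)), key),
                 xyz = xyz),
            class = "spatial_index")
}

#' @rdname build_spatial_index
#' @param index a `spatial_index`.
#' @param point length-3 query point.
#' @param radius query radius in Angstrom.
#' @return sorted integer vector of atom indices within `radius` of `point`.
#' @export
query_spatial_index <- function(index, point, radius) {
  stopifnot(inherits(index, "spatial_index"), length(point) == 3, radius >= 0)
  cell <- index$cell
  lo <- floor((point - radius) / cell)
  hi <- floor((point + radius) / cell)
  keys <- as.vector(outer(
    as.vector(outer(lo[1]:hi[1], lo[2]:hi[2], paste, sep = ",")),
    lo[3]:hi[3], paste, sep = ","))
  cand <- unlist(index$map[keys], use.names = FALSE)
  if (is.null(cand) || !length(cand)) return(integer(0))
  d2 <- colSums((t(index$xyz[cand, , drop = FALSE]) - point)^2)
  sort(cand[d2 <= radius^2])
}
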