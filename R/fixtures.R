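# Deterministic generators of synthetic receptors, ligands, decoy pose
# sets and labeled screening tables. Geometry is idealized (1.5 A bonds,
# tetrahedral chain angles): plausible contact geometry is all the pair
# potentials need, chemical realism is not attempted. Every generator is a
# pure function of its arguments and seed.

fixture_atom_line <- function(serial, name, xyz, charge, ad_type) {
  sprintf("ATOM  %5d %-4s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          serial, name, "LIG", "A", 1L, xyz[1], xyz[2], xyz[3], 1, 0,
          charge, ad_type)
}

# unit directions for shell placement: octahedron, then cube corners
shell_directions <- function(n) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1),
                expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)) /
                  sqrt(3))
  dirs <- as.matrix(dirs)
  if (n > nrow(dirs)) {
    stop("at most ", nrow(dirs), " shell atoms supported", call. = FALSE)
  }
  unname(dirs[seq_len(n), , drop = FALSE])
}

#' Toy pocket with a known optimum
#'
#' Builds a synthetic receptor shell of `n_receptor` atoms placed
#' symmetrically on a sphere around the origin, and a single-atom ligand at
#' the pocket center. The shell radius defaults to the sum of the two
#' atomic radii under `params`, so every contact sits at surface distance
#' zero and -- for a single-minimum (Vinardo-style) steric term -- the
#' global minimum pose is the center by symmetry. `d_offset` shifts the
#' shell radius away from contact to build deliberately displaced optima.
#'
#' Both models are emitted through PDBQT text, so identical arguments give
#' byte-identical files; the text is returned alongside the parsed models.
#'
#' @param n_receptor number of shell atoms (1 to 14).
#' @param ligand_type,receptor_type AutoDock types for the ligand atom and
#'   the shell atoms.
#' @param params parameter set used to resolve contact radii.
#' @param d_offset shell radius offset from contact, Angstrom.
#' @return list with `receptor`, `ligand`, `optimum` (pocket center),
#'   `shell_radius`, and the generated `receptor_text` / `ligand_text`.
#' @export
make_toy_pocket <- function(n_receptor = 6, ligand_type = "C",
                            receptor_type = "C",
                            params = scoring_params("vinardo"),
                            d_offset = 0) {
  el_l <- ad_type_element(ligand_type)
  el_r <- ad_type_element(receptor_type)
  ri <- params$radii[[radius_class(ligand_type, el_l)]]
  rj <- params$radii[[radius_class(receptor_type, el_r)]]
  shell <- ri + rj + d_offset
  if (shell <= 0) stop("infeasible pocket geometry: shell radius <= 0",
                       call. = FALSE)
  dirs <- shell_directions(n_receptor) * shell
  rec_text <- vapply(seq_len(n_receptor), function(i) {
    fixture_atom_line(i, paste0(el_r, i), dirs[i, ], 0, receptor_type)
  }, "")
  lig_text <- c("ROOT",
                fixture_atom_line(1L, paste0(el_l, 1), c(0, 0, 0), 0,
                                  ligand_type),
                "ENDROOT", "TORSDOF 0")
  list(receptor = parse_pdbqt(rec_text, role = "receptor"),
       ligand = parse_pdbqt(lig_text, role = "ligand"),
       optimum = c(0, 0, 0), shell_radius = shell,
       receptor_text = rec_text, ligand_text = lig_text)
}

#' Idealized flexible chain ligand
#'
#' A zig-zag chain of `n_torsions + 3` identically typed atoms with 1.5 A
#' bonds and tetrahedral angles, wrapped in a nested BRANCH tree so that
#' every non-terminal bond is rotatable and every torsion moves at least
#' one off-axis atom. Useful wherever a multi-fragment `ligand_model` with
#' a working torsion tree is needed.
#'
#' @param n_torsions number of rotatable bonds (>= 0).
#' @param atom_type AutoDock type of every atom.
#' @return a `ligand_model` (its `pdbqt_text` attribute holds the source).
#' @export
make_toy_ligand <- function(n_torsions = 2, atom_type = "C") {
  m <- n_torsions + 3L
  step_x <- 1.5 * cos(35.264 * pi / 180)
  step_y <- 1.5 * sin(35.264 * pi / 180)
  xyz <- cbind((seq_len(m) - 1) * step_x,
               rep(c(0, step_y), length.out = m), 0)
  lines <- c("ROOT",
             fixture_atom_line(1L, "C1", xyz[1, ], 0, atom_type),
             fixture_atom_line(2L, "C2", xyz[2, ], 0, atom_type),
             "ENDROOT")
  if (n_torsions > 0) {
    for (k in seq_len(n_torsions)) {
      a <- k + 1L
      lines <- c(lines, sprintf("BRANCH %d %d", a, a + 1L),
                 fixture_atom_line(a + 1L, paste0("C", a + 1L),
                                   xyz[a + 1L, ], 0, atom_type))
      if (k == n_torsions) {
        lines <- c(lines, fixture_atom_line(a + 2L, paste0("C", a + 2L),
                                            xyz[a + 2L, ], 0, atom_type))
      }
    }
    for (k in rev(seq_len(n_torsions))) {
      lines <- c(lines, sprintf("ENDBRANCH %d %d", k + 1L, k + 2L))
    }
  } else {
    lines <- append(lines, fixture_atom_line(3L, "C3", xyz[3, ], 0,
                                             atom_type),
                    after = 3L)
  }
  lines <- c(lines, sprintf("TORSDOF %d", n_torsions))
  model <- parse_pdbqt(lines, role = "ligand")
  attr(model, "pdbqt_text") <- lines
  model
}

#' Decoy pose set with exact RMSD annotations
#'
#' Generates `n` perturbed poses of a ligand by seeded rigid translation,
#' rotation and torsion jitter, steering each pose into one of the
#' requested RMSD bins (cycled in order). Annotated RMSDs are computed with
#' [hungarian_rmsd()] against the input pose, so annotations and the
#' structure-comparison module agree by construction. A bin starting at 0
#' receives the unperturbed pose first.
#'
#' @param model a `ligand_model` (the crystal pose).
#' @param n number of poses.
#' @param rmsd_bins list of `c(lo, hi)` intervals, Angstrom.
#' @param seed integer seed.
#' @param max_tries attempts per pose before declaring a bin unreachable.
#' @return list with `poses` (coordinate matrices), `rmsd` (annotations),
#'   `bin` (bin index per pose), and `model`.
#' @export
make_pose_decoys <- function(model, n,
                             rmsd_bins = list(c(0, 0.5), c(0.5, 1),
                                              c(1, 2), c(2, 4)),
                             seed = 1, max_tries = 400) {
  stopifnot(inherits(model, "ligand_model"), n >= 1)
  set.seed(seed)
  poses <- vector("list", n)
  rmsd <- numeric(n)
  bin <- rep(seq_along(rmsd_bins), length.out = n)
  zero_bin_used <- logical(length(rmsd_bins))
  for (k in seq_len(n)) {
    b <- rmsd_bins[[bin[k]]]
    if (b[1] == 0 && !zero_bin_used[bin[k]]) {
      zero_bin_used[bin[k]] <- TRUE
      poses[[k]] <- model$xyz
      rmsd[k] <- 0
      next
    }
    scale <- max(mean(b), 0.05)
    done <- FALSE
    for (try in seq_len(max_tries)) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      rot <- quat_from_rotvec(stats::rnorm(3) * 0.1 * scale)
      tors <- if (model$n_rot) stats::rnorm(model$n_rot) * 0.1 * scale else
        numeric(0)
      dof <- pose_dof(translation = dir * scale * stats::runif(1, 0.7, 1.1),
                      orientation = rot, torsions = tors)
      xyz <- apply_dof(model, dof)
      rr <- hungarian_rmsd(model, model, probe_xyz = xyz)$rmsd
      if (rr >= b[1] && rr < b[2]) {
        poses[[k]] <- xyz
        rmsd[k] <- rr
        done <- TRUE
        break
      }
      scale <- scale * if (rr < b[1]) 1.25 else 0.8
      scale <- min(max(scale, 1e-3), 100)
    }
    if (!done) {
      stop("could not reach RMSD bin [", b[1], ", ", b[2], ") within ",
           max_tries, " attempts for this ligand", call. = FALSE)
    }
  }
  list(poses = poses, rmsd = rmsd, bin = bin, model = model)
}

#' Labeled screening table
#'
#' Draws predicted energies for `n_active` actives from
#' Normal(-separation, 1) and for `n_decoy` decoys from Normal(0, 1) (lower
#' = better), the standard two-population model of a virtual screen. With
#' `separation = 0` scores are independent of the labels, giving the
#' random-selection null used to calibrate AUC and BEDROC; as the
#' separation grows, AUC approaches 1.
#'
#' @param n_active,n_decoy counts (>= 1).
#' @param separation mean score gap between actives and decoys.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a score table data frame (`complex_id`, `protein_id`,
#'   `predicted`, `label`).
#' @export
make_screening_table <- function(n_active, n_decoy, separation = 2,
                                 seed = NULL) {
  stopifnot(n_active >= 1, n_decoy >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    complex_id = c(sprintf("act%04d", seq_len(n_active)),
                   sprintf("dec%04d", seq_len(n_decoy))),
    protein_id = "P1",
    predicted = c(stats::rnorm(n_active, -separation, 1),
                  stats::rnorm(n_decoy, 0, 1)),
    label = rep(c("active", "decoy"), c(n_active, n_decoy)),
    stringsAsFactors = FALSE
  )
}
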