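# The pair potential. Every heavy-atom pair interacts through a steric
# part: weighted Gaussian attraction(s) on the surface distance
# d = r - Ri - Rj plus a quadratic overlap repulsion for d < 0. Pairs of
# hydrophobic atoms add a piecewise-linear hydrophobic bonus; donor-acceptor
# pairs add a piecewise-linear non-directional H-bond bonus. Both piecewise
# terms are normalized linear ramps (1 at the onset, 0 at the offset) so the
# potential is continuous everywhere.

TERM_NAMES <- c("gauss1", "gauss2", "repulsion", "hydrophobic", "hbond", "lj")

#' Pairwise interaction terms
#'
#' The elementary distance-dependent terms of the scoring function, each a
#' dimensionless shape evaluated on the surface distance `d` (Angstrom) and
#' later multiplied by its weight:
#' * `surface_distance(r, ri, rj)`: `r - ri - rj`, negative when the van der
#'   Waals shells overlap.
#' * `gauss_term(d, o, s)`: `exp(-((d - o) / s)^2)`, peak 1 at `d = o`.
#' * `repulsion_term(d)`: `d^2` for `d <= 0`, else 0.
#' * `hydrophobic_term(d, p1, p2)`: 1 up to `p1`, linear ramp down to 0 at
#'   `p2` (applied only when both atoms are hydrophobic).
#' * `hbond_term(d, h1)`: 1 up to `h1 < 0`, linear ramp `d / h1` down to 0
#'   at contact (applied only to donor-acceptor pairs; metals count as
#'   donors).
#' * `lj_mn_term(r, m, n, well_depth, r_min)`: generic m-n Lennard-Jones
#'   potential on the interatomic distance with minimum `-well_depth` at
#'   `r_min`; available to user-defined parameter sets (e.g. a soft 4-8
#'   steric term).
#'
#' All are vectorized over `d` (or `r`).
#'
#' @param r interatomic distance(s), Angstrom.
#' @param ri,rj atomic radii, Angstrom.
#' @name pair-terms
NULL

#' @rdname pair-terms
#' @export
surface_distance <- function(r, ri, rj) {
  stopifnot(all(r >= 0))
  r - ri - rj
}

#' @rdname pair-terms
#' @param d surface distance(s), Angstrom.
#' @param o,s Gaussian offset and width, Angstrom (`s > 0`).
#' @export
gauss_term <- function(d, o, s) {
  stopifnot(s > 0)
  exp(-((d - o) / s)^2)
}

#' @rdname pair-terms
#' @export
repulsion_term <- function(d) {
  pmin(d, 0)^2
}

#' @rdname pair-terms
#' @param p1,p2 hydrophobic onset and offset, Angstrom (`p1 < p2`).
#' @export
hydrophobic_term <- function(d, p1, p2) {
  stopifnot(p1 < p2)
  ifelse(d <= p1, 1, ifelse(d >= p2, 0, (p2 - d) / (p2 - p1)))
}

#' @rdname pair-terms
#' @param h1 H-bond onset, Angstrom (`h1 < 0`).
#' @export
hbond_term <- function(d, h1) {
  stopifnot(h1 < 0)
  ifelse(d <= h1, 1, ifelse(d >= 0, 0, d / h1))
}

#' @rdname pair-terms
#' @param m,n Lennard-Jones exponents, `0 < m < n`.
#' @param well_depth depth of the minimum (positive).
#' @param r_min location of the minimum, Angstrom.
#' @export
lj_mn_term <- function(r, m, n, well_depth, r_min) {
  if (m >= n || m <= 0) stop("Lennard-Jones exponents require 0 < m < n",
                             call. = FALSE)
  q <- r_min / r
  (well_depth / (n - m)) * (m * q^n - n * q^m)
}

is_donor_class <- function(cls) cls %in% c("donor", "donor_acceptor", "metal")
is_acceptor_class <- function(cls) cls %in% c("acceptor", "donor_acceptor")

hbond_pair <- function(cls_a, cls_b) {
  (is_donor_class(cls_a) & is_acceptor_class(cls_b)) |
    (is_donor_class(cls_b) & is_acceptor_class(cls_a))
}

hydrophobic_pair <- function(cls_a, cls_b) {
  cls_a == "hydrophobic" & cls_b == "hydrophobic"
}

all_weights <- function(params) {
  c(params$weights, lj = if (is.null(params$lj)) 0 else params$lj$weight)
}

# raw (unweighted) term values for vectors of pairs; phob/hb are logical
# masks, rsum = ri + rj (needed by the optional LJ term)
raw_term_values <- function(d, r, phob, hb, params, rsum) {
  cbind(
    gauss1 = gauss_term(d, params$gauss1[["o"]], params$gauss1[["s"]]),
    gauss2 = if (params$gauss2_enabled) {
      gauss_term(d, params$gauss2[["o"]], params$gauss2[["s"]])
    } else rep(0, length(d)),
    repulsion = repulsion_term(d),
    hydrophobic = ifelse(phob, hydrophobic_term(d, params$hydrophobic[["p1"]],
                                                params$hydrophobic[["p2"]]), 0),
    hbond = ifelse(hb, hbond_term(d, params$hbond[["h1"]]), 0),
    lj = if (is.null(params$lj)) rep(0, length(d)) else {
      lj_mn_term(r, params$lj$m, params$lj$n, 1, rsum)
    }
  )
}

# d(weighted pair energy)/dr for vectors of pairs (dd/dr = 1)
pair_energy_slope <- function(d, r, phob, hb, params, rsum) {
  w <- params$weights
  g1 <- gauss_term(d, params$gauss1[["o"]], params$gauss1[["s"]])
  sl <- w[["gauss1"]] * g1 * (-2 * (d - params$gauss1[["o"]]) /
                                params$gauss1[["s"]]^2)
  if (params$gauss2_enabled) {
    g2 <- gauss_term(d, params$gauss2[["o"]], params$gauss2[["s"]])
    sl <- sl + w[["gauss2"]] * g2 * (-2 * (d - params$gauss2[["o"]]) /
                                       params$gauss2[["s"]]^2)
  }
  sl <- sl + w[["repulsion"]] * 2 * pmin(d, 0)
  p1 <- params$hydrophobic[["p1"]]; p2 <- params$hydrophobic[["p2"]]
  sl <- sl + w[["hydrophobic"]] *
    ifelse(phob & d > p1 & d < p2, -1 / (p2 - p1), 0)
  h1 <- params$hbond[["h1"]]
  sl <- sl + w[["hbond"]] * ifelse(hb & d > h1 & d < 0, 1 / h1, 0)
  if (!is.null(params$lj)) {
    q <- rsum / r
    sl <- sl + params$lj$weight * (params$lj$m * params$lj$n / (r * (params$lj$n - params$lj$m))) *
      (q^params$lj$m - q^params$lj$n)
  }
  sl
}

new_score_breakdown <- function(raw_sums, params, n_pairs) {
  w <- all_weights(params)
  weighted <- w * raw_sums[names(w)]
  total <- sum(weighted)
  structure(list(
    total = total,
    per_term_raw = raw_sums,
    per_term_weighted = weighted,
    per_term_percent = if (total != 0) 100 * weighted / total else
      weighted * NA_real_,
    n_pairs_evaluated = n_pairs
  ), class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("<score_breakdown> total", sprintf("%.4f", x$total),
      "over", x$n_pairs_evaluated, "pair(s)\n")
  df <- data.frame(raw = x$per_term_raw,
                   weighted = x$per_term_weighted,
                   percent = x$per_term_percent)
  print(round(df, 4))
  invisible(x)
}

#' Weighted energy of one atom pair
#'
#' Evaluates the full weighted pair potential for two typed atoms at
#' interatomic distance `r`: the steric terms always apply, the hydrophobic
#' term only when both atoms are hydrophobic, and the H-bond term only for
#' donor-acceptor pairings (metals count as donors). Radii are resolved
#' through `params`.
#'
#' @param a,b one-row atom records (rows of `model$atoms`).
#' @param r interatomic distance, Angstrom.
#' @param params a `term_param_set`.
#' @param breakdown return a `score_breakdown` instead of the bare energy?
#' @return numeric energy, or a `score_breakdown`.
#' @export
pair_energy <- function(a, b, r, params, breakdown = FALSE) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (!a$is_heavy || !b$is_heavy) {
    stop("pair energies are defined for heavy atoms only", call. = FALSE)
  }
  ri <- unname(params$radii[[a$radius_class]])
  rj <- unname(params$radii[[b$radius_class]])
  d <- surface_distance(r, ri, rj)
  raw <- raw_term_values(d, r, hydrophobic_pair(a$class, b$class),
                         hbond_pair(a$class, b$class), params, ri + rj)
  bd <- new_score_breakdown(colSums(raw), params, 1L)
  if (breakdown) bd else bd$total
}

#' Ligand-receptor interaction energy
#'
#' Sum of the weighted pair potential over every heavy ligand-receptor atom
#' pair whose surface distance is below the cutoff, with a per-term
#' breakdown. With `use_index = TRUE` candidate receptor atoms come from the
#' receptor's uniform-grid spatial index; the result is identical to the
#' brute-force double loop.
#'
#' @param ligand a `ligand_model` (or coordinates override via `coords`).
#' @param receptor a `receptor_model`.
#' @param params a `term_param_set`.
#' @param coords optional n_atoms x 3 matrix of posed ligand coordinates.
#' @param use_index use the receptor spatial index.
#' @return a `score_breakdown`.
#' @export
intermolecular_energy <- function(ligand, receptor, params, coords = NULL,
                                  use_index = TRUE) {
  stopifnot(inherits(ligand, "ligand_model"),
            inherits(receptor, "receptor_model"))
  lxyz <- coords %||% ligand$xyz
  lheavy <- which(ligand$atoms$is_heavy)
  rheavy <- which(receptor$atoms$is_heavy)
  if (!length(lheavy)) stop("ligand has no heavy atoms", call. = FALSE)
  if (!length(rheavy)) stop("receptor has no heavy atoms", call. = FALSE)
  lrad <- atom_radii(ligand$atoms, params)
  rrad <- atom_radii(receptor$atoms, params)
  rmax <- max(rrad[rheavy])
  raw <- stats::setNames(numeric(length(TERM_NAMES)), TERM_NAMES)
  n_pairs <- 0L
  for (i in lheavy) {
    cand <- if (use_index) {
      query_spatial_index(receptor$index, lxyz[i, ],
                          params$cutoff + lrad[i] + rmax)
    } else rheavy
    cand <- cand[receptor$atoms$is_heavy[cand]]
    if (!length(cand)) next
    r <- sqrt(colSums((t(receptor$xyz[cand, , drop = FALSE]) - lxyz[i, ])^2))
    d <- surface_distance(r, lrad[i], rrad[cand])
    keep <- d < params$cutoff
    if (!any(keep)) next
    cand <- cand[keep]; r <- r[keep]; d <- d[keep]
    vals <- raw_term_values(
      d, r,
      hydrophobic_pair(ligand$atoms$class[i], receptor$atoms$class[cand]),
      hbond_pair(ligand$atoms$class[i], receptor$atoms$class[cand]),
      params, lrad[i] + rrad[cand])
    raw <- raw + colSums(vals)
    n_pairs <- n_pairs + length(cand)
  }
  new_score_breakdown(raw, params, n_pairs)
}

# heavy-atom pairs in different rigid fragments separated by >= 4 bonds
# (or disconnected); these are the pairs whose relative geometry the
# torsions can change, so they enter the intramolecular self-energy
eligible_intra_pairs <- function(model) {
  n <- nrow(model$atoms)
  heavy <- which(model$atoms$is_heavy)
  if (length(heavy) < 2L || model$n_rot == 0L) {
    return(matrix(integer(0), ncol = 2))
  }
  adj <- vector("list", n)
  if (nrow(model$bonds)) {
    for (k in seq_len(nrow(model$bonds))) {
      i <- model$bonds[k, 1]; j <- model$bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  bond_dist <- function(src) {
    dist <- rep(NA_integer_, n)
    dist[src] <- 0L
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    dist
  }
  out <- list()
  for (ii in seq_along(heavy)) {
    i <- heavy[ii]
    dist <- bond_dist(i)
    for (j in heavy[-seq_len(ii)]) {
      if (model$fragments[i] != model$fragments[j] &&
          (is.na(dist[j]) || dist[j] >= 4L)) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) matrix(integer(0), ncol = 2) else do.call(rbind, out)
}

#' Ligand self-energy
#'
#' Weighted pair-potential sum over heavy ligand atom pairs that sit in
#' different rigid fragments and are at least 4 bonds apart (pairs whose
#' relative geometry the torsions can change). A rigid ligand has no
#' eligible pairs and self-energy 0. Used to penalize self-clash during
#' minimization; it does not enter the reported affinity.
#'
#' @inheritParams intermolecular_energy
#' @return numeric energy.
#' @export
intramolecular_energy <- function(ligand, params, coords = NULL) {
  stopifnot(inherits(ligand, "ligand_model"))
  pairs <- ligand$intra_pairs
  if (!nrow(pairs)) return(0)
  lxyz <- coords %||% ligand$xyz
  rad <- atom_radii(ligand$atoms, params)
  i <- pairs[, 1]; j <- pairs[, 2]
  r <- sqrt(rowSums((lxyz[i, , drop = FALSE] - lxyz[j, , drop = FALSE])^2))
  d <- surface_distance(r, rad[i], rad[j])
  keep <- d < params$cutoff
  if (!any(keep)) return(0)
  vals <- raw_term_values(
    d[keep], r[keep],
    hydrophobic_pair(ligand$atoms$class[i[keep]], ligand$atoms$class[j[keep]]),
    hbond_pair(ligand$atoms$class[i[keep]], ligand$atoms$class[j[keep]]),
    params, rad[i[keep]] + rad[j[keep]])
  sum(all_weights(params) * colSums(vals))
}

#' Torsion-scaled predicted affinity
#'
#' Divides the intermolecular energy by `1 + torsion_coeff * n_rot` to
#' approximate the conformational entropy cost of the ligand's rotatable
#' bonds. With `torsion_coeff = 0` this is the identity.
#'
#' @param inter intermolecular energy (or a `score_breakdown`).
#' @param n_rot number of rotatable bonds.
#' @param params a `term_param_set`.
#' @return numeric affinity on the same scale as the input energy.
#' @export
predicted_affinity <- function(inter, n_rot, params) {
  if (inherits(inter, "score_breakdown")) inter <- inter$total
  if (length(n_rot) != 1L || is.na(n_rot) || n_rot < 0) {
    stop("n_rot must be a single non-negative number", call. = FALSE)
  }
  inter / (1 + params$torsion_coeff * n_rot)
}

#' Score a ligand pose against a receptor
#'
#' Convenience wrapper: intermolecular breakdown plus the torsion-scaled
#' affinity (using TORSDOF when the ligand file declares it, else the
#' rotatable-bond count).
#'
#' @inheritParams intermolecular_energy
#' @return list with `breakdown`, `affinity`, `intra` (self-energy) and
#'   `n_rot`.
#' @export
score_complex <- function(ligand, receptor, params, coords = NULL) {
  bd <- intermolecular_energy(ligand, receptor, params, coords)
  n_rot <- if (!is.na(ligand$torsdof)) ligand$torsdof else ligand$n_rot
  list(breakdown = bd,
       affinity = predicted_affinity(bd$total, n_rot, params),
       intra = intramolecular_energy(ligand, params, coords),
       n_rot = n_rot)
}

#' Average per-term contribution across complexes
#'
#' For a set of scored complexes, the average weighted sum of each term
#' divided by the average total, as a percentage. Percentages sum to 100.
#'
#' @param breakdowns list of `score_breakdown` objects.
#' @return named numeric vector, percent per term.
#' @export
term_contributions <- function(breakdowns) {
  if (!length(breakdowns)) stop("empty breakdown list", call. = FALSE)
  stopifnot(all(vapply(breakdowns, inherits, TRUE, "score_breakdown")))
  weighted <- rowMeans(vapply(breakdowns, function(b) b$per_term_weighted,
                              numeric(length(TERM_NAMES))))
  mean_total <- mean(vapply(breakdowns, function(b) b$total, 0))
  if (mean_total == 0) stop("average total energy is zero", call. = FALSE)
  100 * weighted / mean_total
}

#' Steric pair-potential profile and its minima
#'
#' `steric_potential()` evaluates only the weighted steric part of the pair
#' potential (Gaussian attraction(s) plus quadratic repulsion) for two
#' radius classes over interatomic distances `r`. `find_steric_minima()`
#' locates all interior local minima of that profile by a dense grid scan
#' followed by golden-section refinement of each bracket. The Vinardo-style
#' single-Gaussian form has one minimum at contact (`r = ri + rj`); the
#' two-Gaussian Vina form adds an outer long-range minimum.
#'
#' @param r interatomic distances, Angstrom.
#' @param params a `term_param_set`.
#' @param class1,class2 radius classes (e.g. `"CA"` for aromatic carbon).
#' @return `steric_potential()`: energies; `find_steric_minima()`: sorted
#'   vector of minima locations in `r`.
#' @export
steric_potential <- function(r, params, class1 = "CA", class2 = "CA") {
  ri <- unname(params$radii[[class1]])
  rj <- unname(params$radii[[class2]])
  d <- surface_distance(r, ri, rj)
  w <- params$weights
  e <- w[["gauss1"]] * gauss_term(d, params$gauss1[["o"]], params$gauss1[["s"]]) +
    w[["repulsion"]] * repulsion_term(d)
  if (params$gauss2_enabled) {
    e <- e + w[["gauss2"]] * gauss_term(d, params$gauss2[["o"]],
                                        params$gauss2[["s"]])
  }
  e
}

#' @rdname steric_potential
#' @param r_range interval of interatomic distances to scan, Angstrom.
#' @param step grid resolution, Angstrom.
#' @export
find_steric_minima <- function(params, class1 = "CA", class2 = "CA",
                               r_range = c(0.5, 12), step = 0.001) {
  r <- seq(r_range[1], r_range[2], by = step)
  v <- steric_potential(r, params, class1, class2)
  i <- which(diff(sign(diff(v))) > 0) + 1L
  vapply(i, function(k) {
    stats::optimize(steric_potential, lower = r[k - 1L], upper = r[k + 1L],
                    params = params, class1 = class1, class2 = class2,
                    tol = 1e-9)$minimum
  }, 0)
}
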