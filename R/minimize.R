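# Local pose minimization: BFGS over (translation, orientation tangent,
# torsions) with a backtracking Armijo line search. The objective
# (intermolecular + intramolecular energy) is only piecewise-smooth -- the
# repulsion, hydrophobic and H-bond terms have kinks -- so the line search
# is pure backtracking with no curvature interpolation across a joint.

# cartesian energy gradient: dE/dx_i for every ligand atom at the posed
# coordinates (intermolecular + intramolecular contributions)
cartesian_energy_gradient <- function(ligand, receptor, coords, params) {
  n <- nrow(coords)
  grad <- matrix(0, n, 3)
  energy_inter <- 0
  energy_intra <- 0
  lrad <- atom_radii(ligand$atoms, params)
  lheavy <- which(ligand$atoms$is_heavy)
  rheavy <- which(receptor$atoms$is_heavy)
  rrad <- atom_radii(receptor$atoms, params)
  rmax <- if (length(rheavy)) max(rrad[rheavy]) else 0
  w <- all_weights(params)
  small_receptor <- nrow(receptor$xyz) <= 32L  # index gains nothing there
  for (i in lheavy) {
    cand <- if (small_receptor) rheavy else {
      query_spatial_index(receptor$index, coords[i, ],
                          params$cutoff + lrad[i] + rmax)
    }
    cand <- cand[receptor$atoms$is_heavy[cand]]
    if (!length(cand)) next
    diff <- t(t(receptor$xyz[cand, , drop = FALSE]) - coords[i, ]) # rec - lig
    r <- sqrt(rowSums(diff^2))
    d <- surface_distance(r, lrad[i], rrad[cand])
    keep <- d < params$cutoff
    if (!any(keep)) next
    cand <- cand[keep]; r <- r[keep]; d <- d[keep]
    diff <- diff[keep, , drop = FALSE]
    phob <- hydrophobic_pair(ligand$atoms$class[i],
                             receptor$atoms$class[cand])
    hb <- hbond_pair(ligand$atoms$class[i], receptor$atoms$class[cand])
    rsum <- lrad[i] + rrad[cand]
    vals <- raw_term_values(d, r, phob, hb, params, rsum)
    energy_inter <- energy_inter + sum(w * colSums(vals))
    slope <- pair_energy_slope(d, r, phob, hb, params, rsum)
    # dr/dx_i = (x_i - x_j)/r = -diff/r
    grad[i, ] <- grad[i, ] - colSums(diff * (slope / r))
  }
  pairs <- ligand$intra_pairs
  if (nrow(pairs)) {
    i <- pairs[, 1]; j <- pairs[, 2]
    diff <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    r <- sqrt(rowSums(diff^2))
    d <- surface_distance(r, lrad[i], lrad[j])
    keep <- d < params$cutoff
    if (any(keep)) {
      i <- i[keep]; j <- j[keep]; r <- r[keep]; d <- d[keep]
      diff <- diff[keep, , drop = FALSE]
      phob <- hydrophobic_pair(ligand$atoms$class[i], ligand$atoms$class[j])
      hb <- hbond_pair(ligand$atoms$class[i], ligand$atoms$class[j])
      rsum <- lrad[i] + lrad[j]
      vals <- raw_term_values(d, r, phob, hb, params, rsum)
      energy_intra <- energy_intra + sum(w * colSums(vals))
      slope <- pair_energy_slope(d, r, phob, hb, params, rsum)
      gij <- diff * (slope / r)
      for (k in seq_along(i)) {
        grad[i[k], ] <- grad[i[k], ] + gij[k, ]
        grad[j[k], ] <- grad[j[k], ] - gij[k, ]
      }
    }
  }
  list(energy = energy_inter + energy_intra, inter = energy_inter,
       intra = energy_intra, grad = grad)
}

pose_energy <- function(model, receptor, dof, params) {
  coords <- apply_dof(model, dof)
  intermolecular_energy(model, receptor, params, coords,
                        use_index = nrow(receptor$xyz) > 32L)$total +
    intramolecular_energy(model, params, coords)
}

#' Energy and gradient of a posed ligand
#'
#' Total energy (intermolecular plus intramolecular) at the coordinates
#' produced by `dof`, together with its gradient over the pose degrees of
#' freedom: translation (3), orientation in the quaternion's 3-D tangent
#' space (the torque about the rotation center), and one component per
#' torsion (the torque about the rotated bond axis). Matches central finite
#' differences away from the piecewise joints of the potential.
#'
#' @param model a `ligand_model`.
#' @param receptor a `receptor_model`.
#' @param dof a `pose_dof`.
#' @param params a `term_param_set`.
#' @return list with `energy`, `inter`, `intra`, `gradient`
#'   (length `6 + n_rot`), and the posed `coords`.
#' @export
energy_and_gradient <- function(model, receptor, dof, params) {
  coords <- apply_dof(model, dof)
  ce <- cartesian_energy_gradient(model, receptor, coords, params)
  g <- ce$grad
  center <- ligand_centroid(model) + dof$translation
  rel <- sweep(coords, 2, center)
  torque <- c(sum(rel[, 2] * g[, 3] - rel[, 3] * g[, 2]),
              sum(rel[, 3] * g[, 1] - rel[, 1] * g[, 3]),
              sum(rel[, 1] * g[, 2] - rel[, 2] * g[, 1]))
  tor_grad <- vapply(model$torsions, function(tr) {
    a <- coords[tr$axis[1], ]
    u <- coords[tr$axis[2], ] - a
    u <- u / sqrt(sum(u^2))
    idx <- tr$moved
    relA <- t(t(coords[idx, , drop = FALSE]) - a)
    gi <- g[idx, , drop = FALSE]
    cr <- cbind(relA[, 2] * gi[, 3] - relA[, 3] * gi[, 2],
                relA[, 3] * gi[, 1] - relA[, 1] * gi[, 3],
                relA[, 1] * gi[, 2] - relA[, 2] * gi[, 1])
    sum(colSums(cr) * u)
  }, 0)
  list(energy = ce$energy, inter = ce$inter, intra = ce$intra,
       gradient = c(colSums(g), torque, tor_grad), coords = coords)
}

#' Local minimization of a ligand pose
#'
#' Quasi-Newton (BFGS) descent over the pose degrees of freedom with a
#' backtracking line search enforcing sufficient decrease, starting from
#' `start`. The orientation is updated by composing a tangent-space rotation
#' onto the quaternion and renormalizing. Terminates when the gradient norm
#' falls below `tol`, when no decreasing step can be found, or at
#' `max_iter`. Deterministic given identical inputs; the final energy never
#' exceeds the starting energy.
#'
#' @inheritParams energy_and_gradient
#' @param start starting `pose_dof` (default: the input conformation).
#' @param tol gradient-norm tolerance.
#' @param max_iter iteration cap.
#' @return list with `dof`, `coords`, `energy` (inter + intra), `breakdown`
#'   (intermolecular `score_breakdown` at the final pose), `affinity`
#'   (torsion-scaled), `trajectory` (energy per accepted step, starting
#'   value included), `converged`, `iterations`.
#' @export
local_minimize <- function(model, receptor, start = NULL, params,
                           tol = 1e-6, max_iter = 10000) {
  dof <- start %||% pose_dof(torsions = rep(0, model$n_rot))
  eg <- energy_and_gradient(model, receptor, dof, params)
  if (!is.finite(eg$energy)) {
    stop("non-finite energy at starting pose", call. = FALSE)
  }
  n <- n_dof(dof)
  H <- diag(n)
  h_scaled <- FALSE
  traj <- eg$energy
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- eg$gradient
    if (sqrt(sum(g^2)) < tol) {
      converged <- TRUE
      break
    }
    p <- as.numeric(-H %*% g)
    m <- sum(p * g)
    if (!is.finite(m) || m >= 0) {
      H <- diag(n)
      p <- -g
      m <- -sum(g^2)
    }
    # cap the trial step: steep repulsive walls otherwise propose
    # teleport-sized steps that jump out of the basin entirely
    pn <- sqrt(sum(p^2))
    if (pn > 10) {
      p <- p * (10 / pn)
      m <- m * (10 / pn)
    }
    alpha <- 1
    cand <- NULL
    fc <- Inf
    found <- FALSE
    for (ls in 1:60) {
      cand <- compose_dof_step(dof, alpha * p)
      fc <- pose_energy(model, receptor, cand, params)
      if (is.finite(fc) && fc <= eg$energy + 1e-4 * alpha * m) {
        found <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!found) break
    s <- alpha * p
    eg_new <- energy_and_gradient(model, receptor, cand, params)
    y <- eg_new$gradient - g
    sy <- sum(s * y)
    # relative curvature test: a tiny s.y (near-linear stretch or a
    # piecewise joint) would make 1/s.y explode and stall the line search
    if (is.finite(sy) && sy > 1e-8 * sqrt(sum(s^2) * sum(y^2))) {
      if (!h_scaled) {
        H <- diag(n) * (sy / sum(y^2))
        h_scaled <- TRUE
      }
      rho <- 1 / sy
      Hy <- H %*% y
      H <- H - rho * (s %*% t(Hy)) - rho * (Hy %*% t(s)) +
        (rho^2 * sum(y * Hy) + rho) * (s %*% t(s))
    }
    dof <- cand
    eg <- eg_new
    traj <- c(traj, eg$energy)
  }
  bd <- intermolecular_energy(model, receptor, params, eg$coords)
  n_rot <- if (!is.na(model$torsdof)) model$torsdof else model$n_rot
  list(dof = dof, coords = eg$coords, energy = eg$energy, breakdown = bd,
       affinity = predicted_affinity(bd$total, n_rot, params),
       trajectory = traj, converged = converged, iterations = iter)
}

default_search_box <- function(receptor, pad = 4) {
  heavy <- receptor$xyz[receptor$atoms$is_heavy, , drop = FALSE]
  lo <- apply(heavy, 2, min) - pad
  hi <- apply(heavy, 2, max) + pad
  list(center = (lo + hi) / 2, size = hi - lo)
}

#' Random-restart local search
#'
#' A desk-scale stand-in for a full docking search: `n_starts` local
#' minimizations from pose DOFs sampled uniformly at random -- translation
#' uniform in the search box, orientation uniform on the rotation group,
#' torsions uniform in (-pi, pi] -- ranked by torsion-scaled predicted
#' affinity (ties keep sampling order). Reproducible for a fixed seed.
#'
#' @inheritParams local_minimize
#' @param n_starts number of restarts (>= 1).
#' @param seed integer RNG seed.
#' @param box `list(center =, size =)` in Angstrom; derived from the
#'   receptor extent (4 A padding) when `NULL`.
#' @return list with `poses` (minimization results sorted by affinity,
#'   each carrying its sampled `start`) and `summary` (data frame of start
#'   index, energy, affinity, in ranked order).
#' @export
random_restart_search <- function(model, receptor, n_starts, seed, params,
                                  box = NULL, tol = 1e-6, max_iter = 10000) {
  stopifnot(n_starts >= 1)
  box <- box %||% default_search_box(receptor)
  if (any(box$size <= 0)) stop("empty search box", call. = FALSE)
  set.seed(seed)
  c0 <- ligand_centroid(model)
  results <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    target <- box$center + (stats::runif(3) - 0.5) * box$size
    start <- pose_dof(
      translation = target - c0,
      orientation = random_unit_quaternion(),
      torsions = if (model$n_rot) stats::runif(model$n_rot, -pi, pi) else
        numeric(0))
    res <- local_minimize(model, receptor, start, params,
                          tol = tol, max_iter = max_iter)
    res$start <- start
    results[[k]] <- res
  }
  aff <- vapply(results, `[[`, 0, "affinity")
  ord <- order(aff)
  list(poses = results[ord],
       summary = data.frame(start = ord,
                            energy = vapply(results, `[[`, 0, "energy")[ord],
                            affinity = aff[ord]))
}
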