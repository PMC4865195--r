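# Scoring-function development screen: enumerate a constrained parameter
# grid, rank candidates by average post-minimization RMSD (cheap, and a
# good predictor of docking ability), re-dock a short-list, and quantify
# how well scoring correlation vs average RMSD predict docking success.

#' Parameter-grid specification
#'
#' Axes are named by the parameter-file vocabulary understood by
#' [set_param()] (`"weight_gauss1"`, `"radius_N"`, `"gauss1_width"`, ...),
#' each a `c(start, stop, step)` triple. Radii axes are subject to the
#' built-in physical constraints `C >= C_A`, `N > O` and `N - O <= 0.10` A
#' (evaluated against the base parameter set for radii not on the grid).
#'
#' @param axes named list of `c(start, stop, step)` triples.
#' @param radii_constraints apply the radii constraints?
#' @return a `grid_spec`.
#' @export
grid_spec <- function(axes, radii_constraints = TRUE) {
  stopifnot(is.list(axes), length(axes) > 0, !is.null(names(axes)))
  for (nm in names(axes)) {
    a <- axes[[nm]]
    if (length(a) != 3 || a[3] <= 0 || a[1] > a[2]) {
      stop("axis ", nm, " must be c(start, stop, step) with step > 0 and ",
           "start <= stop", call. = FALSE)
    }
  }
  structure(list(axes = axes, radii_constraints = radii_constraints),
            class = "grid_spec")
}

radii_constraints_ok <- function(values) {
  # values: named vector with radius_C, radius_CA, radius_N, radius_O
  values[["radius_C"]] >= values[["radius_CA"]] &
    values[["radius_N"]] > values[["radius_O"]] &
    values[["radius_N"]] - values[["radius_O"]] <= 0.10 + 1e-12
}

#' Enumerate a constrained parameter grid
#'
#' Yields every combination of the axis values exactly once, as parameter
#' sets derived from `base`, dropping combinations that violate the radii
#' constraints. An infeasible specification returns an empty list with a
#' warning.
#'
#' @param spec a `grid_spec`.
#' @param base the parameter set the candidates are perturbations of.
#' @return named list of `term_param_set`s (`cand_0001`, ...), with
#'   attributes `n_total` (full Cartesian count) and `n_kept`.
#' @export
generate_grid <- function(spec, base = scoring_params("vinardo")) {
  stopifnot(inherits(spec, "grid_spec"))
  seqs <- lapply(spec$axes, function(a) seq(a[1], a[2], by = a[3]))
  grid <- expand.grid(seqs, KEEP.OUT.ATTRS = FALSE)
  n_total <- nrow(grid)
  if (spec$radii_constraints) {
    rk <- c("radius_C", "radius_CA", "radius_N", "radius_O")
    keep <- vapply(seq_len(nrow(grid)), function(i) {
      vals <- stats::setNames(
        vapply(rk, function(key) {
          if (key %in% names(grid)) grid[i, key] else
            base$radii[[sub("^radius_", "", key)]]
        }, 0), rk)
      radii_constraints_ok(vals)
    }, TRUE)
    grid <- grid[keep, , drop = FALSE]
  }
  if (nrow(grid) == 0L) {
    warning("constraint set is infeasible: the grid is empty",
            call. = FALSE)
    return(structure(list(), n_total = n_total, n_kept = 0L))
  }
  out <- lapply(seq_len(nrow(grid)), function(i) {
    ps <- base
    for (key in names(grid)) ps <- set_param(ps, key, grid[i, key])
    ps$name <- sprintf("cand_%04d", i)
    validate_param_set(ps)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  structure(out, n_total = n_total, n_kept = length(out))
}

dataset_complex <- function(cx, what) {
  if (is.null(cx[[what]])) stop("dataset complex lacks '", what, "'",
                                call. = FALSE)
  cx[[what]]
}

#' Minimization screen over candidate scoring functions
#'
#' For every candidate parameter set, minimizes each crystal ligand pose in
#' its receptor and averages the symmetry-corrected RMSD between minimized
#' and crystal pose over the dataset; a low average indicates the function
#' keeps a local minimum near the experimental geometry, a prerequisite of
#' docking ability. When the dataset provides experimental affinities, the
#' Pearson scoring correlation of the minimized-pose affinities is reported
#' too. Candidates are ranked by ascending average RMSD; per-complex
#' minimization failures are recorded, never silently dropped.
#'
#' @param candidates list of `term_param_set`s (see [generate_grid()]).
#' @param dataset list of complexes, each `list(receptor =, ligand =,
#'   affinity = )` (`affinity` optional, higher = stronger).
#' @param top_k how many leading candidates to short-list (the screen
#'   convention: 20 after minimization, 5 after re-docking).
#' @param tol,max_iter minimizer settings.
#' @return a `screen_report`: list with `report` (data frame: candidate,
#'   avg_rmsd, scoring_r, sorted ascending by avg_rmsd), `top` (the
#'   short-listed candidates), `per_complex` (RMSD matrix), `errors`.
#' @export
minimization_screen <- function(candidates, dataset, top_k = 20,
                                tol = 1e-6, max_iter = 2000) {
  stopifnot(length(candidates) > 0, length(dataset) > 0)
  ids <- names(candidates) %||% sprintf("cand_%04d", seq_along(candidates))
  rmsd_mat <- matrix(NA_real_, length(candidates), length(dataset),
                     dimnames = list(ids, NULL))
  aff_mat <- rmsd_mat
  errors <- list()
  for (ci in seq_along(candidates)) {
    ps <- candidates[[ci]]
    for (di in seq_along(dataset)) {
      cx <- dataset[[di]]
      res <- tryCatch({
        fit <- local_minimize(dataset_complex(cx, "ligand"),
                              dataset_complex(cx, "receptor"),
                              params = ps, tol = tol, max_iter = max_iter)
        list(rmsd = hungarian_rmsd(cx$ligand, cx$ligand,
                                   probe_xyz = fit$coords)$rmsd,
             # scoring ability is judged on the crystal pose, as in
             # regression-style training
             affinity = score_complex(cx$ligand, cx$receptor, ps)$affinity)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- list(candidate = ids[ci],
                                              complex = di,
                                              message = conditionMessage(res))
      } else {
        rmsd_mat[ci, di] <- res$rmsd
        aff_mat[ci, di] <- res$affinity
      }
    }
  }
  exp_aff <- vapply(dataset, function(cx) cx$affinity %||% NA_real_, 0)
  scoring_r <- vapply(seq_along(candidates), function(ci) {
    ok <- is.finite(aff_mat[ci, ]) & is.finite(exp_aff)
    if (sum(ok) >= 3 && stats::sd(aff_mat[ci, ok]) > 0 &&
        stats::sd(exp_aff[ok]) > 0) {
      stats::cor(-aff_mat[ci, ok], exp_aff[ok])
    } else NA_real_
  }, 0)
  report <- data.frame(candidate = ids,
                       avg_rmsd = rowMeans(rmsd_mat, na.rm = TRUE),
                       scoring_r = scoring_r,
                       stringsAsFactors = FALSE)
  report <- report[order(report$avg_rmsd), ]
  rownames(report) <- NULL
  keep <- report$candidate[seq_len(min(top_k, nrow(report)))]
  structure(list(report = report, top = candidates[keep],
                 per_complex = rmsd_mat, errors = errors),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>", nrow(x$report), "candidate(s),",
      ncol(x$per_complex), "complex(es),", length(x$errors),
      "failure(s)\n")
  print(utils::head(x$report, 10))
  invisible(x)
}

#' Re-docking screen over candidate scoring functions
#'
#' Runs the random-restart search for every candidate on every complex and
#' scores a complex as successfully docked when the best-ranked pose lies
#' within 2 A (symmetry-corrected) of the crystal pose. Deterministic for a
#' fixed seed: every (candidate, complex) search gets a seed derived from
#' `seed` and its indices.
#'
#' @inheritParams minimization_screen
#' @param n_starts restarts per complex.
#' @param seed integer base seed.
#' @param box optional search box passed to [random_restart_search()].
#' @return data frame: candidate, docking_pct (plus an `errors` attribute).
#' @export
docking_screen <- function(candidates, dataset, n_starts = 8, seed = 1,
                           box = NULL, tol = 1e-6, max_iter = 2000) {
  stopifnot(length(candidates) > 0, length(dataset) > 0)
  ids <- names(candidates) %||% sprintf("cand_%04d", seq_along(candidates))
  success <- matrix(NA, length(candidates), length(dataset))
  errors <- list()
  for (ci in seq_along(candidates)) {
    for (di in seq_along(dataset)) {
      cx <- dataset[[di]]
      res <- tryCatch({
        srch <- random_restart_search(
          dataset_complex(cx, "ligand"), dataset_complex(cx, "receptor"),
          n_starts = n_starts, seed = seed + 7919L * ci + di,
          params = candidates[[ci]], box = box, tol = tol,
          max_iter = max_iter)
        best <- srch$poses[[1]]
        docking_success(hungarian_rmsd(cx$ligand, cx$ligand,
                                       probe_xyz = best$coords)$rmsd)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- list(candidate = ids[ci],
                                              complex = di,
                                              message = conditionMessage(res))
      } else {
        success[ci, di] <- res
      }
    }
  }
  out <- data.frame(candidate = ids,
                    docking_pct = 100 * rowMeans(success, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  attr(out, "errors") <- errors
  out
}

#' Does scoring ability or minimization RMSD predict docking ability?
#'
#' Given a per-candidate table holding docking success, scoring
#' correlation and average post-minimization RMSD, computes the Pearson
#' correlation of docking success against each predictor together with the
#' fitted linear trends. On realistic candidate families the average RMSD
#' is the far better predictor.
#'
#' @param report data frame with columns `docking_pct`, `scoring_r`,
#'   `avg_rmsd` (e.g. a merge of [minimization_screen()] and
#'   [docking_screen()] output).
#' @return list with `r_scoring`, `r_rmsd`, and linear fits `fit_scoring`,
#'   `fit_rmsd`.
#' @export
predictor_diagnostics <- function(report) {
  need <- c("docking_pct", "scoring_r", "avg_rmsd")
  if (!all(need %in% names(report))) {
    stop("report must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ok <- stats::complete.cases(report[, need])
  if (sum(ok) < 3) stop("need at least 3 complete candidates",
                        call. = FALSE)
  rep <- report[ok, ]
  list(r_scoring = stats::cor(rep$docking_pct, rep$scoring_r),
       r_rmsd = stats::cor(rep$docking_pct, rep$avg_rmsd),
       fit_scoring = stats::lm(docking_pct ~ scoring_r, data = rep),
       fit_rmsd = stats::lm(docking_pct ~ avg_rmsd, data = rep))
}
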