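# Scoring-function evaluation statistics over score tables. Sign
# convention, declared once and used throughout: lower (more negative)
# predicted energy = better rank; experimental affinities are on a
# higher-is-stronger scale (e.g. pKd). Ties in any ranking are broken
# deterministically by input order.

#' Score tables
#'
#' The evaluation functions consume plain data frames with (a subset of)
#' the columns `complex_id`, `protein_id`, `predicted` (energy, lower =
#' stronger), `experimental` (affinity, higher = stronger), `label`
#' (`"active"`/`"decoy"`/`"unknown"`) and `pose_rmsd` (Angstrom).
#' `read_score_table()` reads such a table from delimited text (TSV by
#' default), `write_score_table()` writes one.
#'
#' @param path file path.
#' @param sep field separator.
#' @return a data frame.
#' @export
read_score_table <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, quote = "")
}

#' @rdname read_score_table
#' @param records a score table data frame.
#' @export
write_score_table <- function(records, path, sep = "\t") {
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Scoring power: affinity correlation
#'
#' Pearson correlation between predicted and experimental binding
#' affinities. Predicted energies are negated before correlating so that
#' "more negative energy tracks stronger experimental affinity" counts as
#' positive correlation.
#'
#' @param records score table with `predicted` and `experimental`.
#' @return Pearson R.
#' @export
scoring_power <- function(records) {
  ok <- is.finite(records$predicted) & is.finite(records$experimental)
  records <- records[ok, ]
  if (nrow(records) < 3L) stop("need at least 3 records", call. = FALSE)
  if (stats::sd(records$predicted) == 0 ||
      stats::sd(records$experimental) == 0) {
    stop("zero variance in scores or affinities", call. = FALSE)
  }
  stats::cor(-records$predicted, records$experimental)
}

#' Ranking power: within-protein ligand ordering
#'
#' Each protein contributes one group of exactly three ligands with known,
#' distinct experimental affinities. "High" success requires the predicted
#' energies to order all three ligands exactly as the experimental
#' affinities do; "low" success only requires the strongest experimental
#' binder to get the best (lowest) predicted energy.
#'
#' @param records score table with `protein_id`, `predicted`,
#'   `experimental`.
#' @return list with `high` and `low` success percentages and `n_groups`.
#' @export
ranking_power <- function(records) {
  groups <- split(records, records$protein_id)
  bad <- vapply(groups, nrow, 0L) != 3L
  if (any(bad)) {
    stop("every protein group must have exactly 3 ligands; offending: ",
         paste(names(groups)[bad], collapse = ", "), call. = FALSE)
  }
  high <- vapply(groups, function(g) {
    identical(order(g$predicted), order(-g$experimental))
  }, TRUE)
  low <- vapply(groups, function(g) {
    which.min(g$predicted) == which.max(g$experimental)
  }, TRUE)
  list(high = 100 * mean(high), low = 100 * mean(low),
       n_groups = length(groups))
}

#' Docking power: best-pose identification among decoy poses
#'
#' For each complex, poses are ranked by predicted energy (ties keep input
#' order). Success at top-N means a pose within `threshold` of the
#' reference (by annotated RMSD) appears among the N best-scored poses.
#'
#' @param records score table with `complex_id`, `predicted`, `pose_rmsd`.
#' @param threshold RMSD success threshold, Angstrom.
#' @return list with `top1`, `top2`, `top3` success percentages and
#'   `n_complexes`.
#' @export
docking_power <- function(records, threshold = 2.0) {
  if (anyNA(records$pose_rmsd)) {
    stop("missing RMSD annotation(s) in pose records", call. = FALSE)
  }
  groups <- split(records, records$complex_id)
  hit_at <- function(g, n) {
    ord <- order(g$predicted)  # stable: ties by input order
    any(docking_success(g$pose_rmsd[ord][seq_len(min(n, nrow(g)))],
                        threshold))
  }
  list(top1 = 100 * mean(vapply(groups, hit_at, TRUE, 1L)),
       top2 = 100 * mean(vapply(groups, hit_at, TRUE, 2L)),
       top3 = 100 * mean(vapply(groups, hit_at, TRUE, 3L)),
       n_complexes = length(groups))
}

#' Screening power: true-binder retrieval from a compound pool
#'
#' For each protein, the full compound pool (best pose per compound) is
#' ranked by predicted energy (ties by input order) and the known true
#' binder's rank is compared against the top 1%, 3% and 5% cut-offs,
#' each computed as `ceiling(level * pool size)` -- so with a 195-compound
#' pool, top 1% means rank <= 2.
#'
#' @param records score table with `protein_id`, `complex_id` (compound
#'   identity) and `predicted`.
#' @param true_binder named character vector: protein_id -> complex_id of
#'   its known best binder.
#' @param levels fractional cut-offs.
#' @return list with `top1`, `top3`, `top5` success percentages (one per
#'   level), `n_proteins`, and the per-protein true-binder `ranks`.
#' @export
screening_power <- function(records, true_binder,
                            levels = c(0.01, 0.03, 0.05)) {
  groups <- split(records, records$protein_id)
  ranks <- vapply(names(groups), function(p) {
    g <- groups[[p]]
    if (!p %in% names(true_binder)) {
      stop("no true binder declared for protein ", p, call. = FALSE)
    }
    hit <- which(g$complex_id == true_binder[[p]])
    if (!length(hit)) {
      stop("true binder ", true_binder[[p]], " absent from pool of protein ",
           p, call. = FALSE)
    }
    rank(g$predicted, ties.method = "first")[hit[1]]
  }, 0)
  pool <- vapply(groups, nrow, 0L)
  succ <- lapply(levels, function(lv) 100 * mean(ranks <= ceiling(lv * pool)))
  out <- stats::setNames(succ, paste0("top", round(100 * levels)))
  c(out, list(n_proteins = length(groups), ranks = ranks))
}

as_active <- function(label) {
  if (is.logical(label)) return(label)
  label == "active"
}

#' ROC AUC: overall enrichment
#'
#' Area under the ROC curve for recovering actives from a ranked list,
#' computed as the Mann-Whitney statistic: the fraction of (active, decoy)
#' pairs in which the active is ranked better (lower predicted energy),
#' ties counting 1/2. 0.5 is the random expectation, 1 a perfect ranking.
#'
#' @param predicted predicted energies (lower = better rank).
#' @param label `"active"`/`"decoy"` labels (or logical actives).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(predicted, label) {
  act <- as_active(label)
  n1 <- sum(act)
  n0 <- sum(!act)
  if (n1 == 0L || n0 == 0L) {
    stop("need at least one active and one decoy", call. = FALSE)
  }
  rk <- rank(-predicted)  # higher rank = better (more negative energy)
  (sum(rk[act]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' BEDROC: early enrichment
#'
#' Boltzmann-enhanced discrimination of the ROC curve with exponential
#' weight `alpha` (Truchon-Bayly formulation), bounded in \[0, 1\] by
#' construction. Large `alpha` concentrates the weight on the top of the
#' ranking; with `alpha = 20` about 80% of the score comes from the top 8%.
#' For a random ranking the expectation is `Ra / (1 - exp(-alpha * Ra))`
#' with active fraction `Ra = n_active / N`, which approaches the nominal
#' `1 / alpha` (0.05 at `alpha = 20`) as the active fraction becomes small.
#' Rank ties are broken by input order.
#'
#' @inheritParams roc_auc
#' @param alpha exponential weighting parameter (> 0).
#' @return BEDROC value in \[0, 1\].
#' @export
bedroc <- function(predicted, label, alpha = 20) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  act <- as_active(label)
  n <- sum(act)
  if (n == 0L) stop("need at least one active", call. = FALSE)
  big_n <- length(predicted)
  ra <- n / big_n
  ranks <- rank(predicted, ties.method = "first")[act]
  rie <- sum(exp(-alpha * ranks / big_n)) /
    ((n / big_n) * (1 - exp(-alpha)) / (exp(alpha / big_n) - 1))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Closed-form random-ranking expectation of BEDROC
#'
#' `Ra / (1 - exp(-alpha * Ra))` for active fraction `Ra`; the null against
#' which observed early enrichment is judged. Tends to `1 / alpha` for
#' small active fractions.
#'
#' @param n_active,n_total counts.
#' @param alpha exponential weighting parameter.
#' @return expected BEDROC of a label-independent ranking.
#' @export
bedroc_random_expectation <- function(n_active, n_total, alpha = 20) {
  ra <- n_active / n_total
  ra * sinh(alpha / 2) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}
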