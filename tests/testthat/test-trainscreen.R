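vinardo <- scoring_params("vinardo")

test_that("grid enumeration honors counts and radii constraints", {
  g1 <- generate_grid(grid_spec(list(weight_gauss1 = c(-0.05, -0.03, 0.01))),
                      base = vinardo)
  expect_length(g1, 3L)
  expect_equal(vapply(g1, function(p) p$weights[["gauss1"]], 0),
               c(cand_0001 = -0.05, cand_0002 = -0.04, cand_0003 = -0.03))

  # two radii axes: count equals an independent brute-force filter
  spec <- grid_spec(list(radius_N = c(1.60, 1.80, 0.10),
                         radius_O = c(1.55, 1.75, 0.10)))
  g2 <- generate_grid(spec, base = vinardo)
  full <- expand.grid(N = seq(1.60, 1.80, 0.10), O = seq(1.55, 1.75, 0.10))
  want <- sum(full$N > full$O & full$N - full$O <= 0.10 + 1e-12)
  expect_length(g2, want)
  expect_equal(attr(g2, "n_total"), nrow(full))
  # every kept candidate satisfies the constraints; no duplicates
  combos <- t(vapply(g2, function(p) p$radii[c("N", "O")], numeric(2)))
  expect_true(all(combos[, 1] > combos[, 2]))
  expect_true(all(combos[, 1] - combos[, 2] <= 0.10 + 1e-12))
  expect_equal(nrow(unique(combos)), length(g2))

  # infeasible constraints: explicit empty result with a diagnostic
  bad <- grid_spec(list(radius_N = c(1.0, 1.2, 0.1),
                        radius_O = c(1.6, 1.7, 0.1)))
  expect_warning(g3 <- generate_grid(bad, base = vinardo), "infeasible")
  expect_length(g3, 0L)
  expect_error(grid_spec(list(radius_N = c(2, 1, 0.1))), "start <= stop")
})

test_that("minimization screen ranks candidates by closeness of minima", {
  # polar contacts (pure steric term, no piecewise ramps): the minimum
  # sits exactly at the contact distance and moves analytically with the
  # radii
  dataset <- lapply(1:3, function(i) contact_complex("N", vinardo))
  base <- vinardo
  displaced <- set_param(vinardo, "radius_N", 1.7 + 0.5)
  # no repulsion, no contact attraction, strong long-range attraction:
  # the only minimum sits 3 A outside the contact shell
  longrange <- set_param(set_param(set_param(vinardo,
                                             "weight_repulsion", 0),
                                   "weight_gauss1", 0),
                         "weight_gauss2", -0.1)
  cands <- list(base = base, displaced = displaced, longrange = longrange)
  rep1 <- minimization_screen(cands, dataset, top_k = 2)
  expect_s3_class(rep1, "screen_report")
  expect_equal(rep1$report$candidate[1], "base")
  expect_lt(rep1$report$avg_rmsd[1], 0.05)
  rmsds <- stats::setNames(rep1$report$avg_rmsd, rep1$report$candidate)
  expect_gt(rmsds[["displaced"]], rmsds[["base"]])
  expect_gt(rmsds[["longrange"]], rmsds[["displaced"]])
  expect_length(rep1$top, 2L)
  expect_length(rep1$errors, 0L)
  # determinism: identical candidates give identical averages
  rep2 <- minimization_screen(cands, dataset, top_k = 2)
  expect_identical(rep1$report, rep2$report)
})

test_that("average post-minimization RMSD grows with the displacement", {
  # inflating the nitrogen radius by dr moves the N-N pair minimum out by
  # exactly 2 * dr, so the post-minimization RMSD tracks the displacement
  dataset <- lapply(1:2, function(i) contact_complex("N", vinardo))
  deltas <- c(0, 0.25, 0.5, 0.75)
  cands <- lapply(deltas, function(d) set_param(vinardo, "radius_N",
                                                1.7 + d))
  names(cands) <- sprintf("delta_%.2f", deltas)
  rep <- minimization_screen(cands, dataset)
  rmsds <- rep$report$avg_rmsd[match(names(cands), rep$report$candidate)]
  expect_true(all(diff(rmsds) > 0))
  expect_equal(rmsds, 2 * deltas, tolerance = 0.02)
})

test_that("docking screen separates dockable from displaced candidates", {
  cx <- make_toy_pocket(3, ligand_type = "N", receptor_type = "N",
                        params = vinardo)
  dataset <- list(list(receptor = cx$receptor, ligand = cx$ligand),
                  list(receptor = cx$receptor, ligand = cx$ligand))
  box <- list(center = cx$optimum, size = c(3, 3, 3))
  cands <- list(good = vinardo,
                displaced = set_param(vinardo, "radius_N", 1.7 + 1.25))
  d1 <- docking_screen(cands, dataset, n_starts = 3, seed = 5, box = box,
                       tol = 1e-4)
  expect_equal(d1$docking_pct[d1$candidate == "good"], 100)
  expect_equal(d1$docking_pct[d1$candidate == "displaced"], 0)
  d2 <- docking_screen(cands, dataset, n_starts = 3, seed = 5, box = box,
                       tol = 1e-4)
  expect_identical(d1, d2)
})

test_that("predictor diagnostics recover exact and hand-computed trends", {
  # docking ability an exact linear function of average RMSD
  rep <- data.frame(docking_pct = c(90, 70, 50, 30),
                    avg_rmsd = c(0.5, 1.5, 2.5, 3.5),
                    scoring_r = c(0.62, 0.55, 0.60, 0.58))
  di <- predictor_diagnostics(rep)
  expect_equal(di$r_rmsd, -1, tolerance = 1e-12)
  expect_equal(unname(stats::coef(di$fit_rmsd)), c(100, -20),
               tolerance = 1e-9)
  # scoring column against the textbook Pearson formula
  x <- rep$scoring_r - mean(rep$scoring_r)
  y <- rep$docking_pct - mean(rep$docking_pct)
  expect_equal(di$r_scoring, sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
               tolerance = 1e-12)
  expect_error(predictor_diagnostics(rep[1:2, ]), "at least 3")
  expect_error(predictor_diagnostics(rep[, 1:2]), "must contain")
})
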