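test_that("scoring power follows the sign convention and closed form", {
  exact <- data.frame(predicted = -(1:5), experimental = 1:5)
  expect_equal(scoring_power(exact), 1)
  flipped <- data.frame(predicted = 1:5, experimental = 1:5)
  expect_equal(scoring_power(flipped), -1)

  # 5-point hand table against the textbook formula (explicit sums)
  tab <- data.frame(predicted = c(-6.2, -7.1, -5.0, -8.3, -6.9),
                    experimental = c(5.1, 6.0, 4.2, 7.8, 5.5))
  x <- -tab$predicted
  y <- tab$experimental
  want <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(scoring_power(tab), want, tolerance = 1e-12)
  expect_equal(scoring_power(tab), 0.9685730, tolerance = 1e-6)

  expect_error(scoring_power(data.frame(predicted = c(1, 1, 1),
                                        experimental = 1:3)),
               "zero variance")
  expect_error(scoring_power(data.frame(predicted = 1:2,
                                        experimental = 1:2)),
               "at least 3")
})

test_that("ranking power distinguishes high and low success", {
  g <- function(id, pred, expv) {
    data.frame(protein_id = id, predicted = pred, experimental = expv)
  }
  # perfectly ordered / top-only / reversed
  tab <- rbind(g("p1", c(-9, -7, -5), c(9, 7, 5)),
               g("p2", c(-9, -5, -7), c(9, 7, 5)),
               g("p3", c(-5, -7, -9), c(9, 7, 5)))
  rp <- ranking_power(tab)
  expect_equal(rp$high, 100 / 3, tolerance = 1e-12)
  expect_equal(rp$low, 200 / 3, tolerance = 1e-12)

  all_good <- rbind(g("p1", c(-9, -7, -5), c(9, 7, 5)),
                    g("p2", c(-1, -3, -2), c(4, 8, 6)))
  expect_equal(ranking_power(all_good)$high, 100)
  expect_equal(ranking_power(all_good)$low, 100)
  rev_tab <- g("p1", c(-5, -7, -9), c(9, 7, 5))
  expect_equal(ranking_power(rev_tab)$high, 0)
  expect_equal(ranking_power(rev_tab)$low, 0)
  expect_error(ranking_power(g("p1", c(-1, -2), c(1, 2))), "exactly 3")
})

test_that("docking power checks topN by score with ties by input order", {
  pose_tab <- function(id, pred, rmsd) {
    data.frame(complex_id = id, predicted = pred, pose_rmsd = rmsd)
  }
  best_first <- pose_tab("c1", c(-9, -8, -7), c(0.5, 3, 3))
  third_only <- pose_tab("c2", c(-9, -8, -7), c(3, 3, 1.2))
  none <- pose_tab("c3", c(-9, -8, -7), c(3, 4, 5))
  dp <- docking_power(rbind(best_first, third_only, none))
  expect_equal(dp$top1, 100 / 3, tolerance = 1e-12)
  expect_equal(dp$top2, 100 / 3, tolerance = 1e-12)
  expect_equal(dp$top3, 200 / 3, tolerance = 1e-12)
  expect_error(docking_power(pose_tab("c1", -1, NA)), "missing RMSD")
})

test_that("screening power uses ceiling cut-offs on the pool size", {
  pool <- function(rank_of_binder) {
    pred <- seq(-10, -10 + 0.01 * 194, length.out = 195)
    data.frame(protein_id = "p1",
               complex_id = sprintf("lig%03d", order(order(pred))),
               predicted = pred)[1:195, ]
  }
  run <- function(rank) {
    tab <- pool(rank)
    screening_power(tab, c(p1 = sprintf("lig%03d", rank)))
  }
  # rank 1 and rank 2 of 195 are both top 1% (ceiling(1.95) = 2)
  expect_equal(run(1)$top1, 100)
  expect_equal(run(2)$top1, 100)
  expect_equal(run(3)$top1, 0)
  expect_equal(run(3)$top3, 100)   # ceiling(0.03 * 195) = 6
  r10 <- run(10)                   # ceiling(0.05 * 195) = 10
  expect_equal(r10$top1, 0)
  expect_equal(r10$top3, 0)
  expect_equal(r10$top5, 100)
  expect_error(screening_power(pool(1), c(p1 = "nope")), "absent from pool")
})

test_that("ROC AUC equals pair counting and the trapezoidal oracle", {
  perfect <- c(-9, -8, -1, 0)
  expect_equal(roc_auc(perfect, c("active", "active", "decoy", "decoy")), 1)

  lab <- c("active", "decoy", "active", "decoy", "decoy", "active")
  sc <- c(-7.0, -6.5, -6.5, -5.0, -4.0, -3.5)  # one active-decoy tie
  got <- roc_auc(sc, lab)
  # exhaustive pair counting, ties = 1/2
  act <- which(lab == "active")
  dec <- which(lab == "decoy")
  cnt <- 0
  for (i in act) for (j in dec) {
    cnt <- cnt + if (sc[i] < sc[j]) 1 else if (sc[i] == sc[j]) 0.5 else 0
  }
  expect_equal(got, cnt / (length(act) * length(dec)), tolerance = 1e-12)
  expect_equal(got, 11 / 18, tolerance = 1e-12)
  # trapezoidal ROC integration (pROC) as an independent route
  ext <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = sc, levels = c("decoy", "active"),
    direction = ">", quiet = TRUE)))
  expect_equal(got, ext, tolerance = 1e-12)

  # reversal identity in the absence of ties
  set.seed(3)
  sc2 <- stats::rnorm(40)
  lab2 <- rep(c("active", "decoy"), 20)
  expect_equal(roc_auc(-sc2, lab2), 1 - roc_auc(sc2, lab2),
               tolerance = 1e-12)
  expect_error(roc_auc(1:3, c("active", "active", "active")),
               "at least one")
})

test_that("BEDROC matches its closed form, bounds and monotonicity", {
  # frozen hand example: N = 10, actives at ranks 1, 4, 10, alpha = 20
  pred <- seq(-10, -1, length.out = 10)
  lab <- rep("decoy", 10)
  lab[c(1, 4, 10)] <- "active"
  expect_equal(bedroc(pred, lab, alpha = 20), 0.8689619, tolerance = 1e-6)

  # min-max RIE scaling as an independent formulation (large N)
  set.seed(8)
  n <- 10; big_n <- 1000; alpha <- 20
  sc <- stats::rnorm(big_n)
  lb <- rep("decoy", big_n)
  lb[sample(big_n, n)] <- "active"
  ranks <- rank(sc, ties.method = "first")[lb == "active"]
  rie_of <- function(rk) {
    sum(exp(-alpha * rk / big_n)) /
      ((n / big_n) * (1 - exp(-alpha)) / (exp(alpha / big_n) - 1))
  }
  alt <- (rie_of(ranks) - rie_of((big_n - n + 1):big_n)) /
    (rie_of(1:n) - rie_of((big_n - n + 1):big_n))
  expect_equal(bedroc(sc, lb, alpha), alt, tolerance = 1e-3)

  # saturation: all actives on top of a large pool
  top <- c(rep("active", 5), rep("decoy", 495))
  expect_gte(bedroc(seq_len(500), top, alpha = 20), 0.99)

  # moving an active up one rank never decreases BEDROC
  sc3 <- as.numeric(1:30)
  lb3 <- rep("decoy", 30)
  lb3[c(5, 14, 22)] <- "active"
  b0 <- bedroc(sc3, lb3)
  lb4 <- rep("decoy", 30)
  lb4[c(5, 13, 22)] <- "active"
  expect_gte(bedroc(sc3, lb4), b0)
  expect_error(bedroc(1:4, c("active", rep("decoy", 3)), alpha = 0),
               "alpha")
})

test_that("rank-based powers are invariant to monotone score transforms", {
  set.seed(21)
  transforms <- list(function(x) 3 * x + 2,
                     function(x) x^3,
                     function(x) exp(x / 4) - 5)
  # ranking / docking / screening / AUC / BEDROC under each transform
  rk <- data.frame(protein_id = rep(sprintf("p%d", 1:6), each = 3),
                   predicted = stats::rnorm(18),
                   experimental = stats::rnorm(18))
  dk <- data.frame(complex_id = rep(sprintf("c%d", 1:5), each = 4),
                   predicted = stats::rnorm(20),
                   pose_rmsd = stats::runif(20, 0, 4))
  sc <- stats::rnorm(60)
  lb <- rep(c("active", "decoy"), c(12, 48))
  scr <- data.frame(protein_id = "p1",
                    complex_id = sprintf("l%02d", 1:40),
                    predicted = stats::rnorm(40))
  binder <- c(p1 = "l07")
  base <- list(ranking_power(rk), docking_power(dk),
               screening_power(scr, binder),
               roc_auc(sc, lb), bedroc(sc, lb))
  for (f in transforms) {
    rk2 <- rk; rk2$predicted <- f(rk$predicted)
    dk2 <- dk; dk2$predicted <- f(dk$predicted)
    scr2 <- scr; scr2$predicted <- f(scr$predicted)
    expect_equal(ranking_power(rk2), base[[1]])
    expect_equal(docking_power(dk2), base[[2]])
    expect_equal(screening_power(scr2, binder), base[[3]])
    expect_equal(roc_auc(f(sc), lb), base[[4]], tolerance = 1e-12)
    expect_equal(bedroc(f(sc), lb), base[[5]], tolerance = 1e-12)
  }
  # scoring power (a Pearson statistic) is invariant under positive affine
  # transforms of the energies
  tab <- data.frame(predicted = stats::rnorm(20),
                    experimental = stats::rnorm(20))
  expect_equal(scoring_power(transform(tab, predicted = 3 * predicted + 2)),
               scoring_power(tab), tolerance = 1e-12)
})

test_that("score tables round-trip through delimited text", {
  tab <- make_screening_table(5, 10, 1.5, seed = 4)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, tmp)
  back <- read_score_table(tmp)
  expect_equal(back$complex_id, tab$complex_id)
  expect_equal(back$predicted, tab$predicted, tolerance = 1e-12)
  expect_equal(back$label, tab$label)
})
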