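cm_of <- function(TP, TN, FP, FN) {
  predicted <- c(rep("upper", TP), rep("lower", TN),
                 rep("upper", FP), rep("lower", FN))
  truth <- c(rep("upper", TP), rep("lower", TN),
             rep("lower", FP), rep("upper", FN))
  confusion_matrix(predicted, truth)
}

test_that("confusion-matrix metrics reproduce the printed formulas", {
  perfect <- compute_metrics(cm_of(9, 9, 0, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  # 15 correct of 18: the minimum test accuracy seen across balanced runs
  m18 <- compute_metrics(cm_of(8, 7, 2, 1))
  expect_equal(m18$accuracy, 15 / 18)
  expect_equal(round(m18$accuracy, 3), 0.833)

  m12 <- compute_metrics(cm_of(5, 5, 1, 1))
  expect_equal(m12$accuracy, 10 / 12)
  expect_equal(m12$precision, 5 / 6)
  expect_equal(m12$recall, 5 / 6)
  expect_equal(m12$f1, 5 / 6)

  # harmonic mean identity and range invariants on enumerated matrices
  for (TP in 0:3) for (TN in 0:3) for (FP in 0:3) for (FN in 0:3) {
    if (TP + TN + FP + FN == 0) next
    r <- suppressWarnings(compute_metrics(cm_of(TP, TN, FP, FN)))
    vals <- c(r$accuracy, r$precision, r$recall, r$f1)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_true(r$f1 >= min(r$precision, r$recall) - 1e-12)
    expect_true(r$f1 <= max(r$precision, r$recall) + 1e-12)
    if (r$precision + r$recall > 0 && !length(r$undefined))
      expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
  }

  zero_den <- suppressWarnings(compute_metrics(cm_of(0, 5, 0, 2)))
  expect_equal(zero_den$precision, 0)
  expect_true("precision" %in% zero_den$undefined)
  expect_error(compute_metrics(cm_of(0, 0, 0, 0)), "empty")
})

test_that("AUC equals the brute-force pairwise concordance probability", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.35, 0.1)
  labels <- c("upper", "lower", "upper", "upper", "lower", "lower")
  r <- roc_auc(scores, labels)
  expect_equal(r$auc, o_auc_concordance(scores, labels))

  sep <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c("upper", "upper", "lower", "lower"))
  expect_equal(sep$auc, 1)

  set.seed(5)
  for (rep in 1:10) {
    sc <- round(runif(12), 2)  # rounding forces occasional ties
    lb <- sample(c("upper", "lower"), 12, replace = TRUE,
                 prob = c(0.4, 0.6))
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc, o_auc_concordance(sc, lb))
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(qlogis(pmin(pmax(sc, 0.01), 0.99)), lb)$auc,
                 roc_auc(pmin(pmax(sc, 0.01), 0.99), lb)$auc)
  }
  # independent scores and labels at large n give AUC near 1/2
  set.seed(6)
  sc <- runif(2000); lb <- sample(c("upper", "lower"), 2000, replace = TRUE)
  expect_lt(abs(roc_auc(sc, lb)$auc - 0.5), 0.05)
  expect_error(roc_auc(c(0.1, 0.9), c("upper", "upper")), "both classes")
})

test_that("paired t and Wilcoxon match closed-form and exhaustive-enumeration oracles", {
  set.seed(7)
  a <- runif(10); b <- a + rnorm(10, 0.05, 0.08)
  r <- paired_tests(a, b)
  expect_equal(r$t_statistic, o_paired_t(a, b), tolerance = 1e-12)
  expect_equal(r$t_pvalue,
               2 * stats::pt(-abs(r$t_statistic), df = 9), tolerance = 1e-12)
  expect_equal(r$w_pvalue, o_wilcoxon_exact(a - b), tolerance = 1e-12)
  expect_equal(r$n_pairs, 10L)

  # constant positive shift: W at its extreme, exact two-sided p = 2/2^10
  shift <- runif(10)
  rs <- paired_tests(shift + 0.1, shift)
  expect_equal(rs$w_statistic, 55)          # sum of all ranks 1..10
  expect_equal(rs$w_pvalue, 2 / 2^10)
  expect_equal(rs$w_pvalue, o_wilcoxon_exact(rep(0.1, 10)))

  # identical series degenerate to t = 0, p = 1 with a warning
  expect_warning(rid <- paired_tests(a, a), "degenerate")
  expect_equal(rid$t_statistic, 0)
  expect_equal(rid$t_pvalue, 1)

  expect_error(paired_tests(a, b[1:5]), "matched")
  expect_error(paired_tests(1, 2), "at least two")

  # enumeration oracle across random small samples without ties
  for (n in c(6, 9, 12)) {
    d <- rnorm(n)
    r2 <- paired_tests(d + rnorm(n, 0, 1e-9), rep(0, n) - d + d)
    # simpler: direct difference series
    x <- rnorm(n); y <- x - d
    r2 <- paired_tests(x, y)
    expect_equal(r2$w_pvalue, o_wilcoxon_exact(d), tolerance = 1e-10)
  }
})

test_that("video-level prediction averages segment probabilities with ties to the positive class", {
  # constant-weight model: logits identical across segments
  m <- build_model(tiny_arch(), 3, seed = 8)
  v <- tiny_video(T = 60, H = 16, W = 16, label = "upper", seed = 9)
  cfgseg <- segment_config(2, 2)
  p1 <- predict_video(m, v, cfgseg, seed = 1)
  expect_true(p1$score >= 0 && p1$score <= 1)
  expect_true(p1$label %in% c("upper", "lower"))
  expect_identical(predict_video(m, v, cfgseg, seed = 2),
                   predict_video(m, v, cfgseg, seed = 2))

  vlong <- tiny_video(T = 100, H = 16, W = 16, seed = 10)
  expect_equal(predict_video(m, vlong, cfgseg, seed = 1)$n_segments, 10L)

  # a model with all-zero head gives identical logits (0, 0) for every
  # segment: mean probability 1/2 per class, tie resolved to "upper"
  mz <- m
  mz$params$head$W[] <- 0; mz$params$head$b[] <- 0
  pz <- predict_video(mz, v, cfgseg, seed = 3)
  expect_equal(pz$score, 0.5)
  expect_equal(pz$label, "upper")
})
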