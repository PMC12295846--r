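test_that("balanced subsets use every minority video plus a seeded majority sample", {
  dc <- dummy_corpus(6, 31)
  cfg <- experiment_config(n_runs = 4, balanced_per_class = 6,
                           master_seed = 3, epochs = 1)
  runs <- make_balanced_runs(dc$upper, dc$lower, cfg)
  expect_length(runs, 4L)
  for (r in runs) {
    expect_length(r, 12L)
    labs <- vapply(r, `[[`, "", "label")
    expect_equal(sum(labs == "upper"), 6L)
    expect_equal(sum(labs == "lower"), 6L)
    ids <- vapply(r, `[[`, "", "video_id")
    expect_equal(anyDuplicated(ids), 0L)
  }
  # pure function of the master seed (bitwise across calls)
  expect_identical(runs, make_balanced_runs(dc$upper, dc$lower, cfg))
  cfg2 <- cfg; cfg2$arch <- rpanet_arch(stage_widths = c(2, 2, 2, 2, 2))
  expect_identical(runs, make_balanced_runs(dc$upper, dc$lower, cfg2))

  # majority class of exactly the balanced size: every video used
  dc2 <- dummy_corpus(4, 4)
  cfg3 <- experiment_config(n_runs = 2, balanced_per_class = 4, epochs = 1)
  runs3 <- make_balanced_runs(dc2$upper, dc2$lower, cfg3)
  expect_setequal(vapply(runs3[[1]], `[[`, "", "video_id"),
                  vapply(c(dc2$upper, dc2$lower), `[[`, "", "video_id"))

  expect_error(make_balanced_runs(dc$upper, dc$lower[1:3], cfg), "too few")
})

test_that("70:15:15 video-level splits are exhaustive, disjoint, and stratified", {
  dc <- dummy_corpus(60, 60)
  videos <- c(dc$upper, dc$lower)
  cfg <- experiment_config(balanced_per_class = 60, epochs = 1)
  sp <- split_videos(videos, cfg, run_seed = 17)
  expect_length(sp$train, 84L)
  expect_length(sp$val, 18L)
  expect_length(sp$test, 18L)
  # stratification: 42 per class in training
  expect_equal(sum(vapply(sp$train, `[[`, "", "label") == "upper"), 42L)
  # union equals the input, pairwise disjoint (leakage check)
  ids <- lapply(sp, function(part) vapply(part, `[[`, "", "video_id"))
  expect_setequal(unlist(ids), vapply(videos, `[[`, "", "video_id"))
  expect_length(intersect(ids$train, ids$val), 0L)
  expect_length(intersect(ids$train, ids$test), 0L)
  expect_length(intersect(ids$val, ids$test), 0L)
  expect_identical(split_videos(videos, cfg, 17), sp)
  expect_error(split_videos(videos[1:2], cfg, 1), "at least 3")
  dsmall <- dummy_corpus(3, 3)
  expect_error(split_videos(c(dsmall$upper, dsmall$lower), cfg, 1), "empty")
})

test_that("a short training run records finite history and is seed-reproducible", {
  corpus <- tiny_train_corpus()
  videos <- c(corpus$upper, corpus$lower)
  cfg <- experiment_config(n_runs = 1, balanced_per_class = 3, epochs = 2,
                           learning_rate = 1e-3,
                           segment = segment_config(2, 2),
                           arch = tiny_arch())
  splits <- list(train = videos[1:4], val = videos[5], test = videos[6])
  model <- build_model(cfg$arch, 3, seed = 1)
  rr <- train_run(model, splits, cfg, run_seed = 5)
  expect_s3_class(rr, "run_result")
  expect_equal(nrow(rr$history), 2L)
  expect_true(all(is.finite(rr$history$train_loss)))
  expect_true(all(is.finite(rr$history$val_loss)))
  expect_true(rr$incorrect_count <= length(splits$test))
  expect_equal(nrow(rr$predictions), 1L)

  rr2 <- train_run(build_model(cfg$arch, 3, seed = 1), splits, cfg,
                   run_seed = 5)
  expect_identical(rr$history, rr2$history)
  expect_identical(rr$predictions, rr2$predictions)
})

test_that("multi-run aggregation gives t-intervals, extremes, and error histograms", {
  mk_result <- function(acc, wrong) {
    structure(list(run_index = 1L,
                   metrics = structure(list(accuracy = acc, precision = acc,
                                            recall = acc, f1 = acc, auc = acc,
                                            undefined = character(0)),
                                       class = "metrics_report"),
                   incorrect_count = wrong),
              class = "run_result")
  }
  # two-point closed form: mean 0.95, CI mean +/- t_{.975,1} * sd / sqrt(2)
  agg <- aggregate_runs(list(mk_result(1.0, 0L), mk_result(0.9, 2L)))
  acc <- agg$table[agg$table$metric == "accuracy", ]
  expect_equal(acc$mean, 0.95)
  halfwidth <- stats::qt(0.975, df = 1) * stats::sd(c(1, 0.9)) / sqrt(2)
  expect_equal(acc$ci_lower, 0.95 - halfwidth)
  expect_equal(acc$ci_upper, 0.95 + halfwidth)
  expect_equal(acc$max, 1.0)
  expect_equal(acc$min, 0.9)

  # identical runs collapse the interval to zero width
  agg0 <- aggregate_runs(list(mk_result(0.8, 1L), mk_result(0.8, 1L)))
  a0 <- agg0$table[agg0$table$metric == "accuracy", ]
  expect_equal(a0$ci_lower, a0$ci_upper)

  aggh <- aggregate_runs(list(mk_result(1, 0L), mk_result(1, 1L),
                              mk_result(1, 1L), mk_result(1, 2L)))
  expect_equal(as.vector(aggh$incorrect_histogram), c(1L, 2L, 1L))
  expect_equal(names(aggh$incorrect_histogram), c("0", "1", "2"))

  expect_error(aggregate_runs(list(mk_result(1, 0L))), "at least 2")
})

test_that("the fitting interface returns a classed model with working methods", {
  corpus <- tiny_train_corpus()
  videos <- c(corpus$upper, corpus$lower)
  fit <- rpanet(videos, val = videos[1:2], arch = tiny_arch(),
                segment = segment_config(2, 2), epochs = 2,
                learning_rate = 1e-3, seed = 2)
  expect_s3_class(fit, "rpanet")
  expect_equal(nrow(fit$history), 2L)
  expect_output(print(fit), "RPA 3D video classifier")
  pr <- predict(fit, videos[1:3], seed = 1)
  expect_equal(nrow(pr), 3L)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  expect_identical(pr, predict(fit, videos[1:3], seed = 1))
  cf <- coef(fit)
  expect_equal(length(cf), n_params(fit$model))
  expect_true(is.numeric(cf))
  pdf_file <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  expect_silent(plot(fit))
  grDevices::dev.off()
  expect_true(file.size(pdf_file) > 0)
})
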