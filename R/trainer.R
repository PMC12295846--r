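# Experimental protocol: balanced per-run subsets reused across
# configurations, stratified 70:15:15 video-level splits, segment-level
# optimization with on-the-fly segment sampling, and multi-run aggregation
# with 95% confidence intervals.

#' Experiment configuration
#'
#' @param n_runs number of independent balanced runs (default 20).
#' @param split_ratios train/validation/test video-level ratios, summing
#'   to 1.
#' @param balanced_per_class videos per class in each balanced subset
#'   (default 60: all minority-class videos plus as many sampled
#'   majority-class videos).
#' @param batch_size segments per optimization step (default 2).
#' @param learning_rate initial Adam learning rate (default 1e-4).
#' @param epochs training epochs per run (default 50).
#' @param master_seed seed from which every run's subset, split,
#'   initialization and sampling stream is derived.
#' @param segment a [segment_config()].
#' @param arch an [rpanet_arch()].
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_runs = 20L,
                              split_ratios = c(0.70, 0.15, 0.15),
                              balanced_per_class = 60L,
                              batch_size = 2L,
                              learning_rate = 1e-4,
                              epochs = 50L,
                              master_seed = 1L,
                              segment = segment_config(10L, 15L),
                              arch = rpanet_arch()) {
  if (abs(sum(split_ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  if (any(split_ratios <= 0)) stop("all split ratios must be positive")
  if (n_runs < 1 || balanced_per_class < 1 || batch_size < 1 || epochs < 1)
    stop("all counts must be positive")
  if (learning_rate <= 0) stop("learning rate must be positive")
  structure(list(n_runs = as.integer(n_runs), split_ratios = split_ratios,
                 balanced_per_class = as.integer(balanced_per_class),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 master_seed = as.integer(master_seed),
                 segment = segment, arch = arch),
            class = "experiment_config")
}

#' Balanced per-run video subsets
#'
#' Each of the `n_runs` subsets contains every minority-class ("upper")
#' video plus `balanced_per_class` majority-class ("lower") videos sampled
#' without replacement.  The subsets are a pure function of
#' `cfg$master_seed`, so the same subsets are reused across segment or
#' architecture configurations.
#'
#' @param upper,lower lists of [video_record()]s per class.
#' @param cfg an [experiment_config()].
#' @return a list of `n_runs` video lists, each of size
#'   `length(upper) + balanced_per_class`.
#' @export
make_balanced_runs <- function(upper, lower, cfg) {
  k <- cfg$balanced_per_class
  if (length(lower) < k)
    stop("too few majority-class videos: need at least ", k)
  if (length(upper) > k)
    stop("balanced_per_class must be at least the minority-class size")
  .with_seed(derive_seed(cfg$master_seed, 0L, "subsets"), {
    lapply(seq_len(cfg$n_runs), function(i) {
      c(upper, lower[sample.int(length(lower), k)])
    })
  })
}

#' Stratified video-level train/validation/test split
#'
#' Within each class, `round(r_train * n)` videos go to training,
#' `round(r_val * n)` to validation, and the remainder to testing;
#' assignment is deterministic given `run_seed`.  The split is always at
#' the video level, never the segment level, so no video leaks across
#' splits.
#'
#' @param videos list of [video_record()]s.
#' @param cfg an [experiment_config()].
#' @param run_seed integer seed for this run's split.
#' @return list with `train`, `val`, `test` video lists.
#' @export
split_videos <- function(videos, cfg, run_seed) {
  if (length(videos) < 3) stop("need at least 3 videos to split")
  labels <- vapply(videos, `[[`, "", "label")
  r <- cfg$split_ratios
  parts <- list(train = list(), val = list(), test = list())
  .with_seed(run_seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_tr <- round(r[1] * n)
      n_va <- round(r[2] * n)
      parts$train <- c(parts$train, videos[idx[seq_len(n_tr)]])
      parts$val <- c(parts$val, videos[idx[n_tr + seq_len(n_va)]])
      parts$test <- c(parts$test,
                      videos[idx[setdiff(seq_len(n), seq_len(n_tr + n_va))]])
    }
  })
  if (any(vapply(parts, length, 0L) == 0))
    stop("a split is empty; use more videos or different ratios")
  parts
}

.label_int <- function(label) ifelse(label == "upper", 1L, 2L)

# One optimization pass over the given segments (a batch).
.train_batch <- function(model, adam, segs, labels, lr) {
  x <- array(0, c(length(segs), dim(segs[[1]]$data)))
  for (i in seq_along(segs)) x[i, , , , ] <- segs[[i]]$data
  fwd <- .model_fwd(model, x, keep = TRUE)
  ce <- .softmax_ce(fwd$logits, labels)
  if (!is.finite(ce$loss))
    stop("training diverged: non-finite loss (lr = ", lr, ")")
  bwd <- .model_bwd(model, fwd, ce$dlogits)
  st <- .adam_step(model$params, bwd$grads, adam, lr)
  model$params <- st$params
  acc <- mean(max.col(ce$prob) == labels)
  list(model = model, adam = st$state, loss = ce$loss, acc = acc)
}

# Segment-level loss/accuracy on one freshly sampled segment per video.
.eval_segments <- function(model, videos, segment) {
  segs <- lapply(videos, sample_training_segment, config = segment)
  labels <- .label_int(vapply(segs, `[[`, "", "label"))
  x <- array(0, c(length(segs), dim(segs[[1]]$data)))
  for (i in seq_along(segs)) x[i, , , , ] <- segs[[i]]$data
  ce <- .softmax_ce(.model_fwd(model, x)$logits, labels)
  list(loss = ce$loss, acc = mean(max.col(ce$prob) == labels))
}

#' Train one run
#'
#' Optimizes softmax cross-entropy on raw logits with Adam; every epoch
#' draws one fresh random segment per training video (segments are
#' generated on the fly) and consumes them in batches of
#' `cfg$batch_size`.  Validation records segment-level loss/accuracy on
#' one random segment per validation video per epoch; the test split is
#' evaluated at the end with video-level multi-segment prediction.
#'
#' @param model an untrained `rpanet_model` (raw-logit output of width 2).
#' @param splits result of [split_videos()].
#' @param cfg an [experiment_config()].
#' @param run_seed integer seed driving all of this run's segment
#'   sampling.
#' @param run_index integer label for bookkeeping.
#' @param keep_model keep the trained weights in the result.
#' @return an object of class `run_result` with the per-epoch `history`,
#'   the test `metrics` (including AUC), `incorrect_count`, and per-video
#'   test `predictions`.
#' @export
train_run <- function(model, splits, cfg, run_seed, run_index = 1L,
                      keep_model = FALSE) {
  stopifnot(inherits(model, "rpanet_model"))
  train <- splits$train
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     train_acc = NA_real_, val_loss = NA_real_,
                     val_acc = NA_real_)
  adam <- .adam_init(model$params)
  .with_seed(run_seed, {
    for (e in seq_len(cfg$epochs)) {
      ord <- sample.int(length(train))
      losses <- c(); accs <- c()
      for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        segs <- lapply(train[b], sample_training_segment, config = cfg$segment)
        labels <- .label_int(vapply(segs, `[[`, "", "label"))
        st <- .train_batch(model, adam, segs, labels, cfg$learning_rate)
        model <- st$model; adam <- st$adam
        losses <- c(losses, st$loss); accs <- c(accs, st$acc)
      }
      hist$train_loss[e] <- mean(losses)
      hist$train_acc[e] <- mean(accs)
      ve <- .eval_segments(model, splits$val, cfg$segment)
      hist$val_loss[e] <- ve$loss
      hist$val_acc[e] <- ve$acc
    }
    truth <- vapply(splits$test, `[[`, "", "label")
    preds <- lapply(splits$test, function(v)
      predict_video(model, v, cfg$segment))
    scores <- vapply(preds, `[[`, 0, "score")
    labels <- vapply(preds, `[[`, "", "label")
    cm <- confusion_matrix(labels, truth)
    auc <- if (length(unique(truth)) == 2)
      roc_auc(scores, truth)$auc else NA_real_
    metrics <- compute_metrics(cm, auc = auc)
    structure(list(run_index = as.integer(run_index), history = hist,
                   metrics = metrics, cm = cm,
                   incorrect_count = cm$FP + cm$FN,
                   predictions = data.frame(
                     video_id = vapply(splits$test, `[[`, "", "video_id"),
                     truth = truth, score = scores, label = labels,
                     stringsAsFactors = FALSE),
                   model = if (keep_model) model else NULL),
              class = "run_result")
  })
}

#' Aggregate multi-run results
#'
#' Mean, 95% Student-t confidence interval (`mean +/- t * sd / sqrt(n)`),
#' maximum and minimum of every metric across runs, plus the histogram of
#' per-run incorrect-prediction counts.
#'
#' @param results list of `run_result`s (length >= 2).
#' @return an object of class `run_summary` with a `table` data frame and
#'   an `incorrect_histogram` table.
#' @export
aggregate_runs <- function(results) {
  if (length(results) < 2) stop("need at least 2 runs to aggregate")
  mn <- c("accuracy", "precision", "recall", "f1", "auc")
  per_run <- sapply(mn, function(m)
    vapply(results, function(r) r$metrics[[m]], 0))
  per_run <- matrix(per_run, nrow = length(results),
                    dimnames = list(NULL, mn))
  n <- nrow(per_run)
  tcrit <- stats::qt(0.975, df = n - 1)
  tab <- data.frame(
    metric = mn,
    mean = colMeans(per_run),
    sd = apply(per_run, 2, stats::sd),
    row.names = NULL)
  tab$ci_lower <- tab$mean - tcrit * tab$sd / sqrt(n)
  tab$ci_upper <- tab$mean + tcrit * tab$sd / sqrt(n)
  tab$max <- apply(per_run, 2, max)
  tab$min <- apply(per_run, 2, min)
  wrong <- vapply(results, `[[`, 0L, "incorrect_count")
  structure(list(table = tab, per_run = per_run,
                 incorrect_histogram = table(wrong), n_runs = n),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, digits = 3, ...) {
  cat("summary over", x$n_runs, "runs:\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits = digits)
  print(tab, row.names = FALSE)
  cat("incorrect predictions per run:\n")
  print(x$incorrect_histogram)
  invisible(x)
}

#' Run the full balanced multi-run experiment
#'
#' Builds the `n_runs` balanced subsets, and for each: a stratified
#' 70:15:15 split, a freshly initialized model, training, and video-level
#' test evaluation.  Every random stream is derived deterministically from
#' `cfg$master_seed`, so an attention-ablated rerun (same seed,
#' `arch$attention = FALSE`) sees the same subsets, splits and segment
#' draws — paired arms for [paired_tests()].
#'
#' @param upper,lower class-wise lists of [video_record()]s.
#' @param cfg an [experiment_config()].
#' @param input_channels input channel count.
#' @param verbose print a line per run.
#' @return an object of class `rpanet_experiment` with `results`,
#'   `summary`, and `cfg`.
#' @export
run_experiment <- function(upper, lower, cfg, input_channels = 3L,
                           verbose = FALSE) {
  subsets <- make_balanced_runs(upper, lower, cfg)
  results <- vector("list", cfg$n_runs)
  for (i in seq_len(cfg$n_runs)) {
    splits <- split_videos(subsets[[i]], cfg,
                           derive_seed(cfg$master_seed, i, "split"))
    model <- build_model(cfg$arch, input_channels,
                         seed = derive_seed(cfg$master_seed, i, "init"))
    results[[i]] <- train_run(model, splits, cfg,
                              run_seed = derive_seed(cfg$master_seed, i, "train"),
                              run_index = i)
    if (verbose)
      message(sprintf("run %d/%d: test accuracy %.3f", i, cfg$n_runs,
                      results[[i]]$metrics$accuracy))
  }
  structure(list(results = results, summary = aggregate_runs(results),
                 cfg = cfg),
            class = "rpanet_experiment")
}

#' @export
print.rpanet_experiment <- function(x, ...) {
  cat("balanced multi-run experiment (", x$cfg$n_runs, " runs, N = ",
      x$cfg$segment$frames_per_segment, ", G = ",
      x$cfg$segment$frame_gap, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}
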