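# The classic modelling interface: one fitting function returning a
# classed object with print / summary / coef / predict / plot methods.

#' Fit a residual parallel-attention 3D video classifier
#'
#' Trains the five-stage RPA network on a list of labeled videos by
#' segment-level optimization: every epoch draws one fresh random segment
#' per training video and minimizes softmax cross-entropy on raw logits
#' with Adam.
#'
#' @param videos list of [video_record()]s (training split).
#' @param val optional list of [video_record()]s monitored each epoch.
#' @param arch an [rpanet_arch()] describing the network.
#' @param segment a [segment_config()]; default N = 10 frames with frame
#'   gap G = 15 (segment span 150).
#' @param epochs training epochs (default 50).
#' @param batch_size segments per optimization step (default 2).
#' @param learning_rate initial Adam learning rate (default 1e-4).
#' @param seed integer seed controlling weight initialization and all
#'   segment sampling.
#' @param verbose print one line per epoch.
#' @return an object of class `rpanet` containing the trained
#'   `rpanet_model`, the per-epoch `history` and the configuration.
#' @examples
#' cfg <- synth_config(n_upper = 2, n_lower = 2, length_range = c(20, 40),
#'                     frame_size = c(16, 16))
#' corpus <- generate_corpus(cfg)
#' fit <- rpanet(c(corpus$upper, corpus$lower),
#'               arch = rpanet_arch(stage_widths = c(2, 2, 2, 2, 4)),
#'               segment = segment_config(2, 2), epochs = 1, seed = 1)
#' predict(fit, corpus$upper[[1]])
#' @export
rpanet <- function(videos, val = NULL, arch = rpanet_arch(),
                   segment = segment_config(10L, 15L),
                   epochs = 50L, batch_size = 2L, learning_rate = 1e-4,
                   seed = 1L, verbose = FALSE) {
  stopifnot(length(videos) >= 1)
  in_ch <- dim(videos[[1]]$frames)[4]
  model <- build_model(arch, in_ch, seed = derive_seed(seed, 0L, "init"))
  hist <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                     train_acc = NA_real_, val_loss = NA_real_,
                     val_acc = NA_real_)
  adam <- .adam_init(model$params)
  .with_seed(derive_seed(seed, 0L, "train"), {
    for (e in seq_len(epochs)) {
      ord <- sample.int(length(videos))
      losses <- c(); accs <- c()
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        segs <- lapply(videos[b], sample_training_segment, config = segment)
        labels <- .label_int(vapply(segs, `[[`, "", "label"))
        st <- .train_batch(model, adam, segs, labels, learning_rate)
        model <- st$model; adam <- st$adam
        losses <- c(losses, st$loss); accs <- c(accs, st$acc)
      }
      hist$train_loss[e] <- mean(losses)
      hist$train_acc[e] <- mean(accs)
      if (!is.null(val)) {
        ve <- .eval_segments(model, val, segment)
        hist$val_loss[e] <- ve$loss
        hist$val_acc[e] <- ve$acc
      }
      if (verbose)
        message(sprintf("epoch %d: loss %.4f acc %.3f", e,
                        hist$train_loss[e], hist$train_acc[e]))
    }
  })
  structure(list(model = model, history = hist, arch = arch,
                 segment = segment, seed = as.integer(seed),
                 learning_rate = learning_rate, batch_size = batch_size,
                 call = match.call()),
            class = "rpanet")
}

#' @export
print.rpanet <- function(x, ...) {
  cat("Fitted RPA 3D video classifier\n")
  cat("  segments: N =", x$segment$frames_per_segment,
      ", G =", x$segment$frame_gap,
      "(span", x$segment$segment_span, "frames)\n")
  print(x$model)
  e <- nrow(x$history)
  cat(sprintf("  final training loss %.4f, accuracy %.3f (%d epochs)\n",
              x$history$train_loss[e], x$history$train_acc[e], e))
  invisible(x)
}

#' @export
summary.rpanet <- function(object, ...) {
  print(object)
  cat("\ntraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Predict video classes from a fitted classifier
#'
#' @param object an `rpanet` fit.
#' @param newdata a [video_record()] or a list of them.
#' @param max_segments inference segment cap (default 10).
#' @param seed optional seed for inference segment selection.
#' @param ... unused.
#' @return a data frame with one row per video: `video_id`, `score` (mean
#'   positive-class probability), `label`.
#' @export
predict.rpanet <- function(object, newdata, max_segments = 10L,
                           seed = NULL, ...) {
  if (inherits(newdata, "video_record")) newdata <- list(newdata)
  out <- lapply(seq_along(newdata), function(i) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, i, "predict")
    predict_video(object$model, newdata[[i]], object$segment,
                  max_segments = max_segments, seed = s)
  })
  data.frame(video_id = vapply(newdata, `[[`, "", "video_id"),
             score = vapply(out, `[[`, 0, "score"),
             label = vapply(out, `[[`, "", "label"),
             stringsAsFactors = FALSE)
}

#' @export
coef.rpanet <- function(object, ...) {
  leaves <- .tree_flatten(object$model$params)
  unlist(lapply(leaves, as.vector))
}

#' Plot training curves of a fitted classifier
#'
#' @param x an `rpanet` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rpanet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "accuracy", ...)
  invisible(x)
}
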