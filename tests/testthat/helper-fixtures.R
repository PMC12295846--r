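# Small fixtures built in code: tiny videos, tiny architectures.

tiny_video <- function(T = 10L, H = 4L, W = 4L, label = "upper",
                       id = "v1", seed = 1L) {
  set.seed(seed)
  video_record(array(runif(T * H * W * 3), c(T, H, W, 3L)), label, id)
}

# n dummy videos with alternating labels (1 frame each, 2x2) — enough for
# split/balance bookkeeping tests without any real pixels.
dummy_corpus <- function(n_upper, n_lower, seed = 1L) {
  set.seed(seed)
  mk <- function(label, i)
    video_record(array(runif(12), c(1L, 2L, 2L, 3L)), label,
                 sprintf("%s_%03d", label, i))
  list(upper = lapply(seq_len(n_upper), mk, label = "upper"),
       lower = lapply(seq_len(n_lower), mk, label = "lower"))
}

tiny_arch <- function(widths = c(2L, 2L, 2L, 2L, 2L), ...) {
  rpanet_arch(stage_widths = widths, ...)
}

# smallest corpus on which the fitting loop runs end to end
tiny_train_corpus <- function(seed = 1L) {
  cfg <- synth_config(n_upper = 3L, n_lower = 3L, length_range = c(8L, 20L),
                      frame_size = c(16L, 16L), seed = seed)
  generate_corpus(cfg)
}
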