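# Full network: five RPA blocks interleaved with four downsample stages,
# then global average pooling, flattening, and a dense layer producing raw
# class logits (loss-side softmax).

#' Architecture configuration
#'
#' @param stage_widths channel counts of the five RPA stages.
#' @param spatial_kernel,temporal_kernel odd kernel sizes of every (2+1)D
#'   convolution.
#' @param reduction_ratio cSE bottleneck reduction ratio `r`.
#' @param sw_bypass_threshold channel count below which P-scSE3D runs in its
#'   shorted (additive-only) form.
#' @param attention include P-scSE3D after each residual block; `FALSE`
#'   gives the attention-ablated network of plain residual blocks with
#'   identical depth and width.
#' @param n_classes number of output classes.
#' @return an object of class `rpanet_arch`.
#' @export
rpanet_arch <- function(stage_widths = c(16L, 32L, 64L, 128L, 256L),
                        spatial_kernel = 3L, temporal_kernel = 3L,
                        reduction_ratio = 2L, sw_bypass_threshold = 32L,
                        attention = TRUE, n_classes = 2L) {
  if (length(stage_widths) != 5L)
    stop("the network has exactly five RPA stages; give five stage widths")
  if (any(stage_widths < 1)) stop("stage widths must be positive")
  if (spatial_kernel %% 2 == 0 || temporal_kernel %% 2 == 0)
    stop("kernel sizes must be odd")
  if (any(stage_widths < reduction_ratio))
    stop("every stage width must be at least the reduction ratio")
  structure(list(stage_widths = as.integer(stage_widths),
                 spatial_kernel = as.integer(spatial_kernel),
                 temporal_kernel = as.integer(temporal_kernel),
                 reduction_ratio = as.integer(reduction_ratio),
                 sw_bypass_threshold = as.integer(sw_bypass_threshold),
                 attention = isTRUE(attention),
                 n_rpa = 5L, n_downsample = 4L,
                 n_classes = as.integer(n_classes)),
            class = "rpanet_arch")
}

#' Build an untrained network
#'
#' Stages run RPA1 -> down -> RPA2 -> down -> RPA3 -> down -> RPA4 -> down
#' -> RPA5 -> global average pool -> flatten -> dense logits.  All weights
#' use seeded variance-scaling initialization.
#'
#' @param arch an [rpanet_arch()] configuration.
#' @param input_channels channels of the input volume (3 for RGB video).
#' @param seed integer seed for weight initialization.
#' @return an object of class `rpanet_model`.
#' @export
build_model <- function(arch = rpanet_arch(), input_channels = 3L, seed = 1L) {
  stopifnot(inherits(arch, "rpanet_arch"))
  w <- arch$stage_widths
  cins <- c(as.integer(input_channels), w[-5L])
  params <- .with_seed(seed, {
    stages <- vector("list", 5L)
    for (i in 1:5) {
      stages[[i]] <- unclass(rpa_init(
        cins[i], w[i], k = arch$spatial_kernel, t = arch$temporal_kernel,
        r = arch$reduction_ratio,
        sw_bypass_threshold = arch$sw_bypass_threshold,
        attention = arch$attention))
    }
    list(stages = stages,
         head = list(W = .init_mat(w[5L], arch$n_classes, w[5L]),
                     b = numeric(arch$n_classes)))
  })
  structure(list(arch = arch, params = params,
                 input_channels = as.integer(input_channels),
                 seed = as.integer(seed)),
            class = "rpanet_model")
}

# Forward pass on a (B, T, H, W, C) array.  Returns logits and, when
# keep = TRUE, the caches needed for backpropagation plus the activation of
# the network's last convolution (second conv of stage 5's residual block).
.model_fwd <- function(model, x, keep = FALSE) {
  d <- dim(x)
  if (length(d) != 5L || d[5] != model$input_channels)
    stop("input must be a 5-D (batch, time, height, width, channel) array with ",
         model$input_channels, " channels")
  if (d[3] < 16L || d[4] < 16L)
    stop("input height and width must be at least 16 to survive 4 halvings")
  X <- .as_mat(x)
  dims <- d[1:4]
  caches <- vector("list", 9L)
  dim_trace <- vector("list", 9L)
  tap <- NULL; tap_dims <- NULL
  for (i in 1:5) {
    dim_trace[[2 * i - 1]] <- dims
    st <- .rpa_fwd(X, dims, model$params$stages[[i]])
    if (i == 5L) { tap <- st$conv2_out; tap_dims <- dims }
    caches[[2 * i - 1]] <- if (keep) st$cache else NULL
    X <- st$y
    if (i < 5L) {
      dim_trace[[2 * i]] <- dims
      pl <- .pool_fwd(X, dims)
      caches[[2 * i]] <- if (keep) pl$cache else NULL
      X <- pl$y
      dims <- pl$dims
    }
  }
  gp <- .gap_fwd(X, dims)
  logits <- sweep(gp$y %*% model$params$head$W, 2L, model$params$head$b, "+")
  out <- list(logits = logits)
  if (keep) {
    out$caches <- caches
    out$dim_trace <- dim_trace
    out$gap <- gp
    out$pooled <- gp$y
    out$tap <- tap
    out$tap_dims <- tap_dims
    out$in_dims <- d
  }
  out
}

# Backward pass from dlogits.  Returns the parameter-gradient tree and,
# on request, the gradient w.r.t. the input volume (optionally with the
# guided-backpropagation ReLU rule) and the gradient at the last
# convolution's output (for Grad-CAM).
.model_bwd <- function(model, fwd, dlogits, guided = FALSE) {
  grads <- list(stages = vector("list", 5L), head = NULL)
  grads$head <- list(W = crossprod(fwd$pooled, dlogits),
                     b = colSums(dlogits))
  dX <- tcrossprod(dlogits, model$params$head$W)
  dX <- .gap_bwd(dX, fwd$gap$cache)
  dtap <- NULL
  for (i in 5:1) {
    if (i < 5L) {
      cin <- ncol(dX)
      dX <- .pool_bwd(dX, fwd$caches[[2 * i]], cin)
    }
    bb <- .rpa_bwd(dX, fwd$caches[[2 * i - 1]],
                   model$params$stages[[i]], guided)
    if (i == 5L) dtap <- bb$dtap
    dX <- bb$dx
    grads$stages[[i]] <- bb$grads
  }
  list(grads = grads, dinput = dX, dtap = dtap)
}

#' Run the network forward
#'
#' @param model an `rpanet_model`.
#' @param x a 5-D input volume (batch, time, height, width, channels) or a
#'   single segment's 4-D stack (time, height, width, channels).
#' @return a `batch x n_classes` matrix of raw logits.
#' @export
model_logits <- function(model, x) {
  if (length(dim(x)) == 4L) dim(x) <- c(1L, dim(x))
  .model_fwd(model, x)$logits
}

#' Count trainable parameters of a model
#'
#' @param model an `rpanet_model`.
#' @param bias include bias/offset vectors (default `TRUE`).
#' @return total number of trainable scalar parameters.
#' @export
n_params <- function(model, bias = TRUE) {
  leaves <- .tree_flatten(model$params)
  if (!bias) {
    drop <- grepl("\\.(bs|bt|b|b1|b2|beta)$", names(leaves))
    leaves <- leaves[!drop]
  }
  sum(vapply(leaves, length, integer(1)))
}

# Closed-form parameter count (independent of the stored arrays); used to
# audit the architecture.
.n_params_formula <- function(arch, input_channels = 3L, bias = TRUE) {
  k <- arch$spatial_kernel; tk <- arch$temporal_kernel
  w <- arch$stage_widths
  cins <- c(as.integer(input_channels), w[-5L])
  conv_n <- function(ci, co) {
    m <- mid_channels(ci, co, k, tk)
    n <- k^2 * ci * m + tk * m * co
    if (bias) n <- n + m + co
    n
  }
  total <- 0
  for (i in 1:5) {
    ci <- cins[i]; co <- w[i]
    total <- total + conv_n(ci, co) + conv_n(co, co) +  # two (2+1)D convs
      (if (bias) 4 else 2) * co                         # layer-norm scale (+offset)
    if (ci != co) total <- total + ci * co              # projection skip
    if (arch$attention) {
      mid <- max(1L, co %/% arch$reduction_ratio)
      total <- total + co * mid + mid * co + co         # cSE + sSE weights
      if (bias) total <- total + mid + co + 1
    }
  }
  total <- total + w[5L] * arch$n_classes
  if (bias) total <- total + arch$n_classes
  as.integer(total)
}

#' Count trainable layers of a model
#'
#' Audits the architecture: five RPA stages, four downsample stages (which
#' carry no weights) and one classification head.
#'
#' @param model an `rpanet_model`.
#' @return a named integer vector with components `rpa`, `downsample`,
#'   `head`.
#' @export
layer_counts <- function(model) {
  c(rpa = length(model$params$stages),
    downsample = model$arch$n_downsample,
    head = 1L)
}

#' Save / load a model checkpoint
#'
#' The weights are stored in R's native serialization format; the
#' architecture is additionally written to a sidecar JSON file so a
#' checkpoint is self-describing.
#'
#' @param model an `rpanet_model`.
#' @param path checkpoint file path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rpanet_model"))
  saveRDS(model, path)
  json <- jsonlite::toJSON(unclass(model$arch), auto_unbox = TRUE, digits = NA)
  writeLines(json, paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "rpanet_model"))
  model
}

#' @export
print.rpanet_model <- function(x, ...) {
  cat("3D RPA network (", if (x$arch$attention) "with" else "without",
      " P-scSE3D)\n", sep = "")
  cat("  stage widths:", paste(x$arch$stage_widths, collapse = "-"), "\n")
  cat("  kernels: spatial", x$arch$spatial_kernel,
      "x", x$arch$spatial_kernel,
      ", temporal", x$arch$temporal_kernel, "\n")
  cat("  parameters:", format(n_params(x), big.mark = ","), "\n")
  invisible(x)
}
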