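# Network building blocks: (2+1)D convolution, residual block, cSE3D /
# sSE3D / P-scSE3D attention, RPA block, downsampling.
#
# User-facing operations take a 5-D feature volume (batch, time, height,
# width, channels) plus a parameter object created by the matching *_init()
# function, and return a feature volume of the same spatiotemporal extent.

.check_volume <- function(x) {
  if (!is.array(x) || length(dim(x)) != 5L)
    stop("a feature volume must be a 5-D array (batch, time, height, width, channels)")
  if (any(dim(x) < 1L)) stop("all feature-volume axes must have length >= 1")
  if (!all(is.finite(x))) stop("feature volume contains non-finite values")
  invisible(x)
}

.init_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Parameter-matched middle width for a (2+1)D convolution
#'
#' The factorization of a `t x k x k` 3-D convolution into a spatial
#' `1 x k x k` convolution (to `M` channels) and a temporal `t x 1 x 1`
#' convolution chooses `M` so that the factorized weight count
#' `k^2 C_in M + t M C_out` stays at or below the full 3-D count
#' `t k^2 C_in C_out`.
#'
#' @param c_in,c_out input and output channel counts.
#' @param k odd spatial kernel size.
#' @param t odd temporal kernel size.
#' @return a positive integer middle width.
#' @export
mid_channels <- function(c_in, c_out, k = 3L, t = 3L) {
  max(1L, as.integer(floor(t * k^2 * c_in * c_out / (k^2 * c_in + t * c_out))))
}

#' Initialize a (2+1)D convolution
#'
#' Weights use variance-scaling (fan-in) normal initialization; draws come
#' from the current RNG unless `seed` is given.
#'
#' @param c_in,c_out input/output channel counts.
#' @param k,t odd spatial/temporal kernel sizes.
#' @param m middle channel count; default [mid_channels()].
#' @param seed optional integer seed.
#' @return a parameter object of class `conv2plus1d_params`.
#' @export
conv2plus1d_init <- function(c_in, c_out, k = 3L, t = 3L, m = NULL, seed = NULL) {
  if (c_in < 1 || c_out < 1) stop("channel counts must be positive")
  if (k < 1 || t < 1 || k %% 2 == 0 || t %% 2 == 0)
    stop("kernel sizes must be odd positive integers")
  if (is.null(m)) m <- mid_channels(c_in, c_out, k, t)
  p <- .with_seed(seed, list(
    Ws = .init_mat(k * k * c_in, m, k * k * c_in),
    bs = numeric(m),
    Wt = .init_mat(t * m, c_out, t * m),
    bt = numeric(c_out)
  ))
  # layer metadata lives in attributes so the list itself is a pure
  # numeric parameter tree (aligned with gradient / optimizer-state trees)
  attr(p, "k") <- as.integer(k); attr(p, "t") <- as.integer(t)
  attr(p, "c_in") <- as.integer(c_in); attr(p, "c_out") <- as.integer(c_out)
  attr(p, "m") <- as.integer(m)
  class(p) <- "conv2plus1d_params"
  p
}

.conv21_fwd <- function(X, dims, p) {
  sp <- .conv_sp_fwd(X, dims, p$Ws, p$bs, attr(p, "k"))
  tm <- .conv_tm_fwd(sp$y, dims, p$Wt, p$bt, attr(p, "t"))
  list(y = tm$y, cache = list(sp = sp$cache, tm = tm$cache))
}

.conv21_bwd <- function(dY, cache, p) {
  bt <- .conv_tm_bwd(dY, cache$tm, p$Wt)
  bs <- .conv_sp_bwd(bt$dx, cache$sp, p$Ws)
  list(dx = bs$dx,
       grads = list(Ws = bs$dW, bs = bs$db, Wt = bt$dW, bt = bt$db))
}

#' (2+1)D factorized convolution
#'
#' Applies a `1 x k x k` spatial convolution followed by a `t x 1 x 1`
#' temporal convolution, both with "same" padding, so the spatiotemporal
#' extent of the volume is preserved.
#'
#' @param x a 5-D feature volume.
#' @param params parameters from [conv2plus1d_init()].
#' @return a feature volume with `c_out` channels.
#' @export
conv2plus1d <- function(x, params) {
  .check_volume(x)
  d <- dim(x)
  k <- attr(params, "k"); tk <- attr(params, "t")
  if (d[5] != attr(params, "c_in"))
    stop("input channel count does not match parameters")
  if (k > 2 * d[3] - 1 || k > 2 * d[4] - 1 || tk > 2 * d[2] - 1)
    stop("kernel larger than the zero-padded input")
  out <- .conv21_fwd(.as_mat(x), d[1:4], params)
  .as_vol(out$y, d[1:4])
}

#' Count trainable weights of a (2+1)D convolution
#'
#' @param params parameters from [conv2plus1d_init()].
#' @param bias include bias terms (default `FALSE`, weights only).
#' @return integer parameter count; equals `k^2 c_in m + t m c_out` when
#'   `bias = FALSE`.
#' @export
conv2plus1d_n_params <- function(params, bias = FALSE) {
  n <- length(params$Ws) + length(params$Wt)
  if (bias) n <- n + length(params$bs) + length(params$bt)
  as.integer(n)
}

#' Weight count of the equivalent full 3-D convolution
#'
#' @param c_in,c_out channel counts.
#' @param k,t kernel sizes.
#' @return `t * k^2 * c_in * c_out`.
#' @export
conv3d_n_params <- function(c_in, c_out, k = 3L, t = 3L) {
  as.integer(t * k^2 * c_in * c_out)
}

# ---- Residual block -------------------------------------------------------

#' Initialize a residual block
#'
#' Two (2+1)D convolutions, each followed by layer normalization over the
#' channel axis, with a ReLU between them and an identity (or projected,
#' when `c_in != c_out`) skip connection added to the output.
#'
#' @inheritParams conv2plus1d_init
#' @return a parameter object of class `residual_params`.
#' @export
residual_init <- function(c_in, c_out, k = 3L, t = 3L, seed = NULL) {
  .with_seed(seed, {
    p <- list(
      conv1 = conv2plus1d_init(c_in, c_out, k, t),
      ln1 = list(gamma = rep(1, c_out), beta = numeric(c_out)),
      conv2 = conv2plus1d_init(c_out, c_out, k, t),
      ln2 = list(gamma = rep(1, c_out), beta = numeric(c_out)),
      proj = if (c_in != c_out) .init_mat(c_in, c_out, c_in) else NULL
    )
    attr(p, "c_in") <- as.integer(c_in); attr(p, "c_out") <- as.integer(c_out)
    class(p) <- "residual_params"
    p
  })
}

.res_fwd <- function(X, dims, p) {
  c1 <- .conv21_fwd(X, dims, p$conv1)
  l1 <- .ln_fwd(c1$y, p$ln1$gamma, p$ln1$beta, B = dims[1])
  r1 <- .relu_fwd(l1$y)
  c2 <- .conv21_fwd(r1$y, dims, p$conv2)
  l2 <- .ln_fwd(c2$y, p$ln2$gamma, p$ln2$beta, B = dims[1])
  skip <- if (is.null(p$proj)) X else X %*% p$proj
  list(y = l2$y + skip, conv2_out = c2$y,
       cache = list(X = X, c1 = c1$cache, l1 = l1$cache, r1 = r1$cache,
                    c2 = c2$cache, l2 = l2$cache))
}

# Returns the gradient at the second convolution's output in `dtap`
# (used by Grad-CAM when this is the network's last convolution).
.res_bwd <- function(dY, cache, p, guided = FALSE) {
  bl2 <- .ln_bwd(dY, cache$l2, p$ln2$gamma)
  dtap <- bl2$dx
  bc2 <- .conv21_bwd(dtap, cache$c2, p$conv2)
  dr1 <- .relu_bwd(bc2$dx, cache$r1, guided)
  bl1 <- .ln_bwd(dr1, cache$l1, p$ln1$gamma)
  bc1 <- .conv21_bwd(bl1$dx, cache$c1, p$conv1)
  dX <- bc1$dx
  grads <- list(conv1 = bc1$grads,
                ln1 = list(gamma = bl1$dgamma, beta = bl1$dbeta),
                conv2 = bc2$grads,
                ln2 = list(gamma = bl2$dgamma, beta = bl2$dbeta),
                proj = NULL)
  if (is.null(p$proj)) {
    dX <- dX + dY
  } else {
    dX <- dX + tcrossprod(dY, p$proj)
    grads$proj <- crossprod(cache$X, dY)
  }
  list(dx = dX, grads = grads, dtap = dtap)
}

#' Residual block with (2+1)D convolutions
#'
#' @param x a 5-D feature volume.
#' @param params parameters from [residual_init()].
#' @return a feature volume with `c_out` channels and unchanged extent.
#' @export
residual_block <- function(x, params) {
  .check_volume(x)
  d <- dim(x)
  if (d[5] != attr(params, "c_in"))
    stop("input channel count does not match parameters")
  out <- .res_fwd(.as_mat(x), d[1:4], params)
  .as_vol(out$y, d[1:4])
}

# ---- Squeeze-and-excitation -----------------------------------------------

#' Initialize a 3-D channel squeeze-and-excitation (cSE) block
#'
#' @param c channel count of the input volume.
#' @param r reduction ratio of the excitation bottleneck; `c >= r` required.
#' @param seed optional integer seed.
#' @return a parameter object of class `cse3d_params`.
#' @export
cse3d_init <- function(c, r = 2L, seed = NULL) {
  if (c < r) stop("reduction ratio exceeds the channel count (need c >= r)")
  mid <- max(1L, c %/% r)
  p <- .with_seed(seed, list(
    W1 = .init_mat(c, mid, c), b1 = numeric(mid),
    W2 = .init_mat(mid, c, mid), b2 = numeric(c)
  ))
  attr(p, "c") <- as.integer(c); attr(p, "r") <- as.integer(r)
  class(p) <- "cse3d_params"
  p
}

#' 3-D spatial squeeze and channel excitation (cSE3D)
#'
#' Global average pooling over (time, height, width) squeezes the volume to
#' one value per channel; a two-layer bottleneck (reduction ratio `r`) with
#' a sigmoid produces per-channel gates in (0, 1) that rescale the input.
#'
#' @param x a 5-D feature volume.
#' @param params parameters from [cse3d_init()].
#' @return the recalibrated feature volume (same shape as `x`).
#' @export
cse3d <- function(x, params) {
  .check_volume(x)
  d <- dim(x)
  if (d[5] != attr(params, "c"))
    stop("input channel count does not match parameters")
  .as_vol(.cse_fwd(.as_mat(x), d[1:4], params)$y, d[1:4])
}

#' Initialize a 3-D spatial squeeze-and-excitation (sSE) block
#'
#' @param c channel count of the input volume.
#' @param seed optional integer seed.
#' @return a parameter object of class `sse3d_params`.
#' @export
sse3d_init <- function(c, seed = NULL) {
  p <- .with_seed(seed, list(w = .init_mat(c, 1L, c), b = 0))
  attr(p, "c") <- as.integer(c)
  class(p) <- "sse3d_params"
  p
}

#' 3-D channel squeeze and spatial excitation (sSE3D)
#'
#' A 1x1x1 convolution squeezes the channels to one map; a sigmoid turns it
#' into a per-position gate in (0, 1) that rescales the input.
#'
#' @param x a 5-D feature volume.
#' @param params parameters from [sse3d_init()].
#' @return the recalibrated feature volume (same shape as `x`).
#' @export
sse3d <- function(x, params) {
  .check_volume(x)
  d <- dim(x)
  if (d[5] != attr(params, "c"))
    stop("input channel count does not match parameters")
  .as_vol(.sse_fwd(.as_mat(x), params)$y, d[1:4])
}

#' Initialize a 3-D parallel spatial/channel squeeze-and-excitation block
#'
#' @param c channel count.
#' @param r cSE reduction ratio.
#' @param sw_bypass_threshold channel count below which the max-out branch
#'   is bypassed ("shorted" form).
#' @param seed optional integer seed.
#' @return a parameter object of class `p_scse3d_params`.
#' @export
p_scse3d_init <- function(c, r = 2L, sw_bypass_threshold = 32L, seed = NULL) {
  p <- .with_seed(seed, list(
    cse = cse3d_init(c, r),
    sse = sse3d_init(c)
  ))
  attr(p, "c") <- as.integer(c)
  attr(p, "sw_bypass_threshold") <- as.integer(sw_bypass_threshold)
  class(p) <- "p_scse3d_params"
  p
}

.pscse_fwd <- function(X, dims, p) {
  cf <- .cse_fwd(X, dims, p$cse)
  sf <- .sse_fwd(X, p$sse)
  shorted <- attr(p, "c") < attr(p, "sw_bypass_threshold")
  if (shorted) {
    y <- cf$y + sf$y
    sel <- NULL
  } else {
    sel <- cf$y >= sf$y
    y <- pmax(cf$y, sf$y) + cf$y + sf$y
  }
  list(y = y, cache = list(cf = cf$cache, sf = sf$cache, sel = sel,
                           shorted = shorted))
}

.pscse_bwd <- function(dY, cache, p, guided = FALSE) {
  if (cache$shorted) {
    dc <- dY
    ds <- dY
  } else {
    dc <- dY * (1 + cache$sel)
    ds <- dY * (2 - cache$sel)
  }
  bc <- .cse_bwd(dc, cache$cf, p$cse, guided)
  bs <- .sse_bwd(ds, cache$sf, p$sse)
  list(dx = bc$dx + bs$dx,
       grads = list(cse = list(W1 = bc$dW1, b1 = bc$db1,
                               W2 = bc$dW2, b2 = bc$db2),
                    sse = list(w = bs$dw, b = bs$db)))
}

#' 3-D parallel spatial and channel squeeze-and-excitation (P-scSE3D)
#'
#' Computes `c = cSE(x)` and `s = sSE(x)` and combines them through two
#' parallel branches — a max-out branch `max(c, s)` and an additive branch
#' `c + s` — whose outputs are added.  When the channel count is below
#' `sw_bypass_threshold` the max-out branch is bypassed (the "shorted"
#' form), giving `c + s` only.
#'
#' @param x a 5-D feature volume.
#' @param params parameters from [p_scse3d_init()].
#' @return a feature volume of the same shape as `x`.
#' @export
p_scse3d <- function(x, params) {
  .check_volume(x)
  d <- dim(x)
  if (d[5] != attr(params, "c"))
    stop("input channel count does not match parameters")
  .as_vol(.pscse_fwd(.as_mat(x), d[1:4], params)$y, d[1:4])
}

# ---- RPA block ------------------------------------------------------------

#' Initialize a residual-with-parallel-attention (RPA) block
#'
#' An RPA block is a residual block followed by P-scSE3D attention.
#'
#' @inheritParams residual_init
#' @param r cSE reduction ratio.
#' @param sw_bypass_threshold shorted-switch channel threshold.
#' @param attention include the P-scSE3D stage (set `FALSE` for the
#'   attention-ablated network).
#' @return a parameter object of class `rpa_params`.
#' @export
rpa_init <- function(c_in, c_out, k = 3L, t = 3L, r = 2L,
                     sw_bypass_threshold = 32L, attention = TRUE,
                     seed = NULL) {
  .with_seed(seed, {
    p <- list(
      res = residual_init(c_in, c_out, k, t),
      scse = if (attention)
        p_scse3d_init(c_out, r, sw_bypass_threshold) else NULL
    )
    attr(p, "c_in") <- as.integer(c_in); attr(p, "c_out") <- as.integer(c_out)
    class(p) <- "rpa_params"
    p
  })
}

.rpa_fwd <- function(X, dims, p) {
  rf <- .res_fwd(X, dims, p$res)
  if (is.null(p$scse)) {
    list(y = rf$y, conv2_out = rf$conv2_out,
         cache = list(res = rf$cache, scse = NULL))
  } else {
    af <- .pscse_fwd(rf$y, dims, p$scse)
    list(y = af$y, conv2_out = rf$conv2_out,
         cache = list(res = rf$cache, scse = af$cache))
  }
}

.rpa_bwd <- function(dY, cache, p, guided = FALSE) {
  grads <- list(res = NULL, scse = NULL)
  if (!is.null(cache$scse)) {
    ba <- .pscse_bwd(dY, cache$scse, p$scse, guided)
    dY <- ba$dx
    grads$scse <- ba$grads
  }
  br <- .res_bwd(dY, cache$res, p$res, guided)
  grads$res <- br$grads
  list(dx = br$dx, grads = grads, dtap = br$dtap)
}

#' Residual-with-parallel-attention (RPA) block
#'
#' Equivalent to `p_scse3d(residual_block(x))`.
#'
#' @param x a 5-D feature volume.
#' @param params parameters from [rpa_init()].
#' @return a feature volume with `c_out` channels.
#' @export
rpa_block <- function(x, params) {
  .check_volume(x)
  d <- dim(x)
  if (d[5] != attr(params, "c_in"))
    stop("input channel count does not match parameters")
  .as_vol(.rpa_fwd(.as_mat(x), d[1:4], params)$y, d[1:4])
}

# ---- Downsampling ---------------------------------------------------------

#' Downsample a feature volume
#'
#' Max pooling with kernel and stride 2 along height and width (ceiling
#' sizes), and along time when the temporal extent is at least 2; a
#' singleton temporal axis is left unchanged.  Channels are unchanged.
#'
#' @param x a 5-D feature volume with height and width at least 2.
#' @return the pooled feature volume.
#' @export
downsample <- function(x) {
  .check_volume(x)
  d <- dim(x)
  if (d[3] < 2 || d[4] < 2) stop("height and width must be at least 2")
  out <- .pool_fwd(.as_mat(x), d[1:4])
  .as_vol(out$y, out$dims)
}
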