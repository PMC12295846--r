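# Guided Grad-CAM saliency for the 3D network: class-gradient-weighted
# activation maps from the last convolution, guided backpropagation, their
# combination, and frame-wise overlay rendering.

.target_int <- function(target_class) {
  target_class <- match.arg(target_class, c("upper", "lower"))
  if (target_class == "upper") 1L else 2L
}

.segment_array <- function(segment) {
  if (inherits(segment, "video_segment")) segment$data else segment
}

# Linear-interpolation matrix mapping a length n_in axis to length n_out
# (half-pixel centers, clamped at the borders).
.interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1L) { A[, 1] <- 1; return(A) }
  src <- pmin(pmax(((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5, 0),
              n_in - 1)
  lo <- pmin(floor(src), n_in - 2)
  w <- src - lo
  A[cbind(seq_len(n_out), lo + 1)] <- 1 - w
  A[cbind(seq_len(n_out), lo + 2)] <- A[cbind(seq_len(n_out), lo + 2)] + w
  A
}

# Trilinear upsampling of a (T, H, W) volume to out_dims.
.upsample3 <- function(v, out_dims) {
  d <- dim(v)
  for (ax in 1:3) {
    if (d[ax] == out_dims[ax]) next
    A <- .interp_matrix(out_dims[ax], d[ax])
    perm <- c(ax, setdiff(1:3, ax))
    vp <- aperm(v, perm)
    dp <- dim(vp)
    m <- A %*% matrix(vp, dp[1], dp[2] * dp[3])
    v <- aperm(array(m, c(out_dims[ax], dp[2], dp[3])), order(perm))
    d <- dim(v)
  }
  v
}

.new_heatmap <- function(values, target_class, source_id) {
  mx <- max(values)
  if (mx > 0) values <- values / mx
  structure(list(values = values, target_class = target_class,
                 source_id = source_id),
            class = "rpanet_heatmap")
}

#' @export
print.rpanet_heatmap <- function(x, ...) {
  d <- dim(x$values)
  cat("saliency heatmap for class '", x$target_class, "' (",
      paste(d, collapse = " x "), "), max ", round(max(x$values), 3),
      "\n", sep = "")
  invisible(x)
}

#' 3D Grad-CAM
#'
#' Computes the gradient of the target class logit with respect to the
#' feature maps of the network's last convolution (the second (2+1)D
#' convolution of the fifth RPA stage), averages the gradients over
#' (time, height, width) to obtain per-channel weights, and rectifies the
#' weighted sum of activation maps.  The map is trilinearly upsampled to
#' the segment's frame grid and normalized to maximum 1.
#'
#' @param model a trained `rpanet_model`.
#' @param segment a `video_segment` or an `N x H x W x 3` array.
#' @param target_class `"upper"` or `"lower"`.
#' @return an `rpanet_heatmap` with nonnegative `values` of shape
#'   `N x H x W`; all-zero (with a warning) when the class gradient
#'   vanishes everywhere.
#' @export
grad_cam_3d <- function(model, segment, target_class = "upper") {
  ti <- .target_int(target_class)
  x <- .segment_array(segment)
  d <- dim(x)
  dim(x) <- c(1L, d)
  fwd <- .model_fwd(model, x, keep = TRUE)
  dlogits <- matrix(0, 1, model$arch$n_classes)
  dlogits[1, ti] <- 1
  bwd <- .model_bwd(model, fwd, dlogits)
  wts <- colMeans(bwd$dtap)                   # channel weights
  map <- pmax(as.vector(fwd$tap %*% wts), 0)  # ReLU of weighted sum
  vol <- array(map, fwd$tap_dims[2:4])        # batch of 1: (T', H', W')
  if (all(vol == 0)) warning("class gradient vanishes; heatmap is all zero")
  up <- .upsample3(vol, d[1:3])
  .new_heatmap(up, target_class,
               if (inherits(segment, "video_segment")) segment$source_id
               else "array")
}

#' Guided backpropagation
#'
#' Gradient of the target class logit with respect to the input volume,
#' where every ReLU backward pass additionally zeroes negative incoming
#' gradients (on top of the standard forward mask).
#'
#' @inheritParams grad_cam_3d
#' @return a signed `N x H x W x 3` gradient array.
#' @export
guided_backprop <- function(model, segment, target_class = "upper") {
  ti <- .target_int(target_class)
  x <- .segment_array(segment)
  d <- dim(x)
  dim(x) <- c(1L, d)
  fwd <- .model_fwd(model, x, keep = TRUE)
  dlogits <- matrix(0, 1, model$arch$n_classes)
  dlogits[1, ti] <- 1
  bwd <- .model_bwd(model, fwd, dlogits, guided = TRUE)
  array(bwd$dinput, d)
}

#' Guided Grad-CAM
#'
#' Elementwise product of the upsampled Grad-CAM map with the absolute
#' guided-backpropagation volume (averaged over color channels),
#' max-normalized.
#'
#' @inheritParams grad_cam_3d
#' @return an `rpanet_heatmap` with `values` of shape `N x H x W`.
#' @export
guided_grad_cam <- function(model, segment, target_class = "upper") {
  cam <- suppressWarnings(grad_cam_3d(model, segment, target_class))
  gbp <- guided_backprop(model, segment, target_class)
  g <- apply(abs(gbp), 1:3, mean)
  .new_heatmap(cam$values * g, target_class, cam$source_id)
}

#' Fraction of saliency mass inside a spatial mask
#'
#' @param heatmap an `rpanet_heatmap`.
#' @param mask an `H x W` logical matrix (e.g. from [disc_mask()]).
#' @return the fraction of total heatmap mass (summed over frames) whose
#'   pixels fall inside `mask`; `NA` for an all-zero heatmap.
#' @export
saliency_mass <- function(heatmap, mask) {
  v <- heatmap$values
  tot <- sum(v)
  if (tot == 0) return(NA_real_)
  per_pixel <- apply(v, 2:3, sum)
  sum(per_pixel[mask]) / tot
}

#' Render heatmap overlays on a segment's frames
#'
#' Blends a color-mapped heatmap over each frame at a fixed alpha and
#' writes one PNG per frame.
#'
#' @param heatmap an `rpanet_heatmap`.
#' @param segment the source `video_segment` (or `N x H x W x 3` array).
#' @param dir output directory.
#' @param alpha blend weight of the heatmap layer in `[0, 1]`.
#' @param palette color ramp used for the heatmap.
#' @return character vector of written file paths.
#' @export
overlay <- function(heatmap, segment, dir, alpha = 0.5,
                    palette = c("black", "darkred", "red", "yellow")) {
  x <- .segment_array(segment)
  d <- dim(x)
  stopifnot(all(dim(heatmap$values) == d[1:3]))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ramp <- grDevices::colorRamp(palette)
  paths <- character(d[1])
  for (i in seq_len(d[1])) {
    h <- heatmap$values[i, , ]
    hm_rgb <- ramp(as.vector(h)) / 255
    out <- array(0, c(d[2], d[3], 3L))
    for (ch in 1:3)
      out[, , ch] <- (1 - alpha) * x[i, , , ch] +
        alpha * matrix(hm_rgb[, ch], d[2], d[3])
    paths[i] <- file.path(dir, sprintf("frame_%03d.png", i))
    png::writePNG(pmin(pmax(out, 0), 1), paths[i])
  }
  paths
}

#' Hand-constructed opponent-color reference network
#'
#' Builds a network whose classification provably relies on local
#' red-green color contrast: stage 1 holds a rectified `R - G` channel
#' (and its negation), later stages are center-tap identity maps, the
#' attention gates are constant, and the head reads the two opponent
#' channels.  On a corpus whose class signal is an opponent color shift
#' confined to a known disc ([planted_signal_corpus()]), this model's
#' class evidence occupies exactly that disc, which makes it a ground
#' truth for validating saliency localization.
#'
#' @param arch an [rpanet_arch()]; any stage widths of at least 2 work.
#' @param input_channels input channel count (3 for RGB).
#' @return an `rpanet_model` with deterministic, hand-set weights.
#' @export
opponent_color_model <- function(arch = rpanet_arch(stage_widths = c(4, 4, 8, 8, 16)),
                                 input_channels = 3L) {
  if (any(arch$stage_widths < 2L)) stop("stage widths must be at least 2")
  m <- build_model(arch, input_channels, seed = 1L)
  m$params <- .tree_map(m$params, function(x) x * 0)
  k <- arch$spatial_kernel; tk <- arch$temporal_kernel
  ctr_sp <- (k * k + 1L) %/% 2L   # center offset of the (dh, dw) grid
  ctr_tm <- (tk + 1L) %/% 2L
  for (i in 1:5) {
    st <- m$params$stages[[i]]
    cin1 <- attr(st$res$conv1, "c_in"); m1 <- attr(st$res$conv1, "m")
    if (i == 1L) {
      st$res$conv1$Ws[(ctr_sp - 1L) * cin1 + 1L, 1L] <- 1   # + red
      st$res$conv1$Ws[(ctr_sp - 1L) * cin1 + 2L, 1L] <- -1  # - green
      st$res$conv1$Ws[(ctr_sp - 1L) * cin1 + 1L, 2L] <- -1
      st$res$conv1$Ws[(ctr_sp - 1L) * cin1 + 2L, 2L] <- 1
    } else {
      for (c in 1:2) st$res$conv1$Ws[(ctr_sp - 1L) * cin1 + c, c] <- 1
    }
    for (c in 1:2) st$res$conv1$Wt[(ctr_tm - 1L) * m1 + c, c] <- 1
    cin2 <- attr(st$res$conv2, "c_in"); m2 <- attr(st$res$conv2, "m")
    for (c in 1:2) {
      st$res$conv2$Ws[(ctr_sp - 1L) * cin2 + c, c] <- 1
      st$res$conv2$Wt[(ctr_tm - 1L) * m2 + c, c] <- 1
    }
    st$res$ln1$gamma[] <- 1
    st$res$ln2$gamma[] <- 1
    m$params$stages[[i]] <- st
  }
  m$params$head$W[1L, 1L] <- 1   # upper reads the R-G channel
  m$params$head$W[2L, 2L] <- 1   # lower reads the G-R channel
  m
}
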