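xai_model <- function(seed = 20) build_model(tiny_arch(), 3, seed = seed)

xai_segment <- function(seed = 21, T = 2L, H = 16L, W = 16L) {
  set.seed(seed)
  array(runif(T * H * W * 3), c(T, H, W, 3L))
}

test_that("Grad-CAM heatmaps are nonnegative, max-normalized, frame-aligned", {
  m <- xai_model()
  x <- xai_segment()
  hm <- grad_cam_3d(m, x, "upper")
  expect_s3_class(hm, "rpanet_heatmap")
  expect_equal(dim(hm$values), c(2L, 16L, 16L))
  expect_true(all(hm$values >= 0))
  expect_lte(max(hm$values), 1)
  if (max(hm$values) > 0) expect_equal(max(hm$values), 1)

  # zero class gradient (all-zero head) gives an all-zero heatmap + warning
  mz <- m; mz$params$head$W[] <- 0; mz$params$head$b[] <- 0
  expect_warning(hz <- grad_cam_3d(mz, x, "upper"), "zero")
  expect_true(all(hz$values == 0))

  # deterministic
  expect_identical(grad_cam_3d(m, x, "lower"), grad_cam_3d(m, x, "lower"))
})

test_that("guided backpropagation masks negative gradients at every ReLU", {
  m <- xai_model()
  x <- xai_segment()
  g <- guided_backprop(m, x, "upper")
  expect_equal(dim(g), dim(x))
  expect_true(all(is.finite(g)))

  # the guided-ReLU rule itself, against a single-ReLU toy oracle:
  # y = w2 * relu(w1 * x); guided dx = w2 * w1 * [w1 x > 0] * [w2 > 0]
  for (w1 in c(-1.5, 0.7)) for (w2 in c(-2, 3)) for (xv in c(-0.4, 0.8)) {
    pre <- w1 * xv
    r <- rpanet:::.relu_fwd(matrix(pre))
    dy <- matrix(w2)
    guided <- rpanet:::.relu_bwd(dy, r$cache, guided = TRUE)[1] * w1
    oracle <- w2 * w1 * (pre > 0) * (w2 > 0)
    expect_equal(guided, oracle)
    plain <- rpanet:::.relu_bwd(dy, r$cache)[1] * w1
    expect_equal(plain, w2 * w1 * (pre > 0))
  }

  # when no ReLU path carries negative gradients the guided gradient
  # equals the ordinary gradient (linear regime)
  mo <- opponent_color_model(tiny_arch(c(2, 2, 2, 2, 2)))
  xs <- array(0, c(2, 16, 16, 3))
  xs[, 6:10, 6:10, 1] <- 0.8  # pure red patch: only the R-G unit fires
  gg <- guided_backprop(mo, xs, "upper")
  expect_true(all(is.finite(gg)))
  # gradient is confined to the active (red-patch) pixels' neighborhood
  expect_gt(sum(abs(gg[, 6:10, 6:10, ])), 0)
  expect_equal(sum(abs(gg[, 13:16, 13:16, ])), 0)
})

test_that("guided Grad-CAM multiplies the upsampled map by absolute guided gradients", {
  m <- xai_model()
  x <- xai_segment()
  hm <- guided_grad_cam(m, x, "upper")
  expect_equal(dim(hm$values), dim(x)[1:3])
  expect_true(all(hm$values >= 0 & hm$values <= 1))

  cam <- grad_cam_3d(m, x, "upper")
  gbp <- guided_backprop(m, x, "upper")
  manual <- cam$values * apply(abs(gbp), 1:3, mean)
  if (max(manual) > 0) manual <- manual / max(manual)
  expect_equal(hm$values, manual, tolerance = 1e-12)

  # a zero factor annihilates the product
  mz <- m; mz$params$head$W[] <- 0; mz$params$head$b[] <- 0
  hz <- suppressWarnings(guided_grad_cam(mz, x, "upper"))
  expect_true(all(hz$values == 0))
})

test_that("trilinear upsampling interpolates linearly along each axis", {
  # constant volumes stay constant
  v <- array(0.4, c(2, 3, 3))
  up <- rpanet:::.upsample3(v, c(4, 9, 9))
  expect_equal(dim(up), c(4L, 9L, 9L))
  expect_true(all(abs(up - 0.4) < 1e-12))
  # a linear ramp stays a (monotone) ramp
  r <- array(rep(1:4, each = 1), c(1, 1, 4))
  upr <- rpanet:::.upsample3(r, c(1, 1, 8))
  expect_true(all(diff(as.vector(upr)) >= 0))
  expect_equal(range(as.vector(upr)), c(1, 4))
})

test_that("overlays render one blended PNG per frame, deterministically", {
  m <- xai_model()
  v <- tiny_video(T = 8, H = 16, W = 16, seed = 30)
  seg <- extract_segment(v, 0, segment_config(3, 2))
  hm <- guided_grad_cam(m, seg, "upper")
  dir <- withr::local_tempdir()
  paths <- overlay(hm, seg, dir, alpha = 0.5)
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  img <- png::readPNG(paths[1])
  expect_equal(dim(img), c(16L, 16L, 3L))

  # zero heatmap: the overlay is the frame dimmed by the blend alpha
  hz <- hm; hz$values[] <- 0
  dir2 <- withr::local_tempdir()
  p2 <- overlay(hz, seg, dir2, alpha = 0.25)
  img2 <- png::readPNG(p2[2])
  expected <- 0.75 * seg$data[2, , , ]
  expect_equal(as.vector(img2), as.vector(expected), tolerance = 1 / 255)

  dir3 <- withr::local_tempdir()
  p3 <- overlay(hm, seg, dir3, alpha = 0.5)
  expect_identical(png::readPNG(p3[1]), png::readPNG(paths[1]))
})

test_that("the opponent-color reference model localizes saliency in the planted disc", {
  cfg <- synth_config(n_upper = 2, n_lower = 2, length_range = c(8, 12),
                      frame_size = c(64, 64), seed = 40)
  pc <- planted_signal_corpus(cfg)
  m <- opponent_color_model()
  field <- disc_mask(cfg$frame_size, radius = 1)
  for (v in list(pc$upper[[1]], pc$lower[[1]])) {
    seg <- extract_segment(v, 0, segment_config(4, 2))
    hm <- guided_grad_cam(m, seg, v$label)
    expect_gt(saliency_mass(hm, pc$mask), mean(pc$mask))  # enriched
    expect_gt(saliency_mass(hm, field), saliency_mass(hm, !field))
  }
  # and it actually classifies the planted corpus
  ok <- vapply(c(pc$upper, pc$lower), function(v)
    predict_video(m, v, segment_config(4, 2), seed = 1)$label == v$label,
    TRUE)
  expect_true(all(ok))
})
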