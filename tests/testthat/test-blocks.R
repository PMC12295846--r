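rand_vol <- function(d, seed, lo = -1, hi = 1) {
  set.seed(seed)
  array(runif(prod(d), lo, hi), d)
}

test_that("(2+1)D convolution matches the straight-line oracle and its parameter formula", {
  x <- rand_vol(c(1, 4, 8, 8, 4), seed = 1)
  p <- conv2plus1d_init(4, 8, k = 3, t = 3, m = 6, seed = 2)
  y <- conv2plus1d(x, p)
  expect_equal(dim(y), c(1, 4, 8, 8, 8))
  expect_equal(y, o_conv2plus1d(x, p), tolerance = 1e-12)
  expect_equal(conv2plus1d_n_params(p), 3^2 * 4 * 6 + 3 * 6 * 8)  # 360
  expect_lt(conv2plus1d_n_params(p), conv3d_n_params(4, 8))       # 864

  # identity kernels: k = t = 1, unit weights pass the input through
  pid <- conv2plus1d_init(3, 3, k = 1, t = 1, m = 3, seed = 1)
  pid$Ws <- diag(3); pid$Wt <- diag(3)
  pid$bs[] <- 0; pid$bt[] <- 0
  xi <- rand_vol(c(2, 3, 4, 4, 3), seed = 3)
  expect_equal(conv2plus1d(xi, pid), xi)

  expect_error(conv2plus1d_init(0, 4), "positive")
  expect_error(conv2plus1d_init(3, 4, k = 2), "odd")
})

test_that("residual block composes conv/norm/relu/conv/norm plus (projected) skip", {
  x <- rand_vol(c(1, 3, 6, 6, 4), seed = 4)
  p <- residual_init(4, 4, seed = 5)
  expect_equal(residual_block(x, p), o_residual(x, p), tolerance = 1e-12)

  # zero branch + identity skip returns the input
  pz <- residual_init(4, 4, seed = 6)
  pz$conv1$Ws[] <- 0; pz$conv1$Wt[] <- 0; pz$conv1$bs[] <- 0; pz$conv1$bt[] <- 0
  pz$conv2$Ws[] <- 0; pz$conv2$Wt[] <- 0; pz$conv2$bs[] <- 0; pz$conv2$bt[] <- 0
  pz$ln1$gamma[] <- 0; pz$ln2$gamma[] <- 0
  expect_equal(residual_block(x, pz), x)

  # channel projection when widths differ
  pp <- residual_init(4, 8, seed = 7)
  y <- residual_block(x, pp)
  expect_equal(dim(y), c(1, 3, 6, 6, 8))
  expect_equal(y, o_residual(x, pp), tolerance = 1e-12)
})

test_that("cSE3D matches its pooling/bottleneck/sigmoid oracle and gates lie in (0,1)", {
  x <- rand_vol(c(1, 2, 4, 4, 4), seed = 8)
  p <- cse3d_init(4, r = 2, seed = 9)
  y <- cse3d(x, p)
  expect_equal(dim(y), dim(x))
  expect_equal(y, o_cse3d(x, p), tolerance = 1e-12)
  # gates strictly inside (0,1): |output| < |input| wherever input != 0
  expect_true(all(abs(y) < abs(x) | x == 0))
  expect_equal(cse3d(array(0, dim(x)), p), array(0, dim(x)))
  expect_error(cse3d_init(1, r = 2), "reduction")
})

test_that("sSE3D matches its spatial-gate oracle, including the zero-weight half gate", {
  x <- rand_vol(c(2, 2, 4, 4, 3), seed = 10)
  p <- sse3d_init(3, seed = 11)
  y <- sse3d(x, p)
  expect_equal(dim(y), dim(x))
  expect_equal(y, o_sse3d(x, p), tolerance = 1e-12)

  p0 <- sse3d_init(3, seed = 12)
  p0$w[] <- 0; p0$b <- 0
  expect_equal(sse3d(x, p0), x / 2)   # sigmoid(0) = 1/2
})

test_that("P-scSE3D combines max-out and additive branches, with the shorted switch", {
  x <- rand_vol(c(1, 2, 4, 4, 8), seed = 13)
  p <- p_scse3d_init(8, r = 2, sw_bypass_threshold = 4, seed = 14)  # full form
  expect_equal(p_scse3d(x, p), o_pscse3d(x, p), tolerance = 1e-12)

  psh <- p_scse3d_init(8, r = 2, sw_bypass_threshold = 16, seed = 14)  # shorted
  expect_equal(p_scse3d(x, psh), o_pscse3d(x, psh), tolerance = 1e-12)
  expect_equal(p_scse3d(x, psh), cse3d(x, psh$cse) + sse3d(x, psh$sse),
               tolerance = 1e-12)

  # c = s everywhere => full output is 3c (max(a,a) + 2a)
  c_out <- cse3d(x, p$cse)
  s_out <- sse3d(x, p$sse)
  manual_full <- pmax(c_out, s_out) + c_out + s_out
  expect_equal(p_scse3d(x, p), manual_full, tolerance = 1e-12)

  # full >= shorted elementwise on nonnegative inputs
  xn <- rand_vol(c(1, 2, 4, 4, 8), seed = 15, lo = 0, hi = 1)
  pf <- p_scse3d_init(8, sw_bypass_threshold = 4, seed = 16)
  ps <- pf; attr(ps, "sw_bypass_threshold") <- 16L
  expect_true(all(p_scse3d(xn, pf) >= p_scse3d(xn, ps)))
})

test_that("RPA block equals attention applied after the residual block", {
  x <- rand_vol(c(1, 2, 4, 4, 4), seed = 17)
  p <- rpa_init(4, 8, r = 2, sw_bypass_threshold = 4, seed = 18)
  y <- rpa_block(x, p)
  expect_equal(dim(y)[5], 8)
  step <- residual_block(x, p$res)
  expect_equal(y, p_scse3d(step, p$scse), tolerance = 1e-12)
  expect_equal(y, o_pscse3d(o_residual(x, p$res), p$scse), tolerance = 1e-12)
})

test_that("downsampling halves extents with ceiling sizes and preserves constants", {
  x <- rand_vol(c(1, 8, 10, 6, 4), seed = 19)
  y <- downsample(x)
  expect_equal(dim(y), c(1, 4, 5, 3, 4))

  x1 <- rand_vol(c(2, 1, 4, 4, 3), seed = 20)
  expect_equal(dim(downsample(x1)), c(2, 1, 2, 2, 3))  # singleton time kept

  xc <- array(0.7, c(1, 4, 8, 8, 2))
  expect_true(all(downsample(xc) == 0.7))

  # max pooling dominates: every output is the max of its window
  expect_true(all(downsample(x) <= max(x)))
  expect_error(downsample(rand_vol(c(1, 2, 1, 4, 2), seed = 21)), "at least 2")
})

test_that("the assembled model audits out: shapes, layer counts, parameter formula", {
  arch <- tiny_arch()
  m <- build_model(arch, 3, seed = 1)
  x <- rand_vol(c(2, 10, 16, 16, 3), seed = 22)
  lg <- model_logits(m, x)
  expect_equal(dim(lg), c(2L, 2L))
  expect_equal(layer_counts(m), c(rpa = 5L, downsample = 4L, head = 1L))
  expect_equal(n_params(m), rpanet:::.n_params_formula(arch, 3, bias = TRUE))
  expect_equal(n_params(m, bias = FALSE),
               rpanet:::.n_params_formula(arch, 3, bias = FALSE))
  # deterministic forward pass and seed-deterministic initialization
  expect_identical(model_logits(m, x), lg)
  expect_identical(build_model(arch, 3, seed = 9)$params,
                   build_model(arch, 3, seed = 9)$params)
  expect_error(model_logits(m, rand_vol(c(1, 2, 8, 8, 3), seed = 1)),
               "at least 16")
})

test_that("the factorized parameter count stays below full 3-D at every default stage", {
  arch <- rpanet_arch()  # default widths 16-32-64-128-256
  cins <- c(3L, arch$stage_widths[-5])
  for (i in 1:5) {
    ci <- cins[i]; co <- arch$stage_widths[i]
    p1 <- conv2plus1d_init(ci, co)
    p2 <- conv2plus1d_init(co, co)
    fact <- conv2plus1d_n_params(p1) + conv2plus1d_n_params(p2)
    full <- conv3d_n_params(ci, co) + conv3d_n_params(co, co)
    expect_lt(fact, full)
    m1 <- attr(p1, "m")
    expect_equal(conv2plus1d_n_params(p1), 9 * ci * m1 + 3 * m1 * co)
  }
})

test_that("model checkpoints round-trip with a JSON architecture sidecar", {
  m <- build_model(tiny_arch(), 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  js <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(js$stage_widths, tiny_arch()$stage_widths)
  x <- rand_vol(c(1, 2, 16, 16, 3), seed = 23)
  expect_identical(model_logits(m, x), model_logits(m2, x))
})
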