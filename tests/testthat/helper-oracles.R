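# Independent straight-line / brute-force oracle implementations used to
# check the vectorized network operations.  Everything here is plain
# nested loops over array coordinates, sharing no code with the package
# internals.

# brute-force frame-index enumeration for a segment
o_segment_indices <- function(T, start, N, G) {
  out <- integer(0)
  for (i in 0:(N - 1)) {
    idx <- start + i * G
    if (idx < T) out <- c(out, idx)
  }
  out
}

# (2+1)D convolution by nested loops; same weight layout as the package
# (offset-major, channel-minor rows; spatial offsets (dh, dw) with dh
# fastest; zero padding).
o_conv2plus1d <- function(x, p) {
  d <- dim(x)
  B <- d[1]; T <- d[2]; H <- d[3]; W <- d[4]; cin <- d[5]
  k <- attr(p, "k"); tk <- attr(p, "t")
  m <- attr(p, "m"); cout <- attr(p, "c_out")
  pk <- (k - 1) / 2; pt <- (tk - 1) / 2
  offs <- expand.grid(dh = -pk:pk, dw = -pk:pk)
  mid <- array(0, c(B, T, H, W, m))
  for (b in 1:B) for (t in 1:T) for (h in 1:H) for (w in 1:W) for (mm in 1:m) {
    acc <- p$bs[mm]
    for (j in seq_len(nrow(offs))) for (c in 1:cin) {
      hh <- h + offs$dh[j]; ww <- w + offs$dw[j]
      if (hh >= 1 && hh <= H && ww >= 1 && ww <= W)
        acc <- acc + x[b, t, hh, ww, c] * p$Ws[(j - 1) * cin + c, mm]
    }
    mid[b, t, h, w, mm] <- acc
  }
  out <- array(0, c(B, T, H, W, cout))
  for (b in 1:B) for (t in 1:T) for (h in 1:H) for (w in 1:W) for (co in 1:cout) {
    acc <- p$bt[co]
    for (j in 1:tk) for (mm in 1:m) {
      tt <- t + (j - 1 - pt)
      if (tt >= 1 && tt <= T)
        acc <- acc + mid[b, tt, h, w, mm] * p$Wt[(j - 1) * m + mm, co]
    }
    out[b, t, h, w, co] <- acc
  }
  out
}

# per-sample layer normalization with per-channel affine
o_layernorm <- function(x, gamma, beta, eps = 1e-3) {
  d <- dim(x)
  out <- x
  for (b in 1:d[1]) {
    v <- x[b, , , , , drop = FALSE]
    mu <- mean(v)
    sd2 <- mean((v - mu)^2)
    xhat <- (v - mu) / sqrt(sd2 + eps)
    for (c in 1:d[5]) out[b, , , , c] <- xhat[, , , , c] * gamma[c] + beta[c]
  }
  out
}

o_residual <- function(x, p) {
  z1 <- o_conv2plus1d(x, p$conv1)
  a1 <- pmax(o_layernorm(z1, p$ln1$gamma, p$ln1$beta), 0)
  z2 <- o_conv2plus1d(a1, p$conv2)
  n2 <- o_layernorm(z2, p$ln2$gamma, p$ln2$beta)
  d <- dim(n2)
  skip <- if (is.null(p$proj)) x else {
    s <- array(0, d)
    for (b in 1:d[1]) for (t in 1:d[2]) for (h in 1:d[3]) for (w in 1:d[4])
      s[b, t, h, w, ] <- as.vector(x[b, t, h, w, ] %*% p$proj)
    s
  }
  n2 + skip
}

o_cse3d <- function(x, p) {
  d <- dim(x)
  out <- x
  for (b in 1:d[1]) {
    pooled <- apply(x[b, , , , , drop = FALSE], 5, mean)
    z1 <- pmax(as.vector(pooled %*% p$W1) + p$b1, 0)
    gate <- 1 / (1 + exp(-(as.vector(z1 %*% p$W2) + p$b2)))
    for (c in 1:d[5]) out[b, , , , c] <- x[b, , , , c] * gate[c]
  }
  out
}

o_sse3d <- function(x, p) {
  d <- dim(x)
  out <- x
  for (b in 1:d[1]) for (t in 1:d[2]) for (h in 1:d[3]) for (w in 1:d[4]) {
    z <- sum(x[b, t, h, w, ] * p$w) + p$b
    out[b, t, h, w, ] <- x[b, t, h, w, ] / (1 + exp(-z))
  }
  out
}

o_pscse3d <- function(x, p) {
  cc <- o_cse3d(x, p$cse)
  ss <- o_sse3d(x, p$sse)
  if (attr(p, "c") < attr(p, "sw_bypass_threshold")) cc + ss
  else pmax(cc, ss) + cc + ss
}

# AUC as the exhaustive pairwise concordance probability (ties count 1/2)
o_auc_concordance <- function(scores, labels, positive = "upper") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exact two-sided Wilcoxon signed-rank p-value by enumerating all 2^n sign
# assignments (no-ties case)
o_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    vs[m + 1] <- sum(r[signs == 1])
  }
  ev <- n * (n + 1) / 4
  mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12)
}

# closed-form paired t statistic
o_paired_t <- function(a, b) {
  d <- a - b
  mean(d) / (sd(d) / sqrt(length(d)))
}
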