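# Internal tensor engine.
#
# A feature volume with axes (batch B, time T, height H, width W, channels C)
# is stored as a plain 5-D array; all layer arithmetic views it as the
# npos x C matrix obtained by collapsing (B, T, H, W) in column-major order
# (batch fastest).  Convolutions are im2col gathers followed by one BLAS
# matrix multiply; every layer has a matching hand-derived backward pass.

.as_mat <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 5L)
  dim(x) <- c(prod(d[1:4]), d[5])
  x
}

.as_vol <- function(m, dims) {
  dim(m) <- c(dims, ncol(m))
  m
}

# 0-based (t, h, w) coordinates for every linear position over dims (B,T,H,W)
.coords <- function(dims) {
  B <- dims[1]; T <- dims[2]; H <- dims[3]
  p <- 0:(prod(dims) - 1L)
  list(
    t = (p %/% B) %% T,
    h = (p %/% (B * T)) %% H,
    w = p %/% (B * T * H)
  )
}

# Linear source index for a (dt, dh, dw) displacement; NA where the
# displaced coordinate leaves the volume (zero padding).
.offset_idx <- function(dims, dt, dh, dw, co) {
  B <- dims[1]; T <- dims[2]; H <- dims[3]; W <- dims[4]
  ok <- (co$t + dt) >= 0L & (co$t + dt) < T &
        (co$h + dh) >= 0L & (co$h + dh) < H &
        (co$w + dw) >= 0L & (co$w + dw) < W
  idx <- seq_len(prod(dims)) + (dt + (dh + dw * H) * T) * B
  idx[!ok] <- NA_integer_
  idx
}

.gather <- function(X, idx, fill = 0) {
  if (!anyNA(idx)) return(X[idx, , drop = FALSE])
  Y <- matrix(fill, nrow = length(idx), ncol = ncol(X))
  ok <- which(!is.na(idx))
  Y[ok, ] <- X[idx[ok], , drop = FALSE]
  Y
}

.add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))

# Index maps depend only on (dims, kernel); they are identical on every
# optimization step, so cache them per session.
.idx_cache <- new.env(parent = emptyenv())

.cached_idxs <- function(key, builder) {
  v <- get0(key, envir = .idx_cache, inherits = FALSE)
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = .idx_cache)
  }
  v
}

.sp_idxs <- function(dims, k) {
  .cached_idxs(paste0("sp:", paste(dims, collapse = "x"), ":", k), function() {
    p <- (k - 1L) %/% 2L
    co <- .coords(dims)
    offs <- expand.grid(dh = -p:p, dw = -p:p)
    lapply(seq_len(nrow(offs)), function(j)
      .offset_idx(dims, 0L, offs$dh[j], offs$dw[j], co))
  })
}

.tm_idxs <- function(dims, tk) {
  .cached_idxs(paste0("tm:", paste(dims, collapse = "x"), ":", tk), function() {
    p <- (tk - 1L) %/% 2L
    co <- .coords(dims)
    lapply(-p:p, function(dt) .offset_idx(dims, dt, 0L, 0L, co))
  })
}

# ---- (2+1)D convolution pieces -------------------------------------------

# Spatial 1 x k x k convolution, "same" padding.  W has k*k*C_in rows
# (offset-major, channel-minor) and M columns.
.conv_sp_fwd <- function(X, dims, W, b, k) {
  cin <- ncol(X)
  idxs <- .sp_idxs(dims, k)
  Xcol <- matrix(0, nrow(X), k * k * cin)
  for (j in seq_along(idxs)) {
    Xcol[, ((j - 1L) * cin + 1L):(j * cin)] <- .gather(X, idxs[[j]])
  }
  Y <- .add_bias(Xcol %*% W, b)
  list(y = Y, cache = list(Xcol = Xcol, idxs = idxs, cin = cin, n = nrow(X)))
}

.conv_sp_bwd <- function(dY, cache, W) {
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, W)
  cin <- cache$cin
  dX <- matrix(0, cache$n, cin)
  for (j in seq_along(cache$idxs)) {
    idx <- cache$idxs[[j]]
    cols <- ((j - 1L) * cin + 1L):(j * cin)
    if (!anyNA(idx)) {
      dX[idx, ] <- dX[idx, , drop = FALSE] + dXcol[, cols, drop = FALSE]
    } else {
      ok <- which(!is.na(idx))
      tgt <- idx[ok]
      dX[tgt, ] <- dX[tgt, , drop = FALSE] +
        dXcol[ok, cols, drop = FALSE]
    }
  }
  list(dx = dX, dW = dW, db = db)
}

# Temporal t x 1 x 1 convolution, "same" padding.  W has t*M rows.
.conv_tm_fwd <- function(X, dims, W, b, tk) {
  cin <- ncol(X)
  idxs <- .tm_idxs(dims, tk)
  Xcol <- matrix(0, nrow(X), tk * cin)
  for (j in seq_along(idxs)) {
    Xcol[, ((j - 1L) * cin + 1L):(j * cin)] <- .gather(X, idxs[[j]])
  }
  Y <- .add_bias(Xcol %*% W, b)
  list(y = Y, cache = list(Xcol = Xcol, idxs = idxs, cin = cin, n = nrow(X)))
}

.conv_tm_bwd <- .conv_sp_bwd  # same gather/scatter structure

# ---- Layer normalization ---------------------------------------------------
#
# Normalizes each sample's whole feature volume (all positions and
# channels) to zero mean / unit variance, with a learned per-channel scale
# and offset.  Per-sample statistics avoid the degenerate per-position
# case (e.g. constant-black border pixels, where a per-position inverse
# standard deviation explodes and distorts input gradients).

.ln_fwd <- function(X, gamma, beta, eps = 1e-3, B = 1L) {
  n <- nrow(X) / B
  g <- rep_len(seq_len(B), nrow(X))
  cnt <- n * ncol(X)
  mu <- rowSums(rowsum(X, g, reorder = TRUE)) / cnt
  xc <- X - mu[g]
  v <- rowSums(rowsum(xc * xc, g, reorder = TRUE)) / cnt
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv[g]
  Y <- xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
  list(y = Y, cache = list(xhat = xhat, inv = inv, g = g, cnt = cnt))
}

.ln_bwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  g <- cache$g
  dxhat <- dY * rep(gamma, each = nrow(dY))
  m1 <- rowSums(rowsum(dxhat, g, reorder = TRUE)) / cache$cnt
  m2 <- rowSums(rowsum(dxhat * xhat, g, reorder = TRUE)) / cache$cnt
  dX <- cache$inv[g] * (dxhat - m1[g] - xhat * m2[g])
  list(dx = dX, dgamma = colSums(dY * xhat), dbeta = colSums(dY))
}

# ---- Pointwise nonlinearities --------------------------------------------

.relu_fwd <- function(X) list(y = pmax(X, 0), cache = X > 0)

# guided = TRUE additionally zeroes negative incoming gradients
# (guided-backpropagation rule)
.relu_bwd <- function(dY, cache, guided = FALSE) {
  dX <- dY * cache
  if (guided) dX <- dX * (dY > 0)
  dX
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- Squeeze-and-excitation primitives -----------------------------------

# cSE: spatial squeeze (global average pool per batch element) + channel
# excitation through a bottleneck of width C/r with sigmoid gates.
.cse_fwd <- function(X, dims, p) {
  B <- dims[1]
  n <- nrow(X) / B
  g <- rep_len(seq_len(B), nrow(X))
  pooled <- rowsum(X, g, reorder = TRUE) / n
  z1 <- sweep(pooled %*% p$W1, 2L, p$b1, "+")
  a1 <- pmax(z1, 0)
  z2 <- sweep(a1 %*% p$W2, 2L, p$b2, "+")
  gate <- .sigmoid(z2)                      # B x C
  Y <- X * gate[g, , drop = FALSE]
  list(y = Y, cache = list(X = X, pooled = pooled, z1 = z1, a1 = a1,
                           gate = gate, g = g, n = n))
}

.cse_bwd <- function(dY, cache, p, guided = FALSE) {
  g <- cache$g; gate <- cache$gate
  dgate <- rowsum(dY * cache$X, g, reorder = TRUE)
  dX <- dY * gate[g, , drop = FALSE]
  dz2 <- dgate * gate * (1 - gate)
  dW2 <- crossprod(cache$a1, dz2)
  db2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, p$W2)
  dz1 <- da1 * (cache$z1 > 0)
  if (guided) dz1 <- dz1 * (da1 > 0)
  dW1 <- crossprod(cache$pooled, dz1)
  db1 <- colSums(dz1)
  dpooled <- tcrossprod(dz1, p$W1)
  dX <- dX + dpooled[g, , drop = FALSE] / cache$n
  list(dx = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# sSE: channel squeeze (1x1x1 conv to one channel) + spatial sigmoid gate.
.sse_fwd <- function(X, p) {
  z <- as.vector(X %*% p$w) + p$b
  s <- .sigmoid(z)
  list(y = X * s, cache = list(X = X, s = s))
}

.sse_bwd <- function(dY, cache, p) {
  s <- cache$s
  ds <- rowSums(dY * cache$X)
  dz <- ds * s * (1 - s)
  dX <- dY * s + tcrossprod(cbind(dz), p$w)
  list(dx = dX, dw = crossprod(cache$X, cbind(dz)), db = sum(dz))
}

# ---- Max pooling, stride 2 spatially, stride 2 temporally when T >= 2 ----

.pool_out_dims <- function(dims) {
  st <- if (dims[2] >= 2L) 2L else 1L
  c(dims[1], as.integer(ceiling(dims[2] / st)),
    as.integer(ceiling(dims[3] / 2)), as.integer(ceiling(dims[4] / 2)))
}

.pool_fwd <- function(X, dims) {
  B <- dims[1]; T <- dims[2]; H <- dims[3]; W <- dims[4]
  st <- if (T >= 2L) 2L else 1L
  odims <- .pool_out_dims(dims)
  nout <- prod(odims)
  co <- .coords(odims)
  bidx <- (0:(nout - 1L)) %% B
  cand <- expand.grid(dt = 0:(st - 1L), dh = 0:1, dw = 0:1)
  idxs <- vector("list", nrow(cand))
  Y <- matrix(-Inf, nout, ncol(X))
  Arg <- matrix(0L, nout, ncol(X))
  for (j in seq_len(nrow(cand))) {
    ti <- co$t * st + cand$dt[j]
    hi <- co$h * 2L + cand$dh[j]
    wi <- co$w * 2L + cand$dw[j]
    ok <- ti < T & hi < H & wi < W
    idx <- bidx + B * (ti + T * (hi + H * wi)) + 1L
    idx[!ok] <- NA_integer_
    idxs[[j]] <- idx
    G <- .gather(X, idx, fill = -Inf)
    upd <- G > Y
    Y[upd] <- G[upd]
    Arg[upd] <- j
  }
  list(y = Y, dims = odims,
       cache = list(idxs = idxs, Arg = Arg, nin = prod(dims)))
}

.pool_bwd <- function(dY, cache, cin) {
  dX <- matrix(0, cache$nin, cin)
  for (j in seq_along(cache$idxs)) {
    idx <- cache$idxs[[j]]
    sel <- cache$Arg == j
    rows <- which(!is.na(idx) & rowSums(sel) > 0)
    if (!length(rows)) next
    contrib <- dY[rows, , drop = FALSE] * sel[rows, , drop = FALSE]
    tgt <- idx[rows]
    dX[tgt, ] <- dX[tgt, , drop = FALSE] + contrib
  }
  dX
}

# ---- Global average pooling + dense head ---------------------------------

.gap_fwd <- function(X, dims) {
  B <- dims[1]
  n <- nrow(X) / B
  g <- rep_len(seq_len(B), nrow(X))
  list(y = rowsum(X, g, reorder = TRUE) / n, cache = list(g = g, n = n))
}

.gap_bwd <- function(dY, cache) {
  dY[cache$g, , drop = FALSE] / cache$n
}

# ---- Softmax cross-entropy on raw logits ---------------------------------

.softmax <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# labels: integer class indices in 1..K; returns mean loss and dlogits
.softmax_ce <- function(logits, labels) {
  p <- .softmax(logits)
  n <- nrow(logits)
  picked <- p[cbind(seq_len(n), labels)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- p
  dl[cbind(seq_len(n), labels)] <- dl[cbind(seq_len(n), labels)] - 1
  list(loss = loss, dlogits = dl / n, prob = p)
}

# ---- Parameter-tree helpers ----------------------------------------------

# Parameter trees are (possibly nested, possibly attribute-carrying) lists
# whose leaves are numeric arrays; NULL leaves (absent components) are
# preserved.  Maps keep the input's structure and attributes.
.tree_map <- function(x, f) {
  if (is.list(x)) {
    for (i in seq_along(x)) if (!is.null(x[[i]])) x[[i]] <- .tree_map(x[[i]], f)
    x
  } else if (is.null(x)) NULL else f(x)
}

.tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    for (i in seq_along(a)) if (!is.null(a[[i]])) a[[i]] <- .tree_map2(a[[i]], b[[i]], f)
    a
  } else if (is.null(a)) NULL else f(a, b)
}

.tree_flatten <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    nms <- names(x)
    if (is.null(nms)) nms <- rep("", length(x))
    for (i in seq_along(x)) {
      if (is.null(x[[i]])) next
      nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, .tree_flatten(x[[i]], paste0(prefix, nm, ".")))
    }
    out
  } else {
    stats::setNames(list(x), sub("\\.$", "", prefix))
  }
}

.n_leaf_values <- function(x) {
  sum(vapply(.tree_flatten(x), length, integer(1)))
}

# Adam optimizer over a parameter tree.
.adam_init <- function(params) {
  list(m = .tree_map(params, function(x) x * 0),
       v = .tree_map(params, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- .tree_map2(state$m, state$v,
                    function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  params <- .tree_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# ---- Seeding helpers ------------------------------------------------------

# Evaluate expr under a temporary RNG state seeded with `seed`; NULL seed
# uses (and advances) the ambient RNG.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash used to split one experiment seed into
#' independent per-run / per-purpose streams, so that subset sampling,
#' splitting, weight initialization and segment sampling are separately
#' reproducible.  The result is always in `[0, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param index nonnegative integer stream index.
#' @param salt optional string distinguishing purposes.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index = 0L, salt = "") {
  h <- (as.numeric(master) %% 2147483647) + 1
  mix <- function(h, v) ((h * 48271) %% 2147483647 + v) %% 2147483647
  h <- mix(h, as.numeric(index) + 1)
  if (nzchar(salt)) for (cc in utf8ToInt(salt)) h <- mix(h, cc)
  h <- mix(h, 12345)
  as.integer(h %% 2147483646)
}
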