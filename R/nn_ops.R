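# Low-level differentiable operations for the encoder-decoder network.
# Every *_forward returns list(out, cache); every *_backward consumes the
# upstream gradient and the cache and returns gradients for inputs and
# parameters. Correctness of the analytic gradients is established by
# finite-difference checks in the test suite.

# ---------------------------------------------------------------------------
# seeded RNG scope

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

glorot <- function(n_in, n_out, dims = c(n_in, n_out)) {
  lim <- sqrt(6 / (n_in + n_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# ---------------------------------------------------------------------------
# dense / linear

linear_forward <- function(x, W, b) {
  out <- x %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = out, cache = list(x = x, W = W))
}

linear_backward <- function(dout, cache) {
  list(dx = dout %*% t(cache$W),
       dW = t(cache$x) %*% dout,
       db = colSums(dout))
}

# ---------------------------------------------------------------------------
# 1-D convolution over the length axis (same padding, odd kernel width).
# x: N x Cin; W: (kw*Cin) x Cout with offset-major layout; b: Cout.

conv1d_forward <- function(x, W, b, kw) {
  stopifnot(kw %% 2L == 1L)
  n <- nrow(x); cin <- ncol(x)
  pad <- (kw - 1L) %/% 2L
  cols <- matrix(0, n, kw * cin)
  for (o in seq_len(kw)) {
    off <- o - pad - 1L            # row shift in [-pad, pad]
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    cols[ok, ((o - 1L) * cin + 1L):(o * cin)] <- x[src[ok], , drop = FALSE]
  }
  out <- sweep(cols %*% W, 2L, b, "+")
  list(out = out, cache = list(cols = cols, W = W, kw = kw, n = n,
                               cin = cin))
}

conv1d_backward <- function(dout, cache) {
  kw <- cache$kw; n <- cache$n; cin <- cache$cin
  pad <- (kw - 1L) %/% 2L
  dcols <- dout %*% t(cache$W)
  dx <- matrix(0, n, cin)
  for (o in seq_len(kw)) {
    off <- o - pad - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    dx[src[ok], ] <- dx[src[ok], ] +
      dcols[ok, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
  }
  list(dx = dx,
       dW = t(cache$cols) %*% dout,
       db = colSums(dout))
}

# ---------------------------------------------------------------------------
# 2-D convolution on an N x N x Cin array (same padding, odd square kernel).
# Implemented as a gather (im2col via a precomputed index vector, with a
# sentinel row standing for the zero padding) followed by one BLAS matmul;
# the backward scatter is a single rowsum() over the same index. Column
# layout of the unrolled matrix (and hence of W's rows) is offset-fastest
# within channel: row (c-1)*k^2 + o of W maps channel c, kernel offset o.

conv2d_index_cache <- new.env(parent = emptyenv())

conv2d_index <- function(n, k) {
  key <- paste(n, k)
  hit <- conv2d_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  idx <- integer(k * k * n * n)
  o <- 0L
  for (dj in -pad:pad) {
    for (di in -pad:pad) {
      si <- i + di; sj <- j + dj
      ok <- si >= 1L & si <= n & sj >= 1L & sj <= n
      lin <- ifelse(ok, si + (sj - 1L) * n, n * n + 1L)
      idx[(o * n * n + 1L):((o + 1L) * n * n)] <- lin
      o <- o + 1L
    }
  }
  conv2d_index_cache[[key]] <- idx
  idx
}

conv2d_forward <- function(a, W, b, k) {
  stopifnot(k %% 2L == 1L)
  n <- dim(a)[1L]; cin <- dim(a)[3L]; cout <- ncol(W)
  idx <- conv2d_index(n, k)
  amat <- rbind(matrix(a, n * n, cin), 0)    # sentinel zero row
  cols <- amat[idx, , drop = FALSE]          # (k^2 n^2) x cin
  dim(cols) <- c(n * n, k * k * cin)         # offset-fastest per channel
  out_mat <- sweep(cols %*% W, 2L, b, "+")
  list(out = array(out_mat, c(n, n, cout)),
       cache = list(cols = cols, W = W, k = k, n = n, cin = cin,
                    idx = idx))
}

conv2d_backward <- function(dout, cache) {
  n <- cache$n; cin <- cache$cin; k <- cache$k
  cout <- ncol(cache$W)
  dout_mat <- matrix(dout, n * n, cout)
  dcols <- dout_mat %*% t(cache$W)
  dim(dcols) <- c(k * k * n * n, cin)
  da_aug <- rowsum(dcols, cache$idx)          # groups sorted: 1..n^2 (+pad)
  da <- da_aug[seq_len(n * n), , drop = FALSE]
  list(da = array(da, c(n, n, cin)),
       dW = t(cache$cols) %*% dout_mat,
       db = colSums(dout_mat))
}

# ---------------------------------------------------------------------------
# layer normalization over the feature axis (per row of an N x d matrix)

layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, d = d))
}

layernorm_backward <- function(dout, cache) {
  d <- cache$d
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2L, cache$gamma, "*")
  # per-row: dx = inv_sd/d * (d*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dx <- (dxhat * d - s1 - xhat * s2) * cache$inv_sd / d
  list(dx = dx,
       dgamma = colSums(dout * xhat),
       dbeta = colSums(dout))
}

# ---------------------------------------------------------------------------
# normalization over spatial cells, per channel (operates on a P x C matrix
# of flattened score-map cells; the decoder's batch-normalization stage)

channelnorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  p <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  v <- colMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv_sd, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, p = p))
}

channelnorm_backward <- function(dout, cache) {
  p <- cache$p
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2L, cache$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- sweep(dxhat * p, 2L, s1, "-") - sweep(xhat, 2L, s2, "*")
  dx <- sweep(dx, 2L, cache$inv_sd / p, "*")
  list(dx = dx,
       dgamma = colSums(dout * xhat),
       dbeta = colSums(dout))
}

# ---------------------------------------------------------------------------
# scaled dot-product attention (single head)

attention_head_forward <- function(Q, K, V, scale) {
  logits <- (Q %*% t(K)) / scale
  A <- softmax_rows(logits)
  list(out = A %*% V, cache = list(Q = Q, K = K, V = V, A = A,
                                   scale = scale))
}

attention_head_backward <- function(dout, cache) {
  A <- cache$A
  dV <- t(A) %*% dout
  dA <- dout %*% t(cache$V)
  dlogits <- A * (dA - rowSums(dA * A))
  list(dQ = (dlogits %*% cache$K) / cache$scale,
       dK = (t(dlogits) %*% cache$Q) / cache$scale,
       dV = dV)
}

# ---------------------------------------------------------------------------
# parameter-tree utilities (params/grads are nested lists of arrays)

tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) {
      out[[k]] <- tree_map(f, a[[k]], if (is.null(b)) NULL else b[[k]])
    }
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

tree_zero <- function(a) tree_map(function(x) x * 0, a)

tree_add <- function(a, b) tree_map(`+`, a, b)

tree_scale <- function(a, s) tree_map(function(x) x * s, a)
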