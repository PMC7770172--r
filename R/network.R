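# The encoder-decoder network: attention blocks over per-base features,
# a pairwise feature assembly, and a three-stage 2-D convolutional decoder
# emitting the symmetric N x N base-pair score matrix S.

#' Model configuration
#'
#' @param d feature dimension (> 4; must be divisible by \code{n_heads}).
#' @param n_blocks number of identical encoder blocks (default 3).
#' @param n_heads attention heads per block.
#' @param d_ff width of the position-wise feed-forward layer (default 2d).
#' @param conv_channels channel widths of the three decoder convolution
#'   stages; the last must be 1 (the score map).
#' @param kernel odd 2-D convolution kernel size.
#' @param lift_kw odd 1-D convolution kernel width for the one-hot lift.
#' @param attention_scale \code{"sqrt_d"} (conventional, divide logits by
#'   the square root of the per-head width) or \code{"d"} (divide by the
#'   full per-head width).
#' @param max_len maximum sequence length accepted by the model.
#' @param seed RNG seed for parameter initialization.
#' @return List of class \code{model_config}.
#' @export
model_config <- function(d = 64L, n_blocks = 3L, n_heads = 4L,
                         d_ff = NULL, conv_channels = c(32L, 16L, 1L),
                         kernel = 3L, lift_kw = 3L,
                         attention_scale = c("sqrt_d", "d"),
                         max_len = 512L, seed = 42L) {
  attention_scale <- match.arg(attention_scale)
  d <- as.integer(d); n_blocks <- as.integer(n_blocks)
  n_heads <- as.integer(n_heads)
  if (d <= 4L) stop("d must exceed 4")
  if (n_blocks < 1L) stop("n_blocks must be at least 1")
  if (d %% n_heads != 0L) stop("d must be divisible by n_heads")
  if (is.null(d_ff)) d_ff <- 2L * d
  conv_channels <- as.integer(conv_channels)
  if (length(conv_channels) != 3L || conv_channels[3L] != 1L)
    stop("conv_channels must give three stages ending in 1 channel")
  structure(list(d = d, n_blocks = n_blocks, n_heads = n_heads,
                 d_ff = as.integer(d_ff), conv_channels = conv_channels,
                 kernel = as.integer(kernel), lift_kw = as.integer(lift_kw),
                 attention_scale = attention_scale,
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, unit norm gains; deterministic
#' given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{model_config}}.
#' @return Nested list of numeric arrays (the parameter tree).
#' @export
init_model_params <- function(cfg) {
  d <- cfg$d
  with_seed(cfg$seed, {
    blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
      list(
        attn = list(Wq = glorot(d, d), bq = numeric(d),
                    Wk = glorot(d, d), bk = numeric(d),
                    Wv = glorot(d, d), bv = numeric(d),
                    Wo = glorot(d, d), bo = numeric(d)),
        ln1 = list(gamma = rep(1, d), beta = numeric(d)),
        ffn = list(W1 = glorot(d, cfg$d_ff), b1 = numeric(cfg$d_ff),
                   W2 = glorot(cfg$d_ff, d), b2 = numeric(d)),
        ln2 = list(gamma = rep(1, d), beta = numeric(d))
      )
    })
    cc <- cfg$conv_channels
    k2 <- cfg$kernel^2
    list(
      lift = list(W = glorot(cfg$lift_kw * 4L, d), b = numeric(d)),
      pos  = list(W = glorot(2L, d), b = numeric(d)),
      blocks = blocks,
      dec = list(
        conv1 = list(W = glorot(k2 * 2L * d, cc[1L],
                                dims = c(k2 * 2L * d, cc[1L])),
                     b = numeric(cc[1L])),
        bn1   = list(gamma = rep(1, cc[1L]), beta = numeric(cc[1L])),
        conv2 = list(W = glorot(k2 * cc[1L], cc[2L]), b = numeric(cc[2L])),
        bn2   = list(gamma = rep(1, cc[2L]), beta = numeric(cc[2L])),
        conv3 = list(W = glorot(k2 * cc[2L], 1L, dims = c(k2 * cc[2L], 1L)),
                     b = numeric(1L))
      )
    )
  })
}

attention_scale_value <- function(cfg) {
  dh <- cfg$d / cfg$n_heads
  if (cfg$attention_scale == "sqrt_d") sqrt(dh) else dh
}

#' Scaled dot-product attention
#'
#' \code{softmax(Q K' / scale) V} with a row-wise softmax, so each output
#' position is a convex combination of the value rows; the attention weight
#' (i, j) expresses how much base j informs the representation of base i.
#'
#' @param Q,K,V N x k matrices with matching inner dimension.
#' @param scale positive scalar divisor for the logits (conventionally
#'   \code{sqrt(k)}).
#' @return N x k matrix.
#' @export
attention <- function(Q, K, V, scale = sqrt(ncol(K))) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V), scale > 0)
  attention_head_forward(Q, K, V, scale)$out
}

# --- encoder -----------------------------------------------------------

encoder_block_forward <- function(x, bp, cfg) {
  d <- cfg$d; nh <- cfg$n_heads; dh <- d %/% nh
  scale <- attention_scale_value(cfg)
  qf <- linear_forward(x, bp$attn$Wq, bp$attn$bq)
  kf <- linear_forward(x, bp$attn$Wk, bp$attn$bk)
  vf <- linear_forward(x, bp$attn$Wv, bp$attn$bv)
  ocat <- matrix(0, nrow(x), d)
  head_caches <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    hf <- attention_head_forward(qf$out[, cols, drop = FALSE],
                                 kf$out[, cols, drop = FALSE],
                                 vf$out[, cols, drop = FALSE], scale)
    ocat[, cols] <- hf$out
    head_caches[[h]] <- hf$cache
  }
  of <- linear_forward(ocat, bp$attn$Wo, bp$attn$bo)
  r1 <- x + of$out
  l1 <- layernorm_forward(r1, bp$ln1$gamma, bp$ln1$beta)
  f1 <- linear_forward(l1$out, bp$ffn$W1, bp$ffn$b1)
  a1 <- relu(f1$out)
  f2 <- linear_forward(a1, bp$ffn$W2, bp$ffn$b2)
  r2 <- l1$out + f2$out
  l2 <- layernorm_forward(r2, bp$ln2$gamma, bp$ln2$beta)
  list(out = l2$out,
       cache = list(qf = qf$cache, kf = kf$cache, vf = vf$cache,
                    heads = head_caches, of = of$cache,
                    l1 = l1$cache, f1 = f1$cache, mask = f1$out > 0,
                    f2 = f2$cache, l2 = l2$cache, dh = dh, nh = nh))
}

encoder_block_backward <- function(dout, cache) {
  l2b <- layernorm_backward(dout, cache$l2)
  dr2 <- l2b$dx
  f2b <- linear_backward(dr2, cache$f2)
  df1 <- f2b$dx * cache$mask
  f1b <- linear_backward(df1, cache$f1)
  dy <- dr2 + f1b$dx                 # residual around the feed-forward
  l1b <- layernorm_backward(dy, cache$l1)
  dr1 <- l1b$dx
  ob <- linear_backward(dr1, cache$of)
  nh <- cache$nh; dh <- cache$dh
  dQ <- dK <- dV <- matrix(0, nrow(dout), nh * dh)
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    hb <- attention_head_backward(ob$dx[, cols, drop = FALSE],
                                  cache$heads[[h]])
    dQ[, cols] <- hb$dQ; dK[, cols] <- hb$dK; dV[, cols] <- hb$dV
  }
  qb <- linear_backward(dQ, cache$qf)
  kb <- linear_backward(dK, cache$kf)
  vb <- linear_backward(dV, cache$vf)
  dx <- dr1 + qb$dx + kb$dx + vb$dx  # residual around attention
  list(dx = dx,
       grads = list(
         attn = list(Wq = qb$dW, bq = qb$db, Wk = kb$dW, bk = kb$db,
                     Wv = vb$dW, bv = vb$db, Wo = ob$dW, bo = ob$db),
         ln1 = list(gamma = l1b$dgamma, beta = l1b$dbeta),
         ffn = list(W1 = f1b$dW, b1 = f1b$db, W2 = f2b$dW, b2 = f2b$db),
         ln2 = list(gamma = l2b$dgamma, beta = l2b$dbeta)))
}

encoder_forward_cached <- function(x, blocks, cfg) {
  caches <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    bf <- encoder_block_forward(x, blocks[[b]], cfg)
    x <- bf$out
    caches[[b]] <- bf$cache
  }
  list(out = x, caches = caches)
}

encoder_backward_cached <- function(dout, caches) {
  grads <- vector("list", length(caches))
  for (b in rev(seq_along(caches))) {
    bb <- encoder_block_backward(dout, caches[[b]])
    dout <- bb$dx
    grads[[b]] <- bb$grads
  }
  list(dx = dout, grads = grads)
}

#' Run the attention encoder
#'
#' Applies \code{n_blocks} identical blocks, each consisting of multi-head
#' attention with a residual connection and layer normalization, followed
#' by a position-wise feed-forward layer with its own residual and layer
#' normalization.
#'
#' @param x N x d input encoding from \code{\link{assemble_input}}.
#' @param params model parameter tree from \code{\link{init_model_params}}
#'   (its \code{blocks} entry is used).
#' @param cfg the \code{\link{model_config}}.
#' @return N x d matrix of per-base hidden states.
#' @export
encoder_forward <- function(x, params, cfg) {
  encoder_forward_cached(x, params$blocks, cfg)$out
}

# --- pairwise assembly --------------------------------------------------

pairwise_forward <- function(H) {
  n <- nrow(H); d <- ncol(H)
  fa <- array(0, c(n, n, 2L * d))
  for (ch in seq_len(d)) {
    sym <- outer(H[, ch], H[, ch], "+") / 2
    fa[, , ch] <- sym
    fa[, , d + ch] <- sym
  }
  fa
}

pairwise_backward <- function(dfa) {
  n <- dim(dfa)[1L]; d <- dim(dfa)[3L] %/% 2L
  dH <- matrix(0, n, d)
  for (ch in seq_len(d)) {
    g <- dfa[, , ch] + dfa[, , d + ch]
    dH[, ch] <- (rowSums(g) + colSums(g)) / 2
  }
  dH
}

#' Assemble pairwise features from encoder output
#'
#' For every position pair (i, j) the feature vector is the concatenation
#' of the i-th and j-th rows of \code{hidden + projected positions},
#' averaged with its (j, i) counterpart so that features(i, j) equals
#' features(j, i) exactly.
#'
#' @param hidden N x d encoder output.
#' @param pos a \code{\link{position_embedding}} (or an N x d matrix), added
#'   to \code{hidden} before assembly; use 0 to skip.
#' @return N x N x 2d feature array.
#' @export
pairwise_assemble <- function(hidden, pos = 0) {
  proj <- if (inherits(pos, "position_embedding")) pos$projected else pos
  pairwise_forward(hidden + proj)
}

# --- decoder ------------------------------------------------------------

decoder_forward_cached <- function(fa, dp, cfg) {
  k <- cfg$kernel
  n <- dim(fa)[1L]
  c1f <- conv2d_forward(fa, dp$conv1$W, dp$conv1$b, k)
  n1f <- channelnorm_forward(matrix(c1f$out, n * n), dp$bn1$gamma,
                             dp$bn1$beta)
  a1 <- relu(n1f$out)
  c2f <- conv2d_forward(array(a1, c(n, n, cfg$conv_channels[1L])),
                        dp$conv2$W, dp$conv2$b, k)
  n2f <- channelnorm_forward(matrix(c2f$out, n * n), dp$bn2$gamma,
                             dp$bn2$beta)
  a2 <- relu(n2f$out)
  c3f <- conv2d_forward(array(a2, c(n, n, cfg$conv_channels[2L])),
                        dp$conv3$W, dp$conv3$b, k)
  m <- matrix(c3f$out, n, n)
  list(out = (m + t(m)) / 2,
       cache = list(c1 = c1f$cache, n1 = n1f$cache, m1 = n1f$out > 0,
                    c2 = c2f$cache, n2 = n2f$cache, m2 = n2f$out > 0,
                    c3 = c3f$cache, n = n, cfg = cfg))
}

decoder_backward_cached <- function(dS, cache) {
  n <- cache$n
  cfg <- cache$cfg
  dm <- (dS + t(dS)) / 2
  c3b <- conv2d_backward(array(dm, c(n, n, 1L)), cache$c3)
  da2 <- matrix(c3b$da, n * n) * cache$m2
  n2b <- channelnorm_backward(da2, cache$n2)
  c2b <- conv2d_backward(array(n2b$dx, c(n, n, cfg$conv_channels[2L])),
                         cache$c2)
  da1 <- matrix(c2b$da, n * n) * cache$m1
  n1b <- channelnorm_backward(da1, cache$n1)
  c1b <- conv2d_backward(array(n1b$dx, c(n, n, cfg$conv_channels[1L])),
                         cache$c1)
  list(dfa = c1b$da,
       grads = list(conv1 = list(W = c1b$dW, b = c1b$db),
                    bn1 = list(gamma = n1b$dgamma, beta = n1b$dbeta),
                    conv2 = list(W = c2b$dW, b = c2b$db),
                    bn2 = list(gamma = n2b$dgamma, beta = n2b$dbeta),
                    conv3 = list(W = c3b$dW, b = c3b$db)))
}

#' Run the convolutional pairwise decoder
#'
#' Three 2-D convolution stages (normalization and ReLU after the first
#' two, linear single-channel output), followed by symmetrization of the
#' output map as \code{(M + t(M)) / 2}.
#'
#' @param features N x N x c feature array from
#'   \code{\link{pairwise_assemble}}.
#' @param params model parameter tree (its \code{dec} entry is used).
#' @param cfg the \code{\link{model_config}}.
#' @return N x N symmetric score matrix.
#' @export
decoder_forward <- function(features, params, cfg) {
  decoder_forward_cached(features, params$dec, cfg)$out
}

# --- full model ---------------------------------------------------------

#' Compute the base-pair score matrix for a sequence
#'
#' Full forward pass: one-hot encoding, 1-D convolutional lift, position
#' embedding, attention encoder, pairwise assembly (encoder output plus
#' projected positions), convolutional decoder, symmetrization.
#'
#' @param seq an \code{\link{rna_sequence}}.
#' @param params parameter tree from \code{\link{init_model_params}}.
#' @param cfg the \code{\link{model_config}}.
#' @param want_cache keep intermediate activations for backpropagation.
#' @return N x N symmetric score matrix; with \code{want_cache = TRUE}, a
#'   list \code{(S, cache)}.
#' @export
model_forward <- function(seq, params, cfg, want_cache = FALSE) {
  stopifnot(inherits(seq, "rna_sequence"))
  n <- seq$length
  if (n > cfg$max_len)
    stop("sequence length ", n, " exceeds the model length filter (",
         cfg$max_len, ")")
  x <- one_hot(seq)
  liftf <- conv1d_forward(x, params$lift$W, params$lift$b, cfg$lift_kw)
  posf <- linear_forward(cbind(as.numeric(seq_len(n)), seq_len(n) / n),
                         params$pos$W, params$pos$b)
  x0 <- liftf$out + posf$out
  enc <- encoder_forward_cached(x0, params$blocks, cfg)
  H <- enc$out + posf$out
  fa <- pairwise_forward(H)
  dec <- decoder_forward_cached(fa, params$dec, cfg)
  if (!want_cache) return(dec$out)
  list(S = dec$out,
       cache = list(lift = liftf$cache, pos = posf$cache, enc = enc,
                    dec = dec$cache, n = n))
}

model_backward <- function(dS, cache) {
  db <- decoder_backward_cached(dS, cache$dec)
  dH <- pairwise_backward(db$dfa)
  eb <- encoder_backward_cached(dH, cache$enc$caches)
  dx0 <- eb$dx
  dpos_out <- dH + dx0               # positions feed both x0 and H
  liftb <- conv1d_backward(dx0, cache$lift)
  posb <- linear_backward(dpos_out, cache$pos)
  list(lift = list(W = liftb$dW, b = liftb$db),
       pos = list(W = posb$dW, b = posb$db),
       blocks = eb$grads,
       dec = db$grads)
}
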