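test_that("attention degenerates correctly", {
  expect_equal(attention(matrix(1), matrix(1), matrix(1)), matrix(1))
  # constant V: rows of the softmax sum to 1, so output is that constant
  V <- matrix(rep(c(2, -1, 0.5), each = 4), 4, 3)
  Q <- matrix(rnorm(8), 4, 2); K <- matrix(rnorm(8), 4, 2)
  expect_equal(attention(Q, K, V), V)
  # zero K: uniform attention, output = column means of V
  V2 <- matrix(rnorm(12), 4, 3)
  out <- attention(Q, matrix(0, 4, 2), V2)
  expect_equal(out, matrix(rep(colMeans(V2), each = 4), 4, 3))
})

test_that("attention weights are row-stochastic", {
  for (k in 1:10) {
    with_seed_local(k, {
      Q <- matrix(rnorm(24), 6, 4); K <- matrix(rnorm(24), 6, 4)
      A <- pairfold:::softmax_rows(Q %*% t(K) / 2)
      expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-6)
      expect_true(all(A >= 0))
    })
  }
})

test_that("layer normalization centres and scales per position", {
  x <- matrix(rnorm(60, mean = 3, sd = 5), 5, 12)
  ln <- pairfold:::layernorm_forward(x, gamma = rep(1, 12),
                                     beta = numeric(12))
  expect_equal(rowMeans(ln$out), rep(0, 5), tolerance = 1e-8)
  expect_equal(apply(ln$out, 1, function(r) mean(r^2)), rep(1, 5),
               tolerance = 1e-4)
})

test_that("encoder output has shape N x d and is deterministic", {
  cfg <- tiny_model_cfg()
  params <- init_model_params(cfg)
  x <- matrix(rnorm(15 * cfg$d), 15, cfg$d)
  h1 <- encoder_forward(x, params, cfg)
  h2 <- encoder_forward(x, params, cfg)
  expect_equal(dim(h1), c(15L, cfg$d))
  expect_identical(h1, h2)
  # fresh params from the same seed give the same result
  params2 <- init_model_params(cfg)
  expect_identical(h1, encoder_forward(x, params2, cfg))
})

test_that("pairwise features are symmetric by construction", {
  H <- matrix(rnorm(6 * 5), 6, 5)
  fa <- pairwise_assemble(H)
  expect_equal(dim(fa), c(6L, 6L, 10L))
  for (ch in 1:10) expect_equal(fa[, , ch], t(fa[, , ch]))
  # diagonal entries are self-combinations; off-diagonals order-invariant
  expect_equal(fa[2, 2, 1:5], H[2, ])
  expect_equal(fa[1, 4, 1:5], (H[1, ] + H[4, ]) / 2)
  expect_equal(fa[1, 4, ], fa[4, 1, ])
})

test_that("decoder emits a symmetric map, zero under zero weights", {
  cfg <- tiny_model_cfg()
  params <- init_model_params(cfg)
  fa <- pairwise_assemble(matrix(rnorm(7 * cfg$d), 7, cfg$d))
  S <- decoder_forward(fa, params, cfg)
  expect_equal(dim(S), c(7L, 7L))
  expect_lt(max(abs(S - t(S))), 1e-6)
  zero <- params
  zero$dec <- pairfold:::tree_map(function(x) x * 0, zero$dec)
  zero$dec$bn1$gamma[] <- 1; zero$dec$bn2$gamma[] <- 1
  expect_equal(decoder_forward(fa, zero, cfg), matrix(0, 7, 7))
  # permuting the two sequence axes of the symmetric input changes nothing
  expect_equal(decoder_forward(aperm(fa, c(2, 1, 3)), params, cfg), S)
})

test_that("model_forward composes the pipeline and enforces the filter", {
  cfg <- tiny_model_cfg()
  params <- init_model_params(cfg)
  seq <- parse_sequence("GGGAAAUCCCAUGGC")
  S1 <- model_forward(seq, params, cfg)
  S2 <- model_forward(seq, params, cfg)
  expect_equal(dim(S1), c(15L, 15L))
  expect_lt(max(abs(S1 - t(S1))), 1e-6)
  expect_identical(S1, S2)
  short_cfg <- model_config(d = 8, n_blocks = 1, n_heads = 2, d_ff = 12,
                            conv_channels = c(4, 3, 1), max_len = 10)
  expect_error(model_forward(seq, params, short_cfg), "length filter")
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- tiny_model_cfg()
  p <- init_model_params(cfg)
  sq <- parse_sequence("GGGAAAUCCCAUG")
  truth <- rna_structure(rbind(c(0, 9), c(1, 8)), 13)
  mks <- list(m1 = canonical_mask(sq), m2 = distance_mask(13))
  lossfun <- function(pp) {
    training_loss(model_forward(sq, pp, cfg), truth, mks,
                  pos_weight = 2)$loss
  }
  fw <- model_forward(sq, p, cfg, want_cache = TRUE)
  ls <- training_loss(fw$S, truth, mks, pos_weight = 2)
  g <- pairfold:::model_backward(ls$dS, fw$cache)
  probe <- list(
    list(list("lift", "W"), 5), list(list("pos", "W"), 3),
    list(list("dec", "conv1", "W"), 17),
    list(list("dec", "bn1", "gamma"), 2),
    list(list("dec", "conv3", "W"), 4),
    list(list("blocks", 1L, "attn", "Wq"), 11),
    list(list("blocks", 1L, "attn", "Wo"), 7),
    list(list("blocks", 1L, "ln1", "gamma"), 3),
    list(list("blocks", 1L, "ffn", "W1"), 9),
    list(list("blocks", 1L, "ln2", "beta"), 2))
  get_leaf <- function(tree, path) {
    for (nm in path) tree <- tree[[nm]]
    tree
  }
  set_leaf <- function(tree, path, idx, delta) {
    if (length(path) == 1L) {
      tree[[path[[1]]]][idx] <- tree[[path[[1]]]][idx] + delta
    } else {
      tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], idx,
                                    delta)
    }
    tree
  }
  eps <- 1e-5
  for (pr in probe) {
    up <- lossfun(set_leaf(p, pr[[1]], pr[[2]], eps))
    dn <- lossfun(set_leaf(p, pr[[1]], pr[[2]], -eps))
    num <- (up - dn) / (2 * eps)
    ana <- get_leaf(g, pr[[1]])[pr[[2]]]
    expect_lt(abs(num - ana) / max(1e-7, abs(num), abs(ana)), 1e-4)
  }
})
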