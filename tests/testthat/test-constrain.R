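test_that("canonical mask marks exactly the A-U/G-C/G-U cells", {
  m <- canonical_mask(rna_sequence("GACU"))
  expect_equal(sum(m), 6)  # (G,C),(G,U),(A,U) and transposes
  expect_equal(m[1, 3], 1)  # G-C
  expect_equal(m[1, 4], 1)  # G-U
  expect_equal(m[2, 4], 1)  # A-U
  expect_equal(m, t(m))
  expect_equal(canonical_mask(rna_sequence("AAAA")), matrix(0, 4, 4))
  mn <- canonical_mask(rna_sequence("ANAU"))
  expect_equal(sum(mn[2, ]), 0)
  expect_equal(sum(mn[, 2]), 0)
})

test_that("distance mask zeroes a band of width 3 around the diagonal", {
  m8 <- distance_mask(8)
  expect_equal(sum(m8), 20)  # 2 * sum_{k=4..7} (8-k)
  expect_true(all(diag(m8) == 0))
  expect_equal(distance_mask(4), matrix(0, 4, 4))
  expect_equal(m8, t(m8))
})

test_that("pairing penalty is the relu of row-sum excess", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- 0; a[2, 1] <- 1; a[3, 1] <- 1; a[3, 2] <- 1
  # row sums 0, 1, 2 -> relu(-1)+relu(0)+relu(1) = 1
  expect_equal(pairing_penalty(a), 1)
  valid <- pairs_to_matrix(rbind(c(0, 5), c(1, 4)), 7)
  expect_equal(pairing_penalty(valid), 0)
  allones <- matrix(1, 4, 4); diag(allones) <- 0
  expect_equal(pairing_penalty(allones), 8)
})

test_that("objective rewards fit and penalizes violations", {
  cfg <- decode_config(s = 0, w = 0, rho = 0, squash = FALSE)
  n <- 10
  S <- matrix(0, n, n); S[1, 6] <- S[6, 1] <- 1
  a0 <- matrix(0, n, n)
  expect_equal(objective(S, a0, cfg), 0)
  a1 <- a0; a1[1, 6] <- a1[6, 1] <- 1
  expect_equal(objective(S, a1, cfg), -1)
  # with a large penalty weight, overloading a row worsens the objective
  cfgw <- decode_config(s = 0, w = 10, rho = 0, squash = FALSE)
  a2 <- a1; a2[1, 9] <- a2[9, 1] <- 1   # row 1 now sums to 2
  expect_gt(objective(S, a2, cfgw), objective(S, a1, cfgw))
})

test_that("decode matches brute force on a hand-built stem instance", {
  seq <- parse_sequence("GGGAAACC")
  S <- matrix(-5, 8, 8)
  S[1, 8] <- S[8, 1] <- 5   # (0,7)
  S[2, 7] <- S[7, 2] <- 5   # (1,6)
  dec <- constrained_decode(S, seq)
  expect_equal(dec$pairs, rna_structure(rbind(c(0, 7), c(1, 6)), 8)$pairs)
  bf <- brute_force_decode(sigmoid_scores(S), seq, s = 0.5)
  expect_equal(bf$pairs, dec$pairs)
})

test_that("degenerate decodes return the empty structure", {
  seq <- parse_sequence("GGGAAACC")
  low <- matrix(-3, 8, 8)
  expect_equal(nrow(constrained_decode(low, seq)$pairs), 0)
  tiny <- parse_sequence("GAUC")
  any_scores <- matrix(3, 4, 4)
  expect_equal(nrow(constrained_decode(any_scores, tiny)$pairs), 0)
})

test_that("decoded structures always satisfy the hard constraints", {
  for (k in 1:60) {
    ex <- random_example(k, n_range = c(10, 50))
    S <- random_scores(ex$n, seed = 40000 + k)
    dec <- constrained_decode(S, ex$seq,
                              decode_config(s = 0, squash = FALSE))
    expect_true(satisfies_hard_constraints(dec, ex$seq))
  }
})

test_that("gradient decoding tracks the brute-force optimum at small N", {
  exact <- 0
  for (k in 1:60) {
    n <- 8 + (k %% 7)
    struct <- sample_structure(n, seed = 50000 + k)
    seq <- sample_sequence(struct, seed = 51000 + k)
    S <- random_scores(n, seed = 52000 + k)
    cfg <- decode_config(s = 0, squash = FALSE)
    dec <- constrained_decode(S, seq, cfg)
    bf <- brute_force_decode(S, seq, s = 0)
    sc_dec <- matching_score(S, dec, 0)
    sc_bf <- matching_score(S, bf, 0)
    expect_gte(sc_dec, 0.95 * sc_bf)
    if (identical(dec$pairs, bf$pairs)) exact <- exact + 1
  }
  expect_gte(exact / 60, 0.8)
})

test_that("raising the threshold never adds pairs", {
  for (k in 1:10) {
    ex <- random_example(k, n_range = c(15, 30))
    S <- random_scores(ex$n, seed = 60000 + k)
    previous <- Inf
    for (s in c(-0.5, -0.2, 0, 0.2, 0.5)) {
      dec <- constrained_decode(S, ex$seq,
                                decode_config(s = s, squash = FALSE))
      expect_lte(nrow(dec$pairs), previous)
      previous <- nrow(dec$pairs)
    }
  }
})

test_that("crossing pairs decode as pseudoknots (no nesting restriction)", {
  seq <- parse_sequence("GAAAAGGAUCAACCA")  # 15 nt
  pk_pairs <- rbind(c(0, 9), c(1, 8), c(5, 13), c(6, 12))
  stopifnot(max(pk_pairs) <= 14)
  S <- matrix(-5, 15, 15)
  for (r in seq_len(nrow(pk_pairs))) {
    S[pk_pairs[r, 1] + 1, pk_pairs[r, 2] + 1] <- 5
    S[pk_pairs[r, 2] + 1, pk_pairs[r, 1] + 1] <- 5
  }
  dec <- constrained_decode(S, seq)
  expect_equal(dec$pairs, rna_structure(pk_pairs, 15)$pairs)
  expect_true(detect_pseudoknots(dec)$pseudoknotted)
})

test_that("brute force rejects long sequences and resolves exclusivity", {
  seq <- parse_sequence(paste(rep("GACU", 5), collapse = ""))
  expect_error(brute_force_decode(matrix(0, 20, 20), seq), "N <= 14")
  # two mutually exclusive pairs sharing a base: larger net score wins
  s2 <- parse_sequence("GAAAACU")
  S <- matrix(-1, 7, 7)
  S[1, 6] <- S[6, 1] <- 0.3   # (0,5) G-C
  S[1, 7] <- S[7, 1] <- 0.8   # (0,6) G-U
  bf <- brute_force_decode(S, s2, s = 0)
  expect_equal(bf$pairs, rna_structure(rbind(c(0, 6)), 7)$pairs)
  # all net scores negative: empty set is optimal
  expect_equal(nrow(brute_force_decode(matrix(-1, 7, 7), s2, s = 0)$pairs),
               0)
})
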