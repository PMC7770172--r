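# Seeded synthetic fixtures shared across test files. Everything is
# generated in code; nothing is read from disk except in round-trip tests
# that write their own temporary files.

random_example <- function(k, n_range = c(20, 40), pk_prob = 0.3,
                           sigma = 0) {
  n <- n_range[1] + (k %% (n_range[2] - n_range[1] + 1L))
  struct <- sample_structure(n, pk_prob = pk_prob, seed = 10000 + k)
  seq <- sample_sequence(struct, seed = 20000 + k)
  S <- noisy_score_matrix(struct, sigma, seed = 30000 + k)
  list(seq = seq, struct = struct, S = S, n = n)
}

## random symmetric score matrix over [-1, 1], seeded
random_scores <- function(n, seed) {
  with_seed_local(seed, {
    S <- matrix(runif(n * n, -1, 1), n, n)
    (S + t(S)) / 2
  })
}

sigmoid_scores <- function(S) 1 / (1 + exp(-S))

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

## a valid-structure predicate matching the three hard constraints
satisfies_hard_constraints <- function(struct, seq) {
  p <- struct$pairs
  if (nrow(p) == 0L) return(TRUE)
  m1 <- canonical_mask(seq)
  all(abs(p[, 1L] - p[, 2L]) >= 4L) &&
    !anyDuplicated(as.vector(p)) &&
    all(m1[cbind(p[, 1L] + 1L, p[, 2L] + 1L)] == 1)
}

## tiny model configuration used wherever a network is needed quickly
tiny_model_cfg <- function(seed = 7L) {
  model_config(d = 8L, n_blocks = 1L, n_heads = 2L, d_ff = 12L,
               conv_channels = c(4L, 3L, 1L), seed = seed)
}
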