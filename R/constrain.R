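# Hard-constraint decoding: converts a real-valued base-pair score matrix
# into a valid pairing matrix. The three hard constraints are (1) only
# A-U / G-C Watson-Crick and G-U wobble pairs, (2) |i - j| >= 4 so hairpin
# loops keep at least 3 unpaired bases, (3) at most one partner per base.
# Constraints 1-2 are 0/1 masks applied multiplicatively; constraint 3 is a
# relu penalty on row sums, enforced by penalized gradient descent on a
# relaxed [0,1] pairing variable, then exactly by a discrete cleanup.

#' Canonical-pair constraint mask
#'
#' Symmetric N x N 0/1 matrix with 1 exactly where the unordered base pair
#' is A-U, G-C or G-U; positions holding the unknown base N never pair.
#'
#' @param seq an \code{\link{rna_sequence}}.
#' @return N x N 0/1 matrix.
#' @export
canonical_mask <- function(seq) {
  stopifnot(inherits(seq, "rna_sequence"))
  ch <- strsplit(seq$bases, "")[[1]]
  allowed <- function(x, y) {
    (outer(ch == x, ch == y, "&") | outer(ch == y, ch == x, "&"))
  }
  m <- allowed("A", "U") | allowed("G", "C") | allowed("G", "U")
  storage.mode(m) <- "double"
  m
}

#' Minimum-hairpin-loop distance mask
#'
#' Symmetric N x N 0/1 matrix that zeroes every cell within distance 3 of
#' the diagonal (including the diagonal itself): a pair (i, j) requires
#' |i - j| >= 4, i.e. a hairpin loop of at least 3 unpaired bases.
#'
#' @param n sequence length.
#' @return N x N 0/1 matrix.
#' @export
distance_mask <- function(n) {
  stopifnot(n >= 1L)
  idx <- seq_len(n)
  m <- abs(outer(idx, idx, "-")) > 3L
  storage.mode(m) <- "double"
  m
}

constraint_masks <- function(seq) {
  list(m1 = canonical_mask(seq), m2 = distance_mask(seq$length))
}

#' Single-pairing relu penalty
#'
#' \code{sum_n relu(rowsum_n(a) - 1)}: zero exactly when every base carries
#' at most one unit of pairing mass.
#'
#' @param a symmetric nonnegative N x N matrix (relaxed pairing variable).
#' @return Nonnegative scalar.
#' @export
pairing_penalty <- function(a) {
  sum(pmax(rowSums(a) - 1, 0))
}

#' Decoding configuration
#'
#' @param s pairing threshold subtracted from the (optionally squashed)
#'   scores; a cell can only end up paired when its score exceeds s.
#' @param w weight of the single-pairing relu penalty.
#' @param rho L1 sparsity weight.
#' @param iters number of gradient-descent iterations T.
#' @param step gradient step size.
#' @param squash apply a sigmoid to the raw scores before decoding (maps
#'   arbitrary network outputs to [0,1] so the default s = 0.5 thresholds
#'   at raw score 0).
#' @param init_gain slope of the initialization \code{a0 =
#'   sigmoid(init_gain * (S - s))}: a sigmoid-squashed copy of the masked
#'   score matrix centred on the threshold.
#' @param cut binarization cutoff on the relaxed variable.
#' @param signs \code{"penalty"} (default): the relu and L1 terms penalize
#'   violations under the maximization; \code{"as_printed"}: the literal
#'   sign layout of the objective, which rewards them (kept for
#'   comparison).
#' @return List of class \code{decode_config}.
#' @export
decode_config <- function(s = 0.5, w = 1.0, rho = 0.01, iters = 300L,
                          step = 3, squash = TRUE, init_gain = 4,
                          cut = 0.5, signs = c("penalty", "as_printed")) {
  signs <- match.arg(signs)
  stopifnot(iters >= 1L, step > 0, w >= 0, rho >= 0, init_gain > 0)
  structure(list(s = s, w = w, rho = rho, iters = as.integer(iters),
                 step = step, squash = isTRUE(squash),
                 init_gain = init_gain, cut = cut, signs = signs),
            class = "decode_config")
}

#' Decoding objective (minimized form)
#'
#' \code{-( 1/2 sum (S - s) a  -  w sum relu(rowsum(a) - 1)  -
#' rho sum |a| )}: the first term rewards pairing mass where scores exceed
#' the threshold, the second penalizes multi-pairing, the third promotes
#' sparsity. Lower is better. With \code{signs = "as_printed"} the last
#' two terms keep the literal published sign layout instead.
#'
#' @param S N x N score matrix (already on the scale the threshold refers
#'   to; no squashing is applied here).
#' @param a relaxed pairing matrix in [0, 1], masked by the constraints.
#' @param cfg a \code{\link{decode_config}}; \code{s} may also be an N x N
#'   matrix of per-cell thresholds.
#' @return Scalar objective value.
#' @export
objective <- function(S, a, cfg = decode_config()) {
  fit <- 0.5 * sum((S - cfg$s) * a)
  pen <- pairing_penalty(a)
  l1 <- sum(abs(a))
  if (cfg$signs == "penalty") {
    -(fit - cfg$w * pen - cfg$rho * l1)
  } else {
    -(fit + cfg$w * pen + cfg$rho * l1)
  }
}

## Greedy cleanup for constraint 3: while any base has more than one
## partner, keep its highest-scoring pair (ties to the lexicographically
## smaller (i, j)) and drop the rest.
resolve_conflicts <- function(pairs, S) {
  if (nrow(pairs) == 0L) return(pairs)
  repeat {
    idx <- as.vector(pairs)
    dup <- idx[duplicated(idx)]
    if (length(dup) == 0L) return(as_pair_matrix(pairs))
    base <- min(dup)
    hit <- which(pairs[, 1L] == base | pairs[, 2L] == base)
    sc <- S[cbind(pairs[hit, 1L] + 1L, pairs[hit, 2L] + 1L)]
    ord <- order(-sc, pairs[hit, 1L], pairs[hit, 2L])
    drop <- hit[ord[-1L]]
    pairs <- pairs[-drop, , drop = FALSE]
  }
}

#' Decode a score matrix into a valid secondary structure
#'
#' Penalized gradient descent on the relaxed pairing variable
#' \code{a = mask * sigmoid(u)}: (i) initialize u from the (optionally
#' sigmoid-squashed) scores centred on the threshold, (ii) take
#' \code{iters} gradient steps on the objective, symmetrizing after each
#' step, (iii) binarize at \code{cut}, (iv) discrete cleanup: greedily
#' resolve any remaining multi-pairing by score, greedily add positive
#' pairs on still-free bases, and run a 1-swap local search (each step a
#' monotone improvement of the fit term). The output always satisfies all
#' three hard
#' constraints; because nothing restricts pairs to be nested, crossing
#' (pseudoknotted) structures decode naturally.
#'
#' @param S N x N score matrix (network output or user-supplied).
#' @param seq the \code{\link{rna_sequence}} the scores refer to.
#' @param cfg a \code{\link{decode_config}}.
#' @return An \code{\link{rna_structure}}.
#' @export
constrained_decode <- function(S, seq, cfg = decode_config()) {
  stopifnot(inherits(seq, "rna_sequence"), is.matrix(S),
            nrow(S) == seq$length, ncol(S) == seq$length)
  n <- seq$length
  masks <- constraint_masks(seq)
  mask <- masks$m1 * masks$m2
  if (all(mask == 0)) return(rna_structure(NULL, n))
  Sw <- if (cfg$squash) sigmoid(S) else S
  Sw <- (Sw + t(Sw)) / 2
  pen_sign <- if (cfg$signs == "penalty") 1 else -1
  u <- cfg$init_gain * (Sw - cfg$s)
  for (t in seq_len(cfg$iters)) {
    sig <- sigmoid(u)
    a <- mask * sig
    viol <- as.numeric(rowSums(a) > 1)        # relu subgradient per row
    g_a <- -0.5 * (Sw - cfg$s) +
      pen_sign * (cfg$w * matrix(viol, n, n) + cfg$rho)
    g_u <- g_a * mask * sig * (1 - sig)
    u <- u - cfg$step * g_u
    u <- (u + t(u)) / 2
  }
  a <- mask * sigmoid(u)
  hits <- which(a > cfg$cut & upper.tri(a), arr.ind = TRUE)
  pairs <- as_pair_matrix(hits - 1L)
  pairs <- resolve_conflicts(pairs, Sw)
  pairs <- greedy_complete(pairs, Sw, mask, cfg$s, n)
  pairs <- local_improve(pairs, Sw, mask, cfg$s, n)
  rna_structure(pairs, n)
}

## Completion pass: add any allowed pair with net score > 0 whose bases are
## both still free, in descending score order. Monotone improvement of the
## objective's fit term; every hard constraint is preserved.
greedy_complete <- function(pairs, Sw, mask, s, n) {
  net <- Sw - s
  cand <- which(mask == 1 & upper.tri(mask) & net > 0, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(pairs)
  used <- logical(n)
  used[as.vector(pairs) + 1L] <- TRUE
  ord <- order(-net[cand], cand[, 1L], cand[, 2L])
  for (k in ord) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!used[i] && !used[j]) {
      pairs <- rbind(pairs, c(i - 1L, j - 1L))
      used[i] <- TRUE; used[j] <- TRUE
    }
  }
  as_pair_matrix(pairs)
}

## 1-swap local search: for each selected pair, try dropping it and
## greedily refilling the freed bases; keep the move when the total net
## score strictly improves. Repeats until a full sweep makes no change.
local_improve <- function(pairs, Sw, mask, s, n, max_sweeps = 5L) {
  net <- Sw - s
  score_of <- function(p) {
    if (nrow(p) == 0L) 0 else sum(net[cbind(p[, 1L] + 1L, p[, 2L] + 1L)])
  }
  eps <- 1e-9
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    k <- 1L
    while (k <= nrow(pairs)) {
      alt <- greedy_complete(pairs[-k, , drop = FALSE], Sw, mask, s, n)
      if (score_of(alt) > score_of(pairs) + eps) {
        pairs <- alt
        improved <- TRUE
        k <- 1L
      } else {
        k <- k + 1L
      }
    }
    if (!improved) break
  }
  pairs
}

#' Total matched score of a structure under a score matrix
#'
#' \code{1/2 sum (S - s) * A} where A is the structure's pairing matrix,
#' i.e. the sum of (S_ij - s) over its base pairs.
#'
#' @param S N x N score matrix.
#' @param struct an \code{\link{rna_structure}}.
#' @param s threshold.
#' @return Scalar.
#' @export
matching_score <- function(S, struct, s = 0) {
  p <- struct$pairs
  if (nrow(p) == 0L) return(0)
  sum(S[cbind(p[, 1L] + 1L, p[, 2L] + 1L)] - s)
}

#' Exact constrained decoding by enumeration (verification oracle)
#'
#' Finds the 0/1 matching that exactly maximizes \code{1/2 sum (S - s) a}
#' over all structures satisfying the three hard constraints, by
#' depth-first enumeration over the allowed pairs with positive net score
#' (pairs with non-positive net score can never enter a maximizer under
#' the lexicographic tie-break). Ties are broken toward the
#' lexicographically smallest pair set. Intended as an independent check
#' of \code{\link{constrained_decode}} at small N.
#'
#' @param S N x N score matrix (same scale convention as the threshold).
#' @param seq the \code{\link{rna_sequence}}.
#' @param s threshold.
#' @param max_n enumeration bound on the sequence length.
#' @return An \code{\link{rna_structure}}.
#' @export
brute_force_decode <- function(S, seq, s = 0, max_n = 14L) {
  stopifnot(inherits(seq, "rna_sequence"))
  n <- seq$length
  if (n > max_n)
    stop("brute-force enumeration limited to N <= ", max_n, ", got ", n)
  masks <- constraint_masks(seq)
  mask <- masks$m1 * masks$m2
  Ssym <- (S + t(S)) / 2
  net <- Ssym - s
  cand <- which(mask == 1 & upper.tri(mask) & net > 0, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(rna_structure(NULL, n))
  ord <- order(cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  gain <- net[cand]
  np <- nrow(cand)
  suffix <- rev(cumsum(rev(gain)))
  eps <- 1e-9
  best <- list(score = 0, sel = integer(0))
  lex_less <- function(a, b) {      # a, b: index vectors into cand rows
    la <- length(a); lb <- length(b)
    for (k in seq_len(min(la, lb))) {
      if (a[k] != b[k]) return(a[k] < b[k])
    }
    la < lb
  }
  used <- logical(n)
  sel <- integer(0)
  rec <- function(k, score) {
    if (score + (if (k <= np) suffix[k] else 0) < best$score - eps)
      return(invisible())
    if (k > np) {
      if (score > best$score + eps ||
          (abs(score - best$score) <= eps && lex_less(sel, best$sel))) {
        best <<- list(score = score, sel = sel)
      }
      return(invisible())
    }
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!used[i] && !used[j]) {     # include branch first (lex preference)
      used[i] <<- TRUE; used[j] <<- TRUE
      sel <<- c(sel, k)
      rec(k + 1L, score + gain[k])
      sel <<- sel[-length(sel)]
      used[i] <<- FALSE; used[j] <<- FALSE
    }
    rec(k + 1L, score)
  }
  rec(1L, 0)
  if (length(best$sel) == 0L) return(rna_structure(NULL, n))
  rna_structure(cand[best$sel, , drop = FALSE] - 1L, n)
}

#' Read a whitespace-delimited score matrix from a text file
#'
#' Enables use of the constrained decoder as a standalone tool on scores
#' produced elsewhere.
#'
#' @param path text file with N rows of N numbers.
#' @return N x N numeric matrix.
#' @export
read_score_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("score matrix must be square")
  m
}
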