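# Download-free generator of RNA structures, sequences and score matrices
# obeying the hard constraints: nested stems of 2-6 pairs, hairpin loops of
# at least 3 unpaired bases (|i - j| >= 4 for every pair), only A-U/G-C/G-U
# pairs, one partner per base, and optionally one H-type crossing stem.

#' Synthetic dataset configuration
#'
#' @param n_items number of (sequence, structure) examples.
#' @param length_range integer min/max sequence length (min >= 5, the
#'   smallest length admitting one pair at distance 4).
#' @param pk_prob probability of attempting one H-type crossing stem.
#' @param gu_prob probability a generated pair is G-U (otherwise A-U or
#'   G-C with equal probability).
#' @param noise_sigma Gaussian noise scale for score matrices.
#' @param seed RNG seed making the whole dataset reproducible.
#' @return List of class \code{synth_config}.
#' @export
synth_config <- function(n_items = 30L, length_range = c(20L, 40L),
                         pk_prob = 0.2, gu_prob = 0.2, noise_sigma = 0.1,
                         seed = 1L) {
  stopifnot(n_items >= 1L, length(length_range) == 2L,
            length_range[1L] >= 5L,
            length_range[1L] <= length_range[2L],
            pk_prob >= 0, pk_prob <= 1, gu_prob >= 0, gu_prob <= 1,
            noise_sigma >= 0)
  structure(list(n_items = as.integer(n_items),
                 length_range = as.integer(length_range),
                 pk_prob = pk_prob, gu_prob = gu_prob,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synth_config")
}

## sample() treats a length-1 numeric as 1:x; these never do.
sample_one <- function(x) x[sample.int(length(x), 1L)]
shuffle <- function(x) x[sample.int(length(x))]

## Recursively place nested stems inside [lo, hi] (0-based inclusive).
## A stem of length L rooted at (a, b) keeps b - a >= 2L + 2 so even its
## innermost pair satisfies |i - j| >= 4. Returns a list of pair vectors.
place_stems <- function(lo, hi) {
  len <- hi - lo + 1L
  if (len < 7L) return(list())
  # occasionally split into two side-by-side substructures (multi-branch)
  if (len >= 18L && runif(1) < 0.35) {
    m <- lo + sample_one(7:(len - 8L))
    return(c(place_stems(lo, m), place_stems(m + 1L, hi)))
  }
  a <- lo + sample_one(0:min(2L, len - 7L))
  b <- hi - sample_one(0:max(0L, min(2L, hi - a - 6L)))
  l_max <- min(6L, (b - a - 2L) %/% 2L)
  if (l_max < 2L) return(list())
  l <- sample_one(2:l_max)
  pairs <- lapply(0:(l - 1L), function(t) c(a + t, b - t))
  c(pairs, place_stems(a + l, b - l))
}

## Try to thread one H-type crossing stem through an existing structure:
## pair unpaired loop positions u, u+1 inside an existing pair (i, j) with
## unpaired positions v, v-1 downstream of j, so (u, v) crosses (i, j).
add_crossing_stem <- function(pairs, n) {
  if (length(pairs) == 0L) return(pairs)
  paired <- unlist(pairs)
  unpaired <- setdiff(0:(n - 1L), paired)
  anchors <- shuffle(seq_along(pairs))
  for (k in anchors) {
    i <- pairs[[k]][1L]; j <- pairs[[k]][2L]
    us <- unpaired[unpaired > i & unpaired < j]
    us <- us[(us + 1L) %in% unpaired & (us + 1L) < j]
    vs <- unpaired[unpaired > j]
    vs <- vs[(vs - 1L) %in% unpaired & (vs - 1L) > j]
    if (length(us) == 0L || length(vs) == 0L) next
    us <- shuffle(us)
    for (u in us) {
      ok_v <- vs[vs - u >= 6L]       # inner pair (u+1, v-1) needs >= 4
      if (length(ok_v) == 0L) next
      v <- sample_one(ok_v)
      return(c(pairs, list(c(u, v), c(u + 1L, v - 1L))))
    }
  }
  pairs
}

#' Sample a random valid secondary structure
#'
#' Recursively places nested stems (2-6 pairs each, all pairs at distance
#' >= 4, every base paired at most once); with probability \code{pk_prob}
#' one H-type crossing stem is threaded through a hairpin loop, producing a
#' pseudoknot while preserving all constraints. Falls back to fewer (or no)
#' stems when the interval is too tight.
#'
#' @param n sequence length (>= 5).
#' @param pk_prob probability of attempting the crossing stem.
#' @param seed optional RNG seed (deterministic output when set).
#' @return An \code{\link{rna_structure}}.
#' @export
sample_structure <- function(n, pk_prob = 0, seed = NULL) {
  stopifnot(n >= 5L)
  with_seed(seed, {
    pairs <- place_stems(0L, n - 1L)
    if (runif(1) < pk_prob) pairs <- add_crossing_stem(pairs, n)
    rna_structure(pairs, n)
  })
}

#' Sample a sequence compatible with a structure
#'
#' Paired positions are drawn jointly from {A-U, G-C, G-U} (G-U with
#' probability \code{gu_prob}, the two Watson-Crick pairs equally likely
#' otherwise, orientation random); unpaired positions are uniform over
#' A/U/C/G. Every structure pair is therefore canonical by construction.
#'
#' @param struct an \code{\link{rna_structure}}.
#' @param gu_prob wobble-pair probability.
#' @param seed optional RNG seed.
#' @param id label for the sequence.
#' @return An \code{\link{rna_sequence}}.
#' @export
sample_sequence <- function(struct, gu_prob = 0.2, seed = NULL,
                            id = "synthetic") {
  stopifnot(inherits(struct, "rna_structure"))
  with_seed(seed, {
    n <- struct$length
    chars <- sample(c("A", "U", "C", "G"), n, replace = TRUE)
    p <- struct$pairs
    for (k in seq_len(nrow(p))) {
      duo <- if (runif(1) < gu_prob) c("G", "U")
             else if (runif(1) < 0.5) c("A", "U") else c("G", "C")
      if (runif(1) < 0.5) duo <- rev(duo)
      chars[p[k, ] + 1L] <- duo
    }
    rna_sequence(paste(chars, collapse = ""), id = id)
  })
}

#' Synthetic score matrix around a known structure
#'
#' +1 at true-pair cells, -1 everywhere else, plus i.i.d. Gaussian noise of
#' scale \code{noise_sigma}; the result is symmetrized. With zero noise the
#' true pairs are the unique constrained-decoding optimum.
#'
#' @param struct an \code{\link{rna_structure}}.
#' @param noise_sigma noise standard deviation.
#' @param seed optional RNG seed.
#' @return N x N symmetric numeric matrix.
#' @export
noisy_score_matrix <- function(struct, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(struct, "rna_structure"))
  with_seed(seed, {
    n <- struct$length
    S <- 2 * pairs_to_matrix(struct) - 1
    if (noise_sigma > 0)
      S <- S + matrix(rnorm(n * n, sd = noise_sigma), n, n)
    (S + t(S)) / 2
  })
}

#' Generate a synthetic dataset, optionally written to disk
#'
#' Produces \code{n_items} (sequence, structure) examples; when \code{dir}
#' is given, writes one multi-record FASTA, one BPSEQ file per record, and
#' a JSON manifest recording the configuration, so the dataset can be
#' re-read losslessly through the standard-format readers.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param dir optional output directory (created if missing).
#' @return List of records, each with \code{seq}, \code{struct} and
#'   \code{pseudoknotted}; when written, the file names are attached as
#'   attributes \code{"fasta"} and \code{"manifest"}.
#' @export
make_dataset <- function(cfg = synth_config(), dir = NULL) {
  records <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_items), function(k) {
      n <- sample_one(cfg$length_range[1L]:cfg$length_range[2L])
      struct <- sample_structure(n, pk_prob = cfg$pk_prob)
      seq <- sample_sequence(struct, gu_prob = cfg$gu_prob,
                             id = sprintf("synthetic_%03d", k))
      list(seq = seq, struct = struct,
           pseudoknotted = detect_pseudoknots(struct)$pseudoknotted)
    })
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fasta <- file.path(dir, "sequences.fasta")
    write_fasta(lapply(records, `[[`, "seq"), fasta)
    for (k in seq_along(records)) {
      write_bpseq(records[[k]]$seq, records[[k]]$struct,
                  file.path(dir, sprintf("%s.bpseq",
                                         records[[k]]$seq$id)))
    }
    manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(
      list(config = unclass(cfg),
           n_pseudoknotted = sum(vapply(records, `[[`, TRUE,
                                        "pseudoknotted")),
           files = c("sequences.fasta",
                     vapply(records, function(r)
                       sprintf("%s.bpseq", r$seq$id), ""))),
      manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    attr(records, "fasta") <- fasta
    attr(records, "manifest") <- manifest
  }
  records
}
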