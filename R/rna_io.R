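#' @importFrom stats rnorm runif predict
#' @importFrom utils modifyList head
NULL

RNA_ALPHABET <- c("A", "U", "C", "G", "N")

## One-hot row order is A, U, C, G; N encodes as the all-zero row.
ONE_HOT_ROWS <- rbind(
  A = c(1, 0, 0, 0),
  U = c(0, 1, 0, 0),
  C = c(0, 0, 1, 0),
  G = c(0, 0, 0, 1),
  N = c(0, 0, 0, 0)
)

#' Construct an RNA sequence object
#'
#' Holds a validated base string over the alphabet A/U/C/G/N. Positions are
#' 0-based internally; all file formats convert at the I/O boundary.
#'
#' @param bases character scalar over \code{A,U,C,G,N}.
#' @param id text label.
#' @return An object of class \code{rna_sequence} with fields \code{id},
#'   \code{bases} and \code{length}.
#' @export
rna_sequence <- function(bases, id = "seq") {
  stopifnot(is.character(bases), length(bases) == 1L)
  chars <- strsplit(bases, "")[[1]]
  if (length(chars) < 1L) stop("sequence must contain at least one base")
  bad <- setdiff(unique(chars), RNA_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid bases: ", paste(bad, collapse = ", "),
         " (normalize with parse_sequence())")
  }
  structure(list(id = as.character(id), bases = bases,
                 length = length(chars)),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)\n", x$id, x$length))
  cat(x$bases, "\n")
  invisible(x)
}

#' @export
length.rna_sequence <- function(x) x$length

#' Normalize raw text into an RNA sequence
#'
#' Uppercases, maps T to U (DNA-alphabet tolerance) and maps any remaining
#' character outside A/U/C/G to N with a warning, matching the encoder's
#' all-zero N row.
#'
#' @param text raw sequence string; surrounding whitespace is stripped.
#' @param id text label attached to the result.
#' @return An \code{\link{rna_sequence}}.
#' @export
parse_sequence <- function(text, id = "seq") {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (nchar(text) == 0L) stop("empty input: no sequence found")
  text <- toupper(text)
  text <- gsub("T", "U", text, fixed = TRUE)
  chars <- strsplit(text, "")[[1]]
  unknown <- !(chars %in% c("A", "U", "C", "G"))
  if (any(unknown)) {
    warning(sprintf("%d unknown character(s) (%s) mapped to N in '%s'",
                    sum(unknown),
                    paste(unique(chars[unknown]), collapse = ","), id))
    chars[unknown] <- "N"
  }
  rna_sequence(paste(chars, collapse = ""), id = id)
}

#' One-hot encode an RNA sequence
#'
#' @param seq an \code{\link{rna_sequence}}.
#' @return An N x 4 0/1 matrix; row i is the encoding of base i
#'   (columns A, U, C, G; base N gives an all-zero row).
#' @export
one_hot <- function(seq) {
  stopifnot(inherits(seq, "rna_sequence"))
  chars <- strsplit(seq$bases, "")[[1]]
  m <- ONE_HOT_ROWS[chars, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

## Canonicalize a pair set: integer matrix, two columns (i, j), 0-based,
## i < j, ordered by (i, j). Accepts a 2-column matrix, a list of length-2
## vectors, or NULL/empty.
as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) ||
      (is.list(pairs) && length(pairs) == 0L)) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  }
  if (is.list(pairs)) pairs <- do.call(rbind, lapply(pairs, as.integer))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  swap <- pairs[, 1L] > pairs[, 2L]
  if (any(swap)) pairs[swap, ] <- pairs[swap, c(2L, 1L)]
  if (any(pairs[, 1L] == pairs[, 2L])) stop("a base cannot pair with itself")
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

#' Construct a secondary structure
#'
#' A set of base pairs (i, j) with i < j over 0-based positions, each
#' position appearing in at most one pair. The equivalent representation is
#' the symmetric N x N 0/1 pairing matrix with row sums at most one, which
#' also expresses pseudoknots (crossing pairs) that single-tier dot-bracket
#' cannot.
#'
#' @param pairs two-column matrix (or list of length-2 vectors) of 0-based
#'   pair indices; may be empty.
#' @param length sequence length N.
#' @return An object of class \code{rna_structure} with fields \code{pairs}
#'   (canonical two-column integer matrix) and \code{length}.
#' @export
rna_structure <- function(pairs, length) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) > 0L) {
    idx <- as.vector(pairs)
    if (any(idx < 0L) || any(idx >= length))
      stop("pair index out of range [0, ", length - 1L, "]")
    if (anyDuplicated(idx))
      stop("a base may be paired at most once (duplicate index ",
           idx[duplicated(idx)][1L], ")")
  }
  structure(list(pairs = pairs, length = length), class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> N=%d, %d pair(s)%s\n", x$length,
              nrow(x$pairs),
              if (detect_pseudoknots(x)$pseudoknotted) ", pseudoknotted"
              else ""))
  invisible(x)
}

#' @export
length.rna_structure <- function(x) x$length

#' Convert a pair set to the symmetric pairing matrix
#'
#' @param pairs two-column 0-based pair matrix (or \code{rna_structure}).
#' @param n sequence length (ignored when \code{pairs} is a structure).
#' @return N x N symmetric 0/1 matrix with ones exactly at the listed pairs
#'   and their transposes.
#' @export
pairs_to_matrix <- function(pairs, n = NULL) {
  if (inherits(pairs, "rna_structure")) {
    n <- pairs$length
    pairs <- pairs$pairs
  } else {
    stopifnot(!is.null(n))
    pairs <- rna_structure(pairs, n)$pairs  # validates single pairing
  }
  m <- matrix(0, n, n)
  if (nrow(pairs) > 0L) {
    m[cbind(pairs[, 1L] + 1L, pairs[, 2L] + 1L)] <- 1
    m[cbind(pairs[, 2L] + 1L, pairs[, 1L] + 1L)] <- 1
  }
  m
}

#' Recover the pair set from a pairing matrix
#'
#' Inverse of \code{\link{pairs_to_matrix}}. The matrix must be a valid
#' pairing matrix: symmetric 0/1 with zero diagonal and row sums at most 1.
#'
#' @param m N x N matrix.
#' @return Two-column 0-based pair matrix (i < j).
#' @export
matrix_to_pairs <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!all(m %in% c(0, 1))) stop("pairing matrix must be 0/1")
  if (!isTRUE(all.equal(m, t(m)))) stop("pairing matrix must be symmetric")
  if (any(diag(m) != 0)) stop("pairing matrix must have a zero diagonal")
  if (any(rowSums(m) > 1)) stop("each base may be paired at most once")
  idx <- which(m == 1, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  as_pair_matrix(idx - 1L)
}

#' Detect pseudoknots (crossing base pairs)
#'
#' Two pairs (i, j) and (k, l) cross when i < k < j < l; a structure
#' containing any crossing is pseudoknotted and cannot be written in a
#' single dot-bracket tier.
#'
#' @param struct an \code{\link{rna_structure}}.
#' @return List with \code{pseudoknotted} (logical) and \code{crossings}
#'   (list of pairs of crossing base pairs, each a 2 x 2 matrix).
#' @export
detect_pseudoknots <- function(struct) {
  stopifnot(inherits(struct, "rna_structure"))
  p <- struct$pairs
  crossings <- list()
  np <- nrow(p)
  if (np >= 2L) {
    for (a in seq_len(np - 1L)) {
      for (b in (a + 1L):np) {
        i <- p[a, 1L]; j <- p[a, 2L]
        k <- p[b, 1L]; l <- p[b, 2L]
        if (i < k && k < j && j < l) {
          crossings[[length(crossings) + 1L]] <-
            rbind(p[a, ], p[b, ])
        }
      }
    }
  }
  list(pseudoknotted = length(crossings) > 0L, crossings = crossings)
}

# ---------------------------------------------------------------------------
# BPSEQ / CT  (1-based on disk, 0-based in memory)

#' Read a BPSEQ file
#'
#' BPSEQ lines are \code{index base partner} with 1-based indices and
#' partner 0 for unpaired positions. Mutual-partner consistency is enforced;
#' noncanonical pairs are accepted (reference structures are labels, not
#' predictions) but one-to-many pairing is rejected.
#'
#' @param path file path.
#' @param id label for the sequence; defaults to the file name.
#' @return List with \code{seq} (\code{rna_sequence}) and \code{struct}
#'   (\code{rna_structure}).
#' @export
read_bpseq <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nchar(lines) > 0 & !grepl("^#", lines)]
  if (length(lines) == 0L) stop("no BPSEQ records in ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop("malformed BPSEQ line ", which(nf != 3L)[1L], " in ", path)
  idx <- as.integer(vapply(fields, `[[`, "", 1L))
  base <- vapply(fields, `[[`, "", 2L)
  partner <- as.integer(vapply(fields, `[[`, "", 3L))
  n <- length(idx)
  if (!identical(idx, seq_len(n)))
    stop("BPSEQ indices must be 1..N without gaps (line ",
         which(idx != seq_len(n))[1L], ")")
  check_partner_column(partner, n, path)
  seq <- parse_sequence(paste(base, collapse = ""),
                        id = if (is.null(id)) basename(path) else id)
  pairs <- partner_to_pairs(partner)
  list(seq = seq, struct = rna_structure(pairs, n))
}

## partner: 1-based partner vector (0 = unpaired), already validated mutual.
partner_to_pairs <- function(partner) {
  i <- which(partner > 0 & seq_along(partner) < partner)
  if (length(i) == 0L) return(NULL)
  cbind(i - 1L, partner[i] - 1L)
}

check_partner_column <- function(partner, n, path) {
  bad <- which(partner < 0 | partner > n)
  if (length(bad) > 0L)
    stop("partner index out of range at line ", bad[1L], " in ", path)
  self <- which(partner == seq_len(n))
  if (length(self) > 0L)
    stop("base paired with itself at line ", self[1L], " in ", path)
  paired <- which(partner > 0)
  mutual <- partner[partner[paired]] == paired
  if (!all(mutual))
    stop("non-mutual partners at line ", paired[!mutual][1L], " in ", path)
  invisible(TRUE)
}

pairs_to_partner <- function(struct) {
  partner <- integer(struct$length)
  p <- struct$pairs
  if (nrow(p) > 0L) {
    partner[p[, 1L] + 1L] <- p[, 2L] + 1L
    partner[p[, 2L] + 1L] <- p[, 1L] + 1L
  }
  partner
}

#' Write a BPSEQ file
#'
#' @param seq an \code{\link{rna_sequence}}.
#' @param struct an \code{\link{rna_structure}} of the same length.
#' @param path output path.
#' @export
write_bpseq <- function(seq, struct, path) {
  stopifnot(seq$length == struct$length)
  partner <- pairs_to_partner(struct)
  chars <- strsplit(seq$bases, "")[[1]]
  writeLines(sprintf("%d %s %d", seq_len(seq$length), chars, partner), path)
  invisible(path)
}

#' Read a CT file
#'
#' CT dialect: a header line \code{N title}, then per-base lines
#' \code{i base i-1 i+1 partner i} (1-based, partner 0 = unpaired).
#'
#' @inheritParams read_bpseq
#' @return List with \code{seq} and \code{struct} as for
#'   \code{\link{read_bpseq}}.
#' @export
read_ct <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nchar(lines) > 0]
  if (length(lines) < 1L) stop("empty CT file ", path)
  header <- strsplit(lines[[1L]], "[[:space:]]+")[[1L]]
  n <- suppressWarnings(as.integer(header[[1L]]))
  if (is.na(n) || n < 1L) stop("bad CT header in ", path)
  if (length(lines) - 1L != n)
    stop("CT header declares ", n, " bases but file has ",
         length(lines) - 1L)
  fields <- strsplit(lines[-1L], "[[:space:]]+")
  if (any(lengths(fields) < 6L))
    stop("malformed CT line ", which(lengths(fields) < 6L)[1L] + 1L,
         " in ", path)
  idx <- as.integer(vapply(fields, `[[`, "", 1L))
  base <- vapply(fields, `[[`, "", 2L)
  partner <- as.integer(vapply(fields, `[[`, "", 5L))
  if (!identical(idx, seq_len(n)))
    stop("CT indices must be 1..N without gaps in ", path)
  check_partner_column(partner, n, path)
  seq_id <- if (is.null(id)) {
    if (length(header) > 1L) paste(header[-1L], collapse = " ")
    else basename(path)
  } else id
  seq <- parse_sequence(paste(base, collapse = ""), id = seq_id)
  list(seq = seq, struct = rna_structure(partner_to_pairs(partner), n))
}

#' Write a CT file
#'
#' @inheritParams write_bpseq
#' @export
write_ct <- function(seq, struct, path) {
  stopifnot(seq$length == struct$length)
  n <- seq$length
  partner <- pairs_to_partner(struct)
  chars <- strsplit(seq$bases, "")[[1]]
  lines <- c(sprintf("%d %s", n, seq$id),
             sprintf("%d %s %d %d %d %d", seq_len(n), chars,
                     seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                     partner, seq_len(n)))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA (via Biostrings)

#' Read a multi-record FASTA file of RNA sequences
#'
#' @param path file path.
#' @return List of \code{\link{rna_sequence}} objects (normalized through
#'   \code{\link{parse_sequence}}, so DNA alphabets are tolerated).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- vector("list", length(set))
  ids <- names(set)
  for (k in seq_along(set)) {
    out[[k]] <- parse_sequence(as.character(set[[k]]), id = ids[[k]])
  }
  out
}

#' Write RNA sequences to a multi-record FASTA file
#'
#' @param seqs a single \code{\link{rna_sequence}} or a list of them.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  set <- Biostrings::BStringSet(vapply(seqs, `[[`, "", "bases"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Extended dot-bracket (multiple tiers for pseudoknots)

BRACKET_OPEN  <- c("(", "[", "{", "<", LETTERS)
BRACKET_CLOSE <- c(")", "]", "}", ">", letters)

#' Render a structure in extended dot-bracket notation
#'
#' Crossing pairs are assigned greedily (by ascending opening index) to the
#' lowest bracket tier in which they cross nothing already placed; nested
#' structures use only \code{()}, pseudoknots overflow into
#' \code{[], \{\}, <>, Aa...}.
#'
#' @param struct an \code{\link{rna_structure}}.
#' @return A dot-bracket string of length N.
#' @export
to_dotbracket <- function(struct) {
  stopifnot(inherits(struct, "rna_structure"))
  p <- struct$pairs
  out <- rep(".", struct$length)
  if (nrow(p) == 0L) return(paste(out, collapse = ""))
  tiers <- list()  # each a matrix of pairs already placed
  assign_tier <- integer(nrow(p))
  for (a in seq_len(nrow(p))) {   # pairs are sorted by ascending i
    i <- p[a, 1L]; j <- p[a, 2L]
    placed <- FALSE
    for (t in seq_along(tiers)) {
      tp <- tiers[[t]]
      crosses <- (tp[, 1L] < i & i < tp[, 2L] & tp[, 2L] < j) |
                 (i < tp[, 1L] & tp[, 1L] < j & j < tp[, 2L])
      if (!any(crosses)) {
        tiers[[t]] <- rbind(tp, p[a, ]); assign_tier[a] <- t
        placed <- TRUE; break
      }
    }
    if (!placed) {
      tiers[[length(tiers) + 1L]] <- p[a, , drop = FALSE]
      assign_tier[a] <- length(tiers)
    }
  }
  if (length(tiers) > length(BRACKET_OPEN))
    stop("structure needs ", length(tiers), " bracket tiers; only ",
         length(BRACKET_OPEN), " supported")
  for (a in seq_len(nrow(p))) {
    t <- assign_tier[a]
    out[p[a, 1L] + 1L] <- BRACKET_OPEN[t]
    out[p[a, 2L] + 1L] <- BRACKET_CLOSE[t]
  }
  paste(out, collapse = "")
}

#' Parse extended dot-bracket notation
#'
#' Accepts the tiers \code{(), [], \{\}, <>} and \code{Aa}..\code{Zz}.
#' Minimum-distance and canonical-pair rules are deliberately not enforced
#' here: parsed structures are labels, and only the prediction path applies
#' hard constraints.
#'
#' @param text dot-bracket string.
#' @return An \code{\link{rna_structure}}.
#' @export
from_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(trimws(text), "")[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty dot-bracket string")
  stacks <- vector("list", length(BRACKET_OPEN))
  pairs <- list()
  for (pos in seq_len(n)) {
    ch <- chars[[pos]]
    if (ch == ".") next
    t <- match(ch, BRACKET_OPEN)
    if (!is.na(t)) {
      stacks[[t]] <- c(stacks[[t]], pos - 1L)
      next
    }
    t <- match(ch, BRACKET_CLOSE)
    if (is.na(t)) stop("unknown character '", ch, "' at position ", pos)
    st <- stacks[[t]]
    if (length(st) == 0L)
      stop("unbalanced '", ch, "' at position ", pos)
    pairs[[length(pairs) + 1L]] <- c(st[[length(st)]], pos - 1L)
    stacks[[t]] <- st[-length(st)]
  }
  open_left <- which(lengths(stacks) > 0L)
  if (length(open_left) > 0L)
    stop("unbalanced '", BRACKET_OPEN[open_left[1L]], "': ",
         lengths(stacks)[open_left[1L]], " unclosed")
  rna_structure(pairs, n)
}
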