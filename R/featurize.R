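# Input encoding: lift the N x 4 one-hot matrix to d dimensions with a 1-D
# convolution along the sequence, and add a position embedding projected
# from the absolute (1..N) and relative (i/N) base positions.

#' Position embedding for a sequence of length N
#'
#' The absolute positions are 1..N and the relative positions i/N; the
#' two-column position matrix is lifted to N x d by a learned linear map so
#' it can be added to the sequence encoding. With \code{params = NULL} a
#' fresh seeded projection is drawn.
#'
#' @param n sequence length.
#' @param d feature dimension (must exceed 4, the one-hot width).
#' @param params list with \code{W} (2 x d) and \code{b} (length d); if
#'   \code{NULL}, initialized from \code{seed}.
#' @param seed RNG seed used only when \code{params} is \code{NULL}.
#' @return List of class \code{position_embedding} with \code{pos_bas},
#'   \code{pos_rel}, \code{projected} (N x d) and \code{params}.
#' @export
position_embedding <- function(n, d, params = NULL, seed = 1L) {
  stopifnot(n >= 1L)
  if (d <= 4L) stop("feature dimension d must exceed 4, got ", d)
  if (is.null(params)) params <- init_position_params(d, seed)
  stopifnot(identical(dim(params$W), c(2L, as.integer(d))))
  pos_bas <- as.numeric(seq_len(n))
  pos_rel <- pos_bas / n
  pf <- linear_forward(cbind(pos_bas, pos_rel), params$W, params$b)
  structure(list(pos_bas = pos_bas, pos_rel = pos_rel,
                 projected = pf$out, params = params),
            class = "position_embedding")
}

init_position_params <- function(d, seed = 1L) {
  with_seed(seed, list(W = glorot(2L, d), b = numeric(d)))
}

#' Lift a one-hot encoding to d dimensions
#'
#' Applies a 1-D convolution over the length axis (same padding), producing
#' per-position d-dimensional features; output length always equals N.
#'
#' @param onehot N x 4 one-hot matrix from \code{\link{one_hot}}.
#' @param params list with \code{W} ((kw*4) x d) and \code{b} (length d);
#'   if \code{NULL}, initialized from \code{seed}.
#' @param kw odd kernel width (default 3).
#' @param d feature dimension used when initializing fresh params.
#' @param seed RNG seed used only when \code{params} is \code{NULL}.
#' @return N x d numeric matrix with the parameters attached as an
#'   attribute \code{"params"}.
#' @export
lift_encoding <- function(onehot, params = NULL, kw = 3L, d = 64L,
                          seed = 1L) {
  stopifnot(is.matrix(onehot), ncol(onehot) == 4L)
  if (is.null(params)) params <- init_lift_params(d, kw, seed)
  kw <- nrow(params$W) %/% 4L
  out <- conv1d_forward(onehot, params$W, params$b, kw)$out
  attr(out, "params") <- params
  out
}

init_lift_params <- function(d, kw = 3L, seed = 1L) {
  with_seed(seed, list(W = glorot(kw * 4L, d), b = numeric(d)))
}

#' Assemble the model input encoding
#'
#' Elementwise sum of the lifted sequence encoding and the projected
#' position embedding; both must be N x d.
#'
#' @param lifted N x d matrix from \code{\link{lift_encoding}}.
#' @param pos a \code{\link{position_embedding}} (or an N x d matrix).
#' @return N x d numeric matrix.
#' @export
assemble_input <- function(lifted, pos) {
  proj <- if (inherits(pos, "position_embedding")) pos$projected else pos
  if (!identical(dim(lifted), dim(proj)))
    stop("shape mismatch: lifted is ", paste(dim(lifted), collapse = "x"),
         ", position embedding is ", paste(dim(proj), collapse = "x"))
  unname(lifted + proj)
}
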