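# Parameter optimization of the encoder-decoder against true pairing
# matrices, with periodic F1 tracking through the full decode pipeline.
# Sequences are processed one at a time (no padding); a batch is a
# gradient-accumulation group. Optimizer is Adam.

#' Training configuration
#'
#' @param epochs number of passes over the training set.
#' @param batch_size gradient-accumulation group size B.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for shuffling (and any split).
#' @param loss_mode \code{"masked_bce"}: binary cross-entropy between
#'   sigmoid(S) and the true pairing matrix over constraint-allowed cells;
#'   \code{"objective_based"}: the decoding objective evaluated at the true
#'   structure (its fit term only, since valid structures incur no
#'   penalty).
#' @param pos_weight weight on paired cells in the masked BCE
#'   (\code{"auto"} balances classes per sequence; paired cells are a small
#'   minority of allowed cells).
#' @param max_len sequences longer than this are rejected from training.
#' @param val_fraction fraction of the dataset held out for validation
#'   (0 trains on everything and tracks the training-set F1 instead).
#' @param eval_every compute decoded F1 every this many epochs (and at the
#'   final epoch); decoding is much dearer than a gradient step.
#' @param decode decode configuration used for F1 tracking.
#' @return List of class \code{train_config}.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L,
                         learning_rate = 1e-3, seed = 1L,
                         loss_mode = c("masked_bce", "objective_based"),
                         pos_weight = "auto", max_len = 512L,
                         val_fraction = 0, eval_every = 10L,
                         decode = decode_config()) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 loss_mode = loss_mode, pos_weight = pos_weight,
                 max_len = as.integer(max_len),
                 val_fraction = val_fraction,
                 eval_every = as.integer(eval_every), decode = decode),
            class = "train_config")
}

#' Training loss on a score matrix
#'
#' @param S N x N score matrix from \code{\link{model_forward}}.
#' @param truth the reference \code{\link{rna_structure}}.
#' @param masks constraint masks (list with \code{m1}, \code{m2}) for the
#'   sequence; only cells with \code{m1 * m2 = 1} enter the masked BCE.
#' @param mode \code{"masked_bce"} or \code{"objective_based"}.
#' @param pos_weight numeric weight for paired cells, or \code{"auto"}.
#' @param decode decode configuration (supplies the threshold for the
#'   objective-based loss).
#' @return List with \code{loss} (scalar) and \code{dS} (gradient).
#' @export
training_loss <- function(S, truth, masks, mode = "masked_bce",
                          pos_weight = "auto",
                          decode = decode_config()) {
  y <- pairs_to_matrix(truth)
  if (mode == "objective_based") {
    # penalty terms vanish on a valid structure; fit term only
    fit <- -0.5 * sum((S - decode$s) * y)
    return(list(loss = fit, dS = -0.5 * y))
  }
  mask <- masks$m1 * masks$m2
  wpos <- if (identical(pos_weight, "auto")) {
    npos <- sum(mask * y)
    if (npos > 0) max(1, (sum(mask) - npos) / npos) else 1
  } else pos_weight
  wts <- mask * (1 + (wpos - 1) * y)
  denom <- sum(wts)
  if (denom == 0) return(list(loss = 0, dS = S * 0))
  p <- sigmoid(S)
  eps <- 1e-12
  loss <- -sum(wts * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) /
    denom
  list(loss = loss, dS = wts * (p - y) / denom)
}

# --- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                  state$m, state$v)
  list(params = tree_map(`-`, params, upd), state = state)
}

# --- training loop ------------------------------------------------------

eval_f1 <- function(records, params, model_cfg, decode_cfg) {
  counts <- lapply(records, function(r) {
    S <- model_forward(r$seq, params, model_cfg)
    count_confusion_2d(constrained_decode(S, r$seq, decode_cfg), r$struct)
  })
  aggregate_metrics(counts)$f1[1L]
}

#' Train the encoder-decoder on (sequence, structure) pairs
#'
#' Full-batch-shuffled mini-batch training with Adam and analytic
#' backpropagation. Every \code{eval_every} epochs the current model is run
#' through the full pipeline (forward, constrained decode, 2-D F1) on the
#' training set and, when a validation split is configured, on the held-out
#' set; the parameters with the best tracked F1 are retained as the final
#' model.
#'
#' @param dataset list of records with \code{seq} and \code{struct} (as
#'   produced by \code{\link{make_dataset}}).
#' @param model_cfg a \code{\link{model_config}}.
#' @param cfg a \code{\link{train_config}}.
#' @param params optional initial parameter tree (resume training).
#' @param quiet suppress per-epoch progress lines.
#' @return List of class \code{pairfold_model}: \code{params} (best),
#'   \code{final_params}, \code{model_cfg}, \code{train_cfg}, \code{log}
#'   (data frame epoch/loss/train_f1/val_f1) and \code{best_epoch}.
#' @export
train <- function(dataset, model_cfg = model_config(),
                  cfg = train_config(), params = NULL, quiet = TRUE) {
  stopifnot(length(dataset) > 0)
  over <- vapply(dataset, function(r) r$seq$length > cfg$max_len, TRUE)
  if (any(over)) {
    warning(sum(over), " sequence(s) over the length filter (",
            cfg$max_len, ") excluded from training")
    dataset <- dataset[!over]
  }
  stopifnot(length(dataset) > 0)
  masks <- lapply(dataset, function(r) constraint_masks(r$seq))
  if (is.null(params)) params <- init_model_params(model_cfg)
  state <- adam_init(params)
  n <- length(dataset)
  n_val <- floor(cfg$val_fraction * n)
  with_seed(cfg$seed, {
    idx <- shuffle(seq_len(n))
    val_idx <- head(idx, n_val)
    train_idx <- setdiff(idx, val_idx)
    log <- data.frame(epoch = integer(0), loss = numeric(0),
                      train_f1 = numeric(0), val_f1 = numeric(0))
    best <- list(f1 = -Inf, params = params, epoch = 0L)
    for (epoch in seq_len(cfg$epochs)) {
      order <- shuffle(train_idx)
      batches <- split(order, ceiling(seq_along(order) / cfg$batch_size))
      epoch_loss <- 0
      for (batch in batches) {
        acc <- NULL
        for (k in batch) {
          fw <- model_forward(dataset[[k]]$seq, params, model_cfg,
                              want_cache = TRUE)
          ls <- training_loss(fw$S, dataset[[k]]$struct, masks[[k]],
                              mode = cfg$loss_mode,
                              pos_weight = cfg$pos_weight,
                              decode = cfg$decode)
          if (!is.finite(ls$loss))
            stop("training diverged (non-finite loss) at epoch ", epoch,
                 ", sequence ", dataset[[k]]$seq$id)
          epoch_loss <- epoch_loss + ls$loss
          g <- model_backward(ls$dS, fw$cache)
          acc <- if (is.null(acc)) g else tree_add(acc, g)
        }
        acc <- tree_scale(acc, 1 / length(batch))
        st <- adam_step(params, acc, state, cfg$learning_rate)
        params <- st$params
        state <- st$state
      }
      epoch_loss <- epoch_loss / length(train_idx)
      do_eval <- epoch %% cfg$eval_every == 0L || epoch == cfg$epochs
      tf1 <- vf1 <- NA_real_
      if (do_eval) {
        tf1 <- eval_f1(dataset[train_idx], params, model_cfg, cfg$decode)
        if (n_val > 0)
          vf1 <- eval_f1(dataset[val_idx], params, model_cfg, cfg$decode)
        track <- if (n_val > 0) vf1 else tf1
        if (track > best$f1)
          best <- list(f1 = track, params = params, epoch = epoch)
        if (!quiet)
          message(sprintf("epoch %d  loss %.4f  train F1 %.3f  val F1 %s",
                          epoch, epoch_loss, tf1,
                          ifelse(is.na(vf1), "-", sprintf("%.3f", vf1))))
      }
      log <- rbind(log, data.frame(epoch = epoch, loss = epoch_loss,
                                   train_f1 = tf1, val_f1 = vf1))
    }
    structure(list(params = best$params, final_params = params,
                   model_cfg = model_cfg, train_cfg = cfg, log = log,
                   best_epoch = best$epoch, best_f1 = best$f1),
              class = "pairfold_model")
  })
}

#' @export
print.pairfold_model <- function(x, ...) {
  cat(sprintf(
    "<pairfold_model> d=%d blocks=%d; best epoch %d (tracked F1 %.3f)\n",
    x$model_cfg$d, x$model_cfg$n_blocks, x$best_epoch, x$best_f1))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file embedding the parameters and both
#' configurations.
#'
#' @param model a \code{pairfold_model}.
#' @param path file path.
#' @return \code{load_checkpoint} returns the \code{pairfold_model}.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pairfold_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "pairfold_model"))
  model
}

#' Predict secondary structures for new sequences
#'
#' Runs the score network and the hard-constraint decoder on each
#' sequence; sequences over the model's length filter are skipped with a
#' warning.
#'
#' @param object a trained \code{pairfold_model}.
#' @param sequences a single \code{\link{rna_sequence}} or a list of them.
#' @param decode a \code{\link{decode_config}}.
#' @param ... unused.
#' @return List of results, one per accepted sequence, each with
#'   \code{seq}, \code{struct}, \code{scores} (the N x N matrix),
#'   \code{dotbracket} and \code{pseudoknotted}.
#' @export
predict.pairfold_model <- function(object, sequences,
                                   decode = decode_config(), ...) {
  if (inherits(sequences, "rna_sequence")) sequences <- list(sequences)
  out <- list()
  for (seq in sequences) {
    if (seq$length > object$model_cfg$max_len) {
      warning("skipping ", seq$id, ": length ", seq$length,
              " exceeds the length filter (", object$model_cfg$max_len,
              ")")
      next
    }
    S <- model_forward(seq, object$params, object$model_cfg)
    struct <- constrained_decode(S, seq, decode)
    out[[length(out) + 1L]] <-
      list(seq = seq, struct = struct, scores = S,
           dotbracket = to_dotbracket(struct),
           pseudoknotted = detect_pseudoknots(struct)$pseudoknotted)
  }
  out
}
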