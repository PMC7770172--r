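# Structure evaluation: confusion counts and SEN/PPV/F1, in the exact
# base-pair (2-D matrix) mode and the traditional per-base paired-status
# (1-D vector) mode, plus per-family aggregation. TN is counted but never
# enters a headline score: unpaired cells dominate any pairing matrix.

pair_keys <- function(struct) {
  p <- struct$pairs
  if (nrow(p) == 0L) return(character(0))
  paste(p[, 1L], p[, 2L], sep = ":")
}

new_metric_counts <- function(tp, fn, fp, tn, mode, n) {
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 mode = mode, n = as.integer(n)),
            class = "metric_counts")
}

#' Confusion counts over exact base pairs (2-D matrix mode)
#'
#' Compares unordered position pairs (i < j): a predicted pair counts as
#' true positive only when the reference pairs exactly the same two
#' positions. The universe is the N(N-1)/2 upper-triangle cells.
#'
#' @param pred,truth \code{\link{rna_structure}} objects of equal length.
#' @return A \code{metric_counts} object (tp, fn, fp, tn).
#' @export
count_confusion_2d <- function(pred, truth) {
  stopifnot(inherits(pred, "rna_structure"),
            inherits(truth, "rna_structure"))
  if (pred$length != truth$length)
    stop("structure lengths differ: ", pred$length, " vs ", truth$length)
  n <- pred$length
  kp <- pair_keys(pred)
  kt <- pair_keys(truth)
  tp <- length(intersect(kp, kt))
  fp <- length(setdiff(kp, kt))
  fn <- length(setdiff(kt, kp))
  cells <- n * (n - 1) / 2
  new_metric_counts(tp, fn, fp, cells - tp - fp - fn, "matrix2d", n)
}

paired_status <- function(struct) {
  s <- logical(struct$length)
  idx <- as.vector(struct$pairs)
  s[idx + 1L] <- TRUE
  s
}

#' Confusion counts over per-base paired status (1-D vector mode)
#'
#' Each position is scored paired/unpaired with the partner identity
#' ignored, the traditional scoring that systematically flatters
#' predictions relative to the exact-pair 2-D mode: partner agreement
#' implies status agreement but not conversely.
#'
#' @inheritParams count_confusion_2d
#' @return A \code{metric_counts} object.
#' @export
count_confusion_1d <- function(pred, truth) {
  stopifnot(inherits(pred, "rna_structure"),
            inherits(truth, "rna_structure"))
  if (pred$length != truth$length)
    stop("structure lengths differ: ", pred$length, " vs ", truth$length)
  sp <- paired_status(pred)
  st <- paired_status(truth)
  new_metric_counts(sum(sp & st), sum(!sp & st), sum(sp & !st),
                    sum(!sp & !st), "vector1d", pred$length)
}

#' F1 score from sensitivity and positive predictive value
#'
#' The harmonic mean \code{2 * sen * ppv / (sen + ppv)} (0 when both are
#' zero).
#'
#' @param sen,ppv values in [0, 1].
#' @return F1 in [0, 1].
#' @export
f1_score <- function(sen, ppv) {
  ifelse(sen + ppv > 0, 2 * sen * ppv / (sen + ppv), 0)
}

#' SEN/PPV/F1 from confusion counts
#'
#' \code{SEN = TP/(TP+FN)}, \code{PPV = TP/(TP+FP)}, F1 their harmonic
#' mean. Degenerate-denominator conventions: an empty prediction of an
#' empty reference is perfect (scores 1); a denominator that is zero while
#' the other error type is present scores 0.
#'
#' @param counts a \code{metric_counts} object.
#' @return A \code{metric_report} list with \code{sen}, \code{ppv},
#'   \code{f1}, \code{mode}, \code{n_structures} and the counts.
#' @export
scores <- function(counts) {
  stopifnot(inherits(counts, "metric_counts"))
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp
  sen <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else 0
  ppv <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
  structure(list(sen = sen, ppv = ppv, f1 = f1_score(sen, ppv),
                 mode = counts$mode, n_structures = 1L, counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> mode=%s n=%d  SEN=%.4f PPV=%.4f F1=%.4f\n",
              x$mode, x$n_structures, x$sen, x$ppv, x$f1))
  invisible(x)
}

#' Aggregate evaluation results per family and overall
#'
#' Two strategies: \code{mean_per_structure} averages each structure's
#' SEN/PPV/F1 within a family (every structure weighted equally);
#' \code{pooled_counts} sums the confusion counts first and scores the
#' pooled table. Structures with a missing family label are grouped under
#' \code{"other"}.
#'
#' @param counts_list list of \code{metric_counts}, one per structure (all
#'   the same mode).
#' @param by optional character vector of family labels, recycled names
#'   \code{NA} -> \code{"other"}.
#' @param strategy aggregation strategy.
#' @return A data frame with one row per family plus an \code{"overall"}
#'   row: columns \code{family}, \code{n_structures}, \code{sen},
#'   \code{ppv}, \code{f1}.
#' @export
aggregate_metrics <- function(counts_list, by = NULL,
                              strategy = c("mean_per_structure",
                                           "pooled_counts")) {
  strategy <- match.arg(strategy)
  stopifnot(length(counts_list) > 0)
  if (is.null(by)) by <- rep("all", length(counts_list))
  by <- as.character(by)
  by[is.na(by) | !nzchar(by)] <- "other"
  stopifnot(length(by) == length(counts_list))
  groups <- c(split(seq_along(counts_list), by),
              list(overall = seq_along(counts_list)))
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (strategy == "mean_per_structure") {
      reps <- lapply(counts_list[idx], scores)
      data.frame(family = g, n_structures = length(idx),
                 sen = mean(vapply(reps, `[[`, 0, "sen")),
                 ppv = mean(vapply(reps, `[[`, 0, "ppv")),
                 f1 = mean(vapply(reps, `[[`, 0, "f1")))
    } else {
      tot <- new_metric_counts(
        sum(vapply(counts_list[idx], `[[`, 0L, "tp")),
        sum(vapply(counts_list[idx], `[[`, 0L, "fn")),
        sum(vapply(counts_list[idx], `[[`, 0L, "fp")),
        sum(vapply(counts_list[idx], `[[`, 0L, "tn")),
        counts_list[[idx[1L]]]$mode, 0L)
      rep <- scores(tot)
      data.frame(family = g, n_structures = length(idx),
                 sen = rep$sen, ppv = rep$ppv, f1 = rep$f1)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an evaluation table as TSV and/or JSON
#'
#' @param df data frame from \code{\link{aggregate_metrics}}.
#' @param tsv,json optional output paths.
#' @export
write_evaluation <- function(df, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(df, json, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  invisible(df)
}
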