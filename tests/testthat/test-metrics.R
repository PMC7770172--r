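test_that("2-D counts compare exact partners", {
  truth <- rna_structure(rbind(c(0, 7), c(1, 6), c(2, 5)), 10)
  same <- count_confusion_2d(truth, truth)
  expect_equal(c(same$tp, same$fp, same$fn), c(3, 0, 0))
  expect_equal(same$tp + same$fn + same$fp + same$tn, 45)  # C(10,2)
  # a one-off partner is wrong in 2-D mode
  pred <- rna_structure(rbind(c(0, 7)), 8)
  ref <- rna_structure(rbind(c(0, 6)), 8)
  c2 <- count_confusion_2d(pred, ref)
  expect_equal(c(c2$tp, c2$fp, c2$fn), c(0, 1, 1))
  empty <- count_confusion_2d(rna_structure(NULL, 9),
                              rna_structure(rbind(c(0, 5), c(1, 7)), 9))
  expect_equal(c(empty$tp, empty$fn, empty$fp), c(0, 2, 0))
  expect_error(count_confusion_2d(pred, rna_structure(NULL, 9)),
               "lengths differ")
})

test_that("1-D counts compare paired status only", {
  pred <- rna_structure(rbind(c(0, 7)), 8)
  ref <- rna_structure(rbind(c(0, 6)), 8)
  c1 <- count_confusion_1d(pred, ref)
  # position 0 paired in both; 7 predicted only; 6 reference only
  expect_equal(c(c1$tp, c1$fp, c1$fn, c1$tn), c(1, 1, 1, 5))
  same <- count_confusion_1d(ref, ref)
  expect_equal(c(same$fp, same$fn), c(0, 0))
})

test_that("scores implement SEN, PPV and their harmonic mean", {
  cts <- pairfold:::new_metric_counts(3, 1, 1, 40, "matrix2d", 10)
  rep <- scores(cts)
  expect_equal(c(rep$sen, rep$ppv, rep$f1), c(0.75, 0.75, 0.75))
  # published-precision spot check: harmonic mean of 0.972/0.961
  expect_equal(round(f1_score(0.961, 0.972), 3), 0.966)
  # conventions on empty structures
  blank <- scores(pairfold:::new_metric_counts(0, 0, 0, 45, "matrix2d",
                                               10))
  expect_equal(c(blank$sen, blank$ppv, blank$f1), c(1, 1, 1))
  fp_only <- scores(pairfold:::new_metric_counts(0, 0, 2, 43, "matrix2d",
                                                 10))
  expect_equal(fp_only$sen, 0)
  expect_equal(fp_only$f1, 0)
})

test_that("F1 bounds hold for arbitrary counts", {
  for (k in 1:50) {
    with_seed_local(k, {
      tp <- sample(0:20, 1); fn <- sample(0:20, 1); fp <- sample(0:20, 1)
      r <- scores(pairfold:::new_metric_counts(tp, fn, fp, 5,
                                               "matrix2d", 40))
      expect_equal(r$f1, f1_score(r$sen, r$ppv))
      expect_lte(r$f1, (r$sen + r$ppv) / 2 + 1e-12)
      expect_lte(r$f1, 2 * min(r$sen, r$ppv) + 1e-12)
    })
  }
})

test_that("2-D F1 is 1 exactly when the pair sets coincide", {
  for (k in 1:20) {
    ex <- random_example(k)
    perfect <- scores(count_confusion_2d(ex$struct, ex$struct))
    expect_equal(perfect$f1, 1)
    if (nrow(ex$struct$pairs) > 1) {
      damaged <- rna_structure(ex$struct$pairs[-1, , drop = FALSE],
                               ex$struct$length)
      expect_lt(scores(count_confusion_2d(damaged, ex$struct))$f1, 1)
    }
  }
})

test_that("1-D F1 dominates 2-D F1 on every structure pair", {
  for (k in 1:60) {
    n <- 15 + (k %% 26)
    truth <- sample_structure(n, pk_prob = 0.3, seed = 70000 + k)
    pred <- sample_structure(n, pk_prob = 0.3, seed = 71000 + k)
    f2 <- scores(count_confusion_2d(pred, truth))$f1
    f1 <- scores(count_confusion_1d(pred, truth))$f1
    expect_gte(f1, f2 - 1e-12)
  }
})

test_that("aggregation strategies agree on single structures and pool", {
  truth <- rna_structure(rbind(c(0, 7), c(1, 6)), 12)
  miss <- rna_structure(NULL, 12)
  cts <- list(count_confusion_2d(truth, truth),
              count_confusion_2d(miss, truth))
  single <- aggregate_metrics(cts[1])
  expect_equal(single$f1, rep(1, 2))  # family row + overall row
  means <- aggregate_metrics(cts, by = c("fam", "fam"))
  expect_equal(means$f1[means$family == "fam"], 0.5)
  pooled <- aggregate_metrics(cts, by = c("fam", "fam"),
                              strategy = "pooled_counts")
  tot <- pairfold:::new_metric_counts(2, 2, 0, 0, "matrix2d", 0)
  expect_equal(pooled$f1[pooled$family == "fam"], scores(tot)$f1)
  # missing labels fall into "other"
  lab <- aggregate_metrics(cts, by = c("fam", NA))
  expect_true("other" %in% lab$family)
})

test_that("evaluation tables are written as TSV and JSON", {
  cts <- list(count_confusion_2d(rna_structure(rbind(c(0, 5)), 8),
                                 rna_structure(rbind(c(0, 5)), 8)))
  df <- aggregate_metrics(cts, by = "tRNA")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_evaluation(df, tsv = tsv, json = js)
  back <- utils::read.delim(tsv)
  expect_equal(back$f1, df$f1)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$f1, df$f1)
})
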