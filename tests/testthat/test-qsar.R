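test_that("activity labelling follows the endpoint thresholds", {
  lab <- function(type, v) {
    label_activity(activity_record(type, v))$activity_class
  }
  expect_equal(lab("percent_inhibition", 60), "A")
  expect_equal(lab("percent_inhibition", 52), "B")   # strict >
  expect_equal(lab("IC50", 25), "A")                 # inclusive <=
  expect_equal(lab("IC50", 25.1), "B")
  expect_equal(lab("EC50", 1), "A")
  expect_error(label_activity(activity_record("IC50", 10, units = "mM")),
               "units")
  expect_error(activity_record("IC50", -1), ">= 0")
})

synthetic_labelled_records <- function(nA, nB) {
  c(
    lapply(seq_len(nA), function(i) {
      molecule_record(mk_mol(sprintf("A%03d", i), "C", empty_bonds()),
                      activity = label_activity(activity_record("IC50", 5)))
    }),
    lapply(seq_len(nB), function(i) {
      molecule_record(mk_mol(sprintf("B%03d", i), "C", empty_bonds()),
                      activity = label_activity(activity_record("IC50", 80)))
    })
  )
}

test_that("stratified split reproduces the 127/14 class composition", {
  recs <- synthetic_labelled_records(63, 78)
  sp <- stratified_split(recs, c(A = 6, B = 8), seed = 11)
  expect_length(sp$test_ids, 14)
  expect_length(sp$train_ids, 127)
  expect_equal(unname(sp$train_counts), c(57, 70))
  expect_equal(unname(sp$test_counts), c(6, 8))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  sp2 <- stratified_split(recs, c(A = 6, B = 8), seed = 11)
  expect_identical(sp$test_ids, sp2$test_ids)
  expect_false(identical(
    sp$test_ids, stratified_split(recs, c(A = 6, B = 8), seed = 12)$test_ids))
  expect_error(stratified_split(recs, c(A = 100, B = 0), seed = 1),
               "class A")
})

test_that("metric engine matches printed benchmark rows", {
  m <- compute_metrics(confusion_counts(TP = 41, TN = 53, FN = 16, FP = 17))
  expect_equal(round(m$SE, 3), 0.719)
  expect_equal(round(m$SP, 3), 0.757)
  expect_equal(round(m$Q, 3), 0.740)
  expect_equal(round(m$MCC, 3), 0.476)

  m2 <- compute_metrics(confusion_counts(TP = 40, TN = 53, FN = 17, FP = 17))
  expect_equal(round(m2$Q, 3), 0.732)
  expect_equal(round(m2$MCC, 3), 0.459)

  ## symmetric counts: chance level
  m3 <- compute_metrics(confusion_counts(7, 7, 7, 7))
  expect_equal(m3$MCC, 0)
  expect_equal(m3$Q, 0.5)

  ## undefined flags on single-class predictions
  m4 <- compute_metrics(confusion_counts(TP = 5, TN = 0, FP = 0, FN = 0))
  expect_true(all(c("SP", "MCC") %in% m4$undefined))
  expect_error(confusion_counts(0, 0, 0, 0), "zero")
})

test_that("counts invert from printed rates and round-trip", {
  c1 <- counts_from_rates(0.842, 0.786, 57, 70)
  expect_equal(unlist(c1[c("TP", "TN", "FN", "FP")]),
               c(TP = 48, TN = 55, FN = 9, FP = 15))
  c2 <- counts_from_rates(0.667, 0.750, 6, 8)
  expect_equal(unlist(c2[c("TP", "TN", "FN", "FP")]),
               c(TP = 4, TN = 6, FN = 2, FP = 2))
  c3 <- counts_from_rates(1, 1, 5, 5)
  expect_equal(c3$FP + c3$FN, 0)
  expect_error(counts_from_rates(0.830, 0.5, 6, 8), "no integer")

  ## inversion composed with the metric engine is the identity
  for (s in 1:25) {
    tp <- withr::with_seed(s, sample(0:57, 1))
    tn <- withr::with_seed(s + 99, sample(0:70, 1))
    cc <- confusion_counts(TP = tp, TN = tn, FP = 70 - tn, FN = 57 - tp)
    mm <- compute_metrics(cc)
    back <- counts_from_rates(round(mm$SE, 3), round(mm$SP, 3), 57, 70)
    expect_equal(unlist(back[c("TP", "TN")]), c(TP = tp, TN = tn))
  }
})

test_that("cluster-wise metrics mirror the per-cluster protocol", {
  pred <- c("A", "A", "A", "B", "A", "B")
  truth <- c("A", "A", "B", "B", "A", "A")
  cl <- c("I", "I", "II", "II", "II", "I")
  out <- clusterwise_metrics(pred, truth, cl)
  expect_named(out, c("I", "II"))
  ## cluster I: all three truly active, two predicted active
  expect_equal(out[["I"]]$SE, 2 / 3)
  expect_true("SP" %in% out[["I"]]$undefined)
  ## union of per-cluster counts equals the overall counts
  tot <- compute_metrics(confusion_from_predictions(pred, truth))$counts
  agg <- Reduce(`+`, lapply(out, function(m) unlist(m$counts)))
  expect_equal(agg, unlist(tot))

  ## single-class cluster with perfect prediction: SE 1, SP undefined
  allA <- clusterwise_metrics(rep("A", 11), rep("A", 11), rep("I", 11))
  expect_equal(allA[["I"]]$SE, 1)
  expect_equal(allA[["I"]]$Q, 1)
  expect_true("SP" %in% allA[["I"]]$undefined)
})

test_that("balanced RF uses minority-class sampling and is reproducible", {
  lib <- planted_library(1, n = 200)
  ## emulate the 57/70 imbalance on a subset
  idxA <- which(lib$y == "A")[1:57]
  idxB <- which(lib$y == "B")[1:70]
  sel <- c(idxA, idxB)
  X <- lib$dm$matrix[sel, ]
  y <- droplevels(lib$y[sel])
  rf <- train_balanced_rf(X, y, n_trees = 100, seed = 5)
  expect_equal(unname(rf$sampsize), c(57, 57))
  rf2 <- train_balanced_rf(X, y, n_trees = 100, seed = 5)
  expect_identical(rf$oob_votes, rf2$oob_votes)
  expect_identical(rf$importance, rf2$importance)
  expect_error(train_balanced_rf(X, rep("A", nrow(X))), "single class")
  p <- prob_active(rf, X)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("label permutation collapses performance to chance", {
  lib <- planted_library(1, n = 200)
  yperm <- withr::with_seed(7, sample(lib$y))
  rf <- train_balanced_rf(lib$dm$matrix, yperm, n_trees = 200, seed = 7)
  q <- oob_metrics(rf)$Q
  expect_gte(q, 0.35)
  expect_lte(q, 0.65)

  ## MCC between the labels and their random permutations concentrates
  ## near zero
  mccs <- vapply(1:20, function(s) {
    yp <- withr::with_seed(s, sample(as.character(lib$y)))
    compute_metrics(confusion_from_predictions(as.character(lib$y), yp))$MCC
  }, numeric(1))
  expect_true(all(abs(mccs) < 0.2))
})

test_that("SVM and MLP contracts honour the printed hyperparameters", {
  expect_equal(formals(train_svm)$cost, 1e7)
  expect_equal(formals(train_svm)$gamma, 1e-8)
  expect_equal(eval(formals(train_mlp)$hidden), c(200, 200))
  expect_equal(formals(train_mlp)$batch_size, 36)
  expect_equal(formals(train_mlp)$epochs, 100)

  lib <- planted_library(1, n = 200)
  y <- lib$y
  expect_error(train_svm(lib$dm$matrix, rep("A", 200)), "single class")
  expect_error(train_mlp(lib$dm$matrix, rep("B", 200)), "single class")
})

test_that("SVM and MLP comparators recover the planted signal", {
  lib <- planted_library(7, n = 200)
  rf <- train_balanced_rf(lib$dm, lib$y, n_trees = 200, seed = 7)
  top <- names(sort(rf$importance, decreasing = TRUE))[1:50]
  X <- lib$dm$matrix[, top]
  sp <- stratified_split(lib$records, c(A = 14, B = 16), seed = 7)
  svm <- train_svm(X[sp$train_idx, ], lib$y[sp$train_idx], seed = 7)
  mlp <- train_mlp(X[sp$train_idx, ], lib$y[sp$train_idx], seed = 7)
  for (mod in list(svm, mlp)) {
    q <- compute_metrics(confusion_from_predictions(
      predict_class(mod, X[sp$test_idx, ]), lib$y[sp$test_idx]))$Q
    expect_gt(q, 0.7)
    p <- prob_active(mod, X[sp$test_idx, ])
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("consensus prediction takes the per-sample majority", {
  lib <- planted_library(1, n = 200)
  X <- lib$dm$matrix[, 1:60]
  models <- lapply(1:3, function(s) {
    train_balanced_rf(X, lib$y, n_trees = 51, seed = s)
  })
  cons <- consensus_predict(models, X)
  votes <- vapply(models, function(m) as.character(predict_class(m, X)),
                  character(nrow(X)))
  manual <- apply(votes, 1, function(v) {
    if (sum(v == "A") >= 2) "A" else "B"
  })
  expect_equal(as.character(cons), manual)
  expect_error(consensus_predict(models[1:2], X), "odd")
})

test_that("selection sweep ranks, retrains and picks by (Q, MCC)", {
  lib <- planted_library(1, n = 200)
  rf <- train_balanced_rf(lib$dm, lib$y, n_trees = 300, seed = 1)
  sw <- importance_selection_sweep(rf, lib$dm$matrix, lib$y,
                                   k_list = c(12, 25, 2000),
                                   n_trees = 300, seed = 1)
  expect_named(sw$per_k, c("12", "25"))
  expect_match(sw$log, "2000")
  expect_true(sw$chosen_k %in% c(12, 25))
  best <- which.max(vapply(sw$per_k, `[[`, numeric(1), "Q"))
  expect_equal(sw$chosen_k, as.integer(names(sw$per_k)[best]))

  ## k = full descriptor count reproduces the full model metrics
  ksmall <- ncol(lib$dm$matrix)
  sw2 <- importance_selection_sweep(rf, lib$dm$matrix, lib$y,
                                    k_list = ksmall, n_trees = 300,
                                    seed = 1)
  expect_equal(sw2$per_k[[as.character(ksmall)]]$Q, oob_metrics(
    train_balanced_rf(lib$dm$matrix[, sw$ranking], lib$y,
                      n_trees = 300, seed = 1))$Q)
})

test_that("model artifacts and metrics reports round-trip", {
  lib <- planted_library(1, n = 200)
  rf <- train_balanced_rf(lib$dm$matrix[, 1:40], lib$y, n_trees = 50,
                          seed = 2)
  tf <- tempfile(fileext = ".rds")
  save_model(rf, tf)
  back <- load_model(tf)
  expect_identical(prob_active(back, lib$dm$matrix[, 1:40]),
                   prob_active(rf, lib$dm$matrix[, 1:40]))
  saveRDS(list(format = "other"), tf)
  expect_error(load_model(tf), "format")

  m <- compute_metrics(confusion_counts(TP = 41, TN = 53, FN = 16, FP = 17))
  tj <- tempfile(fileext = ".json")
  write_metrics_json(m, tj)
  parsed <- jsonlite::read_json(tj)
  expect_equal(parsed$TP, 41)
  expect_equal(round(parsed$MCC, 3), 0.476)
})
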