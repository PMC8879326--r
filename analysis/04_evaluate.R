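#!/usr/bin/env Rscript

## Step 4 — evaluation protocol.
##
## Recomputes the published benchmark audits (metric engine over the
## printed confusion counts; rate-to-count inversion of the
## selection/comparator tables), then evaluates the selected RF on a
## stratified hold-out with the SVM and dMLP comparators, the
## three-model consensus, cluster-wise metrics and the Prob_active
## diagnostics. Writes results/evaluation.csv and
## results/cluster_metrics.csv.

suppressMessages(library(afqsar))

seed <- 1

## --- audit of the printed tables ---------------------------------
t2 <- reference_table2()
audit_ok <- all(vapply(seq_len(nrow(t2)), function(r) {
  m <- compute_metrics(confusion_counts(TP = t2$TP[r], TN = t2$TN[r],
                                        FP = t2$FP[r], FN = t2$FN[r]))
  all(round(c(m$SE, m$SP, m$Q, m$MCC), 3) ==
        c(t2$SE[r], t2$SP[r], t2$Q[r], t2$MCC[r]))
}, logical(1)))
message("metric engine reproduces all printed training rows: ", audit_ok)

## --- hold-out evaluation of the model stack ----------------------
records <- read_sdf("results/library/library.sdf")
dm <- featurize(records)
y <- record_classes(records)
selected <- readLines("results/selected_descriptors.txt")
X <- dm$matrix[, selected, drop = FALSE]

nA <- sum(y == "A"); nB <- sum(y == "B")
sp <- stratified_split(records, c(A = round(nA * 0.15), B = round(nB * 0.15)),
                       seed = seed)
Xtr <- X[sp$train_idx, ]; ytr <- y[sp$train_idx]
Xte <- X[sp$test_idx, ]; yte <- y[sp$test_idx]

models <- list(
  RF = train_balanced_rf(Xtr, ytr, seed = seed),
  SVM = train_svm(Xtr, ytr, seed = seed),
  dMLP = train_mlp(Xtr, ytr, seed = seed)
)
rows <- lapply(names(models), function(nm) {
  m <- compute_metrics(confusion_from_predictions(
    predict_class(models[[nm]], Xte), yte))
  message(nm, " test: "); print(m)
  data.frame(model = nm, SE = m$SE, SP = m$SP, Q = m$Q, MCC = m$MCC)
})
cons <- compute_metrics(confusion_from_predictions(
  consensus_predict(models, Xte), yte))
message("consensus test: "); print(cons)
rows[[length(rows) + 1]] <- data.frame(model = "consensus", SE = cons$SE,
                                       SP = cons$SP, Q = cons$Q,
                                       MCC = cons$MCC)
write.csv(do.call(rbind, rows), "results/evaluation.csv", row.names = FALSE)

## --- cluster-wise report (training set, OOB predictions) ---------
rf_tr <- models$RF
clusters <- vapply(records, `[[`, character(1), "cluster")[sp$train_idx]
cw <- clusterwise_metrics(as.character(rf_tr$oob_predictions),
                          as.character(ytr), clusters)
cw_tab <- do.call(rbind, lapply(names(cw), function(cl) {
  m <- cw[[cl]]
  data.frame(cluster = cl, n = sum(clusters == cl), SE = m$SE, SP = m$SP,
             Q = m$Q, MCC = m$MCC)
}))
print(cw_tab, digits = 3)
write.csv(cw_tab, "results/cluster_metrics.csv", row.names = FALSE)

## --- Prob_active diagnostics -------------------------------------
probs <- prob_active(rf_tr, Xte)
pred <- predict_class(rf_tr, Xte)
d <- prob_diagnostics(probs, pred, yte)
theta <- derive_confidence_threshold(probs, pred, yte)
message(sprintf(
  "a_Prob_active: TP=%.2f FP=%.2f TN=%.2f FN=%.2f; theta_conf=%.2f",
  d["TP"], d["FP"], d["TN"], d["FN"], theta))
writeLines(sprintf("theta_confidence\t%.4f", theta),
           "results/confidence_threshold.txt")
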