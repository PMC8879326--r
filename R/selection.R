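#' Importance-based descriptor selection sweep
#'
#' Ranks descriptors by the fitted forest's permutation importance
#' (mean decrease in accuracy), then, for each k in the sweep list,
#' retrains a balanced RF on the top-k descriptors and records its OOB
#' metric report. The chosen k maximizes (Q, then MCC) lexicographically.
#' A k larger than the descriptor count is skipped with a log entry.
#'
#' @param model fitted `af_model` of kind "rf" (provides the ranking).
#' @param X design matrix used for retraining.
#' @param y class labels.
#' @param k_list sweep sizes (default `c(12, 25, 50, 100, 150, 200, 250)`).
#' @param n_trees,seed forwarded to [train_balanced_rf()].
#' @return object of class `af_selection`: list with `ranking` (ordered
#'   descriptor names), `per_k` (named list of `af_metrics`), `models`
#'   (per-k fitted models), `chosen_k`, `log`.
#' @export
importance_selection_sweep <- function(model, X, y,
                                       k_list = c(12, 25, 50, 100, 150,
                                                  200, 250),
                                       n_trees = 500, seed = 1) {
  stopifnot(inherits(model, "af_model"), model$kind == "rf")
  X <- as_design_matrix(X)
  ranking <- names(sort(model$importance, decreasing = TRUE))
  per_k <- list(); models <- list(); log <- character(0)
  for (k in k_list) {
    if (k > length(ranking)) {
      log <- c(log, sprintf("k=%d skipped: only %d descriptors available",
                            k, length(ranking)))
      next
    }
    cols <- ranking[seq_len(k)]
    fit <- train_balanced_rf(X[, cols, drop = FALSE], y,
                             n_trees = n_trees, seed = seed)
    models[[as.character(k)]] <- fit
    per_k[[as.character(k)]] <- oob_metrics(fit)
  }
  if (length(per_k) == 0) stop("no sweep size was feasible")
  qs <- vapply(per_k, `[[`, numeric(1), "Q")
  mccs <- vapply(per_k, `[[`, numeric(1), "MCC")
  best <- order(-qs, -mccs)[1]
  structure(list(ranking = ranking, per_k = per_k, models = models,
                 chosen_k = as.integer(names(per_k)[best]), log = log),
            class = "af_selection")
}

#' @export
print.af_selection <- function(x, ...) {
  cat(sprintf("<af_selection: chosen k=%d of {%s}>\n", x$chosen_k,
              paste(names(x$per_k), collapse = ", ")))
  for (k in names(x$per_k)) {
    cat(sprintf("  k=%-4s ", k)); print(x$per_k[[k]])
  }
  invisible(x)
}
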