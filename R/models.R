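#' Train a class-balanced random forest
#'
#' Wraps `randomForest` with per-class stratified bootstrap sampling:
#' each tree is grown on `sampsize = c(m, m)` where `m` is the
#' minority-class count, the device used to neutralize the class
#' imbalance. Out-of-bag votes, OOB predictions and permutation
#' importance (mean decrease in accuracy) are retained.
#'
#' @param X numeric matrix (molecules x descriptors) or
#'   `af_descriptor_matrix`.
#' @param y factor/character of classes ("A" active, "B" inactive).
#' @param n_trees number of trees (default 500).
#' @param seed integer RNG seed.
#' @param mtry optional; defaults to `sqrt(ncol)` as in randomForest.
#' @return model contract of class `af_model` (kind "rf") supporting
#'   [predict_class()], [prob_active()], plus `$oob_votes`,
#'   `$oob_predictions`, `$importance`.
#' @export
train_balanced_rf <- function(X, y, n_trees = 500, seed = 1, mtry = NULL) {
  X <- as_design_matrix(X)
  y <- droplevels(factor(as.character(y), levels = c("A", "B")))
  if (nlevels(y) < 2) stop("training labels contain a single class")
  m <- min(table(y))
  args <- list(x = as.data.frame(X), y = y, ntree = n_trees,
               strata = y, sampsize = c(m, m), importance = TRUE,
               keep.forest = TRUE)
  if (!is.null(mtry)) args$mtry <- mtry
  fit <- withr::with_seed(seed, do.call(randomForest::randomForest, args))
  imp <- randomForest::importance(fit, type = 1)[, 1]
  structure(list(
    kind = "rf", fit = fit, features = colnames(X), seed = seed,
    sampsize = c(m, m),
    oob_votes = fit$votes,          # vote fractions per class
    oob_predictions = fit$predicted,
    importance = imp
  ), class = "af_model")
}

#' Train a support vector machine comparator
#'
#' RBF-kernel C-classification with the printed hyperparameters as
#' defaults (C = 1e7, gamma = 1e-8). The minority class is replicated
#' (deterministic recycling) until the classes have equal size.
#' Features are standardized internally (zero-variance columns left
#' untouched); class probabilities come from e1071's pairwise-coupling
#' calibration.
#'
#' @inheritParams train_balanced_rf
#' @param cost,gamma SVM hyperparameters.
#' @return `af_model` (kind "svm").
#' @export
train_svm <- function(X, y, cost = 1e7, gamma = 1e-8, seed = 1) {
  X <- as_design_matrix(X)
  y <- droplevels(factor(as.character(y), levels = c("A", "B")))
  if (nlevels(y) < 2) stop("training labels contain a single class")
  bal <- balance_by_replication(X, y)
  ctr <- colMeans(bal$X)
  scl <- apply(bal$X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(bal$X, center = ctr, scale = scl)
  fit <- withr::with_seed(seed, e1071::svm(
    x = Xs, y = bal$y, type = "C-classification", kernel = "radial",
    cost = cost, gamma = gamma, probability = TRUE, scale = FALSE))
  structure(list(kind = "svm", fit = fit, features = colnames(X),
                 center = ctr, scale = scl, cost = cost, gamma = gamma,
                 seed = seed),
            class = "af_model")
}

#' Train the deep multilayer perceptron comparator
#'
#' A feed-forward network implemented in-package with the fixed
#' architecture: two hidden layers of 200 relu units, an output layer
#' of 2 sigmoid units (one per class), Glorot-uniform initialization,
#' binary cross-entropy loss averaged over the two output units,
#' Adadelta optimization (rho 0.95), mini-batches of 36, 100 epochs.
#' The minority class is replicated to balance, and features are
#' standardized internally. `prob_active` is the class-A output
#' normalized over the two sigmoid outputs.
#'
#' @inheritParams train_balanced_rf
#' @param hidden hidden layer sizes.
#' @param epochs,batch_size training schedule.
#' @param rho,epsilon Adadelta parameters.
#' @return `af_model` (kind "mlp").
#' @export
train_mlp <- function(X, y, hidden = c(200, 200), epochs = 100,
                      batch_size = 36, rho = 0.95, epsilon = 1e-6,
                      seed = 1) {
  X <- as_design_matrix(X)
  y <- droplevels(factor(as.character(y), levels = c("A", "B")))
  if (nlevels(y) < 2) stop("training labels contain a single class")
  bal <- balance_by_replication(X, y)
  ctr <- colMeans(bal$X)
  scl <- apply(bal$X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(bal$X, center = ctr, scale = scl)
  Yt <- cbind(A = as.numeric(bal$y == "A"), B = as.numeric(bal$y == "B"))
  net <- withr::with_seed(seed, mlp_fit(Xs, Yt, hidden, epochs,
                                        batch_size, rho, epsilon))
  structure(list(kind = "mlp", net = net, features = colnames(X),
                 center = ctr, scale = scl, seed = seed),
            class = "af_model")
}

## ---- MLP internals -------------------------------------------------------

glorot_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

mlp_fit <- function(X, Y, hidden, epochs, batch_size, rho, epsilon) {
  sizes <- c(ncol(X), hidden, ncol(Y))
  L <- length(sizes) - 1
  W <- lapply(seq_len(L), function(l) glorot_uniform(sizes[l], sizes[l + 1]))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  ## Adadelta accumulators
  Eg2_W <- lapply(W, function(w) w * 0); Ed2_W <- Eg2_W
  Eg2_b <- lapply(b, function(x) x * 0); Ed2_b <- Eg2_b
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      xb <- X[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
      ## forward
      act <- vector("list", L + 1); act[[1]] <- xb
      for (l in seq_len(L)) {
        z <- sweep(act[[l]] %*% W[[l]], 2, b[[l]], `+`)
        act[[l + 1]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
      }
      out <- act[[L + 1]]
      ## BCE with sigmoid output: dL/dz = (out - y)/batch
      delta <- (out - yb) / (nrow(xb) * ncol(Y))
      for (l in rev(seq_len(L))) {
        gW <- crossprod(act[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * (act[[l]] > 0)
        }
        ## Adadelta update
        Eg2_W[[l]] <- rho * Eg2_W[[l]] + (1 - rho) * gW^2
        dW <- -sqrt(Ed2_W[[l]] + epsilon) / sqrt(Eg2_W[[l]] + epsilon) * gW
        Ed2_W[[l]] <- rho * Ed2_W[[l]] + (1 - rho) * dW^2
        W[[l]] <- W[[l]] + dW
        Eg2_b[[l]] <- rho * Eg2_b[[l]] + (1 - rho) * gb^2
        db <- -sqrt(Ed2_b[[l]] + epsilon) / sqrt(Eg2_b[[l]] + epsilon) * gb
        Ed2_b[[l]] <- rho * Ed2_b[[l]] + (1 - rho) * db^2
        b[[l]] <- b[[l]] + db
      }
    }
  }
  list(W = W, b = b, sizes = sizes)
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% net$W[[l]], 2, net$b[[l]], `+`)
    a <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  a
}

## ---- shared contract -----------------------------------------------------

as_design_matrix <- function(X) {
  if (inherits(X, "af_descriptor_matrix")) X <- X$matrix
  as.matrix(X)
}

balance_by_replication <- function(X, y) {
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  need <- max(tab) - min(tab)
  if (need == 0) return(list(X = X, y = y))
  pool <- which(y == minority)
  extra <- pool[((seq_len(need) - 1) %% length(pool)) + 1]
  list(X = rbind(X, X[extra, , drop = FALSE]),
       y = factor(c(as.character(y), as.character(y[extra])),
                  levels = levels(y)))
}

check_features <- function(model, X) {
  X <- as_design_matrix(X)
  miss <- setdiff(model$features, colnames(X))
  if (length(miss) > 0) {
    stop("missing descriptor column(s): ", paste(head(miss, 5),
                                                 collapse = ", "))
  }
  X[, model$features, drop = FALSE]
}

#' Predicted class from a fitted model
#' @param model an `af_model`.
#' @param X design matrix with the model's descriptor columns.
#' @return factor of "A"/"B".
#' @export
predict_class <- function(model, X) {
  p <- prob_active(model, X)
  factor(ifelse(p >= 0.5, "A", "B"), levels = c("A", "B"))
}

#' Predicted probability of the active class
#'
#' RF: fraction of tree votes for class A. SVM: pairwise-coupling
#' calibrated probability. MLP: normalized class-A sigmoid output.
#'
#' @inheritParams predict_class
#' @return numeric vector in [0, 1].
#' @export
prob_active <- function(model, X) {
  stopifnot(inherits(model, "af_model"))
  X <- check_features(model, X)
  switch(model$kind,
    rf = {
      v <- stats::predict(model$fit, as.data.frame(X), type = "vote",
                          norm.votes = TRUE)
      as.numeric(v[, "A"])
    },
    svm = {
      Xs <- scale(X, center = model$center, scale = model$scale)
      pr <- stats::predict(model$fit, Xs, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "A"])
    },
    mlp = {
      Xs <- scale(X, center = model$center, scale = model$scale)
      out <- mlp_forward(model$net, Xs)
      as.numeric(out[, 1] / pmax(out[, 1] + out[, 2], 1e-12))
    },
    stop("unknown model kind: ", model$kind))
}

#' @export
print.af_model <- function(x, ...) {
  cat(sprintf("<af_model kind=%s, %d features>\n", x$kind,
              length(x$features)))
  invisible(x)
}

#' Majority-vote consensus prediction
#'
#' @param models list of an odd number of `af_model`s (default trio
#'   RF/SVM/MLP).
#' @param X design matrix.
#' @return factor of "A"/"B".
#' @export
consensus_predict <- function(models, X) {
  if (length(models) %% 2 == 0) {
    stop("consensus needs an odd number of models (tie-unsafe otherwise)")
  }
  votes <- vapply(models, function(m) as.character(predict_class(m, X)),
                  character(nrow(as_design_matrix(X))))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  factor(apply(votes, 1, function(v) {
    if (sum(v == "A") > length(v) / 2) "A" else "B"
  }), levels = c("A", "B"))
}

#' OOB metric report of a balanced RF
#' @param model `af_model` of kind "rf".
#' @return `af_metrics` computed from OOB predictions.
#' @export
oob_metrics <- function(model) {
  stopifnot(model$kind == "rf")
  truth <- model$fit$y
  compute_metrics(confusion_from_predictions(model$oob_predictions, truth))
}

#' Save / load a fitted model artifact
#'
#' Serializes the model contract together with a format version tag so
#' stale artifacts are rejected on load.
#'
#' @param model an `af_model`.
#' @param path artifact path (RDS).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "af_model"))
  saveRDS(list(format = "af_model_v1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "af_model_v1")) {
    stop("unrecognized model artifact format: ", obj$format)
  }
  obj$model
}
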