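#' Construct an activity record
#'
#' @param endpoint_type `"percent_inhibition"`, `"EC50"` or `"IC50"`.
#' @param value endpoint value (>= 0).
#' @param units `"%"` for percent inhibition, `"ug/mL"` for EC50/IC50.
#' @return object of class `af_activity`.
#' @export
activity_record <- function(endpoint_type = c("percent_inhibition",
                                              "EC50", "IC50"),
                            value, units = NA_character_) {
  endpoint_type <- match.arg(endpoint_type)
  if (!is.na(value) && value < 0) stop("endpoint value must be >= 0")
  structure(list(endpoint_type = endpoint_type, value = value,
                 units = units, activity_class = NULL),
            class = "af_activity")
}

#' Assign the binary activity class
#'
#' Activity rule: percent inhibition > 52 percent is active (class A);
#' EC50/IC50 <= 25 ug/mL is active; otherwise inactive (class B). The
#' rule is applied per available endpoint type.
#'
#' @param rec an [activity_record()].
#' @return the record with `activity_class` set to `"A"` or `"B"`.
#' @export
label_activity <- function(rec) {
  if (!inherits(rec, "af_activity")) stop("rec must be af_activity")
  cls <- switch(rec$endpoint_type,
    percent_inhibition = {
      if (!is.na(rec$units) && rec$units != "%") {
        stop("unknown units for percent inhibition: ", rec$units)
      }
      if (rec$value > 52) "A" else "B"
    },
    EC50 = ,
    IC50 = {
      if (!is.na(rec$units) && !rec$units %in% c("ug/mL", "µg/mL")) {
        stop("unknown units for ", rec$endpoint_type, ": ", rec$units)
      }
      if (rec$value <= 25) "A" else "B"
    }
  )
  rec$activity_class <- cls
  rec
}

#' Classes of a record list
#' @param records list of `af_record` with labelled activities.
#' @return factor with levels A, B.
#' @export
record_classes <- function(records) {
  cls <- vapply(records, function(r) {
    if (is.null(r$activity) || is.null(r$activity$activity_class)) {
      NA_character_
    } else {
      r$activity$activity_class
    }
  }, character(1))
  factor(cls, levels = c("A", "B"))
}

#' Stratified train/test split
#'
#' Samples the requested number of test molecules uniformly at random
#' within each activity class, reproducibly at a fixed seed.
#'
#' @param records list of `af_record` with labelled activities.
#' @param test_counts named vector, e.g. `c(A = 6, B = 8)`.
#' @param seed integer RNG seed.
#' @return object of class `af_split`: list with `train_ids`,
#'   `test_ids`, `train_idx`, `test_idx` and per-class counts.
#' @export
stratified_split <- function(records, test_counts, seed) {
  y <- record_classes(records)
  if (anyNA(y)) stop("all records need a labelled activity class")
  ids <- vapply(records, function(r) r$molecule$id, character(1))
  test_idx <- integer(0)
  for (cls in names(test_counts)) {
    pool <- which(y == cls)
    k <- test_counts[[cls]]
    if (k > length(pool)) {
      stop(sprintf("cannot draw %d test molecules from class %s (size %d)",
                   k, cls, length(pool)))
    }
    if (k > 0) {
      test_idx <- c(test_idx,
                    withr::with_seed(seed + match(cls, names(test_counts)),
                                     sample(pool, k)))
    }
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(records), test_idx)
  structure(list(
    train_ids = ids[train_idx], test_ids = ids[test_idx],
    train_idx = train_idx, test_idx = test_idx,
    train_counts = c(table(y[train_idx])),
    test_counts = c(table(y[test_idx]))
  ), class = "af_split")
}

#' Confusion counts
#'
#' @param TP,TN,FP,FN non-negative integers. Class A (active) is the
#'   positive class.
#' @return object of class `af_confusion`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0)) stop("confusion counts must be >= 0")
  if (sum(v) == 0) stop("all confusion counts are zero")
  structure(as.list(v), class = "af_confusion")
}

#' Confusion counts from predictions and truth
#' @param pred,truth factors/characters with levels A (positive), B.
#' @return `af_confusion`.
#' @export
confusion_from_predictions <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  confusion_counts(TP = sum(pred == "A" & truth == "A"),
                   TN = sum(pred == "B" & truth == "B"),
                   FP = sum(pred == "A" & truth == "B"),
                   FN = sum(pred == "B" & truth == "A"))
}

#' Classification metrics: SE, SP, Q, MCC
#'
#' Standard definitions: sensitivity `SE = TP/(TP+FN)`, specificity
#' `SP = TN/(TN+FP)`, overall accuracy `Q = (TP+TN)/total`, Matthews
#' correlation
#' `MCC = (TP TN - FP FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. A zero
#' denominator marks the corresponding metric as undefined (NA plus an
#' `undefined` flag), rendered "-" in reports.
#'
#' @param c an `af_confusion`.
#' @return object of class `af_metrics` with fields SE, SP, Q, MCC and
#'   `undefined` (character vector of undefined metric names).
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "af_confusion"))
  undef <- character(0)
  se <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else {
    undef <- c(undef, "SE"); NA_real_
  }
  sp <- if (c$TN + c$FP > 0) c$TN / (c$TN + c$FP) else {
    undef <- c(undef, "SP"); NA_real_
  }
  q <- (c$TP + c$TN) / (c$TP + c$TN + c$FP + c$FN)
  den <- (c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN)
  mcc <- if (den > 0) {
    (c$TP * c$TN - c$FP * c$FN) / sqrt(den)
  } else {
    undef <- c(undef, "MCC"); NA_real_
  }
  structure(list(SE = se, SP = sp, Q = q, MCC = mcc, undefined = undef,
                 counts = c),
            class = "af_metrics")
}

#' @export
print.af_metrics <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "-" else formatC(v, digits = digits,
                                                    format = "f")
  cat(sprintf("SE=%s SP=%s Q=%s MCC=%s\n", fmt(x$SE), fmt(x$SP),
              fmt(x$Q), fmt(x$MCC)))
  invisible(x)
}

#' Reconstruct integer confusion counts from printed rates
#'
#' Inverts rounded SE/SP back to integer TP/TN given the class sizes:
#' TP is the unique integer in [0, n_active] with
#' `|TP/n_active - SE| < tol` (TN analogously). Errors when no integer
#' or more than one integer matches.
#'
#' @param SE,SP printed sensitivity and specificity.
#' @param n_active,n_inactive class sizes.
#' @param tol rate tolerance (default 0.0005, i.e. 3-decimal rounding).
#' @return `af_confusion`.
#' @export
counts_from_rates <- function(SE, SP, n_active, n_inactive, tol = 5e-4) {
  stopifnot(SE >= 0, SE <= 1, SP >= 0, SP <= 1)
  invert <- function(rate, n, label) {
    cand <- which(abs(seq(0, n) / n - rate) < tol) - 1L
    if (length(cand) == 0) {
      stop(sprintf("no integer count matches %s=%.4f over n=%d at tol %.2g",
                   label, rate, n, tol))
    }
    if (length(cand) > 1) {
      stop(sprintf("ambiguous inversion for %s=%.4f over n=%d at tol %.2g",
                   label, rate, n, tol))
    }
    cand
  }
  TP <- invert(SE, n_active, "SE")
  TN <- invert(SP, n_inactive, "SP")
  confusion_counts(TP = TP, TN = TN, FP = n_inactive - TN,
                   FN = n_active - TP)
}

#' Per-cluster metrics
#'
#' Computes the metric report within each structural cluster.
#' Single-class clusters yield undefined SE or SP (the `undefined`
#' flag), matching the "-" rendering of cluster-wise report tables.
#'
#' @param pred,truth predicted and true classes ("A"/"B").
#' @param clusters cluster label per molecule.
#' @return named list of `af_metrics`, one per non-empty cluster.
#' @export
clusterwise_metrics <- function(pred, truth, clusters) {
  stopifnot(length(pred) == length(truth),
            length(pred) == length(clusters))
  out <- list()
  for (cl in unique(as.character(clusters))) {
    sel <- clusters == cl
    out[[cl]] <- compute_metrics(
      confusion_from_predictions(pred[sel], truth[sel]))
  }
  out[order(match(names(out), CLUSTER_LABELS))]
}

#' Write a metrics report as JSON
#'
#' Mirrors the benchmark-table columns (TP, TN, FN, FP, SE, SP, Q,
#' MCC); undefined metrics are written as null.
#'
#' @param m an `af_metrics`.
#' @param path JSON destination.
#' @export
write_metrics_json <- function(m, path) {
  stopifnot(inherits(m, "af_metrics"))
  out <- list(TP = m$counts$TP, TN = m$counts$TN, FN = m$counts$FN,
              FP = m$counts$FP, SE = m$SE, SP = m$SP, Q = m$Q,
              MCC = m$MCC)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
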