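#' Score a screening library
#'
#' Applies a fitted model to a featurized library and returns one hit
#' per molecule with its predicted class and active-class probability.
#'
#' @param model an `af_model`.
#' @param X_library design matrix (or `af_descriptor_matrix`) holding
#'   the model's selected descriptor columns; row names are molecule
#'   ids.
#' @param theta_conf confidence threshold used to set the
#'   `above_confidence` flag (default 0.59).
#' @return data.frame (class `af_hits`): id, predicted_class,
#'   prob_active, above_confidence, shortlist (all FALSE until
#'   [shortlist()] runs).
#' @export
predict_library <- function(model, X_library, theta_conf = 0.59) {
  X <- as_design_matrix(X_library)
  if (nrow(X) == 0) {
    out <- data.frame(id = character(0), predicted_class = character(0),
                      prob_active = numeric(0),
                      above_confidence = logical(0),
                      shortlist = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("af_hits", "data.frame")
    return(out)
  }
  p <- prob_active(model, X)
  cls <- ifelse(p >= 0.5, "A", "B")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("lib_%05d", seq_len(nrow(X)))
  out <- data.frame(id = ids, predicted_class = cls, prob_active = p,
                    above_confidence = cls == "A" & p > theta_conf,
                    shortlist = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("af_hits", "data.frame")
  out
}

#' Derive the zero-false-positive confidence threshold
#'
#' Operational construction of the applicability threshold: the maximum
#' predicted active-class probability among false-positive predictions
#' on a labelled evaluation set. Every prediction with a probability
#' strictly above the returned threshold on that set is then a true
#' positive. When no false positive exists, the threshold falls back to
#' the maximum probability among inactive-truth molecules.
#'
#' @param prob predicted active-class probabilities.
#' @param pred predicted classes ("A"/"B").
#' @param truth true classes.
#' @return single numeric threshold.
#' @export
derive_confidence_threshold <- function(prob, pred, truth) {
  if (length(prob) == 0) stop("empty prediction set")
  pred <- as.character(pred); truth <- as.character(truth)
  fp <- pred == "A" & truth == "B"
  if (any(fp)) {
    max(prob[fp])
  } else if (any(truth == "B")) {
    max(prob[truth == "B"])
  } else {
    0
  }
}

#' Mean predicted probability per confusion cell
#'
#' The a_Prob_active diagnostic: the average active-class probability
#' within each of the four confusion cells. An empty cell is NA.
#'
#' @inheritParams derive_confidence_threshold
#' @return named numeric `c(TP=, FP=, TN=, FN=)`.
#' @export
prob_diagnostics <- function(prob, pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  cellmean <- function(sel) if (any(sel)) mean(prob[sel]) else NA_real_
  c(TP = cellmean(pred == "A" & truth == "A"),
    FP = cellmean(pred == "A" & truth == "B"),
    TN = cellmean(pred == "B" & truth == "B"),
    FN = cellmean(pred == "B" & truth == "A"))
}

#' Flag the docking shortlist
#'
#' Marks hits predicted active with probability at or above the
#' docking-selection threshold (default 0.68) and orders the table by
#' decreasing probability, ties broken by molecule id.
#'
#' @param hits an `af_hits` table from [predict_library()].
#' @param theta_dock threshold in [0, 1].
#' @return reordered `af_hits` with the `shortlist` flag set.
#' @export
shortlist <- function(hits, theta_dock = 0.68) {
  if (theta_dock < 0 || theta_dock > 1) {
    stop("theta_dock must lie in [0, 1]")
  }
  hits$shortlist <- hits$predicted_class == "A" &
    hits$prob_active >= theta_dock
  hits <- hits[order(-hits$prob_active, hits$id), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("af_hits", "data.frame")
  hits
}

#' Concentration unit conversion
#'
#' Converts a mass concentration in micrograms per millilitre to a
#' molar concentration in micromolar: `uM = 1000 * (ug/mL) / MW`.
#'
#' @param conc concentration in ug/mL.
#' @param mw molecular weight in g/mol (> 0).
#' @return concentration in uM.
#' @export
ugml_to_micromolar <- function(conc, mw) {
  if (any(mw <= 0)) stop("molecular weight must be > 0")
  1000 * conc / mw
}

#' Write / read the hit table
#' @param hits `af_hits`.
#' @param path CSV path.
#' @export
write_hits <- function(hits, path) {
  utils::write.csv(as.data.frame(hits), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  class(out) <- c("af_hits", "data.frame")
  out
}
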