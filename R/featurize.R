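#' Featurization configuration
#'
#' @param families descriptor families to compute: any of `"2d"`
#'   (autocorrelations, Burden eigenvalues, E-state types, nitrogen
#'   weighted path, topological charge indices, Mannhold LogP) and
#'   `"rdf"`.
#' @param lags autocorrelation lags (default 1:8).
#' @param burden_k Burden eigenvalue ranks (default 1:5).
#' @param rdf an [rdf_config()].
#' @param charges a [charge_config()] used when partial charges are
#'   still unassigned.
#' @param missing_policy `"zero"` (replace missing with 0, record in
#'   the mask) or `"strict"` (error naming molecule and descriptor).
#' @return object of class `af_featurize_config`.
#' @export
featurize_config <- function(families = c("2d", "rdf"), lags = 1:8,
                             burden_k = 1:5, rdf = rdf_config(),
                             charges = charge_config(),
                             missing_policy = c("zero", "strict")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(all(families %in% c("2d", "rdf")))
  structure(list(families = families, lags = lags, burden_k = burden_k,
                 rdf = rdf, charges = charges,
                 missing_policy = missing_policy),
            class = "af_featurize_config")
}

AUTOCORR_VARIANTS <- c("ATS", "ATSC", "AATS", "AATSC", "Moran", "Geary")

## deterministic column manifest for a configuration
featurize_manifest <- function(cfg) {
  rows <- list()
  if ("2d" %in% cfg$families) {
    for (v in AUTOCORR_VARIANTS) for (w in WEIGHT_CODES) for (l in cfg$lags) {
      rows[[length(rows) + 1]] <- data.frame(
        column = paste0(v, l, w), family = "autocorrelation",
        weight = w, lag = l, stringsAsFactors = FALSE)
    }
    for (end in c("SpMin", "SpMax")) for (k in cfg$burden_k)
      for (w in WEIGHT_CODES) {
        rows[[length(rows) + 1]] <- data.frame(
          column = paste0(end, k, "_Bh", w), family = "burden",
          weight = w, lag = k, stringsAsFactors = FALSE)
      }
    es <- data.frame(
      column = c("SssssC", "maxssssC", "SssCH2", "minHCsats", "SwHBa"),
      family = "estate", weight = NA_character_, lag = NA_integer_,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- es
    rows[[length(rows) + 1]] <- data.frame(
      column = c("WTPT.5", paste0("JGI", 1:3), "MLogP"),
      family = c("path", rep("charge_index", 3), "constitutional"),
      weight = NA_character_, lag = c(NA, 1:3, NA),
      stringsAsFactors = FALSE)
  }
  if ("rdf" %in% cfg$families) {
    nb <- cfg$rdf$n_bins
    rows[[length(rows) + 1]] <- data.frame(
      column = c(paste0("RDFa_", 1:nb), paste0("RDFb_", 1:nb),
                 paste0("RDFc_", 1:nb)),
      family = "rdf",
      weight = rep(c("a", "b", "c"), each = nb),
      lag = rep(1:nb, 3), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

featurize_one <- function(mol, cfg) {
  man <- featurize_manifest(cfg)
  out <- setNames(rep(NA_real_, nrow(man)), man$column)
  if ("2d" %in% cfg$families) {
    dmat <- topo_distance_matrix(mol)
    ws <- lapply(setNames(WEIGHT_CODES, WEIGHT_CODES),
                 function(w) atom_weights(mol, w))
    n <- nrow(dmat)
    for (l in cfg$lags) {
      idx <- which(dmat == l & upper.tri(dmat), arr.ind = TRUE)
      D <- nrow(idx)
      for (w in WEIGHT_CODES) {
        wv <- ws[[w]]
        nm <- paste0(AUTOCORR_VARIANTS, l, w)
        if (D == 0) { out[nm] <- NA_real_; next }
        wi <- wv[idx[, 1]]; wj <- wv[idx[, 2]]
        wbar <- mean(wv)
        ats <- sum(wi * wj)
        atsc <- sum((wi - wbar) * (wj - wbar))
        out[nm[1]] <- ats
        out[nm[2]] <- atsc
        out[nm[3]] <- ats / D
        out[nm[4]] <- atsc / D
        s2n <- sum((wv - wbar)^2) / n
        out[nm[5]] <- if (s2n > 0) (atsc / D) / s2n else NA_real_
        s2g <- if (n > 1) sum((wv - wbar)^2) / (n - 1) else 0
        out[nm[6]] <- if (s2g > 0) (sum((wi - wj)^2) / (2 * D)) / s2g else
          NA_real_
      }
    }
    for (w in WEIGHT_CODES) {
      ev <- burden_spectrum(mol, w)
      for (k in cfg$burden_k) {
        out[paste0("SpMin", k, "_Bh", w)] <-
          if (k <= length(ev)) ev[k] else NA_real_
        out[paste0("SpMax", k, "_Bh", w)] <-
          if (k <= length(ev)) ev[length(ev) - k + 1] else NA_real_
      }
    }
    out["SssssC"] <- estate_atomtype(mol, "ssssC", "sum")
    out["maxssssC"] <- estate_atomtype(mol, "ssssC", "max")
    out["SssCH2"] <- estate_atomtype(mol, "ssCH2", "sum")
    out["minHCsats"] <- estate_atomtype(mol, "HCsats", "min")
    out["SwHBa"] <- estate_atomtype(mol, "wHBa", "sum")
    out["WTPT.5"] <- weighted_path_nitrogen(mol)
    for (k in 1:3) {
      out[paste0("JGI", k)] <- topological_charge_index(mol, k)[["JGI"]]
    }
    out["MLogP"] <- mannhold_logp(mol)
  }
  if ("rdf" %in% cfg$families) {
    r <- rdf_descriptors(mol, cfg$rdf)
    out[names(r)] <- r
  }
  out
}

#' Compute the descriptor design matrix
#'
#' Runs the configured descriptor families over a list of molecule
#' records in a deterministic column order (autocorrelations, Burden
#' eigenvalues, E-state atom types, WTPT-5, JGI1-3, Mannhold LogP,
#' RDF a/b/c). Partial charges are assigned on the fly (using
#' `config$charges`) for molecules that lack them when a
#' charge-dependent descriptor is requested. Missing descriptor values
#' are handled per the missing policy: `"zero"` imputes 0 and flags the
#' cell in `missing_mask`; `"strict"` errors, naming the molecule and
#' descriptor.
#'
#' @param records list of `af_record` (or `af_molecule`).
#' @param config an [featurize_config()].
#' @return object of class `af_descriptor_matrix`: list with `matrix`
#'   (molecules x descriptors), `missing_mask`, `manifest`.
#' @export
featurize <- function(records, config = featurize_config()) {
  if (inherits(records, "af_record") || inherits(records, "af_molecule")) {
    records <- list(records)
  }
  mols <- lapply(records, function(r) {
    if (inherits(r, "af_record")) r$molecule else r
  })
  needs_charge <- "rdf" %in% config$families || "2d" %in% config$families
  mols <- lapply(mols, function(m) {
    if (needs_charge && anyNA(m$atoms$partial_charge)) {
      assign_partial_charges(m, config$charges)
    } else m
  })
  man <- featurize_manifest(config)
  X <- matrix(NA_real_, nrow = length(mols), ncol = nrow(man),
              dimnames = list(vapply(mols, `[[`, character(1), "id"),
                              man$column))
  for (i in seq_along(mols)) {
    X[i, ] <- featurize_one(mols[[i]], config)
  }
  mask <- is.na(X)
  if (config$missing_policy == "strict" && any(mask)) {
    bad <- which(mask, arr.ind = TRUE)[1, ]
    stop(sprintf("descriptor %s missing for molecule %s",
                 colnames(X)[bad[2]], rownames(X)[bad[1]]))
  }
  X[mask] <- 0
  structure(list(matrix = X, missing_mask = mask, manifest = man),
            class = "af_descriptor_matrix")
}

#' @export
print.af_descriptor_matrix <- function(x, ...) {
  cat(sprintf("<af_descriptor_matrix: %d molecules x %d descriptors, %d imputed cells>\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$missing_mask)))
  invisible(x)
}

#' Write a descriptor matrix and its column manifest
#'
#' @param dm an `af_descriptor_matrix`.
#' @param path CSV destination for the matrix (first column `id`).
#' @param manifest_path optional JSON destination for the manifest.
#' @export
write_descriptor_matrix <- function(dm, path, manifest_path = NULL) {
  df <- data.frame(id = rownames(dm$matrix), dm$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(dm$manifest, manifest_path, dataframe = "rows")
  }
  invisible(path)
}
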