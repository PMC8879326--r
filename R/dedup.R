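#' Canonical deduplication key for a molecule
#'
#' Two key providers are available:
#' \describe{
#'   \item{`"inchi"`}{(default) standard InChI computed by the OpenBabel
#'     command-line tool from the written V2000 block. Includes the
#'     stereo layer perceived from 3D coordinates, so enantiomers with
#'     specified geometry receive different keys while
#'     stereo-unspecified constitutional duplicates collide.}
#'   \item{`"graph"`}{a constitution-only canonical key computed
#'     in-package: bonds are expanded into coloured bond-vertices
#'     (colour = bond order) and the coloured graph is canonically
#'     labelled (BLISS, via igraph), making the key invariant to atom
#'     ordering. No stereo layer.}
#' }
#'
#' @param mol an `af_molecule` (standardized).
#' @param provider `"inchi"` or `"graph"`.
#' @return single string.
#' @export
dedup_key <- function(mol, provider = c("inchi", "graph")) {
  provider <- match.arg(provider)
  if (provider == "inchi") {
    dedup_keys(list(mol), provider = "inchi")[[1]]
  } else {
    graph_key(mol)
  }
}

#' Batch variant of [dedup_key()]
#'
#' @param mols list of `af_molecule`.
#' @inheritParams dedup_key
#' @return character vector of keys.
#' @export
dedup_keys <- function(mols, provider = c("inchi", "graph")) {
  provider <- match.arg(provider)
  if (provider == "graph") {
    return(vapply(mols, graph_key, character(1)))
  }
  if (Sys.which("obabel") == "") {
    stop("OpenBabel ('obabel') is required for the inchi key provider; ",
         "use provider = 'graph' instead")
  }
  sdf <- tempfile(fileext = ".sdf")
  out <- tempfile(fileext = ".inchi")
  on.exit(unlink(c(sdf, out)), add = TRUE)
  write_sdf(lapply(mols, molecule_record), sdf)
  system2("obabel", c(sdf, "-oinchi", "-O", out), stdout = FALSE,
          stderr = FALSE)
  keys <- readLines(out, warn = FALSE)
  keys <- keys[grepl("^InChI=", keys)]
  if (length(keys) != length(mols)) {
    stop(sprintf(
      "InChI conversion returned %d keys for %d molecules; check inputs",
      length(keys), length(mols)))
  }
  keys
}

## constitution-only canonical key: colour atoms by
## (element, formal charge, explicit H count), expand each bond into a
## bond-vertex coloured by its order, canonically label with BLISS and
## serialize the canonical adjacency.
graph_key <- function(mol) {
  hi <- heavy_indices(mol)
  if (length(hi) == 0) hi <- seq_len(n_atoms(mol))  # H2-like corner
  nh <- explicit_h_counts(mol)
  pos <- match(seq_len(n_atoms(mol)), hi)
  a <- mol$atoms[hi, , drop = FALSE]
  atom_color <- paste(a$element, a$formal_charge, nh[hi], sep = "/")
  b <- mol$bonds
  keep <- b$a1 %in% hi & b$a2 %in% hi
  b <- b[keep, , drop = FALSE]
  n <- length(hi)
  m <- nrow(b)
  if (m == 0) {
    return(paste0("G1:", paste(sort(atom_color), collapse = "|")))
  }
  ## vertices: 1..n atoms, n+1..n+m bond-vertices
  edges <- rbind(
    cbind(pos[b$a1], n + seq_len(m)),
    cbind(pos[b$a2], n + seq_len(m))
  )
  g <- igraph::make_empty_graph(n + m, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  colors <- c(atom_color, paste0("bond", b$order))
  color_id <- as.integer(factor(colors, levels = sort(unique(colors))))
  cp <- igraph::canonical_permutation(g, colors = color_id)
  gc <- igraph::permute(g, cp$labeling)
  perm_color <- character(n + m)
  perm_color[cp$labeling] <- colors
  el <- igraph::as_edgelist(gc)
  el <- t(apply(el, 1, sort))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0("G1:", paste(perm_color, collapse = "|"), ";",
         paste(el[, 1], el[, 2], sep = "-", collapse = ","))
}

#' Remove duplicate molecule records
#'
#' Keeps the first occurrence of each key; when `against` is supplied,
#' records whose key also occurs in `against` are dropped as well
#' (cross-set duplicates). Records may carry a precomputed key in
#' `properties$DEDUP_KEY`, which takes precedence over on-the-fly
#' computation; otherwise keys come from [dedup_keys()].
#'
#' @param records list of `af_record`.
#' @param against optional second list of `af_record` (reference set).
#' @param provider key provider passed to [dedup_keys()].
#' @return surviving records in input order, with a `removal_log`
#'   attribute (data.frame: id, key, reason).
#' @export
deduplicate <- function(records, against = NULL,
                        provider = c("inchi", "graph")) {
  provider <- match.arg(provider)
  keys <- record_keys(records, provider)
  ref_keys <- if (is.null(against) || length(against) == 0) character(0) else
    record_keys(against, provider)
  keep <- logical(length(records))
  reason <- character(0); rid <- character(0); rkey <- character(0)
  seen <- character(0)
  for (i in seq_along(records)) {
    k <- keys[i]
    if (k %in% ref_keys) {
      rid <- c(rid, records[[i]]$molecule$id); rkey <- c(rkey, k)
      reason <- c(reason, "duplicate_of_reference_set")
    } else if (k %in% seen) {
      rid <- c(rid, records[[i]]$molecule$id); rkey <- c(rkey, k)
      reason <- c(reason, "internal_duplicate")
    } else {
      keep[i] <- TRUE
      seen <- c(seen, k)
    }
  }
  out <- records[keep]
  attr(out, "removal_log") <- data.frame(id = rid, key = rkey,
                                         reason = reason,
                                         stringsAsFactors = FALSE)
  out
}

record_keys <- function(records, provider) {
  cached <- vapply(records, function(r) {
    k <- r$properties$DEDUP_KEY
    if (is.null(k)) NA_character_ else k
  }, character(1))
  todo <- which(is.na(cached))
  if (length(todo) > 0) {
    cached[todo] <- dedup_keys(lapply(records[todo], `[[`, "molecule"),
                               provider = provider)
  }
  cached
}

#' Write a removal log as plain text
#' @param records output of [deduplicate()].
#' @param path destination file.
#' @export
write_removal_log <- function(records, path) {
  log <- attr(records, "removal_log")
  if (is.null(log) || nrow(log) == 0) {
    writeLines("no records removed", path)
  } else {
    writeLines(sprintf("%s\t%s\t%s", log$id, log$reason, log$key), path)
  }
  invisible(path)
}
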