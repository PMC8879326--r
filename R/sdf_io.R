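#' Read an MDL SDF (V2000) file
#'
#' Strict reader for multi-molecule V2000 SD files. Each connection-table
#' block becomes one [molecule_record()]; data items (`> <KEY>` blocks)
#' are captured verbatim as key/string properties on the record. `M  CHG`
#' lines override formal charges. V3000 blocks are rejected: the pipeline
#' is fixed to the V2000 dialect.
#'
#' @param path SDF file path.
#' @return list of `af_record`, in file order.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("SDF file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  ## split on $$$$ delimiters
  ends <- grep("^\\$\\$\\$\\$\\s*$", lines)
  if (length(ends) == 0) {
    if (length(trimws(lines)) == 0 || all(trimws(lines) == "")) {
      return(list())
    }
    ends <- length(lines) + 1L  # single block without terminator
    lines <- c(lines, "$$$$")
  }
  starts <- c(1L, head(ends, -1) + 1L)
  records <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:(ends[b] - 1L)]
    block <- block[cumsum(nchar(trimws(block)) > 0 | seq_along(block) <= 4) > 0]
    records[[b]] <- parse_sdf_block(block, b)
  }
  records[!vapply(records, is.null, logical(1))]
}

parse_sdf_block <- function(block, block_index) {
  if (all(trimws(block) == "")) return(NULL)
  if (length(block) < 4) {
    stop(sprintf("SDF block %d: truncated header", block_index))
  }
  name <- trimws(block[1])
  counts <- block[4]
  if (grepl("V3000", counts, fixed = TRUE)) {
    stop(sprintf(
      "SDF block %d: V3000 connection tables are not supported (V2000 only)",
      block_index))
  }
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 0 || nb < 0) {
    stop(sprintf("SDF block %d: malformed counts line: '%s'",
                 block_index, counts))
  }
  body <- block[-(1:4)]
  if (length(body) < na + nb) {
    stop(sprintf(
      "SDF block %d: counts line claims %d atoms and %d bonds but only %d lines follow",
      block_index, na, nb, length(body)))
  }
  atom_lines <- body[seq_len(na)]
  bond_lines <- if (nb > 0) body[na + seq_len(nb)] else character(0)
  ## atom block
  xs <- suppressWarnings(as.numeric(substr(atom_lines, 1, 10)))
  ys <- suppressWarnings(as.numeric(substr(atom_lines, 11, 20)))
  zs <- suppressWarnings(as.numeric(substr(atom_lines, 21, 30)))
  els <- trimws(substr(atom_lines, 32, 34))
  if (any(is.na(xs) | is.na(ys) | is.na(zs)) || any(els == "")) {
    bad <- which(is.na(xs) | is.na(ys) | is.na(zs) | els == "")[1]
    stop(sprintf("SDF block %d: malformed atom line %d: '%s'",
                 block_index, bad, atom_lines[bad]))
  }
  unknown <- setdiff(unique(els), SUPPORTED_ELEMENTS)
  if (length(unknown) > 0) {
    stop(sprintf("SDF block %d: unsupported element(s): %s",
                 block_index, paste(unknown, collapse = ", ")))
  }
  ## legacy charge column (positions 37-39): 0 none, 1..7 codes
  oldchg <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  oldchg[is.na(oldchg)] <- 0L
  fc <- ifelse(oldchg == 0L, 0L, 4L - oldchg)
  atoms <- data.frame(element = els, x = xs, y = ys, z = zs,
                      formal_charge = as.integer(fc),
                      partial_charge = NA_real_,
                      stringsAsFactors = FALSE)
  ## bond block
  if (nb > 0) {
    a1 <- suppressWarnings(as.integer(substr(bond_lines, 1, 3)))
    a2 <- suppressWarnings(as.integer(substr(bond_lines, 4, 6)))
    oo <- suppressWarnings(as.integer(substr(bond_lines, 7, 9)))
    if (any(is.na(a1) | is.na(a2) | is.na(oo))) {
      bad <- which(is.na(a1) | is.na(a2) | is.na(oo))[1]
      stop(sprintf("SDF block %d: malformed bond line %d: '%s'",
                   block_index, bad, bond_lines[bad]))
    }
    bonds <- data.frame(a1 = a1, a2 = a2, order = oo)
  } else {
    bonds <- empty_bonds()
  }
  rest <- if (length(body) > na + nb) body[(na + nb + 1L):length(body)] else
    character(0)
  ## properties block: M CHG overrides, until M END
  mend <- grep("^M  END", rest)
  prop_lines <- if (length(mend) > 0) rest[seq_len(mend[1] - 1L)] else
    character(0)
  for (pl in grep("^M  CHG", prop_lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substr(pl, 7, nchar(pl))),
                                "\\s+")[[1]])
    npair <- toks[1]
    if (length(toks) < 1 + 2 * npair) {
      stop(sprintf("SDF block %d: malformed M  CHG line", block_index))
    }
    ## a CHG block resets legacy column charges
    atoms$formal_charge <- 0L
    for (p in seq_len(npair)) {
      atoms$formal_charge[toks[2 * p]] <- toks[2 * p + 1]
    }
  }
  ## data items
  props <- list()
  if (length(mend) > 0 && mend[1] < length(rest)) {
    data_lines <- rest[(mend[1] + 1L):length(rest)]
    heads <- grep("^>", data_lines)
    for (hidx in seq_along(heads)) {
      h <- heads[hidx]
      key <- sub(".*<([^>]+)>.*", "\\1", data_lines[h])
      to <- if (hidx < length(heads)) heads[hidx + 1] - 1L else
        length(data_lines)
      val <- data_lines[(h + 1L):to]
      val <- val[trimws(val) != "" | seq_along(val) == 1]
      props[[key]] <- paste(trimws(val[trimws(val) != ""]), collapse = "\n")
    }
  }
  id <- if (nzchar(name)) name else sprintf("mol_%03d", block_index)
  mol <- molecule(id, atoms, bonds, source = "sdf")
  if (!is.null(props$PARTIAL_CHARGES)) {
    pc <- as.numeric(strsplit(props$PARTIAL_CHARGES, "\\s+")[[1]])
    if (length(pc) == nrow(atoms)) mol$atoms$partial_charge <- pc
  }
  rec <- molecule_record(mol,
                         activity = activity_from_properties(props),
                         cluster = props$CLUSTER)
  rec$properties <- props
  rec
}

activity_from_properties <- function(props) {
  if (is.null(props$ENDPOINT_TYPE) || is.null(props$ENDPOINT_VALUE)) {
    return(NULL)
  }
  rec <- activity_record(endpoint_type = props$ENDPOINT_TYPE,
                         value = as.numeric(props$ENDPOINT_VALUE),
                         units = if (is.null(props$UNITS)) NA_character_ else
                           props$UNITS)
  label_activity(rec)
}

#' Write molecule records to an MDL SDF (V2000) file
#'
#' Coordinates are written at 4 decimal places; formal charges go into
#' `M  CHG` lines; assigned partial charges are preserved through a
#' `PARTIAL_CHARGES` data item; activity and cluster annotations are
#' written as `ENDPOINT_TYPE`/`ENDPOINT_VALUE`/`UNITS`/`CLUSTER` items.
#' Output is byte-deterministic for identical input.
#'
#' @param records list of `af_record` (or a single record / `af_molecule`).
#' @param path output path.
#' @export
write_sdf <- function(records, path) {
  if (inherits(records, "af_record")) records <- list(records)
  if (inherits(records, "af_molecule")) {
    records <- list(molecule_record(records))
  }
  out <- character(0)
  for (rec in records) {
    mol <- if (inherits(rec, "af_record")) rec$molecule else rec
    a <- mol$atoms
    b <- mol$bonds
    lines <- c(
      mol$id,
      "  afqsar  3D",
      "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
              nrow(a), nrow(b))
    )
    xyz <- a[, c("x", "y", "z")]
    xyz[is.na(xyz)] <- 0
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      xyz$x, xyz$y, xyz$z, a$element))
    if (nrow(b) > 0) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", b$a1, b$a2, b$order))
    }
    chg <- which(a$formal_charge != 0)
    if (length(chg) > 0) {
      for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
        lines <- c(lines, paste0(
          "M  CHG", sprintf("%3d", length(grp)),
          paste0(sprintf("%4d%4d", grp, a$formal_charge[grp]),
                 collapse = "")))
      }
    }
    lines <- c(lines, "M  END")
    props <- if (inherits(rec, "af_record")) rec$properties else list()
    if (all(is.finite(a$partial_charge))) {
      props$PARTIAL_CHARGES <- paste(sprintf("%.8f", a$partial_charge),
                                     collapse = " ")
    }
    if (inherits(rec, "af_record")) {
      if (!is.null(rec$activity)) {
        props$ENDPOINT_TYPE <- rec$activity$endpoint_type
        props$ENDPOINT_VALUE <- format(rec$activity$value)
        if (!is.na(rec$activity$units)) props$UNITS <- rec$activity$units
        if (!is.null(rec$activity$activity_class)) {
          props$ACTIVITY_CLASS <- rec$activity$activity_class
        }
      }
      if (!is.null(rec$cluster)) props$CLUSTER <- rec$cluster
    }
    for (key in names(props)) {
      lines <- c(lines, sprintf(">  <%s>", key), props[[key]], "")
    }
    out <- c(out, lines, "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an activity table
#'
#' CSV contract: columns `id`, `smiles` (optional), `endpoint_type`,
#' `endpoint_value`, `units`, `cluster` (optional).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "endpoint_type", "endpoint_value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("activity CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Parse SMILES via OpenBabel
#'
#' Delegates SMILES interpretation to the OpenBabel command-line tool and
#' re-reads its V2000 output. The result has no meaningful coordinates;
#' run [embed_3d()] before computing 3D descriptors.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional identifiers (defaults to the SMILES strings).
#' @return list of `af_molecule`.
#' @export
parse_smiles <- function(smiles, ids = smiles) {
  if (Sys.which("obabel") == "") {
    stop("OpenBabel ('obabel') is required for SMILES input")
  }
  smi <- tempfile(fileext = ".smi")
  sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(smi, sdf)), add = TRUE)
  writeLines(paste(smiles, ids), smi)
  system2("obabel", c(smi, "-osdf", "-O", sdf), stdout = FALSE,
          stderr = FALSE)
  lapply(read_sdf(sdf), function(r) r$molecule)
}
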