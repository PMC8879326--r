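#' Keep the largest connected component
#'
#' Salt/solvent stripping: retains only the connected component with the
#' most heavy atoms. Ties are broken by larger summed atomic mass, then
#' by the lowest original first-atom index. Atom indices are compacted;
#' formal and partial charges of the kept atoms are preserved.
#'
#' @param mol an `af_molecule`.
#' @return standardized `af_molecule`.
#' @export
standardize <- function(mol) {
  if (!inherits(mol, "af_molecule")) stop("standardize expects af_molecule")
  if (n_atoms(mol) < 1) stop("cannot standardize an empty molecule")
  g <- full_graph(mol)
  comp <- igraph::components(g)$membership
  ids <- unique(comp)
  if (length(ids) == 1) return(mol)
  heavy <- !is_hydrogen(mol)
  mass <- element_property(mol$atoms$element, "mass")
  stats <- t(vapply(ids, function(cid) {
    m <- comp == cid
    c(n_heavy = sum(heavy & m), mass = sum(mass[m]),
      first = min(which(m)))
  }, c(n_heavy = 0, mass = 0, first = 0)))
  ord <- order(-stats[, "n_heavy"], -stats[, "mass"], stats[, "first"])
  keep_id <- ids[ord[1]]
  keep <- which(comp == keep_id)
  remap <- match(seq_len(n_atoms(mol)), keep)
  b <- mol$bonds
  b <- b[b$a1 %in% keep & b$a2 %in% keep, , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  molecule(mol$id, mol$atoms[keep, , drop = FALSE], b, mol$source)
}

is_connected_mol <- function(mol) {
  igraph::is_connected(full_graph(mol))
}
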