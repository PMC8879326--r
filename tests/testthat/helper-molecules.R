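## fixture molecules built in code ------------------------------------------

mk_mol <- function(id, el, bonds, fc = NULL, xyz = NULL) {
  atoms <- data.frame(element = el, x = NA_real_, y = NA_real_,
                      z = NA_real_, formal_charge = 0L,
                      partial_charge = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(fc)) atoms$formal_charge <- as.integer(fc)
  if (!is.null(xyz)) { atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3] }
  molecule(id, atoms, bonds)
}

chain_bonds <- function(n, order = 1L) {
  if (n < 2) return(empty_bonds())
  data.frame(a1 = seq_len(n - 1), a2 = 2:n, order = order)
}

## ethanol with explicit hydrogens and plausible 3D coordinates
fix_ethanol <- function() {
  el <- c("C", "C", "O", rep("H", 6))
  bonds <- data.frame(
    a1 = c(1, 2, 1, 1, 1, 2, 2, 3),
    a2 = c(2, 3, 4, 5, 6, 7, 8, 9),
    order = 1L)
  xyz <- rbind(
    c(0.000, 0.000, 0.000), c(1.512, 0.000, 0.000),
    c(2.033, 1.320, 0.000),
    c(-0.400, -0.520, 0.880), c(-0.400, -0.520, -0.880),
    c(-0.400, 1.030, 0.000),
    c(1.910, -0.520, 0.880), c(1.910, -0.520, -0.880),
    c(3.000, 1.290, 0.000))
  mk_mol("ethanol", el, bonds, xyz = xyz)
}

fix_ethane <- function() add_hydrogens(mk_mol("ethane", c("C", "C"),
                                              chain_bonds(2)))

fix_propane <- function() add_hydrogens(mk_mol("propane", rep("C", 3),
                                               chain_bonds(3)))

fix_neopentane <- function() {
  bonds <- data.frame(a1 = 1, a2 = 2:5, order = 1L)
  add_hydrogens(mk_mol("neopentane", rep("C", 5), bonds))
}

fix_benzene <- function() {
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 4L)
  add_hydrogens(mk_mol("benzene", rep("C", 6), bonds))
}

## random heavy-atom tree with n nodes and valence-respecting degrees
random_tree_mol <- function(n, seed, elements = c("C", "C", "C", "N", "O")) {
  withr::with_seed(seed, {
    el <- character(n)
    el[1] <- "C"
    deg <- integer(n)
    cap <- function(e) c(C = 4, N = 3, O = 2, S = 2)[e]
    bonds <- empty_bonds()
    for (i in seq_len(n)[-1]) {
      open <- which(deg[seq_len(i - 1)] < cap(el[seq_len(i - 1)]))
      p <- if (length(open) == 1) open else sample(open, 1)
      el[i] <- sample(elements, 1)
      bonds <- rbind(bonds, data.frame(a1 = p, a2 = i, order = 1L))
      deg[p] <- deg[p] + 1L; deg[i] <- 1L
    }
    mk_mol(sprintf("tree%d", seed), el, bonds)
  })
}

## permute atom order of a molecule, remapping bonds
permute_mol <- function(mol, perm) {
  inv <- order(perm)
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- mol$bonds
  b$a1 <- inv[b$a1]; b$a2 <- inv[b$a2]
  molecule(mol$id, atoms, b, mol$source)
}

## memoised planted-rule libraries shared across test files
.lib_cache <- new.env(parent = emptyenv())
planted_library <- function(seed, n = 200) {
  key <- sprintf("s%d_n%d", seed, n)
  if (is.null(.lib_cache[[key]])) {
    recs <- generate_library(synthetic_config(n_molecules = n, seed = seed))
    dm <- featurize(recs)
    .lib_cache[[key]] <- list(records = recs, dm = dm,
                              y = record_classes(recs))
  }
  .lib_cache[[key]]
}

## small embedded+charged random molecules for descriptor oracles
oracle_molecules <- function(n_mol = 50, seed = 404) {
  key <- sprintf("oracle_%d_%d", n_mol, seed)
  if (is.null(.lib_cache[[key]])) {
    recs <- generate_library(synthetic_config(
      n_molecules = n_mol, heavy_range = c(8, 18), seed = seed))
    .lib_cache[[key]] <- lapply(recs, `[[`, "molecule")
  }
  .lib_cache[[key]]
}
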