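#' Construct a molecule
#'
#' The package-wide molecule container: a named list with an atom table
#' (element, Cartesian coordinates in Angstrom, formal charge in e and,
#' once assigned, partial charge in e) and a bond table (1-based atom
#' indices and bond order). Bond order uses the MDL convention
#' 1/2/3/4, where 4 denotes an aromatic bond.
#'
#' @param id molecule identifier.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`,
#'   `formal_charge` (optional, default 0), `partial_charge` (optional).
#' @param bonds data.frame with columns `a1`, `a2`, `order`; may have
#'   zero rows for a single-atom molecule.
#' @param source free-text provenance.
#' @return object of class `af_molecule`.
#' @export
molecule <- function(id, atoms, bonds = empty_bonds(), source = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) < 1) stop("molecule must contain at least one atom")
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (is.null(atoms$partial_charge)) atoms$partial_charge <- NA_real_
  for (cc in c("x", "y", "z")) if (is.null(atoms[[cc]])) atoms[[cc]] <- NA_real_
  bad <- setdiff(unique(atoms$element), SUPPORTED_ELEMENTS)
  if (length(bad) > 0) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  }
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(bonds) > 0) {
    if (any(bonds$a1 == bonds$a2)) stop("bond connects an atom to itself")
    if (any(bonds$a1 < 1 | bonds$a2 < 1 |
            bonds$a1 > nrow(atoms) | bonds$a2 > nrow(atoms))) {
      stop("bond references an atom index outside the atom table")
    }
    key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
    if (!all(bonds$order %in% 1:4)) stop("bond order must be 1, 2, 3 or 4")
  }
  structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         source = source),
    class = "af_molecule"
  )
}

#' @export
print.af_molecule <- function(x, ...) {
  nh <- sum(x$atoms$element != "H")
  cat(sprintf("<af_molecule %s: %d atoms (%d heavy), %d bonds>\n",
              x$id, nrow(x$atoms), nh, nrow(x$bonds)))
  invisible(x)
}

#' @rdname molecule
#' @export
empty_bonds <- function() {
  data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
}

n_atoms <- function(mol) nrow(mol$atoms)

is_hydrogen <- function(mol) mol$atoms$element == "H"

heavy_indices <- function(mol) which(!is_hydrogen(mol))

coords_matrix <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

has_coords <- function(mol) {
  all(is.finite(as.matrix(mol$atoms[, c("x", "y", "z")])))
}

#' Molecular weight
#'
#' Sum of atomic masses over all atoms (explicit hydrogens included).
#'
#' @param mol an `af_molecule`.
#' @return molecular weight in g/mol.
#' @export
molecular_weight <- function(mol) {
  sum(element_property(mol$atoms$element, "mass"))
}

## numeric bond order: aromatic (MDL 4) contributes 1.5
bond_order_numeric <- function(order) {
  ifelse(order == 4, 1.5, as.numeric(order))
}

## adjacency over all atoms (explicit H included)
full_graph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds) > 0) mol$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol)))
  )
}

## hydrogen-suppressed graph; vertices keep their heavy-atom order.
## Returns list(graph, index) where index maps heavy position -> atom index.
heavy_graph <- function(mol) {
  hi <- heavy_indices(mol)
  pos <- match(seq_len(n_atoms(mol)), hi)
  b <- mol$bonds
  keep <- b$a1 %in% hi & b$a2 %in% hi
  b <- b[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(a1 = pos[b$a1], a2 = pos[b$a2]),
    directed = FALSE,
    vertices = data.frame(name = seq_along(hi))
  )
  list(graph = g, index = hi, order = bond_order_numeric(b$order),
       edges = cbind(pos[b$a1], pos[b$a2]))
}

## explicit hydrogens attached to each atom
explicit_h_counts <- function(mol) {
  h <- rep(0L, n_atoms(mol))
  if (nrow(mol$bonds) == 0) return(h)
  ish <- is_hydrogen(mol)
  for (k in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
    if (ish[a2]) h[a1] <- h[a1] + 1L
    if (ish[a1]) h[a2] <- h[a2] + 1L
  }
  h
}

## sum of numeric bond orders incident to each atom
valence_sums <- function(mol) {
  v <- rep(0, n_atoms(mol))
  if (nrow(mol$bonds) == 0) return(v)
  o <- bond_order_numeric(mol$bonds$order)
  for (k in seq_len(nrow(mol$bonds))) {
    v[mol$bonds$a1[k]] <- v[mol$bonds$a1[k]] + o[k]
    v[mol$bonds$a2[k]] <- v[mol$bonds$a2[k]] + o[k]
  }
  v
}

#' Fill valences with explicit hydrogens
#'
#' Adds hydrogen atoms to each heavy atom until its bond-order sum
#' reaches the element's standard valence adjusted by formal charge
#' (e.g. N+ takes 4, O- takes 1). Added hydrogens carry NA coordinates
#' when the parent has none; when the parent molecule has 3D
#' coordinates, each new H is placed 1.09 Angstrom from its parent,
#' pointing away from the mean direction of the parent's neighbours.
#'
#' @param mol an `af_molecule`.
#' @return molecule with explicit hydrogens.
#' @export
add_hydrogens <- function(mol) {
  vs <- valence_sums(mol)
  atoms <- mol$atoms
  bonds <- mol$bonds
  hv <- heavy_indices(mol)
  nbr <- vector("list", n_atoms(mol))
  for (k in seq_len(nrow(bonds))) {
    nbr[[bonds$a1[k]]] <- c(nbr[[bonds$a1[k]]], bonds$a2[k])
    nbr[[bonds$a2[k]]] <- c(nbr[[bonds$a2[k]]], bonds$a1[k])
  }
  have_xyz <- has_coords(mol)
  for (i in hv) {
    std <- element_property(atoms$element[i], "std_valence")
    target <- max(0, std + atoms$formal_charge[i])
    need <- round(target - vs[i])
    if (need <= 0) next
    for (q in seq_len(need)) {
      if (have_xyz) {
        p <- as.numeric(atoms[i, c("x", "y", "z")])
        nb <- nbr[[i]]
        dirv <- if (length(nb) > 0) {
          nbxyz <- as.matrix(atoms[nb, c("x", "y", "z")])
          d <- p - colMeans(nbxyz)
          if (sum(d^2) < 1e-8) d <- c(0, 0, 1)
          d / sqrt(sum(d^2))
        } else {
          c(1, 0, 0)
        }
        ## spread multiple H around the away direction
        ang <- 2 * pi * (q - 1) / max(1, need)
        perp <- if (abs(dirv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        perp <- perp - sum(perp * dirv) * dirv
        perp <- perp / sqrt(sum(perp^2))
        perp2 <- c(dirv[2] * perp[3] - dirv[3] * perp[2],
                   dirv[3] * perp[1] - dirv[1] * perp[3],
                   dirv[1] * perp[2] - dirv[2] * perp[1])
        u <- 0.8 * dirv + 0.6 * (cos(ang) * perp + sin(ang) * perp2)
        u <- u / sqrt(sum(u^2))
        hxyz <- p + 1.09 * u
      } else {
        hxyz <- c(NA_real_, NA_real_, NA_real_)
      }
      atoms <- rbind(atoms, data.frame(
        element = "H", x = hxyz[1], y = hxyz[2], z = hxyz[3],
        formal_charge = 0L, partial_charge = NA_real_,
        stringsAsFactors = FALSE
      )[, names(atoms)])
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = nrow(atoms),
                                       order = 1L))
    }
  }
  molecule(mol$id, atoms, bonds, mol$source)
}

#' Construct a molecule record
#'
#' Couples a molecule with an optional activity record and an optional
#' structural-cluster label (one of the roman numerals I-VII).
#'
#' @param molecule an `af_molecule`.
#' @param activity an [activity_record()] or NULL.
#' @param cluster cluster label in I-VII or NULL.
#' @return object of class `af_record`.
#' @export
molecule_record <- function(molecule, activity = NULL, cluster = NULL) {
  if (!inherits(molecule, "af_molecule")) stop("molecule must be af_molecule")
  if (!is.null(cluster)) {
    cluster <- as.character(cluster)
    if (!cluster %in% CLUSTER_LABELS) {
      stop("cluster must be one of ", paste(CLUSTER_LABELS, collapse = ", "))
    }
  }
  structure(list(molecule = molecule, activity = activity,
                 cluster = cluster, properties = list()),
            class = "af_record")
}

#' @export
print.af_record <- function(x, ...) {
  cat(sprintf("<af_record %s cluster=%s class=%s>\n", x$molecule$id,
              if (is.null(x$cluster)) "-" else x$cluster,
              if (is.null(x$activity) || is.null(x$activity$activity_class))
                "-" else x$activity$activity_class))
  invisible(x)
}

#' Seven structural cluster labels
#' @export
CLUSTER_LABELS <- c("I", "II", "III", "IV", "V", "VI", "VII")
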