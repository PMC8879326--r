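#' Heavy-atom weight vector
#'
#' Weights used by the autocorrelation and Burden descriptor families.
#' Codes: `m` mass, `c` partial charge, `v` van der Waals volume,
#' `e` Sanderson electronegativity, `p` polarizability, `i` first
#' ionization potential, `s` intrinsic (I-)state.
#'
#' @param mol an `af_molecule`.
#' @param weight one of `"m","c","v","e","p","i","s"` or a full column
#'   name of [atom_property_table()].
#' @return numeric vector over heavy atoms (atom-table order).
#' @export
atom_weights <- function(mol, weight) {
  hi <- heavy_indices(mol)
  code <- c(m = "mass", v = "vdw_volume", e = "sanderson_en",
            p = "polarizability", i = "ionization")
  if (weight %in% names(code)) weight <- code[[weight]]
  if (weight %in% colnames(atom_property_table())) {
    return(element_property(mol$atoms$element[hi], weight))
  }
  if (weight %in% c("c", "charge", "partial_charge")) {
    q <- mol$atoms$partial_charge[hi]
    if (anyNA(q)) stop("charge weighting requires assigned partial charges")
    return(q)
  }
  if (weight %in% c("s", "istate")) {
    return(intrinsic_states(mol))
  }
  stop("unknown weight: ", weight)
}

WEIGHT_CODES <- c("m", "c", "v", "e", "p", "i", "s")

#' Topological autocorrelation descriptor
#'
#' Pair sums of atomic weights over heavy-atom pairs at a fixed
#' topological distance (lag). With `P_d` the unordered pairs at
#' distance d, `D = |P_d|`, `wbar` the heavy-atom mean weight and `n`
#' the heavy-atom count:
#' \describe{
#'   \item{ATS}{Broto-Moreau, `sum w_i w_j` over `P_d`}
#'   \item{ATSC}{centred Broto-Moreau (weights replaced by `w - wbar`)}
#'   \item{AATS / AATSC}{the above divided by `D`}
#'   \item{Moran}{`[sum (w_i-wbar)(w_j-wbar)/D] / [sum_i (w_i-wbar)^2/n]`}
#'   \item{Geary}{`[sum (w_i-w_j)^2/(2D)] / [sum_i (w_i-wbar)^2/(n-1)]`}
#' }
#' No pair at the lag, or a zero-variance denominator for Moran/Geary,
#' yields NA (the missing-value policy decides its fate downstream).
#'
#' @param mol an `af_molecule`.
#' @param weight weight code, see [atom_weights()].
#' @param lag topological distance (>= 1).
#' @param variant one of ATS, ATSC, AATS, AATSC, Moran, Geary.
#' @param dmat optional precomputed [topo_distance_matrix()].
#' @param w optional precomputed weight vector.
#' @return single numeric (NA when undefined).
#' @export
autocorrelation <- function(mol, weight, lag,
                            variant = c("ATS", "ATSC", "AATS", "AATSC",
                                        "Moran", "Geary"),
                            dmat = NULL, w = NULL) {
  variant <- match.arg(variant)
  if (lag < 1) stop("lag must be >= 1")
  if (is.null(dmat)) dmat <- topo_distance_matrix(mol)
  if (is.null(w)) w <- atom_weights(mol, weight)
  n <- length(w)
  idx <- which(dmat == lag & upper.tri(dmat), arr.ind = TRUE)
  D <- nrow(idx)
  if (D == 0) return(NA_real_)
  wi <- w[idx[, 1]]; wj <- w[idx[, 2]]
  wbar <- mean(w)
  switch(variant,
    ATS = sum(wi * wj),
    ATSC = sum((wi - wbar) * (wj - wbar)),
    AATS = sum(wi * wj) / D,
    AATSC = sum((wi - wbar) * (wj - wbar)) / D,
    Moran = {
      s2 <- sum((w - wbar)^2) / n
      if (s2 <= 0) return(NA_real_)
      (sum((wi - wbar) * (wj - wbar)) / D) / s2
    },
    Geary = {
      if (n < 2) return(NA_real_)
      s2 <- sum((w - wbar)^2) / (n - 1)
      if (s2 <= 0) return(NA_real_)
      (sum((wi - wj)^2) / (2 * D)) / s2
    })
}

#' Burden-modified eigenvalue spectrum
#'
#' Eigenvalues of the symmetric Burden connectivity matrix over heavy
#' atoms: diagonal entries are atom weights relative to carbon's value;
#' bonded off-diagonal entries are 0.1 x numeric bond order (aromatic =
#' 1.5), plus 0.01 when either partner has degree 1; all non-bonded
#' entries are 0.001.
#'
#' @param mol an `af_molecule`.
#' @param weight weight code (see [atom_weights()]); relative scaling
#'   uses carbon's value of that property (partial-charge and I-state
#'   weights are used as-is, there being no meaningful carbon
#'   reference).
#' @return sorted (increasing) eigenvalue vector.
#' @export
burden_spectrum <- function(mol, weight) {
  hi <- heavy_indices(mol)
  n <- length(hi)
  if (n < 1) stop("burden_spectrum needs at least one heavy atom")
  w <- atom_weights(mol, weight)
  code <- c(m = "mass", v = "vdw_volume", e = "sanderson_en",
            p = "polarizability", i = "ionization")
  if (weight %in% names(code)) {
    w <- w / element_property("C", code[[weight]])
  } else if (weight %in% colnames(atom_property_table())) {
    w <- w / element_property("C", weight)
  } else if (weight %in% c("s", "istate")) {
    w <- w / 2  # intrinsic state of a chain sp3 carbon
  }
  B <- matrix(0.001, n, n)
  diag(B) <- w
  hg <- heavy_graph(mol)
  deg <- as.numeric(igraph::degree(hg$graph))
  if (nrow(hg$edges) > 0) {
    for (k in seq_len(nrow(hg$edges))) {
      i <- hg$edges[k, 1]; j <- hg$edges[k, 2]
      v <- 0.1 * hg$order[k]
      if (deg[i] == 1 || deg[j] == 1) v <- v + 0.01
      B[i, j] <- v; B[j, i] <- v
    }
  }
  sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
}

#' @rdname burden_spectrum
#' @param k rank (1-based from the respective end of the spectrum).
#' @export
spmin_k <- function(mol, weight, k) {
  ev <- burden_spectrum(mol, weight)
  if (k > length(ev)) return(NA_real_)
  ev[k]
}

#' @rdname burden_spectrum
#' @export
spmax_k <- function(mol, weight, k) {
  ev <- burden_spectrum(mol, weight)
  if (k > length(ev)) return(NA_real_)
  ev[length(ev) - k + 1]
}

#' Intrinsic states of heavy atoms
#'
#' Kier-Hall intrinsic state `I = ((2/L)^2 dv + 1)/d` with `L` the
#' principal quantum number, `dv = Zv - h` the valence-electron
#' connectivity (valence electrons minus attached hydrogens) and `d`
#' the heavy-atom sigma connectivity.
#'
#' @param mol an `af_molecule` with hydrogens explicit or countable.
#' @return numeric vector over heavy atoms.
#' @export
intrinsic_states <- function(mol) {
  hi <- heavy_indices(mol)
  nh <- explicit_h_counts(mol)[hi]
  el <- mol$atoms$element[hi]
  L <- element_property(el, "quantum_l")
  zv <- element_property(el, "n_valence")
  delta <- heavy_degrees(mol)
  if (any(delta == 0) && length(hi) > 1) {
    stop("isolated heavy atom: intrinsic state undefined")
  }
  delta[delta == 0] <- NA_real_  # single isolated heavy atom -> NA
  dv <- zv - nh
  ((2 / L)^2 * dv + 1) / delta
}

#' Electrotopological state (E-state) values
#'
#' `S_i = I_i + sum_j (I_i - I_j)/(d_ij + 1)^2` over all heavy atoms
#' `j != i`, with `d` the topological distance on the
#' hydrogen-suppressed graph.
#'
#' @param mol an `af_molecule`.
#' @return numeric vector of per-heavy-atom E-state values.
#' @export
estate_values <- function(mol) {
  I <- intrinsic_states(mol)
  n <- length(I)
  if (n == 1) return(I)
  d <- topo_distance_matrix(mol)
  S <- numeric(n)
  for (i in seq_len(n)) {
    S[i] <- I[i] + sum((I[i] - I[-i]) / (d[i, -i] + 1)^2)
  }
  S
}

## hydrogen E-state: same perturbation formula applied to explicit H
## atoms on the H-included graph, with I_H = 5 (L = 1, dv = 1, d = 1).
## Package convention, documented in the methods vignette.
hydrogen_estate_values <- function(mol) {
  ish <- is_hydrogen(mol)
  if (!any(ish)) return(numeric(0))
  g <- full_graph(mol)
  d <- igraph::distances(g)
  hi <- heavy_indices(mol)
  Ih <- 5
  Iheavy <- intrinsic_states(mol)
  hs <- numeric(sum(ish))
  hidx <- which(ish)
  for (k in seq_along(hidx)) {
    i <- hidx[k]
    hs[k] <- Ih + sum((Ih - Iheavy) / (d[i, hi] + 1)^2)
  }
  names(hs) <- hidx
  hs
}

## ---- E-state atom typing -------------------------------------------------

## shipped atom-type table; each entry returns matching indices
## (heavy-atom positions, or explicit-H positions for H types)
estate_type_match <- function(mol, type) {
  hi <- heavy_indices(mol)
  el <- mol$atoms$element[hi]
  nh <- explicit_h_counts(mol)[hi]
  deg <- heavy_degrees(mol)
  hg <- heavy_graph(mol)
  maxord <- rep(0, length(hi))
  if (nrow(hg$edges) > 0) {
    for (k in seq_len(nrow(hg$edges))) {
      i <- hg$edges[k, 1]; j <- hg$edges[k, 2]
      maxord[i] <- max(maxord[i], hg$order[k])
      maxord[j] <- max(maxord[j], hg$order[k])
    }
  }
  switch(type,
    ## quaternary carbon: four single bonds to heavy atoms, no H
    ssssC = which(el == "C" & deg == 4 & nh == 0 & maxord <= 1),
    ## -CH2-: carbon, two heavy single bonds, two hydrogens
    ssCH2 = which(el == "C" & deg == 2 & nh == 2 & maxord <= 1),
    ## weak H-bond acceptors: ether/thioether O or S (two single
    ## bonds, no H), pyridine-like aromatic N without H, and F
    wHBa = which((el %in% c("O", "S") & deg == 2 & nh == 0 & maxord <= 1) |
                   (el == "N" & maxord == 1.5 & nh == 0) |
                   el == "F"),
    ## H on a saturated carbon whose heavy neighbours are all
    ## saturated carbons (H-type: matches explicit hydrogens)
    HCsats = {
      ish <- which(is_hydrogen(mol))
      sat_c <- rep(FALSE, n_atoms(mol))
      sat_c[hi[el == "C" & maxord <= 1]] <- TRUE
      nbr <- vector("list", n_atoms(mol))
      for (k in seq_len(nrow(mol$bonds))) {
        nbr[[mol$bonds$a1[k]]] <- c(nbr[[mol$bonds$a1[k]]], mol$bonds$a2[k])
        nbr[[mol$bonds$a2[k]]] <- c(nbr[[mol$bonds$a2[k]]], mol$bonds$a1[k])
      }
      ok <- vapply(ish, function(h) {
        parent <- nbr[[h]]
        length(parent) == 1 && sat_c[parent] &&
          all(vapply(nbr[[parent]], function(x) {
            is_hydrogen(mol)[x] || sat_c[x]
          }, logical(1)))
      }, logical(1))
      ish[ok]
    },
    stop("unknown E-state atom type: ", type)
  )
}

ESTATE_TYPES <- c("ssssC", "ssCH2", "wHBa", "HCsats")

#' Atom-type E-state aggregate
#'
#' Aggregates E-state values over atoms matching a shipped atom-type
#' pattern. Heavy-atom types (`ssssC`, `ssCH2`, `wHBa`) aggregate
#' [estate_values()]; hydrogen types (`HCsats`) aggregate the hydrogen
#' E-state. No matching atom yields NA.
#'
#' @param mol an `af_molecule`.
#' @param type_pattern one of `"ssssC"`, `"ssCH2"`, `"wHBa"`, `"HCsats"`.
#' @param agg `"sum"`, `"max"` or `"min"`.
#' @return single numeric (NA when no atom matches).
#' @export
estate_atomtype <- function(mol, type_pattern, agg = c("sum", "max", "min")) {
  agg <- match.arg(agg)
  idx <- estate_type_match(mol, type_pattern)
  if (length(idx) == 0) return(NA_real_)
  if (type_pattern == "HCsats") {
    hs <- hydrogen_estate_values(mol)
    vals <- hs[as.character(idx)]
  } else {
    vals <- estate_values(mol)[idx]
  }
  switch(agg, sum = sum(vals), max = max(vals), min = min(vals))
}

#' Nitrogen weighted-path descriptor (WTPT-5 convention)
#'
#' Sum over nitrogen atoms of `1 + sum over simple paths starting at
#' the nitrogen of the product over path bonds of
#' 1/sqrt(deg_i * deg_j)` (Randic path weights; degrees on the
#' hydrogen-suppressed graph; each directed start counted once).
#' Molecules without nitrogen return 0 (a defined zero, not missing).
#'
#' @param mol an `af_molecule`.
#' @return single numeric.
#' @export
weighted_path_nitrogen <- function(mol) {
  hi <- heavy_indices(mol)
  el <- mol$atoms$element[hi]
  nidx <- which(el == "N")
  if (length(nidx) == 0) return(0)
  deg <- heavy_degrees(mol)
  adj <- heavy_adjacency(mol)
  n <- length(hi)
  nbr <- lapply(seq_len(n), function(i) which(adj[i, ] == 1))
  total <- 0
  for (s in nidx) {
    acc <- new.env()
    acc$sum <- 0
    visited <- rep(FALSE, n)
    dfs <- function(v, wprod) {
      visited[v] <<- TRUE
      for (u in nbr[[v]]) {
        if (!visited[u]) {
          w2 <- wprod / sqrt(deg[v] * deg[u])
          acc$sum <- acc$sum + w2
          dfs(u, w2)
        }
      }
      visited[v] <<- FALSE
    }
    dfs(s, 1)
    total <- total + 1 + acc$sum
  }
  total
}

#' Galvez topological charge indices
#'
#' With A the heavy-atom adjacency matrix and Q the inverse-square
#' topological distance matrix (zero diagonal), `M = A Q` and
#' `CT_ij = M_ij - M_ji`. `GGI_k` sums `|CT_ij|` over pairs at
#' topological distance k; `JGI_k = GGI_k / (n - 1)`.
#'
#' @param mol an `af_molecule` with >= 2 heavy atoms.
#' @param k topological distance order.
#' @return named numeric `c(GGI, JGI)`; NA when no pair at distance k.
#' @export
topological_charge_index <- function(mol, k) {
  d <- topo_distance_matrix(mol)
  n <- nrow(d)
  if (n < 2) stop("topological charge index needs >= 2 heavy atoms")
  A <- heavy_adjacency(mol)
  Q <- ifelse(d == 0, 0, 1 / d^2)
  M <- A %*% Q
  CT <- M - t(M)
  sel <- d == k & upper.tri(d)
  if (!any(sel)) return(c(GGI = NA_real_, JGI = NA_real_))
  ggi <- sum(abs(CT[sel]))
  c(GGI = ggi, JGI = ggi / (n - 1))
}

#' Mannhold LogP
#'
#' Atom-count estimate of the octanol-water partition coefficient:
#' `1.46 + 0.11 * nC - 0.11 * nHet` with `nC` the carbon count and
#' `nHet` the non-carbon heavy-atom count.
#'
#' @param mol an `af_molecule`.
#' @return single numeric.
#' @export
mannhold_logp <- function(mol) {
  hi <- heavy_indices(mol)
  el <- mol$atoms$element[hi]
  1.46 + 0.11 * sum(el == "C") - 0.11 * sum(el != "C")
}
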