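#' @title Element property tables
#' @description Per-element data used across the descriptor engine:
#'   atomic mass (u), Bondi van der Waals radius-derived volume (A^3),
#'   Sanderson electronegativity (dimensionless), dipole polarizability
#'   (A^3), first ionization potential (eV), number of valence electrons,
#'   principal quantum number of the valence shell and standard valence
#'   (used to fill implicit hydrogens). Table version: "v1" (values from
#'   standard physico-chemical compilations; swappable, see
#'   [atom_property_table()]).
#' @keywords internal
#' @name element-tables
NULL

SUPPORTED_ELEMENTS <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

.element_df <- local({
  el <- SUPPORTED_ELEMENTS
  r_vdw <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
             P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)
  data.frame(
    element = el,
    mass = c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
             P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904)[el],
    vdw_volume = (4 / 3) * pi * r_vdw[el]^3,
    sanderson_en = c(H = 2.592, C = 2.746, N = 3.194, O = 3.654, S = 2.957,
                     P = 2.515, F = 4.000, Cl = 3.475, Br = 3.219,
                     I = 2.778)[el],
    polarizability = c(H = 0.667, C = 1.760, N = 1.100, O = 0.802, S = 2.900,
                       P = 3.630, F = 0.557, Cl = 2.180, Br = 3.050,
                       I = 5.350)[el],
    ionization = c(H = 13.598, C = 11.260, N = 14.534, O = 13.618, S = 10.360,
                   P = 10.487, F = 17.423, Cl = 12.968, Br = 11.814,
                   I = 10.451)[el],
    n_valence = c(H = 1, C = 4, N = 5, O = 6, S = 6, P = 5, F = 7, Cl = 7,
                  Br = 7, I = 7)[el],
    quantum_l = c(H = 1, C = 2, N = 2, O = 2, S = 3, P = 3, F = 2, Cl = 3,
                  Br = 4, I = 5)[el],
    std_valence = c(H = 1, C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                    Br = 1, I = 1)[el],
    stringsAsFactors = FALSE
  )
})
rownames(.element_df) <- .element_df$element

#' Element-level atom property table
#'
#' Returns the versioned per-element property table used by the weighted
#' descriptors. Weight codes follow descriptor-naming conventions:
#' `m` mass, `v` van der Waals volume, `e` Sanderson electronegativity,
#' `p` polarizability, `i` first ionization potential. The two per-atom
#' weights (`c` partial charge, `s` intrinsic state) are computed per
#' molecule, not stored here.
#'
#' @param version table version string; only "v1" is shipped.
#' @return data.frame keyed by element symbol.
#' @export
atom_property_table <- function(version = "v1") {
  if (!identical(version, "v1")) {
    stop("unknown atom property table version: ", version)
  }
  .element_df
}

element_property <- function(elements, property) {
  bad <- setdiff(unique(elements), SUPPORTED_ELEMENTS)
  if (length(bad) > 0) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  }
  .element_df[elements, property]
}
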