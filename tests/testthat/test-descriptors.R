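test_that("topological distances match a BFS oracle", {
  path3 <- mk_mol("p3", rep("C", 3), chain_bonds(3))
  expect_equal(topo_distance_matrix(path3)[1, 3], 2L)
  ring6 <- mk_mol("r6", rep("C", 6),
                  data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 1L))
  expect_equal(max(topo_distance_matrix(ring6)), 3L)
  for (s in 1:5) {
    m <- random_tree_mol(12, seed = s)
    expect_equal(topo_distance_matrix(m),
                 matrix(as.integer(oracle_distances(m)), 12, 12))
  }
  two_frag <- mk_mol("frag", c("C", "C"), empty_bonds())
  expect_error(topo_distance_matrix(two_frag), "disconnected")
})

test_that("autocorrelation variants match hand values and the pair-sum oracle", {
  p3 <- mk_mol("p3", rep("C", 3), chain_bonds(3))
  expect_equal(autocorrelation(p3, NULL, 1, "ATS", w = rep(1, 3)), 2)
  ## centred variants vanish for uniform weights
  expect_equal(autocorrelation(p3, NULL, 1, "ATSC", w = rep(7, 3)), 0)
  expect_equal(autocorrelation(p3, NULL, 2, "ATSC", w = rep(7, 3)), 0)

  for (s in 1:6) {
    m <- random_tree_mol(10, seed = 100 + s)
    w <- atom_weights(m, "m")
    for (v in c("ATS", "ATSC", "AATS", "AATSC", "Moran", "Geary")) {
      for (lag in 1:8) {
        got <- autocorrelation(m, "m", lag, v)
        want <- oracle_autocorrelation(m, w, lag, v)
        if (is.na(want)) expect_true(is.na(got)) else
          expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("autocorrelation invariants hold", {
  m <- random_tree_mol(12, seed = 7)
  dmat <- topo_distance_matrix(m)
  w <- atom_weights(m, "e")
  for (lag in 1:5) {
    D <- sum(dmat == lag & upper.tri(dmat))
    if (D == 0) next
    expect_equal(autocorrelation(m, "e", lag, "AATS") * D,
                 autocorrelation(m, "e", lag, "ATS"), tolerance = 1e-10)
    ## ATS scales quadratically in the weights
    expect_equal(autocorrelation(m, NULL, lag, "ATS", w = 3 * w),
                 9 * autocorrelation(m, NULL, lag, "ATS", w = w),
                 tolerance = 1e-9)
    ## Moran / Geary are invariant under affine reweighting
    for (v in c("Moran", "Geary")) {
      expect_equal(autocorrelation(m, NULL, lag, v, w = 2.5 * w - 4),
                   autocorrelation(m, NULL, lag, v, w = w),
                   tolerance = 1e-9)
    }
  }
})

test_that("Burden spectrum matches closed forms and is permutation invariant", {
  single <- mk_mol("one", "S", empty_bonds())
  expect_equal(burden_spectrum(single, "m"),
               32.06 / 12.011, tolerance = 1e-12)

  ## two bonded terminal atoms: eigenvalues d -/+ (0.1 + 0.01)
  two <- mk_mol("two", c("C", "C"), chain_bonds(2))
  d <- 1  # mass relative to carbon
  expect_equal(burden_spectrum(two, "m"), c(d - 0.11, d + 0.11),
               tolerance = 1e-12)

  m <- random_tree_mol(8, seed = 21)
  ev <- burden_spectrum(m, "e")
  for (r in 1:5) {
    perm <- withr::with_seed(r, sample(nrow(m$atoms)))
    expect_equal(burden_spectrum(permute_mol(m, perm), "e"), ev,
                 tolerance = 1e-10)
  }
  ## agreement with the naive assembly
  tab <- atom_property_table()
  wrel <- tab[m$atoms$element, "polarizability"] / tab["C", "polarizability"]
  expect_equal(burden_spectrum(m, "p"), oracle_burden(m, wrel),
               tolerance = 1e-10)
  expect_true(is.na(spmin_k(two, "m", 5)))
  expect_equal(spmax_k(two, "m", 1), d + 0.11, tolerance = 1e-12)
})

test_that("E-state values match hand calculations", {
  expect_equal(estate_values(fix_ethane()), c(2, 2))
  expect_equal(estate_values(fix_propane()), c(2.125, 1.25, 2.125))
  ## symmetric atoms share S values
  neo <- fix_neopentane()
  S <- estate_values(neo)
  expect_equal(length(unique(round(S[2:5], 10))), 1)
  for (s in 1:5) {
    m <- random_tree_mol(9, seed = 300 + s)
    expect_equal(estate_values(m), oracle_estate(m), tolerance = 1e-10)
  }
})

test_that("atom-type E-state aggregates follow the shipped table", {
  neo <- fix_neopentane()
  expect_equal(estate_atomtype(neo, "ssssC", "max"), estate_values(neo)[1],
               tolerance = 1e-12)
  expect_equal(estate_atomtype(fix_propane(), "ssCH2", "sum"), 1.25)
  expect_true(is.na(estate_atomtype(fix_benzene(), "ssCH2", "sum")))
  expect_true(is.na(estate_atomtype(fix_propane(), "ssssC", "max")))
  ## hydrogen type: every propane H sits on a saturated carbon
  expect_false(is.na(estate_atomtype(fix_propane(), "HCsats", "min")))
  expect_error(estate_atomtype(fix_propane(), "nonsense"), "atom type")
})

test_that("nitrogen weighted paths match exhaustive enumeration", {
  expect_equal(weighted_path_nitrogen(fix_propane()), 0)
  nc <- mk_mol("nc", c("N", "C"), chain_bonds(2))
  expect_equal(weighted_path_nitrogen(nc), 2)
  for (s in 1:5) {
    m <- random_tree_mol(10, seed = 500 + s,
                         elements = c("C", "C", "N", "N", "O"))
    expect_equal(weighted_path_nitrogen(m), oracle_wtpt_n(m),
                 tolerance = 1e-10)
  }
})

test_that("topological charge indices match hand values", {
  two <- mk_mol("two", c("C", "C"), chain_bonds(2))
  expect_equal(unname(topological_charge_index(two, 1)), c(0, 0))
  p3 <- mk_mol("p3", rep("C", 3), chain_bonds(3))
  tci <- topological_charge_index(p3, 1)
  expect_equal(tci[["GGI"]], 0.5)
  expect_equal(tci[["JGI"]], 0.25)
  for (s in 1:4) {
    m <- random_tree_mol(9, seed = 700 + s)
    for (k in 1:3) {
      got <- topological_charge_index(m, k)
      want <- oracle_tci(m, k)
      if (is.na(want[["GGI"]])) expect_true(is.na(got[["GGI"]])) else {
        expect_equal(got[["GGI"]], want[["GGI"]], tolerance = 1e-10)
        expect_gte(got[["JGI"]], 0)
      }
    }
  }
})

test_that("Mannhold LogP follows the atom-count formula", {
  expect_equal(mannhold_logp(fix_benzene()), 2.12)
  expect_equal(mannhold_logp(mk_mol("o", "O", empty_bonds())), 1.35)
  eq <- mk_mol("eq", c("C", "N", "C", "O"), chain_bonds(4))
  expect_equal(mannhold_logp(eq), 1.46)
})

test_that("featurize produces a deterministic, documented matrix", {
  recs <- planted_library(1, n = 200)$records[1:2]
  cfg <- featurize_config(families = "rdf")
  dm <- featurize(recs, cfg)
  expect_equal(dim(dm$matrix), c(2, 384))
  dm2 <- featurize(recs, cfg)
  expect_identical(dm$matrix, dm2$matrix)

  full <- featurize(recs)
  expect_equal(ncol(full$matrix), nrow(full$manifest))
  expect_equal(ncol(full$matrix),
               6 * 7 * 8 + 2 * 5 * 7 + 5 + 1 + 3 + 1 + 384)
  expect_false(anyDuplicated(colnames(full$matrix)) > 0)
  expect_false(any(is.na(full$matrix)))

  ## a molecule without nitrogen scores WTPT-5 = 0, not missing
  m <- fix_propane()
  dm3 <- featurize(list(molecule_record(m)),
                   featurize_config(families = "2d"))
  expect_equal(unname(dm3$matrix[1, "WTPT.5"]), 0)
  expect_false(dm3$missing_mask[1, "WTPT.5"])

  ## strict policy names the offender
  expect_error(
    featurize(list(molecule_record(m)),
              featurize_config(families = "2d", missing_policy = "strict")),
    "propane")
})

test_that("descriptor engine matches oracles on generated molecules", {
  mols <- oracle_molecules(50)
  reltol <- function(a, b) {
    isTRUE(all.equal(a, b, tolerance = 1e-8))
  }
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    w <- atom_weights(m, "v")
    lag <- (k %% 6) + 1
    for (v in c("ATS", "Geary")) {
      want <- oracle_autocorrelation(m, w, lag, v)
      got <- autocorrelation(m, "v", lag, v)
      if (is.na(want)) expect_true(is.na(got)) else
        expect_true(reltol(got, want))
    }
    expect_true(reltol(estate_values(m), oracle_estate(m)))
    expect_true(reltol(weighted_path_nitrogen(m), oracle_wtpt_n(m)))
    want_rdf <- oracle_rdf(m)
    got_rdf <- rdf_descriptors(m)
    expect_true(reltol(unname(got_rdf[1:128]), unname(want_rdf["a", ])))
    expect_true(reltol(unname(got_rdf[129:256]), unname(want_rdf["b", ])))
    expect_true(reltol(unname(got_rdf[257:384]), unname(want_rdf["c", ])))
  }
})
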