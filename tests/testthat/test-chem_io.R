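sdf_block <- function(mol_lines) paste(c(mol_lines, "$$$$"), collapse = "\n")

ethanol_sdf_lines <- function() {
  m <- fix_ethanol()
  tf <- tempfile(fileext = ".sdf")
  write_sdf(molecule_record(m), tf)
  readLines(tf)
}

test_that("read_sdf parses blocks, counts and coordinates", {
  tf <- tempfile(fileext = ".sdf")
  writeLines(ethanol_sdf_lines(), tf)
  recs <- read_sdf(tf)
  expect_length(recs, 1)
  m <- recs[[1]]$molecule
  expect_equal(nrow(m$atoms), 9)       # 3 heavy + 6 H
  expect_equal(nrow(m$bonds), 8)
  expect_equal(m$atoms$element[1:3], c("C", "C", "O"))
  expect_equal(m$atoms$x[2], 1.512, tolerance = 1e-4)

  ## two blocks preserve file order
  two <- c(ethanol_sdf_lines(), ethanol_sdf_lines())
  two[length(ethanol_sdf_lines()) + 1] <- "ethanol2"
  writeLines(two, tf)
  recs2 <- read_sdf(tf)
  expect_length(recs2, 2)
  expect_equal(recs2[[2]]$molecule$id, "ethanol2")
})

test_that("read_sdf rejects malformed and unsupported input", {
  tf <- tempfile(fileext = ".sdf")
  ## counts line claims 5 atoms but lists 4
  bad <- c("bad", "  x", "",
           "  5  3  0  0  0  0  0  0  0  0999 V2000",
           sprintf("%10.4f%10.4f%10.4f %-3s 0", c(0, 1, 2, 3), 0, 0, "C"),
           "  1  2  1  0", "  2  3  1  0", "  3  4  1  0",
           "M  END", "$$$$")
  writeLines(bad, tf)
  expect_error(read_sdf(tf), "block 1")

  v3k <- c("m", "", "", "  0  0  0     0  0            999 V3000", "M  END",
           "$$$$")
  writeLines(v3k, tf)
  expect_error(read_sdf(tf), "V3000")

  uranium <- c("m", "", "", "  1  0  0  0  0  0  0  0  0  0999 V2000",
               sprintf("%10.4f%10.4f%10.4f %-3s 0", 0, 0, 0, "U"),
               "M  END", "$$$$")
  writeLines(uranium, tf)
  expect_error(read_sdf(tf), "U")
  expect_error(read_sdf(tempfile()), "exist")
})

test_that("SDF round-trip preserves structure, charges and properties", {
  recs <- planted_library(1, n = 200)$records[1:4]
  tf <- tempfile(fileext = ".sdf")
  write_sdf(recs, tf)
  back <- read_sdf(tf)
  expect_length(back, 4)
  for (k in seq_along(recs)) {
    a0 <- recs[[k]]$molecule$atoms; a1 <- back[[k]]$molecule$atoms
    expect_equal(a1$element, a0$element)
    expect_equal(a1$formal_charge, a0$formal_charge)
    expect_lt(max(abs(a1$x - a0$x)), 1e-4 + 1e-12)
    expect_equal(back[[k]]$molecule$bonds[, c("a1", "a2", "order")],
                 recs[[k]]$molecule$bonds[, c("a1", "a2", "order")])
    expect_lt(max(abs(a1$partial_charge - a0$partial_charge)), 1e-6)
    expect_equal(back[[k]]$cluster, recs[[k]]$cluster)
    expect_equal(back[[k]]$activity$activity_class,
                 recs[[k]]$activity$activity_class)
  }
})

test_that("written SDF agrees with an independent reader", {
  skip_if_not_installed("ChemmineR")
  m <- fix_ethanol()
  tf <- tempfile(fileext = ".sdf")
  write_sdf(molecule_record(m), tf)
  suppressWarnings(sdf <- ChemmineR::read.SDFset(tf))
  ab <- ChemmineR::atomblock(sdf[[1]])
  expect_equal(nrow(ab), 9)
  expect_equal(unname(ab[1:3, 1]), m$atoms$x[1:3], tolerance = 1e-4)
  expect_equal(nrow(ChemmineR::bondblock(sdf[[1]])), 8)
})

test_that("standardize keeps the dominant fragment", {
  ## salt pair: 12-atom chain + lone Cl
  salt <- mk_mol("salt", c(rep("C", 12), "Cl"), chain_bonds(12))
  out <- standardize(salt)
  expect_equal(nrow(out$atoms), 12)
  expect_true(all(out$atoms$element == "C"))

  ## already-connected molecule unchanged
  m <- fix_propane()
  expect_equal(nrow(standardize(m)$atoms), nrow(m$atoms))

  ## equal heavy-atom counts: heavier component wins (S > C chain)
  two <- mk_mol("two", c("C", "C", "C", "C", "S", "S"),
                rbind(data.frame(a1 = c(1, 2, 3), a2 = c(2, 3, 4), order = 1L),
                      data.frame(a1 = 5, a2 = 6, order = 1L)))
  ## components: 4xC (mass 48.044) vs 2xS (mass 64.12) -> fewer atoms lose
  expect_equal(nrow(standardize(two)$atoms), 4)
  tie <- mk_mol("tie", c("C", "C", "S", "S"),
                rbind(data.frame(a1 = 1, a2 = 2, order = 1L),
                      data.frame(a1 = 3, a2 = 4, order = 1L)))
  kept <- standardize(tie)
  expect_equal(sort(kept$atoms$element), c("S", "S"))
})

test_that("dedup keys are canonical and stereo-aware", {
  skip_if(Sys.which("obabel") == "", "OpenBabel not on PATH")
  recs <- planted_library(1, n = 200)$records
  m <- recs[[1]]$molecule
  perm <- withr::with_seed(1, sample(nrow(m$atoms)))
  expect_equal(dedup_key(m), dedup_key(permute_mol(m, perm)))

  ## enantiomers: mirrored 3D CHFClBr get different keys
  xyz <- rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.02, 0),
               c(-0.36, -0.51, 0.88), c(-0.36, -0.51, -0.88))
  bonds <- data.frame(a1 = 1, a2 = 2:5, order = 1L)
  mR <- mk_mol("chiR", c("C", "F", "Cl", "Br", "H"), bonds, xyz = xyz)
  xyzm <- xyz; xyzm[, 3] <- -xyzm[, 3]
  mS <- mk_mol("chiS", c("C", "F", "Cl", "Br", "H"), bonds, xyz = xyzm)
  kR <- dedup_key(mR); kS <- dedup_key(mS)
  expect_false(kR == kS)
  ## and the stereo layer is the only difference
  expect_equal(sub("/t.*$", "", kR), sub("/t.*$", "", kS))

  ## constitution-identical, stereo-unspecified (planar placeholder
  ## coordinates): equal keys
  flat <- mk_mol("flat", c("C", "F", "Cl", "Br", "H"), bonds,
                 xyz = rbind(c(0, 0, 0), c(1.3, 0, 0), c(-0.6, 1.1, 0),
                             c(-0.6, -1.1, 0), c(0, -1.3, 0)))
  flat2 <- permute_mol(flat, c(5, 1, 3, 2, 4))
  flat2$id <- "flat2"
  expect_equal(dedup_key(flat), dedup_key(flat2))
})

test_that("graph key provider is permutation invariant", {
  mols <- oracle_molecules(6)
  for (m in mols) {
    k0 <- dedup_key(m, provider = "graph")
    for (r in 1:20) {
      perm <- withr::with_seed(r, sample(nrow(m$atoms)))
      expect_identical(dedup_key(permute_mol(m, perm), provider = "graph"),
                       k0)
    }
  }
  ## distinct constitutions get distinct keys
  expect_false(dedup_key(fix_propane(), provider = "graph") ==
                 dedup_key(fix_neopentane(), provider = "graph"))
})

test_that("deduplicate reproduces the curation record flows", {
  mk_rec <- function(id, key) {
    r <- molecule_record(mk_mol(id, "C", empty_bonds()))
    r$properties$DEDUP_KEY <- key
    r
  }
  ## 142 records with one internal duplicate -> 141 survivors
  model_set <- lapply(seq_len(142), function(i) {
    mk_rec(sprintf("M%03d", i), sprintf("K%03d", i))
  })
  model_set[[142]]$properties$DEDUP_KEY <- "K001"
  surv <- deduplicate(model_set)
  expect_length(surv, 141)
  log <- attr(surv, "removal_log")
  expect_equal(log$reason, "internal_duplicate")

  ## 14,506 library records, 3 keys collide with the model set -> 14,503
  lib <- lapply(seq_len(14506), function(i) {
    mk_rec(sprintf("L%05d", i), sprintf("LK%05d", i))
  })
  for (i in 1:3) lib[[i * 1000]]$properties$DEDUP_KEY <- sprintf("K%03d", i)
  surv2 <- deduplicate(lib, against = surv)
  expect_length(surv2, 14503)
  expect_equal(sort(attr(surv2, "removal_log")$reason),
               rep("duplicate_of_reference_set", 3))

  ## idempotence and empty `against`
  expect_length(deduplicate(surv), 141)
  expect_length(deduplicate(model_set, against = list()), 141)
})
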