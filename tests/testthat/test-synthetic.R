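test_that("configuration guards reject impossible settings", {
  expect_error(synthetic_config(active_fraction = 0), "active_fraction")
  expect_error(synthetic_config(flip_prob = 0.5), "flip_prob")
  expect_error(synthetic_config(heavy_range = c(20, 10)), "heavy-atom")
})

test_that("generated libraries are valid, labelled and deterministic", {
  recs <- generate_library(synthetic_config(n_molecules = 30, seed = 42))
  expect_length(recs, 30)
  tab <- atom_property_table()
  for (r in recs) {
    m <- r$molecule
    ## valences within standard limits (formal-charge adjusted)
    vs <- afqsar:::valence_sums(m)
    lim <- tab[m$atoms$element, "std_valence"] + m$atoms$formal_charge
    expect_true(all(vs <= lim + 1e-9))
    expect_true(afqsar:::is_connected_mol(m))
    expect_true(all(is.finite(as.matrix(m$atoms[, c("x", "y", "z")]))))
    expect_equal(sum(m$atoms$partial_charge), sum(m$atoms$formal_charge),
                 tolerance = 1e-6)
    expect_true(r$cluster %in% CLUSTER_LABELS)
    ## endpoint values are consistent with the stored class
    expect_equal(r$activity$activity_class,
                 label_activity(r$activity)$activity_class)
  }
  ## byte-identical regeneration
  r2 <- generate_library(synthetic_config(n_molecules = 5, seed = 9))
  r3 <- generate_library(synthetic_config(n_molecules = 5, seed = 9))
  d1 <- tempfile(); d2 <- tempfile()
  write_library(r2, d1); write_library(r3, d2)
  expect_identical(readLines(file.path(d1, "library.sdf")),
                   readLines(file.path(d2, "library.sdf")))
  expect_true(file.exists(file.path(d1, "activity.csv")))
  expect_true(file.exists(file.path(d1, "clusters.csv")))
})

test_that("realized class ratio tracks the configured fraction", {
  lib <- planted_library(1, n = 200)
  frac <- mean(lib$y == "A")
  expect_gte(frac, 0.40)
  expect_lte(frac, 0.50)
})

test_that("embedding respects bonded and steric bounds", {
  chain <- add_hydrogens(mk_mol("c5", rep("C", 5), chain_bonds(5)))
  emb <- embed_3d(chain, seed = 3)
  xyz <- as.matrix(emb$atoms[, c("x", "y", "z")])
  d <- sqrt(rowSums((xyz[emb$bonds$a1, ] - xyz[emb$bonds$a2, ])^2))
  heavy <- emb$bonds$a1 <= 5 & emb$bonds$a2 <= 5
  expect_true(all(abs(d[heavy] - 1.5) < 0.3))

  ## same seed, same coordinates
  emb2 <- embed_3d(chain, seed = 3)
  expect_identical(emb$atoms$x, emb2$atoms$x)
  expect_false(identical(emb$atoms$x, embed_3d(chain, seed = 4)$atoms$x))

  ## steric audit over generated molecules: no bonded pair outside
  ## [1.2, 1.9], no non-bonded pair closer than 1.5
  recs <- planted_library(1, n = 200)$records[1:40]
  for (r in recs) {
    m <- r$molecule
    xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
    D <- as.matrix(dist(xyz))
    bonded <- cbind(m$bonds$a1, m$bonds$a2)
    db <- D[bonded]
    expect_true(all(db >= 1.2 & db <= 1.9))
    nb <- D
    nb[bonded] <- NA; nb[bonded[, 2:1]] <- NA
    diag(nb) <- NA
    expect_true(all(nb[!is.na(nb)] > 1.5))
  }
  expect_error(embed_3d(mk_mol("f", c("C", "C"), empty_bonds())),
               "connected")
})

test_that("compiled embedding penalty matches the reference implementation", {
  m <- add_hydrogens(mk_mol("c6", rep("C", 6), chain_bonds(6)))
  n <- nrow(m$atoms)
  b1 <- m$bonds$a1; b2 <- m$bonds$a2
  r0 <- ifelse(m$atoms$element[b1] == "H" | m$atoms$element[b2] == "H",
               1.3, 1.5)
  allp <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  bonded <- matrix(FALSE, n, n)
  bonded[cbind(b1, b2)] <- TRUE; bonded[cbind(b2, b1)] <- TRUE
  nb <- allp[!bonded[allp], , drop = FALSE]
  rs <- data.frame(i = 1L, j = n, target = 5.0, weight = 8)
  for (s in 1:10) {
    par <- withr::with_seed(s, rnorm(3 * n, sd = 2))
    eR <- afqsar:::embed_energy(par, b1, b2, r0, nb, n, rs)
    eC <- afqsar:::embed_energy_cpp(par, b1, b2, r0, nb[, 1], nb[, 2], n,
                                    rs$i, rs$j, rs$target, rs$weight)
    expect_equal(eC, eR, tolerance = 1e-12)
    ## analytic gradient vs central differences
    g <- afqsar:::embed_gradient_cpp(par, b1, b2, r0, nb[, 1], nb[, 2], n,
                                     rs$i, rs$j, rs$target, rs$weight)
    pick <- withr::with_seed(s, sample(3 * n, 4))
    for (k in pick) {
      h <- 1e-6
      pp <- par; pp[k] <- pp[k] + h
      pm <- par; pm[k] <- pm[k] - h
      num <- (afqsar:::embed_energy(pp, b1, b2, r0, nb, n, rs) -
                afqsar:::embed_energy(pm, b1, b2, r0, nb, n, rs)) / (2 * h)
      expect_equal(g[k], num, tolerance = 1e-5)
    }
  }
})

test_that("the planted rule combines motif and charge-pair geometry", {
  cfg <- synthetic_config(seed = 1)
  ## quaternary carbon + strong pair at 5.0 A -> active at zero noise
  el <- c("C", "C", "C", "C", "C", "O")
  bonds <- rbind(data.frame(a1 = 1, a2 = 2:5, order = 1L),
                 data.frame(a1 = 5, a2 = 6, order = 1L))
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0), c(0, 1.5, 0),
               c(0, -1.5, 0), c(0, -6.3, 0))
  m <- mk_mol("rule", el, bonds, xyz = xyz)
  m$atoms$partial_charge <- c(0, 0.45, 0, 0, 0, -0.7)
  ## pair distance: atom2 (0.45e) to atom6 (-0.7e) = sqrt(1.5^2+6.3^2)
  expect_true(afqsar:::planted_rule(m, cfg$window, cfg$charge_threshold) ==
                (sqrt(1.5^2 + 6.3^2) >= 4.5 && sqrt(1.5^2 + 6.3^2) <= 5.5))
  cfg0 <- synthetic_config(flip_prob = 0, seed = 1)
  expect_equal(plant_activity(m, cfg0, seed = 2),
               if (afqsar:::planted_rule(m, cfg$window,
                                         cfg$charge_threshold)) "A" else "B")

  ## same structure with the pair pulled into the window -> active
  m_in <- m
  m_in$atoms$y[6] <- -4.8   # d(2,6) = sqrt(1.5^2 + 4.8^2) ~ 5.03
  expect_true(afqsar:::planted_rule(m_in, cfg$window, cfg$charge_threshold))
  expect_equal(plant_activity(m_in, cfg0, seed = 2), "A")

  ## no motif -> inactive at zero noise regardless of geometry
  m2 <- m
  m2$bonds <- m2$bonds[-1, ]  # break one quaternary bond
  m2 <- molecule("rule2", m2$atoms, m2$bonds)
  expect_false(afqsar:::planted_rule(m2, cfg$window, cfg$charge_threshold))
  expect_equal(plant_activity(m2, cfg0, seed = 5), "B")
})

test_that("label noise flips at the configured binomial rate", {
  cfg <- synthetic_config(flip_prob = 0.1, seed = 3)
  m <- mk_mol("flip", "C", empty_bonds(), xyz = matrix(0, 1, 3))
  m$atoms$partial_charge <- 0
  ## rule is FALSE for this molecule; count A labels = flips
  labs <- vapply(1:1000, function(s) plant_activity(m, cfg, seed = s),
                 character(1))
  flips <- sum(labs == "A")
  ## binomial 99% interval around p = 0.1, n = 1000
  expect_gte(flips, qbinom(0.005, 1000, 0.1))
  expect_lte(flips, qbinom(0.995, 1000, 0.1))
})
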