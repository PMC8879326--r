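#!/usr/bin/env Rscript

## Step 1 — simulate the study library.
##
## Generates the synthetic molecule library that stands in for the
## curated antifouling data set: 200 drug-like molecules with 3D
## coordinates, equalization partial charges, scaffold-family cluster
## labels (I-VII) and a binary activity class from the planted
## motif-plus-charge-geometry rule at 5% label noise. Writes the
## library (SDF + activity/cluster CSVs) under results/library/.

suppressMessages(library(afqsar))

seed <- 1
cfg <- synthetic_config(n_molecules = 200, seed = seed)
message("simulating ", cfg$n_molecules, " molecules (seed ", seed, ") ...")
records <- generate_library(cfg)

write_library(records, "results/library")
y <- record_classes(records)
message(sprintf("library written: %d molecules, %d active / %d inactive (%.2f)",
                length(records), sum(y == "A"), sum(y == "B"),
                mean(y == "A")))
cl <- table(vapply(records, `[[`, character(1), "cluster"))
message("cluster composition: ",
        paste(names(cl), cl, sep = "=", collapse = ", "))
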