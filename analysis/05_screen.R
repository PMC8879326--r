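#!/usr/bin/env Rscript

## Step 5 — virtual screening triage.
##
## Generates a fresh synthetic screening library (different seed from
## the training library), deduplicates it against the training
## molecules, scores it with the selected RF, applies the confidence
## threshold and the docking-selection threshold (Prob_active >= 0.68)
## and writes the ranked hit table under results/.

suppressMessages(library(afqsar))

seed <- 1
records <- read_sdf("results/library/library.sdf")
dm <- featurize(records)
y <- record_classes(records)
selected <- readLines("results/selected_descriptors.txt")
rf <- train_balanced_rf(dm$matrix[, selected, drop = FALSE], y, seed = seed)

message("simulating screening library ...")
lib_cfg <- synthetic_config(n_molecules = 300, seed = seed + 1000)
library_recs <- generate_library(lib_cfg)

## curation: drop cross-set duplicates by canonical key
provider <- if (Sys.which("obabel") != "") "inchi" else "graph"
library_recs <- deduplicate(library_recs, against = records,
                            provider = provider)
message(length(library_recs), " library molecules survive deduplication")

lib_dm <- featurize(library_recs)
theta <- as.numeric(strsplit(readLines(
  "results/confidence_threshold.txt"), "\t")[[1]][2])

hits <- predict_library(rf, lib_dm$matrix[, selected, drop = FALSE],
                        theta_conf = theta)
hits <- shortlist(hits, theta_dock = 0.68)
write_hits(hits, "results/screening_hits.csv")

message(sprintf(
  "screened %d molecules: %d predicted active, %d above theta=%.2f, %d shortlisted (>= 0.68)",
  nrow(hits), sum(hits$predicted_class == "A"),
  sum(hits$above_confidence), theta, sum(hits$shortlist)))
message("top of the ranked list:")
print(head(as.data.frame(hits), 5), digits = 3)
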