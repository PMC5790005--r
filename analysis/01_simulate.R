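#!/usr/bin/env Rscript
# Stage 1 — simulate the study material: a signed interactome with a planted
# two-hub convergence circuit, curated-style seed sets for the degeneration
# and protection conditions, a hidden ground-truth propagation model, a
# 40-row noiseless truth table, and a 50-drug library (planted synergistic
# pair, one-flag-ineligible decoy pair, single actives, nulls).
#
# Writes every external table plus ground_truth.yaml to results/demo/.

library(netscreen)

sc <- scenario(seed = 1)
print(sc)

dat <- generate_scenario_data(sc, outdir = "results/demo")

cat(sprintf("interactome: %d nodes, %d signed edges (%.0f%% inhibitory)\n",
            length(dat$interactome$nodes), nrow(dat$interactome$edges),
            100 * mean(dat$interactome$edges$sign < 0)))
cat(sprintf("planted pair %s + %s: singles %.1f%% / %.1f%%, pair %.1f%%, synergy %.1f pts (ground truth)\n",
            dat$labels$planted_pairs[[1]][1], dat$labels$planted_pairs[[1]][2],
            dat$labels$planted_single_efficacy[1],
            dat$labels$planted_single_efficacy[2],
            dat$labels$planted_pair_efficacy, dat$labels$planted_synergy_pts))
cat(sprintf("truth table: %d rows (%d noisy), tolerance %.2f\n",
            n_restrictions(dat$restrictions),
            length(dat$labels$noisy_rows), sc$restriction_tolerance))
cat("tables written under results/demo/\n")
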