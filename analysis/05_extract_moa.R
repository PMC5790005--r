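#!/usr/bin/env Rscript
# Stage 5 — mode of action of the best candidate: rank non-clamped map nodes
# by how far the pair's propagated state departs from the better single
# drug's state (node-wise highest-single-agent expectation), and compare the
# top nodes against the planted convergence read-outs.

library(netscreen)

model <- read_model_checkpoint("results/demo/model_checkpoint.tsv")
lib <- read_drug_library("results/demo/drug_targets.tsv",
                         "results/demo/drug_metadata.tsv")
sigs <- read_signatures("results/demo/signatures.tsv")
passing <- read_ranked_combinations("results/demo/passing.tsv")
gt <- yaml::read_yaml("results/demo/ground_truth.yaml")

stopifnot(nrow(passing) >= 1)
pair <- list(lib[[passing$drug_a[1]]], lib[[passing$drug_b[1]]])
moa <- extract_moa(model, pair, sigs$protection, top_k = 10)
print(moa, digits = 3)

hit <- intersect(moa$node, unlist(gt$moa_nodes))
cat(sprintf("%d of the top %d mode-of-action nodes are planted read-outs (%s)\n",
            length(hit), nrow(moa), paste(hit, collapse = ", ")))
write.table(moa, "results/demo/moa.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/demo/moa.tsv\n")
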