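#!/usr/bin/env Rscript
# Stage 3 — convert the degeneration map into a propagation model and train
# its sign-constrained edge strengths and biases against the truth table by
# simulated annealing; report restriction satisfaction against a
# label-shuffled chance control and 5-fold cross-validated held-out
# satisfaction. Saves the trained checkpoint for the screening stage.

library(netscreen)

net <- read_interactome("results/demo/interactome.tsv")
seeds <- read_seed_sets("results/demo/seeds.tsv")
map_deg <- expand_map(net, seeds$degeneration)
rt <- read_restrictions("results/demo/restrictions.tsv")

seed <- 101L
fit <- train(build_model(map_deg, seed = seed), rt, seed = seed)
print(fit$report)

ctrl <- train(build_model(map_deg, seed = seed),
              shuffle_restrictions(rt, seed = seed), seed = seed)
cat(sprintf("label-shuffled control satisfaction: %.3f (trained: %.3f)\n",
            ctrl$report$satisfaction, fit$report$satisfaction))

cv <- cross_validate(function() build_model(map_deg, seed = seed), rt,
                     k_folds = 5, seed = seed)
cat(sprintf("5-fold held-out satisfaction: %.3f (folds: %s)\n",
            cv$mean, paste(sprintf("%.2f", cv$per_fold), collapse = " ")))

write_model_checkpoint(fit$model, "results/demo/model_checkpoint.tsv")
cat("wrote results/demo/model_checkpoint.tsv\n")
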