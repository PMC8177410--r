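#!/usr/bin/env Rscript
# Evolve product-unit networks on the simulated cohort: mutation-only
# evolutionary programming over architecture and weights. Writes the
# per-generation trace and the best network.

suppressPackageStartupMessages(library(lripu))
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(cohort_spec(n = 404, seed = 20260901))
cfg <- ea_config(pop_size = 100, generations = 200, seed = 20260902)

ev <- evolve(cohort$design, cfg, verbose = TRUE)
print(ev)

write_trace_csv(ev, "results/epunn_trace.csv")
punn_to_json(ev$best_model, "results/epunn_best.json")

message(sprintf(
  "best network: %d unit(s), %d parameters, fitness %.5f (train CE %.4f)",
  length(ev$best_model$units), n_params(ev$best_model), ev$best_fitness,
  1 / ev$best_fitness - 1))
message("wrote results/epunn_trace.csv and results/epunn_best.json")
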