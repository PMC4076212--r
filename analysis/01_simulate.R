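#!/usr/bin/env Rscript
# Stage 1: generate a DHS-like synthetic survey on the Nigeria 31-region
# graph with known ground truth (fixed effects sized like the published
# adjusted odds ratios, an age effect peaking near 45, a partner-age
# effect peaking near 70, and ICAR + iid state effects), and write the
# records, the adjacency file and the truth for later stages.
library(geoadd)

seed <- 2026L
out <- "results"
dir.create(out, showWarnings = FALSE)

graph <- nigeria_graph()
cfg <- sim_config(n = 25000, graph = graph, tau2_spat = 0.3,
                  tau2_unstr = 0.05, p_underweight = 0.12, seed = seed)
sim <- simulate_survey(cfg)

dir.create("scratch", showWarnings = FALSE)
write_records(sim$records, "scratch/records.csv")  # bulky intermediate
write_adjacency(graph, file.path(out, "graph.txt"))
write_codebook(default_codebook(), file.path(out, "codebook.yaml"))
jsonlite::write_json(
  list(intercept = sim$truth$intercept,
       spatial_effects = as.list(sim$truth$spatial_effects),
       unstructured_effects = as.list(sim$truth$unstructured_effects)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
saveRDS(sim, "scratch/sim.rds")   # scratch only; later stages reload it

cat("simulated", nrow(sim$records), "records over",
    length(graph$regions), "regions\n")
cat("underweight fraction:",
    round(mean(sim$records$bmi < 18.5), 3), "\n")
cat("overweight/obese among the rest:",
    round(mean(sim$truth$y, na.rm = TRUE), 3), "\n")
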