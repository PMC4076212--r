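#!/usr/bin/env Rscript
# Stage 5: the Bayesian geo-additive binary regression.  Fixed effects for
# the categorical covariates, P-spline smooths of respondent and partner
# age (K = 20 cubic basis functions, second-order random-walk prior),
# structured ICAR + unstructured iid state effects, inverse-gamma
# IG(0.001, 0.001) hyperpriors, fitted by Polya-Gamma Gibbs sampling.
library(geoadd)

aset <- readRDS("scratch/aset.rds")
graph <- read_adjacency("results/graph.txt")

mc <- mcmc_config(iterations = 12000, burnin = 2000, thin = 10,
                  seed = 2027L)
t0 <- Sys.time()
draws <- fit_geoadditive(aset, graph, config = mc)
cat("sampling took", round(as.numeric(Sys.time() - t0, units = "mins"), 1),
    "minutes for", nrow(draws$beta), "saved draws\n")

saveRDS(draws, "scratch/draws.rds")

h <- chain_health(draws)
write.csv(h, "results/chain_health.csv", row.names = FALSE)
cat("intercept ESS:", round(h$ess[h$parameter == "(Intercept)"]), "\n")
cat("parameters with |Geweke z| < 3:",
    sprintf("%.1f%%", 100 * mean(abs(h$geweke_z) < 3)), "\n")
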