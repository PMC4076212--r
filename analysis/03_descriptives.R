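#!/usr/bin/env Rscript
# Stage 3: descriptive tables.  First the published worked examples —
# prevalence figures recomputed from the printed cross-tab counts — then
# the same machinery applied to the synthetic analysis set: whole-sample
# description, prevalence cross-tabs by state and covariates, chi-square
# and Mann-Whitney group comparisons, and crude odds ratios.
library(geoadd)

out <- "results"

## Published worked examples (printed counts are the input here)
tab <- published_counts()
w <- tab[tab$variable == "wealth", ]
n_uw <- attr(tab, "underweight_excluded")
n_total <- sum(w$n_case) + sum(w$n_control) + n_uw
cat(sprintf("published sample: %d women; combined prevalence %.1f%%\n",
            n_total, 100 * sum(w$n_case) / n_total))
cat(sprintf("analysis set after excluding %d underweight: %d\n",
            n_uw, n_total - n_uw))
st <- tab[tab$variable == "state", ]
prev <- crude_prevalence(st$n_case, st$n_control)
cat(sprintf("state prevalence range: %.1f%% (%s) to %.1f%% (%s)\n",
            min(prev), st$level[which.min(prev)],
            max(prev), st$level[which.max(prev)]))
rich <- w[w$level == "richest", ]; poor <- w[w$level == "poorest", ]
or_rp <- crude_odds_ratio(rich$n_case, rich$n_control,
                          poor$n_case, poor$n_control)
cat(sprintf("crude OR richest vs poorest: %.2f (%.2f, %.2f)\n",
            or_rp$or, or_rp$lower, or_rp$upper))
write.csv(cbind(st, prevalence = prev),
          file.path(out, "published_state_prevalence.csv"),
          row.names = FALSE)

## Synthetic analysis set
aset <- readRDS("scratch/aset.rds")
ds <- describe_sample(aset$data)
write.csv(ds$continuous, file.path(out, "table1_continuous.csv"),
          row.names = FALSE)
write.csv(ds$categorical, file.path(out, "table1_categorical.csv"),
          row.names = FALSE)
for (v in c("state", "wealth", "educ_respondent", "residence")) {
  ct <- cross_tab(aset, v)
  ct$chi_sq <- attr(ct, "statistic"); ct$p <- attr(ct, "p.value")
  write.csv(ct, file.path(out, paste0("prevalence_by_", v, ".csv")),
            row.names = FALSE)
}
gt <- group_comparisons(aset)
write.csv(gt, file.path(out, "group_tests.csv"), row.names = FALSE)
print(gt)
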