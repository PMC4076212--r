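#!/usr/bin/env Rscript
# Stage 2: read the simulated records back from disk, apply WHO BMI
# categorisation, exclude underweight women, build the binary
# overweight/obesity outcome and report the exclusion ledger.
library(geoadd)

rec <- read_records("scratch/records.csv")
aset <- build_analysis_set(rec)
print(aset)

jsonlite::write_json(aset$ledger, "results/ledger.json", auto_unbox = TRUE)
saveRDS(aset, "scratch/aset.rds")

stopifnot(aset$ledger$retained + aset$ledger$underweight_excluded +
            aset$ledger$incomplete_excluded == aset$ledger$input)
cat("ledger reconciles exactly\n")
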