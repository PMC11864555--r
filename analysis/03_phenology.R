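#!/usr/bin/env Rscript

# Stage 3 — migration phenology statistics.
#
# Per region-year: the median date of migration timing (MDMT, first day the
# running cumulative catch exceeds half the Oct-Dec total) at the coast and
# in the river, and the coastal residence time (riverine minus coastal
# MDMT). Also reports the regional spread of mean coastal MDMT.

library(chumphen)

dat <- read_dataset("results/data")
labels <- read.csv("results/labels.csv", stringsAsFactors = FALSE)

phen <- phenology_table(dat, labels)
write.csv(phen, "results/phenology.csv", row.names = FALSE)

cat("mean coastal MDMT (days since Oct 1) by region and regime:\n")
print(round(tapply(phen$coastal_mdmt, list(phen$region, phen$regime), mean), 1))

cat(sprintf("\nregional sd of mean coastal MDMT: %.2f days\n",
            sd(tapply(phen$coastal_mdmt, phen$region, mean))))

cat("\nmean coastal residence time (days) by region:\n")
print(round(tapply(phen$residence_days, phen$region, mean), 1))

n_flag <- sum(phen$flag != "")
cat(sprintf("\nflagged region-years (negative/undefined residence): %d\n", n_flag))
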