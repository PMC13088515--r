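#!/usr/bin/env Rscript
# Stage 3: fertility phenotypes of risk matings.
#
# For each deficient region, classifies registered matings into risk1
# (carrier sire x carrier dam), risk2 (carrier sire x carrier maternal
# grandsire, dam ungenotyped) and non-risk categories plus carrier-sire /
# non-carrier-sire groups, then contrasts insemination success, stillbirth
# rate and juvenile mortality with two-proportion z-tests.

library(haplolethal)

matings <- read.csv("results/simulation/matings.csv")
foals <- read.csv("results/simulation/foals.csv")
ped <- read.csv("results/simulation/pedigree.csv", colClasses = "character")
regions <- read.delim("results/scan/regions.tsv")

dir.create("results/phenotypes", recursive = TRUE, showWarnings = FALSE)
for (rid in regions$region_id) {
  status <- read.csv(sprintf("results/scan/carrier_status_%s.csv", rid),
                     colClasses = "character")
  cls <- classify_matings(matings, status, ped)
  tab <- mating_category_table(cls, foals)
  write.table(tab$categories,
              sprintf("results/phenotypes/%s_categories.tsv", rid),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tab$contrasts,
              sprintf("results/phenotypes/%s_contrasts.tsv", rid),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ins <- tab$contrasts[tab$contrasts$phenotype == "insemination_success", ]
  for (j in seq_len(nrow(ins)))
    cat(sprintf("%s %-28s success %.1f%% vs %.1f%% (rel diff %.1f%%, p = %.3g)\n",
                rid, ins$comparison[j], 100 * ins$rate_cmp[j],
                100 * ins$rate_ref[j], ins$delta_rel_pct[j], ins$p_value[j]))
}
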