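#!/usr/bin/env Rscript
# Stage 4: multi-locus assisted selection.
#
# Ranks the detected QTL cofactors by explained variance, stacks up to five
# of them into ideotypes per trait, and tracks the ideotype subgroup
# (N/mean/SD/CI), the one-way haplotype ANOVA adjusted R^2, and the
# positive/negative predictive values at the 0.045 g cutoff. Writes
# stack_table.tsv.

suppressMessages(library(seedqtl))
cfg <- analysis_config(seed = as.integer(Sys.getenv("SEEDQTL_SEED", "1")))
out <- "results/multiloci"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

maps <- list(MA = read_map_csv("results/simdata/map_MA.csv"),
             CS = read_map_csv("results/simdata/map_CS.csv"))
genos <- list(MA = read_genotype_csv("results/simdata/geno_MA.csv", "MA", maps$MA),
              CS = read_genotype_csv("results/simdata/geno_CS.csv", "CS", maps$CS))
pheno <- read_phenotype_csv("results/simdata/phenotypes.csv")
blups <- utils::read.csv("results/pheno_stats/blups.csv")
qtl <- utils::read.delim("results/qtl_scan/qtl_results.tsv")

rows <- list()
for (tr in cfg$traits) {
  res <- qtl[qtl$trait == tr & qtl$significance != "none", ]
  if (nrow(res) < 1) next
  rk <- rank_markers(res, tr)
  k_max <- min(5, nrow(rk))
  btr <- blups[blups$trait == tr, ]
  steps <- stack_selection(genos$MA, genos$CS,
                           data.frame(id = btr$id, value = btr$blup),
                           rk, k_max = k_max)
  sedw_mean <- tapply(pheno$SEDW, pheno$id, mean)
  pv <- predictive_value_trajectory(steps, sedw_mean, cutoff = cfg$cutoff_g)
  tabtr <- cbind(trait = tr, rk[seq_len(k_max), c("order", "parent", "cofactor", "favorable")],
                 steps, ppv = pv$ppv, npv = pv$npv)
  rows[[tr]] <- tabtr
  if (any(tabtr$k == k_max) && k_max > 1) {
    message(sprintf("%s: ideotype mean %.4f -> %.4f (-%.1f%%), adj R2 %.2f%% -> %.2f%%",
                    tr, steps$ideotype_mean[1], steps$ideotype_mean[k_max],
                    relative_decrease(steps, k_max),
                    steps$adj_r2_pct[1], steps$adj_r2_pct[k_max]))
  }
}
utils::write.table(do.call(rbind, rows), file.path(out, "stack_table.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
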