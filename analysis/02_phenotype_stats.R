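#!/usr/bin/env Rscript
# Stage 2: descriptive phenotype statistics and BLUPs.
#
# Per-season descriptives (mean, SD, bias-corrected skewness/kurtosis),
# inter-season Spearman correlations, REML variance components and the
# shrunken genotype BLUPs used as the QTL-mapping response. Reads stage 1's
# phenotypes; writes summary.csv, spearman.csv and blups.csv.

suppressMessages(library(seedqtl))
out <- "results/pheno_stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
pheno <- read_phenotype_csv("results/simdata/phenotypes.csv")

summaries <- do.call(rbind, lapply(c("SEDW", "SEDN", "SEDA"),
                                   function(tr) describe_trait(pheno, tr)))
utils::write.csv(summaries, file.path(out, "summary.csv"), row.names = FALSE)

sp_rows <- list(); blup_rows <- list()
for (tr in c("SEDW", "SEDN", "SEDA")) {
  sp <- spearman_between_seasons(pheno, tr)
  sp_rows[[tr]] <- data.frame(trait = tr, mean_rho = sp$mean_rho)
  vc <- fit_variance_components(pheno, tr)
  bl <- compute_blups(pheno, tr, vc)
  blup_rows[[tr]] <- data.frame(id = bl$id, trait = tr,
                                raw_mean = bl$raw_mean, blup = bl$blup)
  message(sprintf("%s: mean inter-season Spearman %.3f; sigma2_g %.4g, sigma2_e %.4g",
                  tr, sp$mean_rho, vc$sigma2_g, vc$sigma2_e))
}
utils::write.csv(do.call(rbind, sp_rows), file.path(out, "spearman.csv"),
                 row.names = FALSE)
utils::write.csv(do.call(rbind, blup_rows), file.path(out, "blups.csv"),
                 row.names = FALSE)
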