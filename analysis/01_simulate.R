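#!/usr/bin/env Rscript
# Stage 1: simulate the MA x CS study population.
#
# Builds the two parental maps (1575 / 1430 cM, ~1 cM marker spacing),
# simulates 573 F1 offspring by Haldane meiosis for each parent, and
# generates four seasons of SEDW/SEDN/SEDA phenotypes under the packaged
# 24-QTL architecture (partially dominant chr18 major locus plus small
# stable QTLs). Also injects the 0.35% intragenic 5'UTR/exon-7
# recombinants used by stage 5. Writes all tables under results/simdata/.

suppressMessages(library(seedqtl))
seed <- as.integer(Sys.getenv("SEEDQTL_SEED", "1"))
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- cross_design(seed = seed)
sim <- simulate_cross(design)

write_map_csv(sim$map_ma, file.path(out, "map_MA.csv"))
write_map_csv(sim$map_cs, file.path(out, "map_CS.csv"))
write_genotype_csv(sim$geno_ma, file.path(out, "geno_MA.csv"))
write_genotype_csv(sim$geno_cs, file.path(out, "geno_CS.csv"))
write_phenotype_csv(sim$pheno, file.path(out, "phenotypes.csv"))

# exon-7 causal SNP calls (b carriers are G/T) and a concordant 5'UTR SSR,
# then inject intragenic recombinants at the design rate
arch <- qtl_architecture()
maj_cm <- arch$position_cm[arch$trait == "SEDW" & arch$chrom == "18"]
sub <- sim$map_cs[sim$map_cs$chrom == "18", ]
mk <- sub$marker[which.min(abs(sub$cm - maj_cm))]
snp <- setNames(ifelse(sim$geno_cs[, mk] == "b", "G/T", "G/G"),
                rownames(sim$geno_cs))
ssr <- setNames(grepl("T", snp), names(snp))
inj <- inject_intragenic_recombinants(snp, ssr,
                                      rate = design$intragenic_recomb_rate,
                                      seed = seed)
calls <- rbind(
  data.frame(id = names(snp), marker = "e7_VviAGL11", call = unname(snp)),
  data.frame(id = names(inj$ssr_calls), marker = "5U_VviAGL11",
             call = ifelse(inj$ssr_calls, "319", "289")))
utils::write.csv(calls, file.path(out, "marker_calls.csv"), row.names = FALSE,
                 quote = FALSE)
writeLines(inj$flipped, file.path(out, "injected_recombinants.txt"))

message(sprintf("simulated %d offspring x (%d + %d) markers, %d seasons; %d intragenic recombinant(s) injected",
                design$n_offspring, nrow(sim$map_ma), nrow(sim$map_cs),
                length(design$seasons), length(inj$flipped)))
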