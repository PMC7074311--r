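test_that("Kruskal-Wallis scan matches hand-computed ranks and flags monomorphic markers", {
  y <- c(1.2, 3.4, 2.2, 5.1, 4.0, 6.3)
  geno <- matrix(c("a", "a", "a", "b", "b", "b",
                   "a", "a", "a", "a", "a", "a"), ncol = 2,
                 dimnames = list(sprintf("o%d", 1:6), c("m1", "mono")))
  res <- kw_scan(y, geno)
  # ranks of y in groups: a = {1, 3, 2}, b = {5, 4, 6}
  H_manual <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(res$H[1], H_manual, tolerance = 1e-12)
  expect_equal(res$p[1], pchisq(H_manual, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(res$excluded[2])
  expect_true(is.na(res$H[2]))
})

test_that("Kruskal-Wallis p-values are uniform under permuted labels", {
  set.seed(11)
  y <- rnorm(60)
  ps <- replicate(200, {
    g <- matrix(sample(rep(c("a", "b"), 30)), ncol = 1,
                dimnames = list(NULL, "m"))
    kw_scan(y, g)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("interval mapping at a marker equals single-marker regression", {
  map <- small_map(spacing = 5)
  set.seed(2)
  geno <- simulate_progeny(map, 300, seed = 2)
  x <- as.numeric(geno[, 7] == "b")
  y <- 0.5 * x + rnorm(300)
  prof <- interval_mapping(y, map, geno, step_cm = 2.5)
  at_marker <- prof[prof$chrom == map$chrom[7] & prof$cm == map$cm[7], ]
  fit1 <- lm(y ~ x); fit0 <- lm(y ~ 1)
  lod_lm <- (300 / 2) * log10(sum(resid(fit0)^2) / sum(resid(fit1)^2))
  expect_equal(at_marker$lod, lod_lm, tolerance = 1e-9)
})

test_that("LOD equals its F-statistic identity on a fixed toy set", {
  y <- c(4.1, 3.8, 5.2, 4.9, 6.0, 5.5, 7.1, 6.6, 4.4, 5.8, 6.9, 5.1)
  x <- c(0, 0, 0, 0, 1, 1, 1, 1, 0, 1, 1, 0)
  map1 <- genetic_map("m1", "1", 0, 100, "MA")
  geno <- matrix(c("a", "b")[x + 1], ncol = 1,
                 dimnames = list(sprintf("o%d", 1:12), "m1"))
  prof <- interval_mapping(y, map1, geno)
  Fstat <- summary(lm(y ~ x))$fstatistic[["value"]]
  expect_equal(prof$lod, (12 / 2) * log10(1 + Fstat / (12 - 2)), tolerance = 1e-9)
})

test_that("cofactor selection keeps true QTLs and drops noise markers", {
  expect_identical(select_cofactors(rnorm(10),
                                    matrix("a", 10, 1,
                                           dimnames = list(NULL, "m")),
                                    character(0)),
                   character(0))

  map <- small_map(n_chrom = 2, len_cm = 60, spacing = 5)
  geno <- simulate_progeny(map, 573, seed = 13)
  x1 <- as.numeric(geno[, "chr1_4600000_1"] == "b")   # 15 cM on chr 1
  x2 <- as.numeric(geno[, "chr2_9100000_1"] == "b")   # 30 cM on chr 2
  set.seed(14)
  # effect sizes give ~48% and ~9% explained variance
  y <- 2 * sqrt(0.48) * x1 + 2 * sqrt(0.09) * x2 + rnorm(573, 0, sqrt(0.43))

  # single strong QTL: only its marker survives among noise candidates
  cands <- c("chr1_4600000_1", "chr2_100000_1", "chr2_18100000_1")
  got <- select_cofactors(2 * x1 + rnorm(573, 0, 1), geno, cands)
  expect_identical(got, "chr1_4600000_1")

  # two unlinked QTLs of large and modest effect: both retained
  got2 <- select_cofactors(y, geno, c("chr1_4600000_1", "chr2_9100000_1",
                                      "chr1_18100000_1"))
  expect_true(all(c("chr1_4600000_1", "chr2_9100000_1") %in% got2))
})

test_that("permutation thresholds order genome-wise above chromosome-wise", {
  map <- small_map(n_chrom = 3, len_cm = 40, spacing = 10)
  geno <- simulate_progeny(map, 200, seed = 5)
  y <- rnorm(200)
  thr <- permutation_thresholds(y, map, geno, n_perm = 200, alpha = 0.05, seed = 8)
  expect_true(all(thr$genome_wide >= thr$chrom_wide))
  thr1 <- permutation_thresholds(y, map, geno, n_perm = 200, alpha = 1, seed = 8)
  expect_true(all(thr1$genome_wide >= thr1$chrom_wide))
  expect_lte(thr1$genome_wide, thr$genome_wide)
  expect_error(permutation_thresholds(y, map, geno, n_perm = 200, alpha = 0),
               "alpha")
  expect_error(permutation_thresholds(y, map, geno, n_perm = 50), "100")
})

test_that("LOD support intervals behave on flat, triangular and random profiles", {
  flat <- data.frame(cm = 0:20, lod = rep(2, 21))
  si <- lod_support_interval(flat, 1)
  expect_equal(c(si$cm_lo, si$cm_hi), c(0, 20))

  tri <- data.frame(cm = 40:60, lod = 5 - 0.5 * abs(40:60 - 50))
  si1 <- lod_support_interval(tri, 1)
  expect_equal(c(si1$cm_lo, si1$cm_hi), c(48, 52))
  expect_equal(si1$peak_cm, 50)

  set.seed(6)
  rnd <- data.frame(cm = 0:50, lod = cumsum(rnorm(51))^2 / 10)
  a <- lod_support_interval(rnd, 1)
  b <- lod_support_interval(rnd, 2)
  expect_lte(b$cm_lo, a$cm_lo)
  expect_gte(b$cm_hi, a$cm_hi)

  # bp interpolation from the map
  map_chr <- data.frame(cm = c(40, 60), bp = c(4e6, 6e6))
  si_bp <- lod_support_interval(tri, 1, map_chr)
  expect_equal(c(si_bp$bp_lo, si_bp$bp_hi), c(4.8e6, 5.2e6))
})

test_that("MQM reports explained variance, class means and the stability rule", {
  map <- small_map(n_chrom = 2, len_cm = 60, spacing = 5)
  geno <- simulate_progeny(map, 400, seed = 23)
  x <- as.numeric(geno[, "chr1_9100000_1"] == "b")
  set.seed(24)
  y <- 0.8 * x + rnorm(400, 0, 0.5)
  thr <- list(genome_wide = 3,
              chrom_wide = c("1" = 2, "2" = 2), alpha = 0.05, n_perm = 1000)

  # seasons 1 and 3 carry the signal, 2 and 4 are noise -> stable
  seas_sig <- cbind(s1 = y + rnorm(400, 0, 0.2), s2 = rnorm(400),
                    s3 = y + rnorm(400, 0, 0.2), s4 = rnorm(400))
  mq <- mqm_scan(y, map, geno, "chr1_9100000_1", thr, season_values = seas_sig)
  expect_equal(mq$cofactor, "chr1_9100000_1")
  expect_equal(mq$significance, "significant")
  expect_true(mq$stable)
  expect_equal(mq$n_seasons_detected, 2)
  expect_gt(mq$mean_b, mq$mean_a)
  r2 <- summary(lm(y ~ x))$r.squared
  expect_equal(mq$pct_var, 100 * r2, tolerance = 1e-6)

  # only one season carries the signal -> not stable
  seas_one <- cbind(s1 = y, s2 = rnorm(400), s3 = rnorm(400), s4 = rnorm(400))
  mq1 <- mqm_scan(y, map, geno, "chr1_9100000_1", thr, season_values = seas_one)
  expect_false(mq1$stable)

  expect_error(mqm_scan(y, map, geno, "nope", thr), "absent")
})

test_that("an unlinked cofactor does not depress the focal QTL's LOD", {
  map <- small_map(n_chrom = 2, len_cm = 60, spacing = 5)
  geno <- simulate_progeny(map, 500, seed = 31)
  x1 <- as.numeric(geno[, "chr1_9100000_1"] == "b")
  x2 <- as.numeric(geno[, "chr2_9100000_1"] == "b")
  set.seed(32)
  y <- 0.8 * x1 + 0.5 * x2 + rnorm(500, 0, 0.6)
  prof_alone <- interval_mapping(y, map, geno)
  prof_cof <- interval_mapping(y, map, geno, cofactors = "chr2_9100000_1")
  pk_alone <- max(prof_alone$lod[prof_alone$chrom == "1"])
  pk_cof <- max(prof_cof$lod[prof_cof$chrom == "1"])
  expect_gte(pk_cof, pk_alone - 0.5)  # Monte-Carlo slack only
})

test_that("SNP names parse to chromosome and physical position", {
  p <- parse_snp_name(c("chr2_5144635_1", "e7_VviAGL11"))
  expect_equal(p$chrom, c("2", NA))
  expect_equal(p$bp, c(5144635, NA))
})

test_that("gene lookup in a support interval follows GFF3 closed coordinates", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tgene\t300\t400\t.\t-\t.\tID=g2",
    "chr1\tsrc\tgene\t500\t600\t.\t+\t.\tID=g3",
    "chr1\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=t1;Parent=g1"
  ), gff)
  genes <- read_gff3_genes(gff)
  expect_equal(nrow(genes), 3)
  hit <- genes_in_interval(genes, "chr1", 150, 350)
  expect_equal(hit$count, 2)
  expect_setequal(hit$genes$gene_id, c("g1", "g2"))
  # closed-interval boundary: touching at a single bp counts
  expect_equal(genes_in_interval(genes, "chr1", 200, 299)$count, 1)
  expect_equal(genes_in_interval(genes, "chr1", 201, 299)$count, 0)
  expect_equal(genes_in_interval(genes[0, ], "chr1", 1, 1e9)$count, 0)

  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tsrc\tgene\t100\t200\t.\t+"), bad)
  expect_error(read_gff3_genes(bad), "line 2")
})
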