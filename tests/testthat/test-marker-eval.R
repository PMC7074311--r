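test_that("phenotype binarization respects the 0.045 g cutoff and boundary rule", {
  x <- c(a = 0.044, b = 0.046, c = 0.045)
  expect_equal(unname(binarize_phenotype(x)), c("seedless", "seeded", "seedless"))
  expect_equal(unname(binarize_phenotype(x, boundary = "strict"))[3], "seeded")
  expect_identical(binarize_phenotype(numeric(0)), character(0))
  expect_error(binarize_phenotype(c(-0.01)), "negative")
})

test_that("contingency metrics reproduce the published cross-validation counts", {
  # RG x AR progeny, exon-7 SNP: 13/4 of 17 seedless, 1/30 of 31 seeded
  m <- metrics_from_counts(tp = 13, fp = 1, fn = 4, tn = 30)
  expect_equal(m$metrics$sensitivity, 13 / 17)
  expect_equal(m$metrics$specificity, 30 / 31)
  expect_equal(m$metrics$mcc,
               (13 * 30 - 1 * 4) / sqrt(14 * 17 * 31 * 34))
  expect_equal(round(m$metrics$mcc, 3), 0.771)
  # identities
  expect_equal(m$metrics$fpr + m$metrics$specificity, 1)
  expect_equal(m$metrics$fnr + m$metrics$sensitivity, 1)
  expect_equal(m$metrics$accuracy, 43 / 48)

  perfect <- contingency_and_metrics(rep(c("seedless", "seeded"), c(5, 7)),
                                     rep(c("seedless", "seeded"), c(5, 7)))
  expect_true(all(unlist(perfect$metrics[c("sensitivity", "specificity",
                                           "precision", "npv", "accuracy",
                                           "mcc")]) == 1))

  worst <- metrics_from_counts(tp = 0, fp = 3, fn = 4, tn = 0)
  expect_equal(worst$metrics$mcc, -1)

  onesided <- contingency_and_metrics(rep("seedless", 6),
                                      rep(c("seedless", "seeded"), 3))
  expect_false(onesided$metrics$mcc_defined)
  expect_true(is.na(onesided$metrics$mcc))

  expect_error(contingency_and_metrics("x", "seedless"), "alphabet")
})

test_that("two-tailed Fisher exact matches full enumeration", {
  expect_equal(fisher_exact_two_tailed(c(1, 1, 1, 1)), 1)
  expect_equal(fisher_exact_two_tailed(c(3, 0, 0, 3)), 0.1, tolerance = 1e-12)
  expect_message(p0 <- fisher_exact_two_tailed(c(0, 0, 3, 4)), "margin")
  expect_equal(p0, 1)

  set.seed(99)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_tailed(tab),
                 fisher_enum_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
  }
  # invariance to transposition
  tab <- matrix(c(13, 1, 4, 30), 2, 2)
  expect_equal(fisher_exact_two_tailed(tab), fisher_exact_two_tailed(t(tab)),
               tolerance = 1e-12)
})

test_that("PIC follows the Botstein formula and its bounds", {
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
  # equifrequent alleles: PIC strictly increases with allele count
  vals <- vapply(2:25, function(k) pic(rep(1 / k, k)), 0)
  expect_true(all(diff(vals) > 0))
  # PIC never exceeds expected heterozygosity
  set.seed(12)
  for (i in 1:20) {
    p <- as.numeric(rmultinom(1, 200, runif(sample(2:8, 1)))) / 200
    p <- p[p > 0]
    expect_lte(pic(p), 1 - sum(p^2) + 1e-12)
  }
})

test_that("recombinant detection round-trips the simulator's flip log", {
  ids <- sprintf("F1_%04d", 1:573)
  set.seed(5)
  snp <- setNames(sample(c("G/G", "G/T"), 573, replace = TRUE), ids)
  ssr <- setNames(grepl("T", snp), ids)
  expect_equal(find_recombinants(ssr, snp)$rate, 0)
  expect_length(find_recombinants(ssr, snp)$discordant, 0)

  inj <- inject_intragenic_recombinants(snp, ssr, rate = 2 / 573, seed = 77)
  found <- find_recombinants(inj$ssr_calls, snp)
  expect_setequal(found$discordant, inj$flipped)

  # two discordant of 573 prints as 0.35%
  ssr2 <- ssr; ssr2[c(10, 200)] <- !ssr2[c(10, 200)]
  expect_equal(find_recombinants(ssr2, snp)$rate_pct, 0.35)
  expect_error(find_recombinants(ssr, snp[-1]), "same ids")
})

test_that("packaged validation counts give coherent marker comparisons", {
  counts <- read.csv(system.file("extdata", "marker_validation_counts.csv",
                                 package = "seedqtl"))
  # the causal SNP is perfect on the variety panel, the SSR is not
  e7 <- counts[counts$material == "varieties_209" & counts$marker == "e7_VviAGL11", ]
  ssr <- counts[counts$material == "varieties_209" & counts$marker == "5U_VviAGL11", ]
  m_e7 <- metrics_from_counts(e7$tp, e7$fp, e7$fn, e7$tn)
  m_ssr <- metrics_from_counts(ssr$tp, ssr$fp, ssr$fn, ssr$tn)
  expect_equal(m_e7$metrics$mcc, 1)
  expect_equal(m_ssr$metrics$sensitivity, 1)
  expect_equal(round(m_ssr$metrics$specificity, 3), 0.938)
  expect_equal(round(m_ssr$metrics$accuracy, 3), 0.952)
  expect_equal(round(m_ssr$metrics$precision, 3), 0.828)
  expect_lt(m_ssr$metrics$mcc, 1)
  expect_lt(fisher_exact_two_tailed(c(ssr$tp, ssr$fp, ssr$fn, ssr$tn)), 1e-10)
})
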