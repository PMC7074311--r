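test_that("marker ranking orders by explained variance with the low class favorable", {
  arch <- qtl_architecture()
  sedw <- arch[arch$trait == "SEDW", ]
  rk <- rank_markers(sedw, "SEDW")
  # the five markers the published stacking model uses, in its order
  expect_equal(rk$cofactor[1:5],
               c("e7_VviAGL11", "chr13_14817494_1", "chr9_5511355_1",
                 "chr13_810814_1", "chr4_19816331_1"))
  # e7 favorable class is b: 0.0410 < 0.1052
  expect_equal(rk$favorable[1], "b")
  expect_equal(rk$favorable[1:5], c("b", "a", "b", "a", "b"))
  expect_true(all(diff(rk$pct_var) <= 0))

  single <- rank_markers(sedw[1, , drop = FALSE])
  expect_equal(nrow(single), 1)
  expect_error(rank_markers(transform(sedw, mean_a = NA), "SEDW"), "means")
})

test_that("single-marker stacking reconstructs the published adjusted R-squared and CI", {
  fx <- two_group_fixture()
  steps <- stack_selection(fx$geno_ma, fx$geno_cs, fx$blup, fx$ranking, k_max = 1)
  expect_equal(steps$ideotype, "b")
  expect_equal(steps$ideotype_n, 217)
  expect_equal(steps$ideotype_mean, 0.0412, tolerance = 1e-10)
  expect_equal(steps$ideotype_sd, 0.0256, tolerance = 1e-10)
  # published adjusted R-squared 52.11% within half a point
  expect_lt(abs(steps$adj_r2_pct - 52.11), 0.5)
  # published 95% CI (0.03776; 0.04462) within print rounding
  expect_lt(abs(steps$ci_lo - 0.03776), 5e-5)
  expect_lt(abs(steps$ci_hi - 0.04462), 5e-5)
  expect_lt(steps$p_value, 1e-10)
})

test_that("stacking is a refinement: R2 never decreases, ideotype never grows", {
  map <- small_map(n_chrom = 3, len_cm = 40, spacing = 10)
  geno_ma <- simulate_progeny(map, 400, seed = 41)
  map_cs <- small_map("CS", n_chrom = 3, len_cm = 40, spacing = 10)
  geno_cs <- simulate_progeny(map_cs, 400, seed = 42)
  set.seed(43)
  markers <- c("chr1_6100000_1", "chr2_6100000_1", "chr3_6100000_1")
  parents <- c("MA", "CS", "MA")
  x <- cbind(as.numeric(geno_ma[, markers[1]] == "b"),
             as.numeric(geno_cs[, markers[2]] == "b"),
             as.numeric(geno_ma[, markers[3]] == "b"))
  y <- -(0.8 * x[, 1] + 0.4 * x[, 2] + 0.2 * x[, 3]) + rnorm(400, 5, 0.7)
  blup <- data.frame(id = rownames(geno_ma), value = y)
  ranking <- data.frame(order = 1:3, parent = parents, cofactor = markers,
                        pct_var = c(30, 10, 3), lod = c(20, 8, 3),
                        favorable = c("b", "b", "b"))
  steps <- stack_selection(geno_ma, geno_cs, blup, ranking, k_max = 3)
  expect_true(all(diff(steps$r2) >= -1e-12))
  expect_true(all(diff(steps$ideotype_n) <= 0))
  # with unlinked 1:1 markers each step roughly halves the ideotype
  expect_lt(abs(steps$ideotype_n[2] / steps$ideotype_n[1] - 0.5), 0.2)

  # ideotype membership is the intersection of per-marker favorable classes
  members <- attr(steps, "members")
  brute <- rownames(geno_ma)[x[, 1] == 1 & x[, 2] == 1 & x[, 3] == 1]
  expect_setequal(members[[3]], brute)

  # null phenotype: adjusted R2 collapses to ~0
  blup0 <- data.frame(id = rownames(geno_ma), value = rnorm(400))
  s0 <- stack_selection(geno_ma, geno_cs, blup0, ranking, k_max = 3)
  expect_lt(max(abs(s0$adj_r2_pct)), 5)
  expect_gt(min(s0$p_value), 1e-4)
})

test_that("relative decreases match the published stacking gains", {
  tab <- multiloci_summary()
  for (tr in c("SEDW", "SEDN", "SEDA")) {
    sub <- tab[tab$trait == tr, ]
    steps <- data.frame(k = sub$k, ideotype_mean = sub$mean)
    got <- relative_decrease(steps, 5)
    want <- c(SEDW = 25.2, SEDN = 32.4, SEDA = 36.2)[[tr]]
    # one-decimal agreement (printed values are truncated, not rounded)
    expect_lt(abs(got - want), 0.06)
  }
  expect_error(relative_decrease(data.frame(k = 1, ideotype_mean = 0), 1), "zero")
})

test_that("predictive values are 1 for a perfectly separating marker", {
  fx <- two_group_fixture(n_b = 30, n_a = 40, mean_b = 0.02, mean_a = 0.10,
                          sd_b = 0.005, sd_a = 0.005)
  steps <- stack_selection(fx$geno_ma, fx$geno_cs, fx$blup, fx$ranking, k_max = 1)
  vals <- setNames(fx$blup$value, fx$blup$id)
  pv <- predictive_value_trajectory(steps, vals, cutoff = 0.045)
  expect_equal(pv$ppv, 1)
  expect_equal(pv$npv, 1)
})
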