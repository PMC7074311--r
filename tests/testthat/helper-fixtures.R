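# Fixture builders shared across the suite.

# A vector of n values with exactly the requested mean and SD.
moment_matched <- function(n, mean, sd) {
  x <- seq_len(n)
  as.numeric(mean + sd * scale(x))
}

# Two-group, one-marker dataset reconstructed from published summaries:
# group sizes/means/SDs are matched exactly, genotype b is the low group.
two_group_fixture <- function(n_b = 217, n_a = 354,
                              mean_b = 0.0412, mean_a = 0.1052,
                              sd_b = 0.0256, sd_a = 0.0320,
                              marker = "e7_VviAGL11") {
  n <- n_a + n_b
  ids <- sprintf("F1_%04d", seq_len(n))
  calls <- c(rep("b", n_b), rep("a", n_a))
  geno_cs <- matrix(calls, ncol = 1, dimnames = list(ids, marker))
  attr(geno_cs, "parent") <- "CS"
  geno_ma <- matrix("a", nrow = n, ncol = 1,
                    dimnames = list(ids, "dummy_marker"))
  attr(geno_ma, "parent") <- "MA"
  value <- c(moment_matched(n_b, mean_b, sd_b),
             moment_matched(n_a, mean_a, sd_a))
  list(geno_ma = geno_ma, geno_cs = geno_cs,
       blup = data.frame(id = ids, value = value, stringsAsFactors = FALSE),
       ranking = data.frame(order = 1, parent = "CS", cofactor = marker,
                            pct_var = 48.4, lod = 90.4, favorable = "b",
                            stringsAsFactors = FALSE))
}

# A small two-chromosome map for fast scans.
small_map <- function(parent = "MA", n_chrom = 2, len_cm = 60, spacing = 5) {
  pieces <- lapply(seq_len(n_chrom), function(chr) {
    cm <- seq(0, len_cm, by = spacing)
    bp <- 1e5 + cm * 3e5
    data.frame(marker = sprintf("chr%d_%d_1", chr, as.integer(bp)),
               chrom = as.character(chr), cm = cm, bp = bp, parent = parent,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, pieces)
  class(map) <- c("genetic_map", "data.frame")
  map
}

# Full enumeration oracle for the two-tailed Fisher exact test ("sum of
# small p", same tie tolerance as the reference implementation).
fisher_enum_oracle <- function(tp, fp, fn, tn) {
  r1 <- tp + fp; c1 <- tp + fn; n <- tp + fp + fn + tn
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  obs <- stats::dhyper(tp, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
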