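# Multi-locus assisted selection: rank QTL cofactors by explained variance,
# stack their favorable genotype classes greedily into ideotypes, and test
# each step by one-way haplotype ANOVA.

#' Rank QTL cofactors for stacking
#'
#' Orders a trait's QTL results by decreasing percent explained variance
#' (ties broken by higher LOD, then marker name) and assigns the favorable
#' genotype class: the class with the lower trait mean, since seedlessness
#' means minimizing seed weight/number (on an exact tie class "a" is kept).
#'
#' @param qtl_results Data frame with columns `trait` (optional if already
#'   filtered), `parent`, `cofactor`, `pct_var`, `lod`, `mean_a`, `mean_b`.
#' @param trait Trait to rank ("SEDW", "SEDN" or "SEDA").
#' @return Data frame `order`, `parent`, `cofactor`, `pct_var`, `lod`,
#'   `favorable`.
#' @export
rank_markers <- function(qtl_results, trait = NULL) {
  res <- qtl_results
  if (!is.null(trait) && "trait" %in% names(res)) res <- res[res$trait == trait, ]
  if (!nrow(res)) stop("no QTL results to rank")
  if (any(!is.finite(res$mean_a)) || any(!is.finite(res$mean_b))) {
    stop("missing genotype-class means")
  }
  ord <- order(-res$pct_var, -res$lod, res$cofactor)
  res <- res[ord, , drop = FALSE]
  data.frame(order = seq_len(nrow(res)), parent = res$parent,
             cofactor = res$cofactor, pct_var = res$pct_var, lod = res$lod,
             favorable = ifelse(res$mean_b < res$mean_a, "b", "a"),
             stringsAsFactors = FALSE)
}

#' Greedy marker stacking into ideotypes
#'
#' Adds ranked markers one at a time. At step k offspring are partitioned
#' by their k-marker genotype string (2^k theoretical factors); the
#' ideotype is the concatenation of the k favorable classes and its
#' subgroup is summarised by N, mean, SD and a t-based 95 percent CI. The
#' phenotype is tested against the observed haplotype factor by a one-way
#' ANOVA; adjusted \eqn{R^2 = 1 - (1 - R^2)(n-1)/(n-g)} uses the number of
#' observed levels g, and a Welch ANOVA p-value (no equal-variance
#' assumption) is reported alongside the classical one. Offspring missing a
#' call at any stacked marker are dropped for that step.
#'
#' @param geno_ma,geno_cs Genotype matrices for the two parents (same
#'   offspring ids in the same order).
#' @param blup Data frame `id`, `value` of the trait values to model
#'   (typically BLUPs).
#' @param ranking Result of [rank_markers()].
#' @param k_max Number of markers to stack (<= nrow(ranking)).
#' @param linked_warn_cm Same-parent markers on one chromosome closer than
#'   this trigger a linkage warning (additivity assumes independence or
#'   >50 cM separation); stacking proceeds.
#' @return Data frame with one row per k (StackStep fields); the ideotype
#'   member ids of each step are kept in the list attribute `members`.
#' @export
stack_selection <- function(geno_ma, geno_cs, blup, ranking, k_max,
                            linked_warn_cm = 50) {
  stopifnot(k_max >= 1, k_max <= nrow(ranking))
  geno_of <- list(MA = geno_ma, CS = geno_cs)
  ids <- rownames(geno_ma)
  if (!identical(ids, rownames(geno_cs))) {
    stop("offspring ids differ between parental genotype matrices")
  }
  calls <- sapply(seq_len(k_max), function(i) {
    g <- geno_of[[ranking$parent[i]]]
    if (is.null(g)) stop("unknown parent label: ", ranking$parent[i])
    if (!ranking$cofactor[i] %in% colnames(g)) {
      stop("marker ", ranking$cofactor[i], " absent from the ",
           ranking$parent[i], " genotype matrix")
    }
    g[, ranking$cofactor[i]]
  })
  colnames(calls) <- ranking$cofactor[seq_len(k_max)]
  .warn_linked(ranking[seq_len(k_max), ], geno_of, linked_warn_cm)
  value <- blup$value[match(ids, blup$id)]
  members <- vector("list", k_max)
  steps <- lapply(seq_len(k_max), function(k) {
    sub <- calls[, seq_len(k), drop = FALSE]
    ok <- is.finite(value) & !apply(is.na(sub), 1, any)
    hap <- apply(sub[ok, , drop = FALSE], 1, paste, collapse = "")
    v <- value[ok]
    ideo <- paste(ranking$favorable[seq_len(k)], collapse = "")
    in_ideo <- hap == ideo
    members[[k]] <<- ids[ok][in_ideo]
    n_i <- sum(in_ideo)
    m_i <- if (n_i) mean(v[in_ideo]) else NA_real_
    sd_i <- if (n_i >= 2) stats::sd(v[in_ideo]) else NA_real_
    ci <- if (n_i >= 2) {
      m_i + c(-1, 1) * stats::qt(0.975, n_i - 1) * sd_i / sqrt(n_i)
    } else c(NA_real_, NA_real_)
    f <- factor(hap)
    g <- nlevels(f)
    n <- length(v)
    fit <- stats::lm(v ~ f)
    r2 <- summary(fit)$r.squared
    adj <- 1 - (1 - r2) * (n - 1) / (n - g)
    p <- if (g >= 2) stats::anova(fit)[["Pr(>F)"]][1] else NA_real_
    welch_p <- if (g >= 2 && all(table(f) >= 2)) {
      tryCatch(stats::oneway.test(v ~ f)$p.value, error = function(e) NA_real_)
    } else NA_real_
    data.frame(k = k, factors = 2^k, ideotype = ideo, n = n,
               ideotype_n = n_i, ideotype_mean = m_i, ideotype_sd = sd_i,
               ci_lo = ci[1], ci_hi = ci[2], r2 = r2,
               adj_r2_pct = 100 * adj, p_value = p, welch_p = welch_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, steps)
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

.warn_linked <- function(ranking, geno_of, linked_warn_cm) {
  for (p in unique(ranking$parent)) {
    g <- geno_of[[p]]
    map <- attr(g, "map")
    if (is.null(map)) next
    sub <- map[match(intersect(ranking$cofactor[ranking$parent == p],
                               map$marker), map$marker), ]
    if (nrow(sub) < 2) next
    for (chr in unique(sub$chrom)) {
      cm <- sort(sub$cm[sub$chrom == chr])
      if (length(cm) >= 2 && min(diff(cm)) < linked_warn_cm) {
        warning("stacked markers on chromosome ", chr, " of ", p,
                " are closer than ", linked_warn_cm,
                " cM; the additivity premise may not hold", call. = FALSE)
      }
    }
  }
}

#' Relative phenotype decrease of a stacking step
#'
#' Percent decrease of the step-k ideotype mean relative to the single best
#' marker (k = 1): `100 * (mean_1 - mean_k) / mean_1`.
#'
#' @param steps Result of [stack_selection()] (or any data frame with `k`
#'   and `ideotype_mean`).
#' @param k Step to compare against k = 1.
#' @return Percent decrease (positive when the mean went down).
#' @export
relative_decrease <- function(steps, k) {
  m1 <- steps$ideotype_mean[steps$k == 1]
  mk <- steps$ideotype_mean[steps$k == k]
  if (!length(m1) || !length(mk)) stop("steps must contain k = 1 and k = ", k)
  if (m1 == 0) stop("k = 1 ideotype mean is zero")
  100 * (m1 - mk) / m1
}

#' Predictive values along the stacking trajectory
#'
#' At each step k, selection predicts "seedless" for the ideotype members
#' and "seeded" for everyone else; the truth is the phenotype binarized at
#' the cutoff. PPV and NPV come from the resulting 2x2 table.
#'
#' @param steps Result of [stack_selection()] (must carry the `members`
#'   attribute).
#' @param pheno_values Named numeric vector of SEDW-scale values per
#'   offspring id used for the truth classification.
#' @param cutoff Seedless/seeded cutoff in trait units (default 0.045 g).
#' @return Data frame `k`, `ppv`, `npv` (NA with a flag message when the
#'   ideotype is empty).
#' @export
predictive_value_trajectory <- function(steps, pheno_values, cutoff = 0.045) {
  members <- attr(steps, "members")
  if (is.null(members)) stop("steps must carry the 'members' attribute")
  ids <- names(pheno_values)
  actual <- binarize_phenotype(pheno_values, cutoff)
  out <- lapply(steps$k, function(k) {
    sel <- members[[k]]
    if (!length(sel)) {
      message("empty ideotype at k = ", k, "; PPV undefined")
      return(data.frame(k = k, ppv = NA_real_, npv = NA_real_))
    }
    predicted <- ifelse(ids %in% sel, "seedless", "seeded")
    cm <- contingency_and_metrics(predicted, actual)
    data.frame(k = k, ppv = cm$metrics$precision, npv = cm$metrics$npv)
  })
  do.call(rbind, out)
}
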