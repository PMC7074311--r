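# Binary predictive-performance evaluation of seedlessness markers.

#' Binarize a seed-weight phenotype
#'
#' Classifies offspring as seedless/seeded at a seed fresh-weight cutoff
#' (0.045 g by default, the conventional boundary between seed traces and
#' developed seeds). By the inclusive convention a value exactly at the
#' cutoff is seedless (a seed trace); set `boundary = "strict"` to classify
#' it seeded instead.
#'
#' @param x Numeric SEDW values in g (>= 0).
#' @param cutoff Positive cutoff in g.
#' @param boundary "inclusive" (<= cutoff is seedless) or "strict".
#' @return Character vector "seedless"/"seeded", names preserved.
#' @export
binarize_phenotype <- function(x, cutoff = 0.045,
                               boundary = c("inclusive", "strict")) {
  boundary <- match.arg(boundary)
  stopifnot(cutoff > 0)
  if (any(x < 0, na.rm = TRUE)) stop("negative seed weight")
  if (!length(x)) return(character(0))
  seedless <- if (boundary == "inclusive") x <= cutoff else x < cutoff
  out <- ifelse(seedless, "seedless", "seeded")
  names(out) <- names(x)
  out
}

#' 2x2 contingency table and classification metrics
#'
#' Tabulates predicted against actual seedless/seeded classes (positive =
#' seedless) and computes sensitivity, specificity, precision (PPV), NPV,
#' accuracy, false positive/negative rates and the Matthews correlation
#' coefficient \eqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#' When any MCC marginal is zero the coefficient is reported as `NA` with
#' `mcc_defined = FALSE` rather than silently set to 0.
#'
#' @param predicted,actual Aligned character vectors with values
#'   "seedless"/"seeded".
#' @return A list `table` (tp, fp, fn, tn) and `metrics`.
#' @export
contingency_and_metrics <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 1)
  lv <- c("seedless", "seeded")
  bad <- setdiff(unique(c(predicted, actual)), lv)
  if (length(bad)) stop("labels outside the binary alphabet: ",
                        paste(bad, collapse = ", "))
  tp <- sum(predicted == "seedless" & actual == "seedless")
  fp <- sum(predicted == "seedless" & actual == "seeded")
  fn <- sum(predicted == "seeded" & actual == "seedless")
  tn <- sum(predicted == "seeded" & actual == "seeded")
  metrics_from_counts(tp, fp, fn, tn)
}

#' @rdname contingency_and_metrics
#' @param tp,fp,fn,tn Non-negative counts (positive class = seedless).
#' @export
metrics_from_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn >= 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  acc <- (tp + tn) / (tp + fp + fn + tn)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc_def <- all(marg > 0)
  mcc <- if (mcc_def) {
    (tp * tn - fp * fn) / sqrt(prod(marg))
  } else NA_real_
  list(
    table = list(tp = tp, fp = fp, fn = fn, tn = tn),
    metrics = list(sensitivity = sens, specificity = spec, precision = prec,
                   npv = npv, accuracy = acc,
                   fpr = if (is.na(spec)) NA_real_ else 1 - spec,
                   fnr = if (is.na(sens)) NA_real_ else 1 - sens,
                   mcc = mcc, mcc_defined = mcc_def)
  )
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with the "sum of small p" two-tailed
#' convention: the p-value sums the probabilities of every table with the
#' observed margins whose point probability does not exceed the observed
#' one. When a margin is zero only one table is feasible and p = 1 by
#' convention.
#'
#' @param tab A list/vector with `tp`, `fp`, `fn`, `tn`, or a 2x2 matrix.
#' @return The two-tailed p-value.
#' @export
fisher_exact_two_tailed <- function(tab) {
  if (is.list(tab)) tab <- unlist(tab[c("tp", "fp", "fn", "tn")])
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(all(is.finite(tab)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    message("degenerate margin; Fisher p = 1 by convention")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Polymorphism information content
#'
#' Botstein's PIC from allele frequencies:
#' \eqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}. A monomorphic
#' locus has PIC 0; PIC is always below the expected heterozygosity
#' \eqn{1 - \sum p_i^2}.
#'
#' @param p Numeric vector of allele frequencies summing to 1.
#' @return The PIC value.
#' @export
pic <- function(p) {
  stopifnot(all(p >= 0))
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))   # second term is sum_{i<j} 2 p_i^2 p_j^2
}

#' SSR/SNP discordance: intragenic recombinant detection
#'
#' Flags offspring whose 5'UTR SSR seedless-allele status disagrees with
#' the exon-7 causal SNP (a T carrier is a seedless-allele carrier). Such
#' discordant individuals are the signature of intragenic recombination
#' between the promoter/5'UTR and the coding region.
#'
#' @param ssr_calls Named logical vector: SSR seedless-allele presence.
#' @param snp_calls Named character vector of "G/G", "G/T", "T/T" calls for
#'   the same ids.
#' @return A list `discordant` (ids), `rate` (fraction of total) and
#'   `rate_pct` (rounded to 2 decimals).
#' @export
find_recombinants <- function(ssr_calls, snp_calls) {
  if (!setequal(names(ssr_calls), names(snp_calls)) ||
      is.null(names(ssr_calls)) || is.null(names(snp_calls))) {
    stop("ssr_calls and snp_calls must be named by the same ids")
  }
  snp_calls <- snp_calls[names(ssr_calls)]
  bad <- setdiff(unique(snp_calls), c("G/G", "G/T", "T/G", "T/T"))
  if (length(bad)) stop("unknown SNP genotype: ", paste(bad, collapse = ", "))
  snp_carrier <- grepl("T", snp_calls, fixed = TRUE)
  disc <- names(ssr_calls)[ssr_calls != snp_carrier]
  rate <- length(disc) / length(ssr_calls)
  list(discordant = disc, rate = rate, rate_pct = round(100 * rate, 2))
}
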