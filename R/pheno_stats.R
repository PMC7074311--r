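#' Descriptive statistics per season for a seed subtrait
#'
#' Summarises one trait season by season: n, mean, SD, bias-corrected
#' sample skewness (the G1 estimator,
#' \eqn{G_1 = g_1 \sqrt{n(n-1)}/(n-2)}) and bias-corrected excess kurtosis
#' (the G2 estimator). Both come from \pkg{e1071} (type 2).
#'
#' @param pheno Long phenotype data frame (`id`, `season`, trait columns).
#' @param trait One of "SEDW", "SEDN", "SEDA".
#' @return A data frame with one row per season: `trait`, `season`, `n`,
#'   `mean`, `sd`, `skewness`, `kurtosis` (excess).
#' @export
describe_trait <- function(pheno, trait) {
  stopifnot(trait %in% names(pheno))
  pieces <- lapply(split(pheno[[trait]], pheno$season), function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3) stop("need at least 3 finite values per season")
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
               skewness = e1071::skewness(x, type = 2),
               kurtosis = e1071::kurtosis(x, type = 2))
  })
  out <- do.call(rbind, pieces)
  out <- cbind(trait = trait, season = names(pieces), out)
  rownames(out) <- NULL
  out
}

#' Spearman correlations between seasons
#'
#' Pairwise Spearman rank correlations (average ranks for ties) of one
#' trait between all season pairs, with two-tailed p-values from the
#' t approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}.
#'
#' @inheritParams describe_trait
#' @return A list with `rho` (season x season matrix), `p` (same shape) and
#'   `mean_rho` (mean of the off-diagonal upper triangle).
#' @export
spearman_between_seasons <- function(pheno, trait) {
  stopifnot(trait %in% names(pheno))
  wide <- tapply(pheno[[trait]], list(pheno$id, pheno$season), mean)
  if (ncol(wide) < 2) stop("need at least 2 seasons")
  seasons <- colnames(wide)
  k <- length(seasons)
  rho <- diag(1, k); dimnames(rho) <- list(seasons, seasons)
  p <- matrix(NA_real_, k, k, dimnames = list(seasons, seasons))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(wide[, c(i, j)])
      if (sum(ok) < 3) stop("fewer than 3 overlapping ids between seasons ",
                            seasons[i], " and ", seasons[j])
      r <- stats::cor(wide[ok, i], wide[ok, j], method = "spearman")
      n <- sum(ok)
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      rho[i, j] <- rho[j, i] <- r
      p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p,
       mean_rho = mean(rho[upper.tri(rho)]))
}

# Profiled REML criterion for the one-way random-genotype model with fixed
# season intercepts: y = X beta + Z u + e, u ~ N(0, sg2), e ~ N(0, se2).
# V = se2 (I + lambda Z Z') with lambda = sg2/se2; all quantities reduce to
# per-genotype and per-season sums via Woodbury because Z'Z = diag(s_i).
.reml_pieces <- function(y, genotype, season, lambda) {
  X <- stats::model.matrix(~ season)
  g <- as.integer(factor(genotype))
  s_i <- tabulate(g)
  w <- lambda / (1 + lambda * s_i)          # shrinkage weight per genotype
  # A' V~^-1 B with V~ = I + lambda ZZ' : A'B - sum_i w_i (sum_i A)(sum_i B)
  gsum <- function(M) rowsum(M, g)          # per-genotype column sums
  Xg <- gsum(X); yg <- gsum(matrix(y))
  XtX <- crossprod(X) - crossprod(Xg * sqrt(w))
  Xty <- crossprod(X, y) - crossprod(Xg * w, yg)
  yty <- sum(y^2) - sum(w * yg^2)
  beta <- solve(XtX, Xty)
  rss <- yty - sum(Xty * beta)              # y' P y numerator
  n <- length(y); p <- ncol(X)
  se2 <- as.numeric(rss) / (n - p)
  logdetV <- sum(log1p(lambda * s_i))
  crit <- (n - p) * log(se2) + logdetV + determinant(XtX, logarithm = TRUE)$modulus
  list(crit = as.numeric(crit), se2 = se2, beta = beta, w = w,
       yg = yg, Xg = Xg, s_i = s_i, g = g)
}

#' REML variance components for genotype across seasons
#'
#' Fits the mixed model trait ~ season (fixed) + genotype (random) by
#' restricted maximum likelihood, profiling the criterion over the single
#' variance ratio \eqn{\lambda = \sigma^2_g/\sigma^2_e} (a one-dimensional
#' optimisation; the one-way layout needs no general mixed-model machinery).
#' Genotypes observed in no season are dropped with a warning.
#'
#' @inheritParams describe_trait
#' @return A list with `sigma2_g`, `sigma2_e`, `n_seasons`, `lambda`.
#' @export
fit_variance_components <- function(pheno, trait) {
  stopifnot(trait %in% names(pheno))
  ok <- is.finite(pheno[[trait]])
  if (!all(ok)) {
    warning(sum(!ok), " non-finite observations dropped")
    pheno <- pheno[ok, , drop = FALSE]
  }
  y <- pheno[[trait]]
  genotype <- factor(pheno$id)
  season <- factor(pheno$season)
  obj <- function(loglam) .reml_pieces(y, genotype, season, exp(loglam))$crit
  opt <- stats::optimize(obj, interval = c(-12, 12))
  lambda <- exp(opt$minimum)
  fit <- .reml_pieces(y, genotype, season, lambda)
  list(sigma2_g = lambda * fit$se2, sigma2_e = fit$se2,
       n_seasons = nlevels(season), lambda = lambda)
}

#' BLUPs of genotype values across seasons
#'
#' Computes, per genotype, the raw season-adjusted mean and its best linear
#' unbiased predictor under the REML fit of [fit_variance_components()]:
#' \eqn{BLUP_i = \hat\mu + k_i (\bar y_i - \hat\mu)} with shrinkage
#' \eqn{k_i = \hat\sigma^2_g / (\hat\sigma^2_g + \hat\sigma^2_e / s_i)}
#' where \eqn{s_i} is the genotype's number of observed seasons; season
#' effects are removed as fixed intercepts before averaging. The grand mean
#' \eqn{\hat\mu} is reported on the scale of the average season.
#'
#' @inheritParams describe_trait
#' @param components Optional result of [fit_variance_components()]
#'   (refitted when NULL).
#' @return A data frame `id`, `n_seasons`, `raw_mean`, `blup`, `shrinkage`.
#' @export
compute_blups <- function(pheno, trait, components = NULL) {
  ok <- is.finite(pheno[[trait]])
  pheno <- pheno[ok, , drop = FALSE]
  if (is.null(components)) components <- fit_variance_components(pheno, trait)
  y <- pheno[[trait]]
  season <- factor(pheno$season)
  genotype <- factor(pheno$id)
  # season-adjusted values on the average-season scale
  seas_mean <- stats::ave(y, season)
  y_adj <- y - seas_mean + mean(seas_mean)
  s_i <- tapply(y_adj, genotype, length)
  raw_mean <- tapply(y_adj, genotype, mean)
  mu <- mean(y_adj)
  k <- components$sigma2_g /
    (components$sigma2_g + components$sigma2_e / as.numeric(s_i))
  data.frame(id = names(raw_mean), n_seasons = as.integer(s_i),
             raw_mean = as.numeric(raw_mean),
             blup = mu + k * (as.numeric(raw_mean) - mu),
             shrinkage = as.numeric(k),
             row.names = NULL, stringsAsFactors = FALSE)
}
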