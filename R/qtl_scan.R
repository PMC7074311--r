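# QTL detection on a pseudo-testcross parent: Kruskal-Wallis single-marker
# scan, Haley-Knott regression interval mapping, automatic cofactor
# selection, multiple-QTL mapping (MQM) and permutation LOD thresholds.

# 0/1 numeric coding of a/b calls (b = 1).
geno01 <- function(geno) {
  out <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  out[geno == "a"] <- 0
  out[geno == "b"] <- 1
  out
}

#' Kruskal-Wallis single-marker scan
#'
#' Nonparametric association between a trait and every marker: the
#' Kruskal-Wallis H statistic (tie-corrected) with its chi-square p-value
#' (1 df for the two pseudo-testcross classes). Monomorphic markers (fewer
#' than 2 observed classes) are flagged and excluded from testing.
#'
#' @param y Numeric trait values, one per offspring.
#' @param geno Genotype matrix from [simulate_progeny()] or [read_genotype_csv()].
#' @return Data frame `marker`, `H`, `p`, `excluded`.
#' @export
kw_scan <- function(y, geno) {
  stopifnot(length(y) == nrow(geno))
  res <- lapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    ok <- !is.na(g) & is.finite(y)
    if (length(unique(g[ok])) < 2) {
      return(data.frame(H = NA_real_, p = NA_real_, excluded = TRUE))
    }
    kw <- stats::kruskal.test(y[ok], factor(g[ok]))
    data.frame(H = unname(kw$statistic), p = kw$p.value, excluded = FALSE)
  })
  out <- do.call(rbind, res)
  cbind(marker = colnames(geno), out, stringsAsFactors = FALSE)
}

# Expected b-carrier probability at grid positions on one chromosome given
# the flanking marker calls, using Haldane transition probabilities (the
# Markov chain has no interference, so conditioning on the nearest observed
# flank on each side is exact).
.expected_geno_chr <- function(map_chr, calls01, grid_cm) {
  m <- nrow(map_chr)
  n <- nrow(calls01)
  X <- matrix(NA_real_, n, length(grid_cm))
  for (k in seq_along(grid_cm)) {
    pos <- grid_cm[k]
    left <- which(map_chr$cm <= pos)
    right <- which(map_chr$cm >= pos)
    li <- if (length(left)) max(left) else NA_integer_
    ri <- if (length(right)) min(right) else NA_integer_
    gl <- if (!is.na(li)) calls01[, li] else rep(NA_real_, n)
    gr <- if (!is.na(ri)) calls01[, ri] else rep(NA_real_, n)
    rl <- if (!is.na(li)) haldane(pos - map_chr$cm[li]) else NA_real_
    rr <- if (!is.na(ri)) haldane(map_chr$cm[ri] - pos) else NA_real_
    p <- rep(0.5, n)
    both <- !is.na(gl) & !is.na(gr)
    if (any(both)) {
      pb <- ifelse(gl[both] == 1, 1 - rl, rl)        # P(Q=b | left)
      qb <- ifelse(gr[both] == 1, 1 - rr, rr)        # P(right | Q=b) symmetry
      pa <- 1 - pb
      qa <- ifelse(gr[both] == 1, rr, 1 - rr)
      p[both] <- pb * qb / (pb * qb + pa * qa)
    }
    onlyl <- !is.na(gl) & is.na(gr)
    if (any(onlyl)) p[onlyl] <- ifelse(gl[onlyl] == 1, 1 - rl, rl)
    onlyr <- is.na(gl) & !is.na(gr)
    if (any(onlyr)) p[onlyr] <- ifelse(gr[onlyr] == 1, 1 - rr, rr)
    X[, k] <- p
  }
  X
}

# LOD scores of grid columns X for trait y given common covariates C
# (intercept always included): LOD = (n/2) log10(RSS0/RSS1).
.lod_columns <- function(y, X, C = NULL) {
  ok <- is.finite(y)
  if (!is.null(C)) ok <- ok & stats::complete.cases(C)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  n <- length(y)
  D <- cbind(rep(1, n), if (!is.null(C)) C[ok, , drop = FALSE])
  qrD <- qr(D)
  ry <- qr.resid(qrD, y)
  RX <- qr.resid(qrD, X)
  rss0 <- sum(ry^2)
  num <- colSums(RX * ry)^2
  den <- colSums(RX^2) * rss0
  r2 <- ifelse(den > 0, num / den, 0)
  r2 <- pmin(r2, 1 - 1e-12)
  (n / 2) * log10(1 / (1 - r2))
}

#' Interval mapping by Haley-Knott regression
#'
#' Scans a grid along each chromosome. At each grid position the phenotype
#' is regressed on the expected b-carrier indicator
#' \eqn{E[x \mid \mathrm{flanking\ markers}]} computed with Haldane
#' probabilities, so the scan is exact single-marker regression at marker
#' positions; \eqn{LOD = (n/2)\log_{10}(RSS_0/RSS_1)}. With `cofactors`
#' (an MQM scan) the cofactor markers enter as covariates, except those on
#' the scanned chromosome within `window_cm` of the test position.
#'
#' @param y Numeric trait values per offspring.
#' @param map A [genetic_map()].
#' @param geno Genotype matrix matching `map`.
#' @param step_cm Grid step (marker positions are always included).
#' @param cofactors Character vector of cofactor marker names (optional).
#' @param window_cm Cofactor exclusion window around the test position.
#' @return Data frame `chrom`, `cm`, `lod` with attribute `peaks` (per
#'   chromosome peak position and LOD; ties broken leftmost).
#' @export
interval_mapping <- function(y, map, geno, step_cm = 1, cofactors = NULL,
                             window_cm = 30) {
  validate_genetic_map(map)
  stopifnot(length(y) == nrow(geno))
  calls <- geno01(geno)
  if (!is.null(cofactors)) {
    missing_cof <- setdiff(cofactors, colnames(geno))
    if (length(missing_cof)) {
      stop("cofactor absent from genotype matrix: ",
           paste(missing_cof, collapse = ", "))
    }
  }
  cof_map <- if (!is.null(cofactors)) map[match(cofactors, map$marker), ] else NULL
  profiles <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    map_chr <- map[idx, , drop = FALSE]
    grid <- sort(unique(c(seq(min(map_chr$cm), max(map_chr$cm), by = step_cm),
                          map_chr$cm)))
    X <- .expected_geno_chr(map_chr, calls[, idx, drop = FALSE], grid)
    if (is.null(cofactors)) {
      lod <- .lod_columns(y, X)
    } else {
      lod <- numeric(length(grid))
      near <- !is.na(match(cof_map$chrom, chr))  # cofactors on this chromosome
      excl_pattern <- vapply(grid, function(pos) {
        paste(which(near & abs(cof_map$cm - pos) <= window_cm), collapse = ",")
      }, "")
      for (pat in unique(excl_pattern)) {
        keep_cof <- cofactors
        if (nzchar(pat)) {
          keep_cof <- cofactors[-as.integer(strsplit(pat, ",")[[1]])]
        }
        C <- if (length(keep_cof)) calls[, keep_cof, drop = FALSE] else NULL
        cols <- which(excl_pattern == pat)
        lod[cols] <- .lod_columns(y, X[, cols, drop = FALSE], C)
      }
    }
    profiles[[chr]] <- data.frame(chrom = chr, cm = grid, lod = lod,
                                  stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, profiles)
  rownames(out) <- NULL
  peaks <- do.call(rbind, lapply(profiles, function(p) {
    i <- which.max(p$lod)  # leftmost on ties
    data.frame(chrom = p$chrom[1], cm = p$cm[i], lod = p$lod[i],
               stringsAsFactors = FALSE)
  }))
  rownames(peaks) <- NULL
  attr(out, "peaks") <- peaks
  class(out) <- c("lod_profile", "data.frame")
  out
}

#' Permutation LOD thresholds
#'
#' Permutes the trait across offspring and records, per permutation, the
#' maximum interval-mapping LOD per chromosome and genome-wide. Thresholds
#' are the empirical (1 - alpha) quantiles of those maxima; the genome-wide
#' threshold is never below any chromosome-wise one under the same
#' permutation stream, since the genome maximum dominates every
#' per-chromosome maximum.
#'
#' @inheritParams interval_mapping
#' @param n_perm Number of permutations (>= 100; 10,000 for publication
#'   scale, 1,000 is the desk default).
#' @param alpha Type-I error rate in (0, 1].
#' @param seed Integer seed for the permutation stream.
#' @return A list `genome_wide` (LOD), `chrom_wide` (named vector),
#'   `alpha`, `n_perm`.
#' @export
permutation_thresholds <- function(y, map, geno, n_perm = 1000, alpha = 0.05,
                                   seed = 1L, step_cm = 1) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (n_perm < 100) stop("use at least 100 permutations")
  validate_genetic_map(map)
  ok <- is.finite(y)
  y <- y[ok]
  calls <- geno01(geno)[ok, , drop = FALSE]
  n <- length(y)
  # grid expectation matrix across all chromosomes
  Xs <- list(); chrom_of <- list()
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    map_chr <- map[idx, , drop = FALSE]
    grid <- sort(unique(c(seq(min(map_chr$cm), max(map_chr$cm), by = step_cm),
                          map_chr$cm)))
    Xs[[chr]] <- .expected_geno_chr(map_chr, calls[, idx, drop = FALSE], grid)
    chrom_of[[chr]] <- rep(chr, length(grid))
  }
  X <- do.call(cbind, Xs)
  chrom_of <- unlist(chrom_of, use.names = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  xss <- colSums(Xc^2)
  Y <- with_seed(derive_seed(seed, "permutations"), {
    vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
  })
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  yss <- colSums(Yc^2)
  r2 <- crossprod(Xc, Yc)^2 / outer(pmax(xss, .Machine$double.eps), yss)
  r2 <- pmin(r2, 1 - 1e-12)
  lod <- (n / 2) * log10(1 / (1 - r2))          # grid x permutation
  chrom_max <- do.call(rbind, lapply(unique(chrom_of), function(chr) {
    apply(lod[chrom_of == chr, , drop = FALSE], 2, max)
  }))
  rownames(chrom_max) <- unique(chrom_of)
  genome_max <- apply(chrom_max, 2, max)
  qfun <- function(v) unname(stats::quantile(v, probs = 1 - alpha, type = 1))
  list(genome_wide = qfun(genome_max),
       chrom_wide = apply(chrom_max, 1, qfun),
       alpha = alpha, n_perm = n_perm)
}

#' Automatic cofactor selection by backward elimination
#'
#' Starts from the candidate markers (typically the markers closest to the
#' peaks of a preliminary scan), fits a joint multiple regression, and
#' repeatedly drops the least significant marker while its partial p-value
#' exceeds `p_drop` (default 0.02). Collinear duplicates are removed first,
#' keeping the earliest candidate in map order. The elimination order is
#' deterministic: on ties the later candidate is dropped.
#'
#' @param y Numeric trait values per offspring.
#' @param geno Genotype matrix.
#' @param candidates Character vector of candidate marker names.
#' @param p_drop Partial p-value threshold to keep a marker.
#' @return Character vector of retained cofactor markers (possibly empty).
#' @export
select_cofactors <- function(y, geno, candidates, p_drop = 0.02) {
  if (!length(candidates)) return(character(0))
  missing_cand <- setdiff(candidates, colnames(geno))
  if (length(missing_cand)) {
    stop("candidate absent from genotype matrix: ",
         paste(missing_cand, collapse = ", "))
  }
  calls <- geno01(geno)[, candidates, drop = FALSE]
  ok <- is.finite(y) & stats::complete.cases(calls)
  yy <- y[ok]; M <- calls[ok, , drop = FALSE]
  # drop exact collinear duplicates, keep first in candidate (map) order
  qrM <- qr(cbind(1, M))
  if (qrM$rank < ncol(M) + 1) {
    keep <- qrM$pivot[seq_len(qrM$rank)] - 1L
    keep <- sort(keep[keep >= 1])
    dropped <- setdiff(seq_len(ncol(M)), keep)
    message("dropping collinear candidate(s): ",
            paste(colnames(M)[dropped], collapse = ", "))
    M <- M[, keep, drop = FALSE]
  }
  current <- colnames(M)
  while (length(current)) {
    fit <- stats::lm(yy ~ M[, current, drop = FALSE])
    aliased <- is.na(stats::coef(fit))[-1]
    if (any(aliased)) {                        # collinearity after row subsetting
      message("dropping aliased candidate(s): ",
              paste(current[aliased], collapse = ", "))
      current <- current[!aliased]
      next
    }
    pvals <- stats::setNames(summary(fit)$coefficients[-1, 4], current)
    worst <- max(pvals)
    if (worst <= p_drop) break
    # drop the later candidate on ties
    drop_name <- rev(names(pvals)[pvals == worst])[1]
    current <- setdiff(current, drop_name)
  }
  current
}

#' LOD support interval around a profile peak
#'
#' The widest contiguous grid interval around the (leftmost) peak on which
#' the LOD stays within `drop` units of the peak; the 2-LOD interval always
#' contains the 1-LOD interval. Physical bounds are interpolated linearly
#' from the chromosome's mapped cM/bp marker positions (clipped at the
#' chromosome ends).
#'
#' @param profile Data frame `cm`, `lod` for one chromosome (e.g. one
#'   chromosome of an [interval_mapping()] result).
#' @param drop LOD drop defining the support (1 or 2, any positive value
#'   accepted).
#' @param map_chr Optional map rows for the chromosome (for bp bounds).
#' @return A list `drop`, `peak_cm`, `cm_lo`, `cm_hi`, `bp_lo`, `bp_hi`.
#' @export
lod_support_interval <- function(profile, drop = 1, map_chr = NULL) {
  stopifnot(drop > 0, nrow(profile) >= 1)
  ord <- order(profile$cm)
  cm <- profile$cm[ord]; lod <- profile$lod[ord]
  peak <- which.max(lod)                       # leftmost on ties
  keep <- lod >= lod[peak] - drop
  lo <- peak; hi <- peak
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  while (hi < length(keep) && keep[hi + 1]) hi <- hi + 1
  out <- list(drop = drop, peak_cm = cm[peak], cm_lo = cm[lo], cm_hi = cm[hi],
              bp_lo = NA_real_, bp_hi = NA_real_)
  if (!is.null(map_chr) && nrow(map_chr) >= 2) {
    interp <- stats::approx(map_chr$cm, map_chr$bp,
                            xout = c(out$cm_lo, out$cm_hi), rule = 2)$y
    out$bp_lo <- interp[1]; out$bp_hi <- interp[2]
  }
  out
}

#' Multiple-QTL mapping around selected cofactors
#'
#' For every cofactor, rescans its chromosome by Haley-Knott regression with
#' the remaining cofactors as covariates (those within `window_cm` of the
#' test position are excluded), and reports the peak within the window of
#' the cofactor as the QTL. Per QTL: peak position and LOD; percent
#' explained variance as the cofactor's partial sum of squares in the joint
#' all-cofactor regression over the total sum of squares; genotype-class
#' means at the cofactor marker; 1- and 2-LOD support intervals; per-season
#' LODs recomputed with the same background cofactors on seasonal trait
#' values; `stable` when the season LOD clears the chromosome-wise
#' threshold in at least two individual seasons; significance "significant"
#' above the genome-wide threshold, "suggestive" above the chromosome-wise
#' one, "none" otherwise.
#'
#' @inheritParams interval_mapping
#' @param cofactors Character vector of cofactor marker names.
#' @param thresholds Result of [permutation_thresholds()].
#' @param season_values Optional numeric matrix (offspring x seasons) of
#'   per-season trait values for the stability call.
#' @return Data frame with one row per cofactor (QtlResult fields).
#' @export
mqm_scan <- function(y, map, geno, cofactors, thresholds,
                     step_cm = 1, window_cm = 30, season_values = NULL) {
  stopifnot(length(cofactors) >= 1)
  missing_cof <- setdiff(cofactors, colnames(geno))
  if (length(missing_cof)) {
    stop("cofactor absent from genotype matrix: ",
         paste(missing_cof, collapse = ", "))
  }
  calls <- geno01(geno)
  ok <- is.finite(y) & stats::complete.cases(calls[, cofactors, drop = FALSE])
  tss <- sum((y[ok] - mean(y[ok]))^2)
  full <- stats::lm(y[ok] ~ calls[ok, cofactors, drop = FALSE])
  rss_full <- sum(stats::resid(full)^2)
  profile <- interval_mapping(y, map, geno, step_cm = step_cm,
                              cofactors = cofactors, window_cm = window_cm)
  rows <- lapply(cofactors, function(cof) {
    mrow <- map[map$marker == cof, ]
    if (!nrow(mrow)) stop("cofactor ", cof, " not on the map")
    chr <- mrow$chrom
    prof_chr <- profile[profile$chrom == chr, , drop = FALSE]
    win <- prof_chr[abs(prof_chr$cm - mrow$cm) <= window_cm, , drop = FALSE]
    i <- which.max(win$lod)
    peak_cm <- win$cm[i]; peak_lod <- win$lod[i]
    # partial SS of this cofactor in the joint regression
    others <- setdiff(cofactors, cof)
    red <- if (length(others)) {
      stats::lm(y[ok] ~ calls[ok, others, drop = FALSE])
    } else stats::lm(y[ok] ~ 1)
    part_ss <- sum(stats::resid(red)^2) - rss_full
    g <- geno[, cof]
    mean_a <- mean(y[ok & g == "a"], na.rm = TRUE)
    mean_b <- mean(y[ok & g == "b"], na.rm = TRUE)
    thr_chr <- thresholds$chrom_wide[[chr]]
    signif <- if (peak_lod >= thresholds$genome_wide) "significant"
              else if (peak_lod >= thr_chr) "suggestive" else "none"
    si1 <- lod_support_interval(win, 1, map[map$chrom == chr, ])
    si2 <- lod_support_interval(win, 2, map[map$chrom == chr, ])
    season_lods <- NULL
    n_detected <- NA_integer_
    if (!is.null(season_values)) {
      keep_cof <- others[!(map$chrom[match(others, map$marker)] == chr &
                             abs(map$cm[match(others, map$marker)] - peak_cm) <= window_cm)]
      C <- if (length(keep_cof)) calls[, keep_cof, drop = FALSE] else NULL
      x <- calls[, cof, drop = FALSE]
      season_lods <- vapply(seq_len(ncol(season_values)), function(s) {
        .lod_columns(season_values[, s], x, C)
      }, 0)
      names(season_lods) <- colnames(season_values)
      n_detected <- sum(season_lods >= thr_chr)
    }
    out <- data.frame(parent = attr(geno, "parent") %||% NA_character_,
                      chrom = chr, position_cm = peak_cm, cofactor = cof,
                      lod = peak_lod, pct_var = 100 * part_ss / tss,
                      mean_a = mean_a, mean_b = mean_b,
                      ci1_lo_cm = si1$cm_lo, ci1_hi_cm = si1$cm_hi,
                      ci2_lo_cm = si2$cm_lo, ci2_hi_cm = si2$cm_hi,
                      ci1_lo_bp = si1$bp_lo, ci1_hi_bp = si1$bp_hi,
                      significance = signif,
                      n_seasons_detected = n_detected,
                      stable = !is.na(n_detected) & n_detected >= 2,
                      stringsAsFactors = FALSE)
    if (!is.null(season_lods)) {
      for (s in names(season_lods)) out[[paste0("lod_", s)]] <- season_lods[[s]]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
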