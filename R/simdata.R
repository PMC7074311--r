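#' Published QTL architecture of the MA x CS cross
#'
#' Loads the packaged table of the 24 QTLs reported for the seed subtraits
#' (SEDW, seed fresh weight per berry in g; SEDN, seeds per berry; SEDA,
#' mean single-seed weight in g) in the Muscat of Alexandria (MA) x Crimson
#' Seedless (CS) F1 population: per QTL the trait, segregating parent,
#' chromosome, cM position, cofactor SNP, LOD, percent explained variance,
#' genotype-class means (a = homozygous <aa>, b = heterozygous <ab>),
#' per-season LODs, and stability/significance calls. Within-class SDs are
#' only published for the chromosome-18 major locus and SEDW (0.0320 g for
#' class a, 0.0256 g for class b); the remaining SD cells are NA and the
#' simulator falls back on per-trait defaults.
#'
#' @return A data frame with one row per QTL.
#' @export
qtl_architecture <- function() {
  path <- system.file("extdata", "qtl_architecture_ma_cs.csv", package = "seedqtl")
  arch <- utils::read.csv(path, stringsAsFactors = FALSE)
  arch$chrom <- as.character(arch$chrom)
  arch
}

#' Published multi-locus stacking summary
#'
#' Loads the packaged table of the published marker-stacking (ideotype)
#' summaries for the three seed subtraits: per stacking step the cofactor
#' added, its favorable genotype class, the cumulative ideotype string, the
#' subgroup size, mean, SD and 95% CI, and the one-way ANOVA adjusted R^2.
#'
#' @return A data frame with one row per stacking step and trait.
#' @export
multiloci_summary <- function() {
  path <- system.file("extdata", "multiloci_summary_ma_cs.csv", package = "seedqtl")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cross design for the population simulator
#'
#' Bundles the design constants of the emulated study: 573 F1 offspring
#' phenotyped over the four seasons 2015-2018. Noise scales are per trait
#' and split into four components, all in trait units (g for SEDW, seeds for
#' SEDN): `season_effect_sd` (additive per-season shift common to all
#' offspring), `polygenic_sd` (a permanent per-offspring effect not tagged
#' by any simulated marker: unmapped polygenic background plus permanent
#' micro-environment), `gxe_sd` (independent genotype-by-season noise) and
#' `residual_sd` (within-season measurement residual). The defaults were
#' chosen once so that, under the packaged QTL architecture, the simulated
#' population reproduces the study's headline conditions: the chromosome-18
#' major locus explains close to half of the SEDW variance on BLUPs, and
#' inter-season rank correlations land near the reported 0.65 (SEDW) and
#' 0.35 (SEDN).
#'
#' @param n_offspring Number of F1 offspring (default 573).
#' @param seasons Character vector of season labels.
#' @param noise Named list per trait (`SEDW`, `SEDN`) of named numeric
#'   vectors with entries `season_effect_sd`, `polygenic_sd`, `gxe_sd`,
#'   `residual_sd`.
#' @param intragenic_recomb_rate Per-offspring probability of an intragenic
#'   5'UTR/exon-7 recombinant (default 2/573, the observed rate).
#' @param missing_rate Fraction of genotype calls masked to NA (default 0).
#' @param seed Integer seed fanned out into named substreams (meiosis,
#'   noise, flips) so each stage is independently reproducible.
#' @return A `cross_design` list.
#' @export
cross_design <- function(n_offspring = 573,
                         seasons = c("2015", "2016", "2017", "2018"),
                         noise = NULL,
                         intragenic_recomb_rate = 2 / 573,
                         missing_rate = 0,
                         seed = 1L) {
  default_noise <- list(
    SEDW = c(season_effect_sd = 0.005, polygenic_sd = 0.0250,
             gxe_sd = 0.0212, residual_sd = 0.0212),
    SEDN = c(season_effect_sd = 0.50, polygenic_sd = 0.732,
             gxe_sd = 0.958, residual_sd = 0.958)
  )
  if (is.null(noise)) noise <- default_noise
  for (tr in names(noise)) {
    if (any(noise[[tr]] < 0)) stop("noise SDs must be non-negative")
  }
  stopifnot(n_offspring >= 1, length(seasons) >= 1,
            intragenic_recomb_rate >= 0, intragenic_recomb_rate <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(
    list(n_offspring = as.integer(n_offspring), seasons = seasons,
         noise = noise, intragenic_recomb_rate = intragenic_recomb_rate,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "cross_design"
  )
}

#' Simulate pseudo-testcross progeny genotypes for one parent
#'
#' Each offspring inherits, per chromosome, a first-marker state a/b with
#' probability 1/2 and then follows a Markov chain along the map: the state
#' switches between adjacent markers with probability
#' `haldane(delta cM)` (no crossover interference). Chromosomes segregate
#' independently. This is the double-haploid view of a pseudo-testcross
#' parent: its heterozygous markers segregate 1:1 and are scored as a single
#' binary call per offspring.
#'
#' @param map A [genetic_map()] for the parent.
#' @param n Number of offspring.
#' @param seed Integer seed (meiosis substream is derived from it).
#' @param missing_rate Fraction of calls masked to NA at random (default 0).
#' @return A character matrix (offspring x markers) with values "a"/"b"
#'   (and NA where masked), rownames `F1_0001`..., and attributes `parent`
#'   and `map`.
#' @export
simulate_progeny <- function(map, n, seed = 1L, missing_rate = 0) {
  validate_genetic_map(map)
  stopifnot(n >= 1)
  parent <- map$parent[1]
  sub_seed <- derive_seed(seed, paste0("meiosis_", parent))
  calls <- with_seed(sub_seed, {
    out <- matrix(0L, nrow = n, ncol = nrow(map))
    col0 <- 1L
    for (chr in unique(map$chrom)) {
      idx <- which(map$chrom == chr)
      m <- length(idx)
      states <- matrix(0L, nrow = n, ncol = m)
      states[, 1] <- stats::rbinom(n, 1L, 0.5)
      if (m > 1) {
        r <- haldane(diff(map$cm[idx]))
        for (j in seq_len(m - 1)) {
          flip <- stats::rbinom(n, 1L, r[j])
          states[, j + 1] <- (states[, j] + flip) %% 2L
        }
      }
      out[, idx] <- states
      col0 <- col0 + m
    }
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(out)) < missing_rate, nrow = n)
      out[mask] <- NA_integer_
    }
    out
  })
  geno <- matrix(c("a", "b")[calls + 1L], nrow = n,
                 dimnames = list(sprintf("F1_%04d", seq_len(n)), map$marker))
  attr(geno, "parent") <- parent
  attr(geno, "map") <- map
  class(geno) <- c("genotype_matrix", class(geno))
  geno
}

# Index of the marker nearest to a cM position on a chromosome of a map.
.nearest_marker <- function(map, chrom, position_cm) {
  idx <- which(map$chrom == as.character(chrom))
  if (!length(idx)) stop("chromosome ", chrom, " not in map for parent ", map$parent[1])
  idx[which.min(abs(map$cm[idx] - position_cm))]
}

#' Simulate multi-season seed phenotypes from a QTL architecture
#'
#' Builds, per offspring, an additive genetic value for SEDW and SEDN:
#' baseline (the mean of the class midpoints of that trait's QTLs) plus, for
#' each QTL, `(mean_b - mean_a) * (I(b) - 1/2)` where I(b) indicates
#' carrying the segregating parent's b class at the marker nearest the QTL
#' position (sampled by the same meiosis chain). A single-QTL architecture
#' therefore reproduces the specified class means exactly. Seasonal values
#' add a per-season shift, a permanent polygenic offspring effect,
#' genotype-by-season noise and a residual; SEDW is censored below at 0 g,
#' SEDN below at 0.1 (a seed-trace equivalent; the field SEDN is a 75-berry
#' average and effectively continuous). SEDA is always recomputed as the
#' row-wise ratio SEDW/SEDN; architecture rows for SEDA are accepted but
#' carry no independent effect, since the ratio identity takes precedence.
#'
#' @param geno_ma,geno_cs Genotype matrices from [simulate_progeny()] for
#'   the two parents (same offspring).
#' @param architecture Data frame as returned by [qtl_architecture()]
#'   (columns trait, parent, chrom, position_cm, mean_a, mean_b at least).
#' @param design A [cross_design()].
#' @return A long-format data frame `id, season, SEDW, SEDN, SEDA`.
#' @export
simulate_phenotypes <- function(geno_ma, geno_cs, architecture, design) {
  stopifnot(nrow(architecture) >= 1)
  bad <- setdiff(unique(architecture$trait), c("SEDW", "SEDN", "SEDA"))
  if (length(bad)) stop("unknown trait in architecture: ", paste(bad, collapse = ", "))
  if (!identical(rownames(geno_ma), rownames(geno_cs))) {
    stop("offspring ids differ between the two parental genotype matrices")
  }
  n <- nrow(geno_ma)
  ids <- rownames(geno_ma)
  seasons <- design$seasons
  s <- length(seasons)
  geno_of <- list(MA = geno_ma, CS = geno_cs)

  genetic_value <- function(trait, fallback_mu) {
    rows <- architecture[architecture$trait == trait, , drop = FALSE]
    if (!nrow(rows)) return(rep(fallback_mu, n))
    mu <- mean((rows$mean_a + rows$mean_b) / 2)
    g <- rep(mu, n)
    for (i in seq_len(nrow(rows))) {
      geno <- geno_of[[rows$parent[i]]]
      if (is.null(geno)) stop("unknown parent label: ", rows$parent[i])
      map <- attr(geno, "map")
      j <- .nearest_marker(map, rows$chrom[i], rows$position_cm[i])
      carrier <- geno[, j] == "b"
      carrier[is.na(carrier)] <- stats::runif(sum(is.na(carrier))) < 0.5
      g <- g + (rows$mean_b[i] - rows$mean_a[i]) * (as.numeric(carrier) - 0.5)
    }
    g
  }

  noise_seed <- derive_seed(design$seed, "noise")
  out <- with_seed(noise_seed, {
    res <- list()
    for (trait in c("SEDW", "SEDN")) {
      sds <- design$noise[[trait]]
      if (is.null(sds)) stop("no noise specification for trait ", trait)
      g <- genetic_value(trait, fallback_mu = if (trait == "SEDW") 0.073 else 3.0)
      u <- stats::rnorm(n, 0, sds[["polygenic_sd"]])
      seas <- stats::rnorm(s, 0, sds[["season_effect_sd"]])
      vals <- matrix(0, nrow = n, ncol = s)
      for (t in seq_len(s)) {
        vals[, t] <- g + u + seas[t] +
          stats::rnorm(n, 0, sds[["gxe_sd"]]) +
          stats::rnorm(n, 0, sds[["residual_sd"]])
      }
      res[[trait]] <- vals
    }
    res
  })
  sedw <- pmax(out$SEDW, 0)
  sedn <- pmax(out$SEDN, 0.1)
  data.frame(
    id = rep(ids, times = s),
    season = rep(seasons, each = n),
    SEDW = as.vector(sedw),
    SEDN = as.vector(sedn),
    SEDA = as.vector(sedw / sedn),
    stringsAsFactors = FALSE
  )
}

#' Inject intragenic recombinants between an SSR and the causal SNP
#'
#' Flips, independently per offspring with the given probability, the
#' seedless-allele status of the 5'UTR SSR call relative to the exon-7 SNP,
#' emulating intragenic recombination between the promoter/5'UTR region and
#' the coding-region causal mutation (observed at 2/573 = 0.35 percent in
#' the emulated cross).
#'
#' @param snp_calls Named character vector of SNP genotypes ("G/G", "G/T",
#'   "T/T"); T is the seedless allele.
#' @param ssr_calls Named logical vector: presence of the SSR seedless
#'   allele, same ids as `snp_calls`.
#' @param rate Flip probability per offspring in [0, 1].
#' @param seed Integer seed (flip substream derived from it).
#' @return A list with `ssr_calls` (after flipping) and `flipped` (ids).
#' @export
inject_intragenic_recombinants <- function(snp_calls, ssr_calls,
                                           rate = 2 / 573, seed = 1L) {
  if (!setequal(names(snp_calls), names(ssr_calls)) ||
      is.null(names(snp_calls)) || is.null(names(ssr_calls))) {
    stop("snp_calls and ssr_calls must be named by the same offspring ids")
  }
  stopifnot(rate >= 0, rate <= 1)
  ssr_calls <- ssr_calls[names(snp_calls)]
  flip <- with_seed(derive_seed(seed, "flips"),
                    stats::runif(length(ssr_calls)) < rate)
  ssr_calls[flip] <- !ssr_calls[flip]
  list(ssr_calls = ssr_calls, flipped = names(ssr_calls)[flip])
}

#' Simulate a complete bi-parental cross
#'
#' Convenience wrapper: builds (or accepts) the two parental maps, simulates
#' both parents' progeny genotypes and the multi-season phenotypes under the
#' given architecture and design.
#'
#' @param design A [cross_design()].
#' @param architecture QTL architecture data frame (default: the packaged
#'   published architecture, [qtl_architecture()]).
#' @param map_ma,map_cs Parental maps (defaults: [default_parent_map()]).
#' @return A list with `map_ma`, `map_cs`, `geno_ma`, `geno_cs`, `pheno`.
#' @export
simulate_cross <- function(design = cross_design(),
                           architecture = qtl_architecture(),
                           map_ma = default_parent_map("MA"),
                           map_cs = default_parent_map("CS")) {
  geno_ma <- simulate_progeny(map_ma, design$n_offspring, seed = design$seed,
                              missing_rate = design$missing_rate)
  geno_cs <- simulate_progeny(map_cs, design$n_offspring, seed = design$seed,
                              missing_rate = design$missing_rate)
  pheno <- simulate_phenotypes(geno_ma, geno_cs, architecture, design)
  list(map_ma = map_ma, map_cs = map_cs, geno_ma = geno_ma,
       geno_cs = geno_cs, pheno = pheno)
}
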