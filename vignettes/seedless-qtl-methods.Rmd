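---
title: "Methods: simulating and mapping the genetic architecture of grapevine seedlessness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and mapping the genetic architecture of grapevine seedlessness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedqtl)
```

## The problem

Stenospermocarpic seedlessness in table grapes — fertilization occurs but
seed development aborts, leaving rudimentary traces — is dominated by a
single partially dominant locus on chromosome 18 (*VviAGL11*), yet
selection on that locus alone misclassifies a substantial fraction of
offspring. `seedqtl` re-creates, on fully synthetic data, the analysis
chain used to dissect this architecture in a bi-parental Muscat of
Alexandria (MA, seeded) × Crimson Seedless (CS, seedless) F1 cross:
population simulation, multi-season phenotype statistics and BLUPs, QTL
scans with cofactors and permutation thresholds, greedy multi-locus
ideotype selection, and binary diagnostic evaluation of the *VviAGL11*
markers. The raw genotypes and phenotypes of the original cross are not
public; the simulator is therefore a first-class module, and every
downstream stage is exercised and tested against it plus against the
published summary tables, which the package carries as fixtures.

## The cross simulator

**Meiosis.** Each parent of a pseudo-testcross segregates its heterozygous
markers 1:1, so one binary call (`a` = homozygous-like class, `b` =
heterozygous class) per parent per marker describes an offspring. Along a
chromosome the calls form a two-state Markov chain: the first marker is
`a`/`b` with probability 1/2 and the state switches between adjacent
markers with probability given by Haldane's map function
$r = (1 - e^{-2d/100})/2$. The Markov property encodes the no-interference
assumption that Haldane's function itself makes, so the simulation is
exact under its own model and `haldane()`/`haldane_inv()` round-trip to
machine precision. Default maps carry 19 chromosomes per parent, 1575 cM
(MA) and 1430 cM (CS) at 1 cM marker spacing, with physical positions
advancing 313 kb/cM and marker names following the `chr{C}_{bp}_1`
convention of the 20K SNP chip so `parse_snp_name()` can recover
coordinates.

**Phenotypes.** The packaged architecture (`qtl_architecture()`) encodes
the 24 published QTL rows: per QTL the trait (SEDW = seed fresh weight per
berry in g, SEDN = seeds per berry, SEDA = SEDW/SEDN), segregating parent,
position, and the two genotype-class means. An offspring's genetic value
for SEDW and SEDN is the trait baseline plus
$(\bar y_b - \bar y_a)(\mathbb{1}[b] - 1/2)$ per QTL, evaluated at the
marker nearest the QTL position; with a single QTL and no noise the class
means are reproduced exactly (0.1052 and 0.0410 g for the chromosome-18
locus and SEDW). Seasonal observations add four noise components, all in
trait units:

* `season_effect_sd` — an additive shift common to all offspring in a
  season;
* `polygenic_sd` — a permanent per-offspring effect not tagged by any
  simulated marker (unmapped polygenic background plus permanent
  micro-environment);
* `gxe_sd` — independent genotype-by-season noise;
* `residual_sd` — the within-season measurement residual.

SEDW is censored below at 0 g and SEDN below at 0.1 (the field SEDN is a
75-berry average, effectively continuous; 0.1 is a seed-trace
equivalent). SEDA is always the row-wise ratio SEDW/SEDN: architecture
rows for SEDA are accepted but add no independent effect, because the
ratio identity takes precedence — the published per-trait class means are
themselves not mutually consistent with a row-wise ratio, so no generator
can honor both, and we chose the identity.

**Why a polygenic term.** The study reports two constraints that a pure
QTL-plus-noise model cannot meet simultaneously: on the BLUP scale the two
chromosome-18 classes have SDs 0.0320/0.0256 g (which fixes the
within-class variance and hence the locus's 48.4% explained variance), and
raw seasonal values correlate at Spearman ≈ 0.65 between seasons. Meeting
the first forces so much season-level noise that the second drops to
≈ 0.3. A permanent non-marker offspring effect raises the inter-season
correlation without adding marker-explained variance, reconciling the
two. The default SDs (SEDW: polygenic 0.0250, G×E 0.0212, residual
0.0212, season 0.005; SEDN: 0.732/0.958/0.958/0.50) were derived from
those two constraints analytically and then adjusted once for the effects
of censoring and BLUP shrinkage; they are packaged defaults representing
the study conditions, not re-estimated quantities. Under them the
simulated population shows chr18 SEDW explained variance of ~45–49% and
inter-season Spearman ≈ 0.68 (SEDW) and ≈ 0.35 (SEDN).

**What the simulator does not emulate.** Segregation distortion (real
classes were 217/354 rather than 1:1), missing genotype calls (off by
default; a masking rate exists for robustness tests), linkage-map errors,
season-specific QTL expression, and the skewed/leptokurtic shapes of the
real trait distributions beyond what the bimodal mixture itself produces.
Passing tests therefore demonstrate that the analysis machinery recovers a
known architecture under its own assumptions — not that it would behave
identically on the real cross.

## Phenotype statistics and BLUPs

`describe_trait()` reports bias-corrected sample skewness (G1) and excess
kurtosis (G2). `spearman_between_seasons()` uses average-rank ties and a
t-approximation for two-tailed p-values. Following the original choice, no
normality transformation is applied anywhere.

The mapping response is the genotype BLUP across seasons from the mixed
model *trait ~ season (fixed) + genotype (random)*. Because the layout is
a one-way classification, REML is solved by profiling the criterion over
the single variance ratio $\lambda = \sigma^2_g/\sigma^2_e$
(one-dimensional optimization on $\log\lambda \in [-12, 12]$; all
quantities reduce to per-genotype sums via Woodbury). The BLUP is
$\hat\mu + k_i(\bar y_i - \hat\mu)$ with
$k_i = \hat\sigma^2_g/(\hat\sigma^2_g + \hat\sigma^2_e/s_i)$ and $s_i$
the genotype's season count, so imbalance simply reduces the shrinkage
denominator. Block effects are accepted as an additional fixed column in
principle but default fixtures omit them (the study gives no block data).
Season enters as fixed intercepts rather than a second random term; with
four seasons a variance component for season would rest on 3 degrees of
freedom, and the fixed choice matches treating seasons as named
environments. One consequence worth knowing: BLUP shrinkage plus censoring
pulls the simulated genotype-class means toward the grand mean, so class
means reported on the BLUP scale (e.g. 0.055 g for the seedless class)
sit above the generating 0.0410 g even though explained variance is
preserved.

## QTL scanning

Interval mapping is Haley–Knott regression: at each grid position the
response is regressed on the expected b-class indicator given the
flanking marker calls under Haldane probabilities, and
$\mathrm{LOD} = (n/2)\log_{10}(RSS_0/RSS_1)$. At a fully informative
marker the expectation collapses to the observed call, so the scan equals
single-marker regression there exactly (tested to 1e-9); this is the
deterministic regression counterpart of the "regression algorithm" of the
original MapQTL analysis. The grid step defaults to 1 cM — the map density
— and marker positions are always included.

Cofactors are chosen from the markers nearest preliminary-scan peaks by
backward elimination on a joint regression, dropping the least significant
marker while its partial p exceeds 0.02 (deterministic order; exact
collinear duplicates are removed first, keeping the earliest in map
order). The MQM rescan adds the retained cofactors as covariates but
excludes any cofactor within 30 cM of the test position (the original
software documents no window; 30 cM comfortably covers the support of the
QTLs involved and is configurable). Per QTL the report carries the peak
LOD and position, the percent explained variance as the cofactor's partial
sum of squares over the total sum of squares in the joint all-cofactor
regression, genotype-class means at the cofactor marker, 1- and 2-LOD
support intervals (leftmost peak on ties; physical bounds interpolated
linearly from the map), and per-season LODs recomputed with the same
cofactors — reusing the BLUP-derived cofactors per season rather than
re-selecting, which is one reading of the original stability procedure; a
QTL is *stable* when at least two individual seasons clear the
chromosome-wise threshold.

Significance thresholds come from permutations of the response across
offspring: the genome-wide threshold is the empirical 95th percentile of
the genome-maximum LOD, chromosome-wise thresholds the per-chromosome
analogue from the same permutation stream (so the genome-wide threshold
can never sit below a chromosome-wise one). The desk default is 1,000
permutations (10,000 at publication scale); the type-I calibration checks
in the test suite use 200 replicate null scans of the full-density map at
n = 573, sizes chosen to make the binomial error of the estimated rate
small relative to the 0.05 target.

## Multi-locus selection

`rank_markers()` orders a trait's QTLs by decreasing explained variance
(ties: higher LOD, then name) and labels the favorable class as the one
with the lower mean — seedlessness is minimized. An exact tie of class
means (one published SEDA row prints identical means) keeps class `a`.
`stack_selection()` adds markers greedily; at step $k$ offspring partition
into at most $2^k$ haplotype classes, of which only the observed ones
enter the one-way ANOVA — the published table reports the theoretical
count as "Factors" but empty subgroups cannot contribute — and the
adjusted $R^2 = 1 - (1-R^2)(n-1)/(n-g)$ uses the observed level count
$g$. That convention reproduces the published single-marker SEDW row
(52.11%) within rounding of the printed inputs; the original software's
convention for deeper rows cannot be verified without the raw data, and
the same formula is simply applied throughout. Because the original
analysis notes unequal variances, a Welch ANOVA p-value is reported
alongside the classical one; the classical adjusted R² remains the
headline statistic, as in the published table. The ideotype subgroup CI is
t-based with $N-1$ df. Same-parent markers closer than 50 cM trigger a
warning (the additivity premise assumes independent segregation or > 50 cM
separation) but stacking proceeds. Unadjusted R² is monotone
non-decreasing in $k$ by partition refinement and asserted exactly in the
tests; the ideotype halves in expectation at each step.

## Marker evaluation

Phenotypes binarize at 0.045 g seed fresh weight; a value exactly at the
cutoff is classified seedless ("seed traces") by default, configurable to
the strict convention — the boundary is a documented decision, not a
published rule. The positive class is seedless throughout. The 2×2
metrics follow the standard definitions, with MCC reported as undefined
(never 0) when a marginal is zero. Fisher's exact test uses the "sum of
small p" two-tailed convention via `stats::fisher.test`, with p = 1 by
convention for a degenerate margin; the test suite checks it against a
full hypergeometric enumeration to 1e-12. PIC follows Botstein
($1 - \sum p_i^2 - \sum_{i<j} 2p_i^2p_j^2$); the published per-marker PIC
values on the 209-variety panel are not recomputable because those allele
frequencies are only shown graphically. SSR dosage is not modelled —
seedless is dominant, so presence of the seedless allele is the binary
predictor. Intragenic recombinants are offspring whose 5′UTR SSR
seedless-allele status disagrees with the exon-7 SNP T-carrier status;
the simulator injects them at 2/573 ≈ 0.35% by default and
`find_recombinants()` recovers the injected list exactly.

## Problem sizes and numerical choices

The packaged analyses run at the study scale: 573 offspring, ~1,500
markers per parent, four seasons. Monte-Carlo experiments use 1,000
permutations for thresholds, 200 null scans for type-I calibration, 7
replicates for the n = 150 power contrast, and 5 replicates for the
stacking PPV comparison — sizes at which the checked contrasts are large
against their binomial errors. Degenerate inputs are contracts, not
crashes: monomorphic markers are flagged and excluded from the
Kruskal–Wallis scan, empty ideotypes flag undefined PPV, support intervals
clip at chromosome ends, and a flat LOD profile yields the whole
chromosome as its support. All randomness flows from one integer seed
fanned into named substreams (meiosis, noise, permutations, flips), so
stages are independently reproducible and byte-identical under a repeated
seed.

## Known limitations

* The generator's class means are exact only in the zero-noise,
  single-QTL limit; with the full architecture the baseline is the mean of
  class midpoints, so marginal means deviate by up to a few thousandths of
  a gram from the per-QTL specification.
* SEDA has no independent genetics; its QTL signal is whatever the
  SEDW/SEDN ratio inherits, which is weaker than the published SEDA rows.
* The power-contrast property is sensitive to the two same-direction
  linked SEDW QTLs on chromosome 13 of MA (60 cM apart): jointly they are
  occasionally genome-wise detectable at n = 150, which the original
  subsampling experiment also hints at by reporting extra "spurious"
  associations.
* REML assumes homoscedastic residuals across seasons; the real trait is
  heteroscedastic between the seeded and seedless modes.
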