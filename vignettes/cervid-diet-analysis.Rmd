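---
title: "Methods: dietary metabarcoding analysis for a multi-species deer community"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary metabarcoding analysis for a multi-species deer community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervidDiet)
```

This vignette is the package's account of its statistical methods: the
models and filters it implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical choices made where the design was genuinely open, and the known
limitations.

## The analysis in one paragraph

Fecal samples from four sympatric deer species are genotyped with two
markers: a mammal 16S fragment that identifies the depositing species, and
the plant trnL P6-loop that profiles the diet. After host assignment and
replicate-consistency filtering, each sample's diet is expressed as
relative read abundances (RRA) — each MOTU's reads divided by the sample
total — which gives every sample equal statistical weight. On these
profiles the package computes diet richness, dietary niche width,
selectivity against forage availability, transect-scale niche overlap, an
ordination of trophic partitioning, and regression models of what drives
overlap.

## Host assignment (mammal marker)

Within one mammal-marker PCR, MOTUs carrying less than 1% of the reads are
removed (dominantly chimeras and tag jumps), as are MOTUs shorter than
40 bp (bacterial fragments; true amplicons for this marker run 60–84 bp).
A PCR retaining fewer than 500 reads indicates failed amplification and is
rejected; exactly 500 reads is kept, reading the rule strictly as
"< 500". The host is the most abundant MOTU exactly matching a reference
sequence. When more than one mammal species remains after filtering, the
top species' best MOTU must be at least twice as abundant as the runner-up
species' best MOTU, otherwise the sample is discarded as ambiguous. Two
open points were settled as follows: ties for the most abundant MOTU are
ambiguous (the dominance ratio cannot exceed 1), and the 2x rule compares
the top MOTU per species rather than species-aggregated reads — with one
MOTU per species in practice the two readings coincide, and the per-MOTU
version is robust to reference libraries that split a species across
several MOTUs.

## Replicate quality control (plant marker)

Each sample has three PCR replicates. Replicates are converted to
within-PCR proportions; the sample barycenter is their arithmetic mean.
Distances of replicates to their own barycenter ("PCR distances") should
be small relative to distances between barycenters of different samples
("sample distances"). The QC threshold is derived from the sample
distances: a normal distribution is fitted to their logs and the 5th
percentile, `exp(mu + qnorm(0.05) * sigma)`, becomes an upper bound on
acceptable PCR distances. The fit uses the unbiased (n−1) standard
deviation; with fewer than 20 positive distances (configurable) the
estimate is refused and an explicit threshold must be supplied. Distances
default to Bray–Curtis on proportions, for consistency with the
dissimilarity used in the ordination; Euclidean-on-Hellinger is available
via `method = "hellinger"`.

Replicates are then discarded in a fixed order: (1) fewer than 1000 total
reads (poor amplification; 999 fails, 1000 passes); (2) PCR distance above
the threshold, with barycenters recomputed after step 1; (3) "clustering
with controls". The published analyses of this kind typically judge
control clustering from a graph partition drawn by eye; as a deterministic
and testable surrogate we use a k-nearest-neighbour rule over the
composition vectors of all surviving replicates and non-empty controls: a
replicate whose majority of k = 5 neighbours are controls is discarded.
Samples left with fewer than two kept replicates are dropped entirely.

Read counts are averaged across kept replicates on the proportion scale
and rescaled by the mean replicate depth. Averaging proportions rather
than raw counts avoids weighting the consensus toward the deepest
replicate; raw-count averaging remains available (`average = "counts"`)
since the convention is not universal. MOTUs with reference similarity
below 95% are removed as likely artifacts, and after RRA conversion MOTUs
that never reach 2.5% in any sample are dropped as sporadic occurrences;
RRA is renormalized after each removal. The sporadic filter is applied
after replicate averaging, following the order in which the quantities are
defined. The threshold is estimated globally rather than per sequencing
library by default; a per-library threshold can be passed explicitly.

## Niche metrics

**Richness** S is the count of strictly positive RRA entries per sample,
taken on the post-QC, post-sporadic-filter MOTU table, before any category
collapsing — i.e., on the final MOTU dataset. Group differences use
pairwise Dunn rank-sum tests: mid-ranks over the pooled values,
`z = (Ri - Rj) / sqrt((N(N+1)/12 - T)(1/ni + 1/nj))` with the usual tie
correction `T`, two-sided normal p-values (the pairwise bracket display
the method supports is inherently two-sided), Benjamini–Hochberg step-up
adjustment over all pairs.

**Dietary niche width** is the Hill number of order 1 of the stratum's
average diet: `DNW = exp(H')` with `H'` the Shannon entropy of the
unweighted mean of the sample RRA vectors. The mean is unweighted because
RRA is designed to give samples equal weight; a read-weighted mean would
reintroduce depth as a hidden weight.

**Pianka's overlap** `O = sum(u v)/sqrt(sum(u^2) sum(v^2))` is computed at
the transect scale per season. Intraspecific overlap on a transect is the
mean over all unordered pairs of conspecific samples (requiring at least
two). Interspecific overlap is the index between the two species' mean
diets on the transect; this stays well-defined with a single sample per
species, matching the replication actually available per transect. A
mean-over-heterospecific-pairs variant is available
(`inter_mode = "pairs"`). Landscape-by-season summaries flag cells resting
on fewer than four transects.

**Jacob's selectivity** `D = (r - p)/(r + p - 2 r p)` contrasts the
transect-average diet proportion `r` of a food category with its
availability `p` from step-point surveys in the species' browsing-height
window (moose 0–3 m, red deer 0–2.3 m, fallow deer 0–1.8 m, roe deer
0–1.5 m). A category eaten but absent from the availability table gets
`p = 0`, hence `D = 1`; `r = p = 0` and `r = p = 1` leave D undefined and
are reported as missing. Single-transect strata carry no SD and are
flagged.

## Trophic partitioning

Profiles are Hellinger-transformed (square roots of RRA — rows are already
relative, so no further standardization is needed), converted to
Bray–Curtis dissimilarities, and ordinated by principal coordinates:
Gower double-centering `B = -1/2 J D^2 J` and eigendecomposition, scores
scaled by the square roots of positive eigenvalues. Negative eigenvalues
(Bray–Curtis is not Euclidean-embeddable) are reported but uncorrected by
default — no Cailliez/Lingoes adjustment — since only the leading axes are
interpreted; each axis' sign is fixed by making its largest-magnitude
score positive, so ordinations are reproducible.

Species separation is tested pairwise on the first two axes. The cited
factor-fitting procedure does not document its internal statistic, so the
package uses a transparent surrogate: centroid R²
(`1 - SS_within/SS_total` of the 2-D scores), with an add-one permutation
p-value under label shuffling and Bonferroni correction over the pairs.
Compact significance letters are derived by the insertion algorithm.
Taxon contributions are least-squares fits of each taxon's RRA on the two
axis-score columns; the arrow is the normalized coefficient direction
scaled by `sqrt(R^2)`, the permutation p-value shuffles rows, and the six
taxa with highest R² are reported by default. Permutations default to
10,000 with a mandatory seed; tests in this package run at 999–3999
permutations to keep the suite fast, which bounds attainable p-values at
1/(n_perm + 1).

## Overlap drivers

The cervid density index pools pellet-group counts over all four species:
per species class, groups divided by the surveyed area of that class
(each surveyed plot contributes its area once, regardless of how many
rows carry its counts), rescaled to groups per 100 m², then summed over
classes. Transects with fewer than 12 of 16 surveyed plots are excluded,
and indices above 25 groups/100 m² are removed as outliers.

Overlap is modeled by beta regression: `y ~ Beta(mu*phi, (1-mu)*phi)` with
`logit(mu) = X beta` and constant precision. The precision link is log —
the convention guarantees positivity and is numerically robust; estimation
is BFGS from a logit-scale least-squares start with the analytic score,
standard errors from the inverse observed information (central differences
of the score), two-sided normal z tests. Exact 0/1 responses are
compressed by `y' = (y(n-1) + 0.5)/n`, applied only in strata that contain
boundary values, to perturb the data minimally. The reported pseudo-R² is
the squared correlation of `logit(fitted)` with `logit(y)`, labeled as
such since conventions differ. Strata below 8 transects are skipped with a
note; predictor pairs with |correlation| above 0.3 are flagged, matching
the screening threshold used for the field covariates. Near-separation can
produce very large coefficients in sparse strata; the fit reports
convergence diagnostics rather than applying penalization.

## The synthetic community generator

`make_default_spec()` encodes the study conditions the generator emulates:

* two landscapes contrasting in deer density (cervid index mean ± SD:
  boreo-nemoral 4.88 ± 2.17 vs coastal-boreal 0.43 ± 0.62 groups/100 m²,
  moment-matched gamma), arable land (15.7 ± 14.4% vs 5.3 ± 7.9%,
  moment-matched beta) and habitat diversity (Shannon 2.10 ± 0.19 vs
  1.95 ± 0.17, truncated normal), drawn independently so predictor
  correlations stay inside the 0.3 screening bound;
* a 210-MOTU plant pool in 77 family-level groups, with named key taxa
  (pine, spruce, juniper, birch, alder, willow, poplar, heather,
  *Vaccinium*, graminoids incl. *Avenella* and *Luzula*, cereals, forbs);
  the generator resolves food categories at 15 rather than the 21 used in
  field summaries, a desk-scale simplification that preserves the
  contrasts the analysis tests;
* species-by-season-by-landscape mean diets: moose winter/spring diets
  pine-dominated (> 50% boreo-nemoral, 35–40% coastal-boreal, ~15% in
  summer–autumn) with graminoids essentially absent (< 1%); graminoids and
  forbs concentrated in the smaller deer, rising from roe through red to
  fallow deer; fallow deer summer diets forb-rich and broad;
* within-category MOTU evenness decreasing from fallow deer (0.8) to
  moose (0.3), which makes per-sample richness and niche width increase
  from moose to fallow deer structurally rather than by tuning;
* across-sample Dirichlet concentration per season — winter 40, spring 30,
  summer–autumn 10 — encoding winter convergence on the few available
  resources and summer individual divergence, the mechanism behind
  seasonal overlap contrasts; these three values were chosen once as the
  generator's study conditions;
* read counts as Dirichlet-multinomial: a replicate-level Dirichlet
  perturbation (concentration 200) of the latent diet, then a multinomial
  draw at log-normal depth (median 8000). A plain multinomial would make
  the replicate-QC stage vacuous; the overdispersion gives it something
  to detect. Two failure mechanisms mirror the two discard rules: 3% of
  replicates draw a sub-1000 depth, and 1.5% are resampled toward the
  contamination profile so the control-clustering rule fires;
* controls (extraction blanks, PCR negatives/positives, primer blanks)
  drawing Poisson totals from per-kind expected read counts around a
  contamination profile of ubiquitous taxa; the published record gives no
  quantitative contamination levels, so these defaults are free
  parameters, generated for the plant marker where they enter the QC;
* a single integer master seed with deterministic per-stratum child seeds,
  so subsets reproduce independently.

Sampling effort defaults to 17 + 16 diet transects with roughly 2.5 moose,
1.8 red, 1.2 roe and 1.5 (boreo-nemoral) or 0.25 (coastal-boreal) fallow
samples per transect and season — fallow deer are rare in the northern
landscape, which propagates realistic sparse-cell behavior (flagged
summaries, skipped regression strata) into the pipeline.

What the generator does **not** emulate: sequence-level artifacts
(chimeras, tag jumps as such), amplification bias between plant taxa,
spatial autocorrelation among transects, year effects, and digestibility
differences between food items. Passing tests therefore show that the
statistics and filters behave correctly under the assumed sampling model,
not that RRA equals ingested biomass in real feces.

## Numerical choices and problem sizes

Tolerances: profile rows must sum to 1 within 1e-9; proportions
round-trip through TSV at ~1e-15. PCoA eigenvalues below 1e-12 of the
leading one count as null. Permutation p-values use the add-one
estimator. Degenerate inputs: zero-read samples are dropped with a
warning; a zero diet vector makes Pianka's index an error rather than a
silent 0; Dunn groups with fewer than two observations are excluded with
a warning.

The test suite exercises the pipeline at deliberately modest sizes chosen
as the package's own verification scale: 4 + 4 transects for
simulation-heavy unit tests, the full default design (~650 samples,
~2600 PCRs) for the end-to-end qualitative checks, 200 replicates for
beta-regression parameter recovery (n = 500, fixed design), 200 null
datasets for the permutation test's size, 999 permutations for ordination
tests, and 10^4 draws for the threshold calibration check.

## Known limitations

* The k-NN control rule and centroid-R² permutation test are documented
  surrogates for procedures the source methods describe only partially;
  both are deterministic and tested, but not byte-identical to any
  specific external implementation.
* Beta regression uses constant precision; variable-dispersion models and
  model selection are out of scope.
* No rarefaction or richness standardization: read depth enters richness
  only through the QC filters.
* Interspecific overlap from mean diets smooths within-species variation
  on a transect; use `inter_mode = "pairs"` where that matters.
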