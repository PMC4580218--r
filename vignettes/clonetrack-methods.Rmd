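---
title: "Methods: clonal variety identification and ancestry estimation"
author: "clonetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal variety identification and ancestry estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrack)
```

## The problem

Vegetatively propagated crops (cassava, yam, potato, banana) move through
farmers' fields as cuttings: a variety is a *genet*, and every plant derived
from it is a *ramet* carrying the same genotype up to genotyping error.
Farmer-reported variety names are unreliable — one genet accumulates several
names (synonymy) and one name covers several genets (homonymy) — so adoption
studies need molecular identification.  Given genome-wide biallelic SNP
dosages (0/1/2, the count of the alternate allele) for field accessions and
for a reference library of known varieties genotyped in duplicate, the
pipeline answers four questions:

1. which accessions are the *same clone* (identity testing),
2. which library variety each accession *is* (matching),
3. what the *ancestry structure* of the germplasm looks like (admixture),
4. whether a *reduced marker panel* would suffice (AIMs).

## Identity testing with a duplicate-calibrated threshold

Between samples $a$ and $b$ the identity-by-state distance is

$$d_{ab} = \frac{1}{|J_{ab}|}\sum_{j \in J_{ab}} \frac{|g_{aj}-g_{bj}|}{2},$$

over the jointly non-missing loci $J_{ab}$.  Distances are computed on raw,
pre-imputation calls: mean-imputation pulls genotypes toward the locus
centroid and would artificially shrink duplicate distances, biasing the
calibration below.

Two ramets of one genet differ only by genotyping error, dominated in
low-depth sequencing by heterozygotes miscalled as homozygotes.  Each such
miscall contributes $1/2$ at its locus, so a clone pair with heterozygosity
$H$ and per-call miscall rate $\varepsilon$ sits at expected distance
$H\varepsilon/2$ — small but not zero.  The identity threshold is therefore
*calibrated*, not assumed: `calibrate_threshold()` takes the distances
between re-genotyped duplicate DNAs of the library, multiplies the maximum
by a safety factor (default 1.25) and rounds up to two decimals.  A warning
fires when the calibrated value is not below the smallest distance between
distinct library duplicate groups — note that in a survey-like library this
can fire legitimately, because independently collected accessions of the
*same* variety form distinct duplicate groups at clone distance.

Samples are grouped at the threshold either by connected components of the
graph with edges $d < t$ (default; a chain $a\!-\!b$, $b\!-\!c$ merges all
three) or by cutting the Ward dendrogram at height $t$.  The Ward tree uses
the Lance–Williams update on squared distances
(`stats::hclust(method = "ward.D2")`), accepting the non-Euclidean IBS
matrix as-is.  The library is collapsed to one representative genotype per
clone group (the member with fewest missing calls), and each field accession
is assigned the nearest library representative iff that distance is below
the threshold.

## The admixture model

Ancestry is estimated under the standard maximum-likelihood admixture model:
individual $i$ draws a fraction $q_{ik}$ of its genome from founder
population $k$ whose alternate-allele frequency at locus $j$ is $f_{kj}$,
and

$$g_{ij} \sim \mathrm{Binomial}\!\left(2,\; p_{ij}\right), \qquad
p_{ij} = \sum_k q_{ik} f_{kj}.$$

`fit_admixture()` maximizes the log-likelihood by block EM with the
classical responsibility updates for $Q$ (rows constrained to the simplex)
and $F$ (clamped to $[\delta, 1-\delta]$, $\delta = 10^{-6}$).  EM was
chosen over quasi-Newton block relaxation because it is simple to verify —
the likelihood provably never decreases, a property the test suite asserts
at every iteration — and reaches the same stationary points.  Three seeded
restarts (default) guard against local optima; supervised mode pins
labelled samples' $Q$ rows to indicator vectors, which reduces the $F$
update to per-founder observed allele frequencies when everything is
labelled (a closed form the tests check).

**Ancestry-support selection.**  A founder that contributes nothing to a
sample sits on the boundary of the simplex, where its ML estimate is
positive with probability about one half — so small spurious ancestry
fractions are expected even at the exact MLE, and comparing nested supports
by raw likelihood can never remove them (the larger model always fits at
least as well).  After convergence each sample's components below 5% are
tentatively zeroed, the restricted fit is re-run for that sample with $F$
fixed, and the restriction is kept unless the likelihood loss exceeds a BIC
penalty, $2\Delta\ell > d\log m_i$ for $d$ dropped components.  This matters
at classification boundaries: an F1 hybrid has true major ancestry exactly
0.5, and without support selection residual spurious mass pushes the
estimate below 0.5 for a sizable minority of F1s.

**Choosing K.**  `cross_validate_k()` partitions the non-missing *entries*
(not samples) into 10 folds, refits with each fold masked, and scores
$\mathrm{mean}\,(g_{ij} - 2\hat p_{ij})^2$ on the masked entries; the best
$K$ minimizes the mean fold error.  Entry-wise masking keeps every sample
and locus in every training set; entries whose locus would lose all
observations in some fold are reassigned and counted.  CV fits use lighter
controls than the final fit (single restart, tol $10^{-5}$, 300 iterations)
because held-out prediction error stabilizes long before the likelihood
tail does and a scan is folds × |K range| fits.

**Label alignment.**  Mixture labels are arbitrary, so any comparison of two
fits first finds the column permutation maximizing summed Pearson
correlation, by exact dynamic programming over column subsets
($O(2^K K)$; constant columns score zero).

## Ancestry classes

Following the purity conventions of variety-identification practice,
`classify_ancestry()` calls a sample **pure** when its largest ancestry
fraction exceeds 0.90, **half-hybrid** when it is at least 0.50 but at most
0.90 (both boundary values fall here: the pure rule is strict ">90%", the
hybrid rule inclusive "at least 50%"), and **multi** otherwise.  The classes
are exhaustive and mutually exclusive; the summary table reports pure
varieties in descending accession count with roman numerals, then one row
per half-hybrid major-ancestry group (excluding the pure members, so rows
never overlap), then a single multi-ancestry row.

## Ancestry-informative markers

Per-locus differentiation among the admixture-derived subpopulations
(samples with maximum ancestry > 0.90, the same purity convention) is
measured with the Weir–Cockerham estimator: variance components $a$ (among
populations), $b$ (among individuals within), $c$ (within individuals) and
$\theta = a/(a+b+c)$, computed from subpopulation sample sizes, allele
frequencies and observed heterozygote fractions.  Monomorphic loci have
$a+b+c = 0$ and undefined $\theta$; they are flagged and excluded from
panels.  An AIM panel keeps loci with $\theta$ above a cutoff, and
`subset_accuracy_experiment()` refits the model in supervised mode on each
panel — and on 20 equal-size panels drawn uniformly *with replacement* —
scoring each refit by the squared Pearson correlation between all aligned
$Q$ entries of the reduced and full fits (per-ancestry-column $R^2$ is also
emitted, since the granularity of "correlations" is a user choice).

## DAPC validation

The admixture model assumes Hardy–Weinberg and linkage equilibrium, both
violated by clonal duplication, so results are cross-checked with an
assumption-free method.  Dosages are column-centered (missing entries at
the locus mean, i.e. zero after centering) and projected onto top singular
vectors with a deterministic sign convention (largest-magnitude loading
positive).  K-means with `n_init` seeded starts is scanned over
$k = 1..k_{max}$ and scored by

$$\mathrm{BIC}(k) = n \log\!\left(W_k/n\right) + k \log n,$$

with $W_k$ the best within-cluster sum of squares ($W_1$ = total SS).  The
cited method prints no formula, so this standard k-means surrogate is this
package's definition; monotone transformations preserve the comparisons
that matter (curve shape and argmin).  It behaves well in the regime PCA
scores actually occupy — many dimensions, most variance non-clusterable —
where splitting a true cluster buys little; in 2–3 informative dimensions
with nothing else, any such penalty under-penalizes and the curve keeps
falling, which is why the scan is always run on a full complement of PCs
(default 70, truncated to rank for small problems).  Linear discriminant
axes are built from the between/within scatter of retained PCs
(ridge-regularized if the within-scatter is singular), and membership
probabilities use a Gaussian kernel with shared unit covariance in the
sphered discriminant space, $\Pr(i \in g) \propto \exp(-d^2_{ig}/2)$,
normalized per individual — the source method's exact posterior is likewise
unspecified.  `compare_clusterings()` cross-tabulates admixture-pure
samples against DAPC maximum-membership clusters and reports per-cluster
agreement plus how many samples each method considers admixed.

## The synthetic-data generator

`emit_scenario()` builds a complete desk-scale survey with known truth:
founder allele-frequency vectors iid Beta(0.5, 0.5) (the U-shaped spectrum
of genome-wide SNP panels) clamped away from fixation; cultivars as pure
HWE draws from one founder; a reference library in which some cultivars
enter more than once under different names and every accession is
genotyped in duplicate; field accessions that are ramets of library
cultivars (popularity skewed), ramets of cultivars from founders absent
from the library, F1 (0.5/0.5), backcross (0.75/0.25) and multi-founder
(Dirichlet, rejected until max < 0.5) individuals; and a naming layer with
synonyms and homonyms.  Every re-genotyped copy passes through the error
model the field actually exhibits: each heterozygous call flips to a random
homozygote with probability $\varepsilon$ (default 0.03) and every call
goes missing with probability $\mu$ (default 0.02).  Read depth is not
simulated; the per-call miscall is the error mode that makes threshold
calibration non-trivial, which is what the tests need.  Founders are
unstructured (no shared drift or phylogeny).

**What passing tests show — and don't.**  On benchmark designs where each
founder is represented by many distinct genotypes (e.g. 48 pure samples per
founder at 2000 loci), the fitted $Q$ recovers the truth to MAE < 0.01 and
classification is essentially perfect.  The default survey-like scenario is
deliberately harsher and exposes a structural limit worth understanding: 34
cultivars spread over 8 founders give each founder only ~4 distinct
genotypes, so the unsupervised components lock onto major *clonal
varieties* rather than deep founders, and founder-level class recovery
saturates near 77%.  This mirrors what the admixture model does on real
clonal surveys — the inferred clusters track the major varieties, and a
substantial share of field accessions scores as admixed — and is why the
clone-identity half of the pipeline (which recovers 100% of clone pairs
with zero false merges on the same scenario) carries the variety
identification, with admixture describing structure.  Real data differ from
the generator in having linkage disequilibrium, shared founder drift,
depth-dependent error and population-specific missingness; none of these
affect the calibration logic, but all can move admixture estimates.

## Numerical choices and problem sizes

* Frequency clamp $\delta = 10^{-6}$; EM tolerance $10^{-6}$ relative
  log-likelihood change, 2000 iterations cap (warn + `converged = FALSE`
  beyond).
* Dosage imputation rounds half away from zero and clamps to {0, 1, 2};
  the knn imputer breaks neighbour ties deterministically by distance
  order.
* Ties in library matching go to the lowest distance, then library order;
  clone-group representatives minimize missing calls, then sample id.
* The test suite exercises the pipeline at sizes chosen to finish quickly
  on one CPU while leaving comfortable recovery margins: ancestry
  benchmarks at $n = 300$, $m = 2000$, $K = 5$; the CV-over-K experiment at
  $n = 150$, $m = 400$ with $K_{true} \in \{3, 5\}$ over $K = 2..8$
  (10 folds, five seeds each); the calibration study with a 30-cultivar
  duplicated library at $\varepsilon = 0.03$, $\mu = 0.02$; the default
  survey scenario with 34 cultivars / 64 library accessions / 900 field
  accessions at $m = 1000$.  These sizes are the package's standing
  benchmark definitions, not limits of the method.

## Known limitations

* No linkage-aware or depth-aware modelling; no Bayesian posterior on Q.
* The BIC-based support selection uses a per-sample approximation (F held
  fixed); it is a classification aid, not a formal test of admixture.
* `hapmap_like` input is this package's documented dialect, not an attempt
  to parse any specific upstream pipeline's files.
* Choosing K remains partly judgment: the CV curve is reported alongside
  the dendrogram/DAPC correspondence, and the two need not agree — the
  package reports both and never auto-reconciles them.
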