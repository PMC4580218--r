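# clonetrack

Molecular identification of clonally propagated crop varieties from
genome-wide SNP genotypes.

## The problem

In vegetatively propagated crops (cassava, yam, potato, ...) a variety is a
single genotype — a *genet* — and every field plant derived from it by
cuttings is a *ramet* of that genet.  Farmer-reported variety names are a
poor guide to identity: one genet collects several names across regions
(synonymy) and one name is reused for distinct genets (homonymy), which
confounds any name-based estimate of variety adoption.  Given biallelic SNP
dosage matrices (0/1/2 = count of the alternate allele, `NA` = missing) for
field accessions and for a reference library of known varieties genotyped in
duplicate, `clonetrack` identifies which accessions are the same clone,
names them against the library, and describes the ancestry structure of the
germplasm.

## What it computes

* **Identity testing** — pairwise identity-by-state distance
  `d_ab = mean(|g_a - g_b| / 2)` over jointly non-missing loci, a Ward
  dendrogram (Lance–Williams update on squared distances), and an identity
  threshold *calibrated from re-genotyped library duplicates*: duplicate
  DNAs differ only by genotyping error (mostly heterozygotes miscalled as
  homozygotes at low read depth), so the threshold is a safety factor
  (default 1.25) times the largest duplicate-pair distance, rounded up to
  two decimals.  Clone groups come from graph components at `d < t` (or a
  dendrogram cut); the library is collapsed to unique cultivars and each
  field accession is matched to the nearest cultivar within the threshold.
* **Ancestry estimation** — the maximum-likelihood admixture model
  `g_ij ~ Binomial(2, sum_k q_ik f_kj)` fit by EM (supervised mode
  available), with 10-fold masked-entry cross-validation to choose the
  number of founder populations K, exact label alignment between fits, and
  classification of each accession as pure (max ancestry > 0.90),
  half-hybrid (>= 0.50) or multi-ancestry.
* **Marker reduction** — per-locus Weir–Cockerham F_ST (components a, b, c
  and theta) among the ancestry-derived subpopulations,
  ancestry-informative-marker panels above F_ST cutoffs, and the accuracy
  (R² against the full-panel fit) of F_ST-selected versus random panels,
  20 random draws with replacement per size.
* **Validation** — DAPC: PCA, a k-means scan scored by
  `BIC(k) = n log(W_k/n) + k log(n)`, linear discriminants and Gaussian
  membership probabilities, cross-tabulated against the admixture clusters.
* **Synthetic surveys** — a generator that emits complete studies (founders,
  cultivars, duplicated library, field clones, F1/backcross/multi hybrids,
  het-miscall and missingness error, noisy farmer names) with full ground
  truth, so the whole pipeline is testable without any data download.

## Worked example

```r
library(clonetrack)

# a desk-scale synthetic survey: 12 cultivars in a duplicated library,
# 80 field accessions including hybrids and varieties missing from the library
params <- sim_params(K_true = 6, m = 1000,
                     n_library_cultivars = 12, n_library_accessions = 16,
                     n_released = 5, library_founders = 5,
                     n_field_clones = 60, n_unrepresented_genets = 1,
                     n_unrepresented_clones = 8, n_f1 = 8, n_backcross = 2,
                     n_multi = 2, seed = 42)
survey <- emit_scenario(params)
lib_ids <- survey$meta$sample_id[survey$meta$source == "library"]
fld_ids <- survey$meta$sample_id[survey$meta$source == "field"]

# 1. calibrate the identity threshold from library duplicates
D_lib <- ibs_distance(survey$genotypes[lib_ids, ])
thr <- calibrate_threshold(D_lib, survey$meta)

# 2. collapse the library, match the field accessions
lib <- collapse_library(survey$genotypes[lib_ids, ], thr, meta = survey$meta)
matches <- match_to_library(survey$genotypes[fld_ids, ], lib)

# 3. ancestry on the whole survey, classes for the field accessions
fit <- fit_admixture(survey$genotypes, K = 6, seed = 1)
classes <- classify_ancestry(fit$Q[fld_ids, ])

# 4. assemble the variety report
D_fld <- ibs_distance(survey$genotypes[fld_ids, ])
asg <- clone_groups(D_fld, thr, G = survey$genotypes[fld_ids, ])
report <- variety_report(asg, matches, classes, survey$meta)
head(summarize_varieties(report, lib), 8)
```

Output (a real run):

```
identity threshold: 0.02   (max duplicate distance 0.0109)
library: 32 samples -> 12 unique cultivars
field accessions matched: 60 of 80

       pure half_hybrid       multi
         63           8           9

                    variety n_accessions         status                      names
1                 Variety I           24       released Released01;Name001;Name002
2                Variety II           11       landrace            Name023;Name022
3               Variety III            8 not_in_library            Name016;Name024
4                Variety IV            7       landrace                    Name018
...
8 50% ancestry from group 4            3         hybrid          Name004;Hybrid003
```

Reading it: the threshold 0.02 clears the worst duplicate pair (0.0109) with
margin; the 32 duplicated library samples collapse back to the 12 cultivars
the generator planted; exactly the 60 field ramets of library cultivars
match (the 8 clones of the unrepresented founder and the 12 hybrids
correctly stay unmatched).  Variety I is the most adopted cultivar and
carries three farmer names — one released name and two local synonyms.  The
ancestry classes are estimates, not bookkeeping: hybrids between
*variety-level* ancestry components split between the half-hybrid and
multi-ancestry classes, which is the expected behaviour of the admixture
model on clonal survey data (see the methods vignette).

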