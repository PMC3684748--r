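# tempodrift

Spatiotemporal population genomics for diploid biallelic SNP panels:
quality control, differentiation statistics, DAPC clustering, and a
temporal outlier test against a Wright–Fisher drift null.

## The problem

Marine species such as Atlantic cod often carry very weak neutral
population structure (multilocus F<sub>ST</sub> of 0.003–0.03) even where
several reproductively distinct components co-occur and mix. Archived
tissue (historical otoliths) genotyped alongside contemporary samples
makes two questions answerable at once: *how many genetic clusters are
present and where*, and *did any locus change more over the decades than
drift and sampling noise allow* — the signature of ongoing selection.
`tempodrift` implements that full analysis for genotype matrices coded as
alternate-allele dosage 0/1/2, plus a synthetic-data generator that
emulates the motivating study design (four clusters, ~935 SNPs on 23
linkage groups, two sampling eras 11–15 generations apart, N<sub>e</sub> ≥
450, elevated missingness in historical samples) so every statistical
claim is testable against planted truth.

## Methods at the core

* **QC** — iterative call-rate filtering (retain > 0.7), replicate
  concordance (discard < 0.9), per-sample summaries (n, variable loci, %
  missing, H<sub>obs</sub>, H<sub>e</sub>).
* **Classical statistics** — Hardy–Weinberg Monte-Carlo tests (10⁵
  allele-shuffling permutations), composite LD r² and pruning (mean r² >
  0.1 within 'pure' samples), two-population Weir–Cockerham
  θ = Σa / Σ(a+b+c), summed per-locus 2×2 chi-square tests of
  allele-frequency homogeneity, Storey q-values (q < 0.05 convention).
* **DAPC** — PCA reduction, K-means scan scored by
  BIC = n·ln(W/n) + K·ln(n), discriminant functions from whitened
  between/within scatter, posterior memberships (uniform priors), the
  pure/mixed rule at mean membership > 0.6, hold-out cross-validation,
  a-score PC selection, DF1/DF2 → red/green recoding, per-locus loadings.
* **Temporal outlier test** — the package's centerpiece. For a location
  sampled at times 0 and t: per-locus
  F<sub>c</sub> = (x−y)² / ((x+y)/2 − xy); effective size
  N̂<sub>e</sub> = t / (2(F̄<sub>c</sub> − 1/(2S̃₀) − 1/(2S̃<sub>t</sub>)))
  with chi-square 95% limits; a null cloud of 10⁵ loci simulated under
  forward Wright–Fisher drift within a single population; per-locus
  p-values conditioned on heterozygosity via the 5 000 nearest simulated
  loci; 95%/99% envelopes; sensitivity reruns at a 7-year generation
  length and at the lower N<sub>e</sub> confidence limit.

## Worked example

```r
library(tempodrift)

sim <- simulate_dataset(sim_config(seed = 2026))   # the default scenario
ds  <- filter_call_rate(sim$dataset)$dataset

pca  <- pca_reduce(ds, 50)
scan <- kmeans_bic_scan(pca$scores, 1:10, seed = 2026)
scan$best_k
#> [1] 4

model <- fit_dapc(pca$scores, scan$assignments$K4, pca = pca)
model
#> dapc_model: 4 groups, 3 DFs
#>   discriminating power: 38.0%, 32.2%, 29.8%

memb <- posterior_membership(model, pca$scores,
                             sample_codes = ds$samples$sample_code)
memb$purity
#>  PUR145  PUR108  PUR245  PUR208  PUR345  PUR308  PUR445  PUR408   MIX50   MIX08
#>  "pure"  "pure"  "pure"  "pure"  "pure"  "pure"  "pure"  "pure"  "pure" "mixed"

res <- temporal_outlier_test(ds, "PUR145", "PUR108", seed = 2026)
res
#> temporal_outlier_result: PUR145 -> PUR108 (t = 13 generations, Ne used = 421)
#>   loci tested: 929 | excluded: 6
#>   outliers: q<0.05: 0 | above 95% envelope: 45 | above 99%: 10
res$ne
#> ne_estimate: Ne = 421 [320, 580] (Fc = 0.0498 over 929 loci, t = 13)
```

Reading of the output: the BIC scan recovers the four planted clusters;
the sample-level purity rule classifies the contemporary 50/50 offshore
mixture as 'mixed' (the historical one lands at 0.6+ by sampling noise —
mixtures of sharply assigned individuals, not admixture). The temporal
test compares a historical and a contemporary sample of the same pure
location: the N<sub>e</sub> estimate brackets the generating value of 500,
and with no selection planted, no locus passes q < 0.05 while about 5% sit
above the 95% envelope, as a calibrated null should.

The same stages run from the shell via the thin wrapper:

```sh
Rscript inst/scripts/tempodrift.R simulate --out run1 --seed 7
Rscript inst/scripts/tempodrift.R qc       --out run1 --seed 7
Rscript inst/scripts/tempodrift.R temporal --out run1 --seed 7
```

Each stage writes TSV artifacts plus a JSON manifest (input hashes,
parameters, seed); exit codes are 0 (ok), 2 (missing input), 3 (invalid
configuration).

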