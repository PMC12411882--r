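# ratiotax

Integrative species delimitation often rests on two quantitative pillars:
morphometric ratios of body measurements (shells, genitalia) and genetic
distances between sequenced loci. `ratiotax` implements both workflows as a
tested, seedable R pipeline for taxonomists who want the numbers behind an
identification key — which body ratio separates two taxa, how much of that
separation is shape rather than size, and how divergent their haplotypes
are.

## What it computes

**Multivariate ratio analysis (MRA).** For a table of strictly positive
measurements *x<sub>sv</sub>* (specimen *s*, variable *v*):

- *isosize* = (∏<sub>v</sub> x<sub>sv</sub>)<sup>1/p</sup>, the geometric
  mean, is the isometric size proxy; its log is the mean log measurement.
- *shape* coordinates are centered log-ratios,
  ln x<sub>sv</sub> − ln(isosize<sub>s</sub>): rows sum to zero and are
  invariant to specimen size.
- **Shape PCA** eigendecomposes the covariance of the shape matrix; each
  component's **PCA Ratio Spectrum** places variables at their loadings, so
  the pair at opposite ends forms the ratio explaining most of that
  component.
- The **Allometry Ratio Spectrum** uses per-variable OLS slopes of shape on
  log isosize; both spectra carry percentile bootstrap confidence intervals
  (default 999 replicates, 68% coverage).
- The **LDA ratio extractor** scores every log-ratio
  ln x<sub>i</sub> − ln x<sub>j</sub> by its standard distance
  D<sub>ij</sub> = |mean<sub>A</sub> − mean<sub>B</sub>| / pooled sd, picks
  the best and a decorrelated second ratio, and decomposes separation into
  D<sub>size</sub> (standard distance of log isosize) and D<sub>shape</sub>
  (Mahalanobis distance of group shape means), giving
  **δ = D<sub>size</sub> / (D<sub>size</sub> + D<sub>shape</sub>)** — near 0
  for shape-driven, near 1 for size-driven separation.

**Multilocus distances.** Pre-aligned FASTA loci are trimmed (0-based
half-open intervals), collapsed to haplotypes by exact string identity,
concatenated with a per-specimen haplotype ledger, and compared with
**Kimura two-parameter** distances, d = −½ ln((1 − 2P − Q)√(1 − 2Q)), under
complete or pairwise deletion, summarised as within/between-group
min–max (mean) percent tables.

**Simulators.** `simulate_measurements()` draws log-normal measurement
tables with a latent allometric size axis and optional planted shape or
size contrasts; `simulate_sequences()` draws two-clade haplotype sets
calibrated in expected K2P divergence (defaults 0.5% within, 19% between).

## Worked example

```r
library(ratiotax)

tbl <- simulate_measurements(variables = genital_vars, n_per_group = 30,
                             planted_pair = c("V", "VA"), offset_sd_units = 3,
                             groups = c("CAR", "CLA"), seed = 42)
pca <- shape_pca(tbl)
pca
#> Shape-space PCA: 60 specimens, 6 variables
#>   % variance (first 3): 51.9, 16.9, 12.3

lda_ratio_extractor(tbl)
#> LDA ratio extractor: CAR vs CLA
#>   best ratio   V/VA  D = 3.12
#>   second ratio P/V  D = 1.56  (|r| with best = 0.31)
#>   D_size = 0.174  D_shape = 3.340  delta = 0.049
```

The extractor recovers the planted vagina/vaginal-appendix contrast as the
best discriminating ratio with standard distance ≈ 3 (the planted effect
size in pooled-sd units), and δ ≈ 0.05 says the separation is almost purely
shape. `mra_report()` renders this as an identification-key style table with
per-group ratio ranges and an overlap flag.

On the molecular side:

```r
sim <- simulate_sequences(n_per_clade = 10, length = 615, seed = 42)
sm <- group_distance_summary(k2p_distances(sim$alignment), sim$population_map)
format_distance_summary(sm)
#> 1 Within cladeA             0.0–1.1 (0.6)
#> 2 Within cladeB             0.2–1.0 (0.6)
#> 3 Between cladeA and cladeB 18.2–19.4 (18.8)
```

Within-clade distances sit near the configured 0.5% and the between-clade
mean near 19% — the regime in which mitochondrial barcoding separates
congeneric land-snail species.

The packaged specimen ledger (`read_accession_ledger()`) ships the
accession/haplotype bookkeeping of a published *Monacha* survey;
`ledger_stats()` recovers its per-locus sequence and haplotype counts, and
`accession_span()` checks them against the deposited accession ranges.

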