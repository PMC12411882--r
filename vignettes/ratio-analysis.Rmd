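---
title: "Morphometric ratio analysis and multilocus distances with ratiotax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric ratio analysis and multilocus distances with ratiotax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiotax)
```

## The problem

Closely related land-snail species are frequently indistinguishable by
shell outline yet cleanly separable by genital measurements and
mitochondrial sequences. Two quantitative questions recur in such
revisions: *which body ratio best separates two candidate taxa, and is that
separation a matter of shape or merely of size?* — and *how divergent are
their haplotypes at the sequenced loci?* `ratiotax` answers both with a
reproducible pipeline: multivariate ratio analysis (MRA) on the
morphometric side and a haplotype/K2P workflow on the molecular side.

## Size and shape in log-ratio space

All MRA machinery works on natural logs of strictly positive measurements.
For specimen $s$ with measurements $x_{s1},\dots,x_{sp}$:

- **isosize** $g_s=(\prod_v x_{sv})^{1/p}$ is the geometric mean; its log
  is the mean log measurement. Multiplying all of a specimen's measurements
  by $c$ multiplies isosize by $c$ — it is the isometric size axis.
- **shape** is the centered log-ratio (clr) vector
  $z_{sv}=\ln x_{sv}-\ln g_s$. Rows sum to zero, so shape lives in the
  $(p-1)$-dimensional subspace orthogonal to the isometric direction, and
  is invariant both to specimen size and (up to a column shift that cancels
  in all contrasts) to the measurement unit of any single variable.

Natural logs are used throughout; spectrum *differences* are base-invariant
up to a common scale, and the natural log matches the method's standard
formulation.

**Shape PCA** (`shape_pca()`) eigendecomposes the sample covariance
(divisor $n-1$) of the clr matrix. The covariance — not correlation —
matrix is deliberate: the clr transform already renders variables
commensurable, and rescaling to unit variance would distort the ratio
geometry. At most $p-1$ eigenvalues are nonzero; retained eigenvectors are
re-projected onto the zero-sum subspace to remove numerical drift and
oriented so their largest-magnitude loading is positive.

**Ratio spectra.** The PCA Ratio Spectrum of component $k$ places each
variable at its loading; the variance of component $k$ explained by the
ratio $x_i/x_j$ grows with $|u_{ik}-u_{jk}|$, so the extreme pair is the
component's summary ratio (`ratio_importance()` ranks all pairs). The
Allometry Ratio Spectrum replaces loadings with OLS slopes of each clr
column on log isosize; slopes sum to zero by construction and vanish under
isometry. Whether to read the bootstrap off PC1 only or any component is
left open by the method's common usage, so `bootstrap_spectrum()` exposes
the component index.

**Bootstrap intervals.** Specimens are resampled with replacement;
replicate eigenvectors are sign-aligned to the point estimate by dot
product before percentile intervals are formed (without alignment the
arbitrary sign of an eigenvector would wreck the quantiles). Defaults are
999 replicates at 68% coverage, the convention for these spectra. Replicates
in which a variable (or log isosize, for the allometry spectrum) becomes
constant are degenerate: they are skipped and counted in the `n_skipped`
attribute. Percentile bounds are clamped to bracket the point estimate so
the interval invariant `ci_lo <= position <= ci_hi` holds even in heavily
skewed small-sample resamples.

**Size–shape correlation.** `size_shape_correlation()` reports Pearson's
$r$ between log isosize and component scores with the closed form
$t=r\sqrt{df/(1-r^2)}$, $df=n-2$. Published tables sometimes print $t$
computed from an unrounded $r$ alongside the rounded $r$; the package
treats the closed-form identity as the contract and tests it against R's
`cor.test()`.

## The LDA ratio extractor

For two groups $A,B$ (each with at least 3 specimens), every unordered
variable pair $(i,j)$ defines a log-ratio $r=\ln x_i-\ln x_j$ scored by the
**standard distance**

$$D_{ij}=\frac{|\bar r_A-\bar r_B|}{s_\text{pooled}},\qquad
s_\text{pooled}=\sqrt{\frac{(n_A-1)s_A^2+(n_B-1)s_B^2}{n_A+n_B-2}}.$$

The best ratio maximises $D_{ij}$ (ties broken lexicographically by pair
name). The second ratio should add independent information, so it is the
highest-$D$ pair whose pooled within-group correlation with the best
log-ratio is below 0.5 in absolute value. The 0.5 threshold is a package
choice — the method only asks for "as little correlated as possible" — and
is configurable; when no pair qualifies the least-correlated pair is
reported with `second_flagged = TRUE`.

Separation is decomposed into:

- $D_\text{size}$: the standard distance between the groups' log isosizes;
- $D_\text{shape}$: the Mahalanobis distance between group clr means under
  the pooled within-group clr covariance, pseudoinverted over directions
  with eigenvalue $>10^{-12}\lambda_\max$ (the clr covariance is rank
  deficient by construction, so a plain inverse does not exist);
- $\delta=D_\text{size}/(D_\text{size}+D_\text{shape})$, reported as `NA`
  when both components vanish (identical groups).

The decomposition is validated against a published worked case: components
0.295 and 0.92 give $\delta=0.243$ to three decimals. For reporting,
`mra_report()` rounds ranges, $D$ and $\delta$ to two decimals and flags a
ratio `key_suitable` when the two groups' ranges do not overlap, matching
the layout of identification-key comparison tables. Reported ratios are
oriented to match the conventional direction for the shell and genital
variable sets (e.g. `V/VA`, `AW/SH`); unknown pairs put the variable with
the larger group-A mean log on top.

```{r lda-example}
tbl <- simulate_measurements(variables = genital_vars, n_per_group = 30,
                             planted_pair = c("V", "VA"),
                             offset_sd_units = 3, seed = 42,
                             groups = c("CAR", "CLA"))
x <- lda_ratio_extractor(tbl)
x
mra_report(x)
```

## The molecular workflow

Loci arrive as pre-aligned FASTA (`read_alignment()`); sequences are
uppercased, length-validated, and restricted to `A C G T N -`. Alignment
ends are trimmed with 0-based half-open column intervals
(`trim_alignment()`); the exact trim coordinates are always study-specific
configuration, only the resulting lengths are contractual.

**Haplotypes.** `collapse_haplotypes()` uses exact string identity,
treating gaps and `N` as ordinary characters. This emulates straightforward
collapsing as done by alignment-transformation tools; an ambiguity-aware
collapser could merge an `N`-bearing sequence into a compatible haplotype
and would give different counts — a documented divergence risk.
`concatenate_loci()` joins loci in order for every specimen present in all
of them (missing specimens are dropped with a warning, or an error in
strict mode), and its ledger maps per-locus haplotype tuples to
concatenated haplotype labels; by construction the concatenated partition
refines every single-locus partition.

**Distances.** `k2p_pair()` implements the Kimura two-parameter estimator
$d=-\tfrac12\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$ with $P$ the transition and
$Q$ the transversion proportion over compared columns. Rates are assumed
uniform across sites (no gamma correction). Saturated pairs
($1-2P-Q\le 0$ or $1-2Q\le 0$) are returned as `NA` with a `saturated`
flag, excluded from summaries, and counted — they never silently propagate.
Complete deletion (the default, matching standard distance-table practice)
removes every column with a gap or `N` in any sequence before any pair is
compared; pairwise deletion is available by flag.
`group_distance_summary()` reports min–max (mean) percent distances within
and between groups; `format_distance_summary()` renders them at one decimal
as in published tables, while JSON/tibble output keeps full precision.

## What the simulators emulate

`simulate_measurements()` draws
$\ln x_{sv}=\mu_v+\beta_v s_s+\text{offsets}+\varepsilon_{sv}$ with latent
size $s\sim N(0,\sigma_\text{size}^2)$ and noise
$\varepsilon\sim N(0,\sigma_\text{noise}^2)$. Defaults: 30
specimens/group, the 7-variable shell set with realistic mm-scale means,
$\beta=1$ (isometry), $\sigma_\text{size}=0.1$,
$\sigma_\text{noise}=0.05$. A planted *shape* contrast adds
$\pm\delta/2$ to the two variables of a chosen pair in group B with
$\delta$ expressed in pooled log-ratio sd units
($\text{sd} = \sqrt2\,\sigma_\text{noise}$); the opposite signs leave
isosize untouched, which makes $\delta$-recovery checks clean. A planted
*size* contrast shifts all log variables of group B equally. For the
pure-size regime checks the package uses a log-size offset of 0.5 — five
latent-size standard deviations, an unambiguous size effect — chosen once
as a realistic "clearly larger taxon" scenario.

`simulate_sequences()` is calibrated in expected K2P distance rather than
explicit rates and times: clade founders diverge from a random ancestor by
$(d_\text{between}-d_\text{within})/2$ expected substitutions/site each and
tips from their founder by $d_\text{within}/2$, so expected pairwise
distances are exactly the configured targets (defaults 0.005 within, 0.19
between — the regime of congeneric mitochondrial divergence). Sites evolve
independently under the two-parameter process with transition/transversion
rate ratio $\kappa$ (default 2) using its closed-form substitution
probabilities. No indels are simulated; a `gap_prob` knob plants gap
columns to exercise deletion masks, and `shared_haplotype_prob` lets
specimens copy an existing clade haplotype.

What passing tests on these simulations do **not** show: real measurement
error is not log-normal-homoscedastic across variables, real populations
are not two clean groups with a single planted contrast, and real
mitochondrial data carry rate heterogeneity, saturation and occasional
introgression that the star-shaped generator deliberately omits. The
simulators validate the machinery, not the biology.

## Numerical choices and degenerate inputs

- Non-positive or missing measurements are rejected naming the offending
  cell; groups need $\ge 3$ specimens, PCA $\ge 3$, allometry $\ge 4$ with
  nonconstant isosize.
- Eigenvalue cutoff for the shape-Mahalanobis pseudoinverse:
  $10^{-12}\lambda_\max$.
- Zero pooled sd with differing means yields $D=\infty$ rather than an
  error; identical groups yield $D=0$ and $\delta=$ `NA`.
- Bootstrap and both simulators consume a single integer seed; equal seeds
  give bit-identical output, and `run_mra()` writes timestamp-free reports
  so identical configurations produce byte-identical files.
- Distance summaries use exact `-0`-free zeros; K2P at the saturation
  boundary ($1-2P-Q=0$) is already flagged saturated.

Problem sizes used by the shipped test-suite experiments — 100 seeded runs
at 30 specimens/group for planted-pair recovery, 40 seeded replicates of
10-per-clade 615-column alignments for divergence calibration, 100 random
instances for the brute-force equivalence check — were chosen as the
smallest designs whose Monte-Carlo error is far below the effects being
verified.

## Known limitations

- Exactly two groups per discriminant comparison; multi-group discriminant
  analysis is out of scope.
- No geometric (landmark) morphometrics — linear measurements only.
- No de novo alignment, tree inference or substitution-model selection;
  inputs must be pre-aligned and pre-oriented.
- Haplotype identity is exact string matching (no IUPAC subsumption).
- K2P assumes uniform rates across sites.
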