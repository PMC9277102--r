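---
title: "Mitonuclear discordance and mtDNA gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitonuclear discordance and mtDNA gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonuclear)
```

## The scientific question

Mitochondrial function depends on protein complexes assembled from both
mtDNA-encoded and nuclear-encoded subunits. In a recently admixed population,
an individual's mtDNA haplogroup can descend from one ancestral population
while much of their nuclear genome descends from another. **Mitonuclear
discordance** quantifies this mismatch per individual: the fraction of global
nuclear ancestry that does not match the continental origin of the mtDNA.
If mismatched subunits interact suboptimally, higher discordance should
depress the expression (or the downstream function) of mtDNA-encoded genes,
and selection since admixture should favor the mtDNA-matching ancestry at
nuclear loci encoding mitochondrial proteins. This package implements the
statistics needed to test these hypotheses in cohorts with genotype,
RNA-seq, and local-ancestry data, plus a synthetic cohort generator so the
whole pipeline can be exercised and validated without protected data.

## The discordance statistic

For a two-way (K = 2) admixture model with ancestry fractions
$a$ (African) and $e = 1 - a$ (European):

$$
D =
\begin{cases}
e = 1 - a, & \text{mtDNA of African origin (major haplogroup L)}\\
a, & \text{mtDNA of European/Eurasian origin (H, I, J, K, T, U, V, W, X)}
\end{cases}
$$

The self-reported population label never enters the formula: the apparent
four cases (admixed/reference population × African/European mtDNA) collapse
to "the fraction not matching the mtDNA side". Carriers of haplogroups
outside the two-way model (A, B, C — Native American; M, N, R, F, Z — Asian)
are excluded, mirroring how such samples are removed in practice.

Two conventions are deliberately fixed and documented rather than
configurable:

* **Major haplogroup = first alphabetic character** of the label. All
  designations in the two-way model are single letters; sub-haplogroup
  suffixes carry no additional continental information here. Two-letter
  clades such as `HV` resolve by their first letter and are counted in a
  log message.
* **K > 2 Q tables**: the non-African/non-European remainder must stay below
  a tolerance (default 0.05) or the sample is rejected; retained samples use
  $e = 1 - a$, matching the subtract-from-100% definition of the European
  component.

## Covariate-adjusted expression

Expression is TPM (transcripts per million), modeled directly — no log
transform, no shrinkage: for each gene and tissue an ordinary
least-squares fit

$$\mathrm{TPM} = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{ischemic\ time} + \varepsilon$$

with age in years and ischemic time in minutes; the residuals are the
"adjusted expression" used everywhere downstream. Samples with a missing
covariate are dropped (never imputed) and listed; a covariate that is
constant across the retained samples is dropped from the design with a
warning; all-zero genes are skipped. Residuals are exactly orthogonal to the
design, which the tests assert at 1e-6 in correlation units.

Candidate covariates are screened with a plain Pearson correlation
(`screen_covariate()`); sex differences are checked with Mood's median test,
implemented as the closed-form 2×2 Pearson chi-square on the
above/not-above-pooled-median table, **without** continuity correction and
with values equal to the pooled median counted as "not above" — a fixed
convention, since the dichotomization of boundary values is otherwise
ambiguous. mtDNA copy number is accepted as an optional covariate column but
stays out of the default design.

The analysis gene set is the 13 mtDNA protein-coding genes minus ND5 and
ND6 (non-strand-specific, poly(A)-selected RNA-seq cannot quantify them
reliably), leaving 11 genes; **11 is therefore the Bonferroni family size**,
applied within tissue and never across tissues. `merge_bicistronic()`
optionally (default off) collapses ATP8/ATP6 and ND4L/ND4 into TPM sums as
an approximation of re-quantifying the shared bicistronic transcripts from
raw reads.

## The three association analyses

All three are one-sided toward the same alternative: lower expression with
higher discordance.

1. **Mann–Whitney U with common-language effect size.** The low-discordance
   population is tested as stochastically greater. Ties are mid-ranked; the
   effect size is $\mathrm{CLES} = U / (n_1 n_2)$ with tied pairs counted
   half, i.e. the probability that a random low-discordance sample exceeds a
   random high-discordance sample. For groups of at most 8 each, the p-value
   is computed by exhaustive enumeration of all label assignments (exact
   under ties, and testable against a brute-force pair-counting oracle);
   above that, by the tie-corrected normal approximation with a 0.5
   continuity correction, matching the behavior of the standard library
   implementations practitioners use.
2. **Permutation test.** Samples are split at the *mean* discordance of the
   tissue; samples exactly at the cutoff go to the low group (the
   high group is "strictly above the mean" — the boundary case must be fixed
   somewhere, and this choice is asserted in tests). The observed statistic
   is mean(low) − mean(high), so the hypothesized effect is positive; labels
   are permuted preserving group sizes, and
   $p = \#\{\text{permuted diff} > \text{observed}\} / n_{\mathrm{perm}}$
   with $n_{\mathrm{perm}} = 1000$ by default. This literal count-above
   formula can return 0; `midp = TRUE` gives the safer
   $(1 + \#\{\ge\}) / (1 + n_{\mathrm{perm}})$ variant. Permutations are
   seeded and exactly reproducible.
3. **Spearman rank correlation**, chosen because discordance is far from
   normally distributed. $\rho$ is the Pearson correlation of mid-ranks, and
   the one-sided p-value for $\rho < 0$ uses the t approximation on the rank
   correlation (the same approximation `cor.test()` uses in the presence of
   ties, which the tests cross-check).

## Local-ancestry enrichment

Nuclear genes are classified `high_mt` (high-confidence mitochondrial:
OXPHOS subunits, mtDNA replication/transcription machinery; 167 genes at
full scale), `low_mt` (other mitochondrially imported proteins; 793) and
`non_mt` (everything else; 17,456). For each gene, local ancestry is
averaged over a 5-Mb window **centered on the gene midpoint** (the window
anchoring is not otherwise determined; midpoint-centering is the symmetric
choice), clamped to chromosome bounds, length-weighted over both haplotypes
and averaged over samples. The unweighted block bootstrap then resamples
whole genes with replacement — the gene, averaged over samples, is the
block — `n_resample` times per replicate, with `n_resample` matched to the
smallest category (167 at full scale), and records the deviation of the
resampled category mean from the global ancestry mean; the empirical 95% CI
is the 2.5/97.5 percentile over `n_replicates` replicates (default 10,000,
a package choice for stable percentiles — the value is not fixed by the
method). Categories are compared with a classical pooled-variance t-test on
the replicate arrays; because replicates are cheap, the p-value scales with
the replicate count, so the replicate count is carried in the output and
the caveat is documented.

**Baseline choice (a genuinely open design point).** The "global ancestry
mean" could be the cohort mean of ADMIXTURE-style Q-table fractions or of
the global fractions recomputed from the local-ancestry segments themselves
(`global_from_local()`). The package defaults to the **local-ancestry-derived
mean**: category deviations are then measured against the very estimates
they aggregate, so any systematic offset between the two estimators — and,
in simulation, the finite-genome sampling noise between a sample's ancestry
*parameter* and its *realized* tract dosage — cancels out of every category
equally instead of biasing all deviations by a shared constant. The Q-table
baseline remains available (`baseline = "q_table"`). The two estimators are
expected to be nearly identical in real data, which is exactly what the QC
correlation check (`global_from_local()` vs the Q table, r > 0.99) asserts.

## The synthetic cohort generator

The generator produces the five artifacts the pipeline consumes, with the
statistical structure the analyses assume. Defaults are chosen once to
describe a realistic admixed cohort and are not tuned afterwards:

| Parameter | Default | Unit / rationale |
|---|---|---|
| `n_aa`, `n_ea` | 101, 688 | genotyped sample counts of the emulated cohort |
| `aa_african_mean` | 0.77 | AA mean African fraction (reported range 73–82%) |
| `aa_african_concentration` | 3.2 | Beta concentration; gives Var ≈ 0.042 for the within-haplogroup discordance spread |
| `ea_african_mean` | 0.01 | EA African fraction near zero |
| `haplogroup_freqs` | observed AA/EA tables | e.g. 88/101 L in AA, 347/688 H in EA |
| `admixture_generations` | 6 | approximate age of the admixture event |
| `chromosome_lengths` | 22 autosomes | approximate GRCh38 bp and sex-averaged Morgans |
| `beta_age`, `beta_ischemic` | 2, −0.3 | TPM per year, TPM per minute |
| `beta_discordance` | −10 | TPM per unit discordance |
| `noise_sd` | 20 | TPM |
| `intercept_range` | 2000–10000 | TPM; mtDNA genes are among the most highly expressed |
| age, ischemic time | U(20, 70) yr, U(60, 1440) min | continuous age (the regression treats age numerically) |

Stage-specific draws derive from one master seed, so a fixed seed
reproduces the cohort bit-for-bit; `truth` records the generating
parameters and each sample's true discordance, computed with the same
operations the analysis uses, so the round trip is exact by construction.

Local tracts use a **Poisson-breakpoint / Bernoulli-ancestry
approximation**, not a coalescent: per haplotype and chromosome the
breakpoint count is Poisson(generations × Morgans) with positions uniform
along the physical chromosome (a flat recombination map), and each tract is
independently African with probability equal to the sample's global African
fraction. This matches the first moments the enrichment test depends on
(expected dosage = global fraction; tract scale ≈ 1/(g·100 cM)) at trivial
cost. TPM values are floored at 0 after noise (TPM is nonnegative by
definition) and the floor count is logged.

The **enrichment injection** (`enrichment_shift`) raises the African tract
probability *inside* the merged high-mt windows by the shift, splitting
tracts at window boundaries. Raising whole overlapping tracts instead would
smear the signal over tract-length (>10 Mb) neighborhoods covering a large
share of the genome, and the injected magnitude would no longer equal the
window-level dosage shift the estimator is supposed to recover; confining
it to the windows keeps "inject +0.05, recover +0.05" a well-posed check.
Even so, the windows themselves enter the global baseline, so the
recoverable deviation is attenuated by the fraction of the genome covered by
high-mt windows. At full scale (167 windows × 5 Mb on a ~2.9-Gb genome,
~25% coverage) *no* whole-genome baseline could return the injected value —
which is why the recovery experiments below use a sparse toy annotation.

### What the generator does not emulate

Realized haplogroup–ancestry correlation (in real admixed cohorts,
European-haplogroup carriers tend to have higher European nuclear ancestry;
the generator draws the two independently, so the marginal discordance
spread is somewhat wider than the within-haplogroup Beta variance);
coalescent tract-length correlations and recombination hotspots; genotype
or phasing error in local-ancestry calls; library-preparation artifacts,
count overdispersion and the mean–variance relation of real RNA-seq;
sex chromosomes. Passing tests therefore validate the *statistics* under
their stated assumptions, not the biology of any particular dataset.

## Validation experiments shipped with the package

The test suite ties every statistic to an independent oracle (exhaustive
pair counting and enumeration, normal-equation solves, closed-form 2×2
chi-square, rank-then-Pearson, `wilcox.test`/`cor.test` cross-checks) and
runs four simulation experiments, with problem sizes chosen to keep the
default suite inside a half-minute while leaving Monte-Carlo error well
below the asserted margins:

* **Null calibration**: 500 cohorts of n = 200 with `beta_discordance = 0`;
  the permutation test's rejection rate at α = 0.05 must sit inside the
  binomial 99% band around 0.05.
* **Effect recovery**: 500 cohorts of n = 600 with `beta_discordance = −10`,
  `noise_sd = 20`; the OLS slope of adjusted expression on discordance must
  cover the truth within 2 SE in ≥ 93% of replicates.
* **Enrichment recovery**: 20 cohorts of 100 admixed samples on 22 uniform
  100-Mb / 1.1-Morgan toy chromosomes with a sparse annotation
  (20/40/200 genes per category, so high-mt windows cover ~4.5% of the toy
  genome) and a +0.05 injected shift; the high-mt mean deviation must
  average within 0.01 of +0.05 with its 95% CI excluding 0 in ≥ 90% of
  experiments, while the non-mt CI contains 0 in ≥ 90%.
* **Estimator consistency**: on a default-scale cohort,
  `global_from_local()` vs the simulated Q table must correlate at r > 0.99,
  and adjusted expression must be orthogonal to both covariates at 1e-6.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; BED is read natively and the
  MSP dialect (1-based inclusive) is converted at the read/write boundary.
  MSP rows are shared intervals, so the format cannot represent a breakpoint
  without an ancestry change: the reader returns the canonical merged form.
* Percentile CIs use R's default quantile definition (type 7).
* Degenerate cases are defined, not errors: constant expression in the
  permutation test yields p = 0 under the literal strict-`>` rule and is
  flagged; identical pooled values in Mood's test give p = 1; zero rank
  variance makes Spearman's rho (and a zero-variance Pearson screen)
  undefined and reported as `NA`; a single-observation group makes the
  discordance variance `NA`.
* Known limitations: the bootstrap t-test p-value depends on the replicate
  count (reported alongside); the MSP writer disaggregates segments onto the
  union of breakpoints, which scales with samples × breakpoints and is meant
  for moderate cohort sizes; Bonferroni is the only multiplicity control
  offered, by design.
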