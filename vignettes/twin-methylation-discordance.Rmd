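---
title: "Paired methylation discordance analysis in monozygotic twins: models and methods"
author: "twindiff package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired methylation discordance analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindiff)
```

## The design and its statistical model

Monozygotic co-twins discordant for type 2 diabetes share their genome, so
any within-pair difference in promoter DNA methylation is, by construction,
non-genetic. The natural analysis is therefore fully paired: for probe $j$
and pair $p$ the quantity of interest is the intra-pair difference

$$d_{jp} = 100\,(\beta_{j,p,\mathrm{T2D}} - \beta_{j,p,\mathrm{nonT2D}})$$

in percentage points, where $\beta \in [0,1]$ is the array methylation
fraction. Per probe, a one-sample $t$-test of $d_{j\cdot}$ against zero
($t_j = \bar d_j \sqrt{n}/s_{d_j}$, two-sided, $n-1$ df) tests for
disease-associated methylation. Pairing removes both the genetic and --
when co-twins are hybridised on the same chip -- the batch component of
variance, which is what makes effects of a few percentage points
addressable at all with $n \le 12$ pairs.

Missing cells (detection-filtered measurements) are handled by
complete-pair analysis per probe: a pair contributes to probe $j$ only if
both co-twins are measured there (`completePairs`, `pairedDifferences`).
How the original analysis handled such cells is not documented; per-probe
complete-pair analysis is the standard choice and is applied uniformly.

## Family-wise error control: step-down maxT with sign flips

With 26,850 probes, raw $P$-values need family-wise control, but probes in
the same promoter are strongly correlated, which Bonferroni ignores. The
package implements the Westfall–Young step-down maxT resampling procedure
(`westfallYoungMaxT`):

1. Under the paired null, the only exchangeable operation is swapping the
   co-twin labels within a pair -- equivalently flipping the sign of
   $d_{\cdot p}$. One flip vector $s \in \{-1,+1\}^n$ is applied **jointly
   to all probes**, preserving the inter-probe correlation in the null
   distribution.
2. Probes are ordered by decreasing $|t|$; for each flip the statistics are
   recomputed and successive maxima taken from the least significant probe
   upward; the adjusted $P$ of rank $r$ is the fraction of flips whose
   successive maximum reaches the observed $|t_{(r)}|$, followed by
   monotonicity enforcement down the ordering.
3. For $n \le 12$ pairs all $2^n$ flip vectors are enumerated (the identity
   included), giving exact permutation proportions with floor $2^{-n}$; for
   larger $n$, $B$ flips are sampled and the positively biased estimator
   $(b+1)/(B+1)$ avoids zero $P$-values. The study-scale configuration
   (10,000 sampled flips) and the exhaustive mode agree within binomial
   Monte-Carlo error, which the test suite asserts against a brute-force
   enumeration oracle written with `t.test`.

The step-down variant (rather than single-step) is used as the canonical
choice for nearly continuous statistics; whether the original analysis was
single-step is not recoverable, and the marginal sign-flip $P$ (`p_perm`)
is reported alongside so either convention can be reconstructed. Probes
with incomplete pairs stay in the family by default, each using its own
complete pairs under every flip; the conservative alternative (dropping
them) is available via `incomplete = "drop"`. Raw $P$-values are
parametric ($t$ distribution), matching how the candidate and explorative
analyses were run.

## Power: exact noncentral-t minimal detectable differences

`minDetectableDifference` solves, by bracketed bisection to $10^{-6}$, for
the smallest $\delta$ with

$$\Pr\!\left(|T_{n-1}(\mathrm{ncp} = \delta\sqrt{n}/s)| >
t_{n-1,1-\alpha'/2}\right) = 0.80, \qquad \alpha' = \alpha/m ,$$

using the exact noncentral $t$ distribution. The exactness matters: with
$n = 5$ pairs and $m = 26{,}850$ Bonferroni tests the solution sits at
$\delta \approx 117$ percentage points ($\mathrm{ncp} \approx 52$), far
outside any normal approximation's validity. Results are reported both
unrounded and rounded to whole points (the conventional reporting); for
the two large-$\delta$, 4-df settings a $\pm$1-point numerical tolerance
is documented since printed values at that scale depend on the tail
internals of the original software. `simulatePower` provides the
independent Monte-Carlo route; the suite asserts the round trip at every
tabulated design.

One subtlety: "a 5-point difference detectable at 80% power with 11 pairs,
SD 5" refers to the *rounded* solution ($\delta = 4.69$); the exact power
at $\delta = 5$ is 0.847. The simulation-based checks are therefore
anchored to the exact noncentral-t curve, not to the rounded 80%.

## The synthetic twin-methylome generator

The generator (`generateTwinBeta`) defines the study conditions for every
stochastic test and is deliberately simple and fully inspectable:

- **Bimodal baselines.** Each probe draws a mixture component
  (weights 0.64/0.23/0.13 for muscle, 0.65/0.20/0.15 for adipose) and a
  baseline from a truncated Beta: low $\mathrm{Beta}(1.5, 15)$ on
  $[0, 0.22]$, mid $\mathrm{Beta}(5, 5)$ on $[0.28, 0.72]$, high
  $\mathrm{Beta}(15, 1.5)$ on $[0.78, 1]$. The truncation margins keep
  probe means clear of the 0.25/0.75 classification thresholds, so the
  tail fractions reproduce the weights; only the two tail fractions are
  empirically constrained, making the mid component a free modelling
  choice.
- **Co-twin similarity by construction.** Co-twins share
  $\text{baseline} + \mathcal N(0, \sigma_{\text{pair}}^2)$
  ($\sigma_{\text{pair}} = 0.02$) before independent individual noise
  $\mathcal N(0, \sigma_{\text{ind}}^2)$ is added and the value truncated
  to $[0,1]$. No correlation parameter is fitted; the within-pair Pearson
  $r$ emerges as
  $(\mathrm{Var_{base}} + \sigma_{\text{pair}}^2) /
   (\mathrm{Var_{base}} + \sigma_{\text{pair}}^2 + \sigma_{\text{ind}}^2)$.
  $\sigma_{\text{ind}}$ was calibrated once against the target mean
  within-pair $r$ (0.95 muscle at $\sigma_{\text{ind}} = 0.078$, 0.97
  adipose at 0.060) and frozen.
- **A known inconsistency, resolved explicitly.** A within-pair $r$ of
  0.95 under this mixture implies an intra-pair difference SD of
  ~11 points, i.e. a pooled SD of absolute promoter differences of
  ~6.6 points rather than the 4 points real promoter data show. The two
  published summaries cannot be met simultaneously under a
  single-noise-scale model (real data concentrate their variance in fewer,
  noisier probes); the calibration pins $r$ and the tail fractions, and
  the repeats-exceed-promoters ordering is preserved. Tests that assume a
  5-point difference SD (the power analyses' assumption) set
  $\sigma_{\text{ind}} = 0.05/\sqrt 2$ explicitly.
- **Effects and truth.** Disease effects are injected additively on the
  T2D twin at named probes (percentage points / 100) before truncation,
  and all latents (baselines, components, pair shifts, effects) are
  returned as ground truth for parameter-recovery tests.
- **Noise on the beta scale.** Noise is added and truncated on the
  $\beta$ scale rather than logit-transformed -- a transparency-over-
  realism simplification. Consequences: mild shrinkage of variance near 0
  and 1, slightly non-normal differences at extreme probes (visible as a
  Shapiro–Wilk rejection fraction a little above nominal), and a small
  truncation bias for effects placed at extreme baselines.

Phenotypes (`generatePhenotypes`) use a shared-pair-component model per
trait; BMI and HbA1c group means/SDs follow the published subject
characteristics, while 2-hour glucose (9.3 ± 1.9 vs 15.0 ± 3.5 mmol/l) and
clamp GIR (6.0 ± 2.0 vs 3.5 ± 1.5 mg/kg/min) are realistic defaults chosen
once for an elderly IGT-vs-T2D contrast, since group values for them are
not tabulated.

The repeat panel (`generateRepeatPanel`) draws, per pair, a latent
intra-pair difference scale for LINE1 of
$\text{base} + c\,|\Delta \mathrm{BMI}| + \mathcal N(0, \sigma)$ (defaults
10, 2 per kg/m², 3 points; D4Z4/NBL2 uncoupled at base 12), then gives
each twin independent site deviations of SD $\text{scale}/\sqrt 2$. With 8
sites per element the per-pair SD of $|d|$ estimates $0.60\times$ the
scale noisily, which attenuates the variation–phenotype correlation; the
corresponding test therefore compares against a Monte-Carlo oracle of the
same latent model rather than a closed form. Defaults give pooled repeat
variation of ~9–10 points against ~6.6 for promoters and a LINE1–BMI
correlation of ~0.7–0.8 at $n = 11$ pairs.

Clone tables (`generateCloneTable`) are per-site binomial draws with 12
clones, matching colony-counting practice.

**What passing tests do and do not show.** The generator reproduces the
*structure* the analysis assumes (bimodality, pairing, small effects,
repeat-element excess variation, binomial validation sampling), so green
tests certify the machinery, calibration and error control. They do not
certify real-data effect sizes, probe-specific biology, cell-type
composition effects, or array measurement error at extreme betas -- all of
which require the deposited cohort data.

## Quality control

The probe filter mirrors array-practice probe vetting at desk scale:
references are bisulfite-converted per strand (forward C→T, reverse G→A;
`bisulfiteConvert`, idempotent per strand), probes are scanned against
both converted strands with a mismatch budget (default 0;
`countAlignments`, backed by `Biostrings::countPattern` and verified
against a quadratic scan oracle), and uniqueness means exactly one hit
across both strands. Gapped BLAT-style hits are out of scope -- the
criterion being replaced is uniqueness, not alignment score -- and the
mismatch budget is a configuration knob since the original tolerance is
unstated. Exclusion order is multi-alignment first, then SNP-in-CpG among
the remainder (the sequential phrasing of the source counts), and the
`QcReport` validity asserts the partition on every run. Detection-P
masking is inclusive at the boundary (mask at $P = 0.05$).

## Global patterns: choices on ambiguous points

- Correlations are Pearson throughout (reported $r$ values name no
  method); Spearman is available behind a flag.
- The pooled ANOVA uses sequential (type I) sums of squares in the order
  pair, status, pair × status -- the order the factors are listed when the
  analysis is described. On data with probe-level baselines the pooled
  pair test is conservative (probe variance sits in the residual); the
  calibration test therefore uses exchangeable data, and the
  pair-similarity signal on structured data is exercised by a degenerate
  construction instead.
- The variation statistic is the SD of absolute intra-pair differences.
  Per-pair scope (SD across a probe set within a pair) feeds the
  variation-versus-phenotype correlations; pooled scope (SD across pairs
  and probes jointly) feeds the repeats-versus-promoters comparison. Both
  are emitted, since the published headline admits either reading. The
  significance of the repeats-vs-promoters contrast is reported as a
  variance-ratio F-test and labelled an interpretation, the original test
  being unstated.

## Enrichment and validation

Gene-set enrichment is a one-sided Fisher exact test (over-representation)
on the 2×2 table restricted to array-represented background genes; a gene
counts as differentially methylated when at least one of its probes has
raw $P < 0.05$. Whether the original pathway software tested one- or
two-sided is not recoverable; one-sided is the pathway-analysis
convention. P-values are intentionally unadjusted, mirroring exploratory
pathway scanning, and the output says so. Validation tests are one-sided
paired t-tests in the direction the array reported (a replication, not a
discovery, hypothesis), and clone summaries average sites without weights.

## Numerical and scale choices

Problem sizes in tests and the acceptance script are chosen for a
single-CPU desk run: 2,000-probe × 11-pair cohorts (exhaustive 2,048
flips, ~0.3 s per maxT call), 200-replicate error-rate studies, 20-seed
calibration averages, 10,000-replicate power simulations. The maxT engine
is vectorised (one matrix product per flip block) and processes
permutations in blocks of 1,024 to bound memory at genome scale; the
full 26,850-probe family runs in minutes. Ties in $|t|$ need no special
handling beyond `cummax` monotonicity enforcement; zero-variance
difference vectors yield $t = 0$ (all-zero) or an explicit degenerate
error (constant nonzero). Seeds are explicit arguments everywhere;
identical seeds give byte-identical outputs, asserted in the pipeline
tests.

## Known limitations

- Beta-scale truncated noise is a simplification; logit-normal noise
  would better match array error structure near the boundaries.
- The generator cannot simultaneously reproduce the published within-pair
  correlation and the promoter difference SD (see above); it pins the
  former.
- The aligner is ungapped and exact/near-exact by design; it is not a
  BLAT re-implementation.
- Real-cohort effect sizes, specific genes and figure-level $r$ values are
  out of reach without the deposited data; nothing in the package claims
  them.
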