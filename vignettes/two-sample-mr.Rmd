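---
title: "Two-sample Mendelian randomization with twosmr: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with twosmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The causal model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome from
observational data. A variant $Z_j$ qualifies as an instrument under three
assumptions: it is robustly associated with the exposure $X$ (relevance),
it is independent of confounders of the exposure-outcome relation
(independence), and it affects the outcome $Y$ only through $X$ (exclusion
restriction). In the two-sample design the variant-exposure associations
$(\hat\beta_{Xj}, \sigma_{Xj})$ and variant-outcome associations
$(\hat\beta_{Yj}, \sigma_{Yj})$ come from two non-overlapping GWAS, which
improves power and avoids winner's-curse correlation between the two
sides. For binary traits both sides are per-allele log-odds ratios.

Each valid instrument identifies the causal effect through its Wald ratio
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$, with first-order standard
error $\sigma_{Yj} / |\hat\beta_{Xj}|$. All estimators in this package
operate on these summary quantities only; no individual-level data are
touched.

# From raw summary statistics to an instrument set

`read_summary_table()` binds a delimited file through a user-supplied
column map and enforces the row invariants (valid allele letters, positive
standard errors, p-values in $(0,1]$, frequencies strictly inside $(0,1)$),
rejecting offending rows with named diagnostics rather than silently
coercing them.

`harmonize()` expresses both studies' effects on the same effect allele.
Non-palindromic variants are aligned by allele identity, allele swap, or
their strand complements; a swap negates $\hat\beta_{Yj}$ and reflects the
outcome frequency. Palindromic variants (A/T, C/G) carry no strand
information in their allele letters, so they are aligned by which side of
0.5 the two allele frequencies fall on — and dropped whenever either
frequency is missing or lies within a window of $\pm 0.08$ of 0.5 (i.e. in
$[0.42, 0.58]$), where sampling noise makes frequency alignment
unreliable. The window is configurable; 0.08 is the half-width commonly
used for this purpose in summary-statistics pipelines. Duplicate variant
IDs are a hard error: silent deduplication corrupts instrument counts.

Instrument selection then proceeds in the conventional order:

* exposure genome-wide significance, $p < 5\times10^{-8}$ (strict
  inequality);
* LD clumping against a user-supplied r² matrix: greedy by ascending
  p-value, keeping a variant only if its r² with every kept variant on the
  same chromosome within 10,000 kb is below 0.001. Ties on p break by
  genomic position, then variant ID, so the result is deterministic. The
  LD panel is an input, not a download — computing r² from a reference
  panel such as 1000 Genomes is outside this package's scope;
* exclusion of variants associated with the outcome at
  $p < 5\times10^{-8}$, which may act on the outcome directly;
* the weak-instrument gate $F > 10$, with $F_j =
  (\hat\beta_{Xj}/\sigma_{Xj})^2$. This squared z-score form is
  self-consistent with the rest of the pipeline: a variant sitting exactly
  at the $5\times10^{-8}$ significance gate has $F = \Phi^{-1}(1 -
  2.5\times10^{-8})^2 \approx 29.7$, so genome-wide-significant
  instruments essentially never trip the $F > 10$ gate.

The per-variant variance explained is recovered from $F$ as $r^2_j = F_j /
(F_j + n - 2)$ and summed over the (independent, post-clumping)
instruments. Every stage logs its input and output counts; the counts are
non-increasing by construction.

# Estimators

Three estimators with complementary validity conditions are computed from
the same instrument set, mirroring standard practice.

**IVW.** The inverse-variance-weighted estimate is the weighted mean of
Wald ratios with weights $w_j = \hat\beta_{Xj}^2 / \sigma_{Yj}^2$,
equivalently a zero-intercept weighted regression of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$. It is efficient when every instrument is valid. The
default multiplicative random-effects model inflates the fixed-effects
standard error $(\sum_j w_j)^{-1/2}$ by $\max\{1, \sqrt{Q/(J-1)}\}$, which
leaves the point estimate unchanged and never reports a smaller standard
error than the fixed model; p-values use the normal distribution. The
first-order weights ignore exposure-side uncertainty; with instruments
gated at $F > 10$ (and in practice $F \ge 30$) the neglected term is
below one part in $F$ of the retained variance.

**Weighted median.** The median of the Wald-ratio distribution under
normalized IVW weights, interpolated at cumulative weight $1/2$ (each
ratio's cumulative weight taken at the centre of its mass). It remains
consistent when up to half of the total weight comes from invalid
instruments. The point estimate is deterministic; its standard error comes
from a parametric bootstrap (effects resampled from normal distributions
with their reported standard errors, 1000 replicates by default), so a
seed is mandatory. Instruments are sorted canonically and oriented to
non-negative exposure effects before bootstrapping, making both the
estimate and its SE invariant to row order and allele flips.

**MR-Egger.** A weighted regression of outcome on exposure effects *with*
an intercept, after orienting all exposure effects non-negative. Under the
InSIDE condition (pleiotropic effects independent of instrument strength)
the slope is a pleiotropy-robust causal estimate and the intercept
estimates the average directional pleiotropic effect per variant; an
intercept significantly away from zero is evidence of directional
pleiotropy. Standard errors carry the same multiplicative overdispersion
floor as IVW, with $J - 2$ residual degrees of freedom, and p-values use
the t distribution — the convention for this estimator, since its slope is
far less precise than IVW's.

Results are reported as log-odds `beta`/`se` plus OR and a 95% CI computed
with the fixed multiplier 1.96; ORs are kept at full precision and rounded
only at presentation. No multiplicity adjustment is applied across the
three estimators (they address the same null from different validity
assumptions); the run summary states this.

# Sensitivity diagnostics

**Heterogeneity.** Cochran's $Q = \sum_j w_j (\hat\theta_j -
\hat\beta_{\mathrm{IVW}})^2$ against $\chi^2_{J-1}$, and $I^2 = \max\{0,
(Q - \mathrm{df})/Q\} \times 100$ banded at the conventional cut-points —
below 25 low, 25–75 moderate (boundary values inclusive), above 75 high.
$I^2$ is reported to two decimals, and $Q$, df, and p are always reported
in full rather than as an inequality.

**Outlier detection.** `mr_presso()` implements a simulation-based
residual test. Each variant's residual is taken against the IVW slope
fitted *without* it; the observed weighted residual sum of squares is
compared with its null distribution from parametric simulation (outcome
effects redrawn around the leave-one-out predictions with their standard
errors, the statistic recomputed identically — leave-one-out fits
included). Per-variant outlier calls use each variant's simulated residual
distribution with Bonferroni correction at $\alpha = 0.05$; when outliers
are found, the estimate is recomputed without them and a distortion test
compares the change to that of removing equally many random variants.
Monte-Carlo p-values use the $(1+k)/(1+n_{\mathrm{sim}})$ estimator so a
reported p is never exactly zero. With 1000 simulations the granularity of
the global p is about $10^{-3}$.

**Influence.** `leave_one_out()` re-estimates the random-effects IVW
effect $J$ times, flagging any exclusion that changes the sign of the
estimate or moves its p-value across 0.05. Although the analysis is only
informative from three instruments upward, the function accepts $J = 2$
(each row then degenerates to the other variant's Wald ratio) with a
warning. `funnel_data()` pairs each Wald ratio with its precision; under
balanced pleiotropy the scatter is symmetric about the pooled estimate.

# Power

`mr_power_binary()` evaluates the standard non-centrality approximation
for a binary outcome: with $b = \ln \mathrm{OR}$, outcome sample size $n$,
case fraction $K$, and instrument variance explained $r^2_{XZ}$, the
expected z-score is $b\sqrt{n\, r^2_{XZ}\, K(1-K)}$ and power follows from
the two-sided normal test at level $\alpha$. Exact identities — power
equals $\alpha$ at $\mathrm{OR} = 1$, symmetry in $\mathrm{OR}
\leftrightarrow 1/\mathrm{OR}$, monotonicity in $n$, $r^2_{XZ}$, and
$|\ln \mathrm{OR}|$ — are enforced by tests. At the dimensions of the
motivating application (outcome GWAS of 361,822 with 682 cases, $r^2 =
15.2\%$, $\mathrm{OR} = 1.21$) the formula gives about 49% power, notably
below the 57% reported by the original study's web-tool run; web-tool
inputs are under-specified in such reports, so the discrepancy is
documented rather than forced into agreement, and every input is exposed
so alternative conventions can be probed. Either value is far below the
80% convention — the analysis this package was validated against is
under-powered on the outcome side, which is exactly what the calculation
is for.

# The synthetic-data generator

`simulate_two_sample()` generates both summary tables directly at the
summary level — the level at which every estimator operates — rather than
via individual-level genotypes; this keeps a full study replicate under a
millisecond without changing what is being tested. Its defaults *are* the
study conditions the package is validated under: $J = 77$ instruments,
causal effect 0.19 on the log-odds scale, an exposure case-control GWAS of
58,284 (14,361 cases) and an outcome GWAS of 361,822 (682 cases),
effect-allele frequencies uniform on $[0.05, 0.95]$.

Per-variant standard errors follow the case-control log-odds
approximation $\sigma = (2p(1-p)\,n\,K(1-K))^{-1/2}$. Instrument strength
is drawn as a noncentrality $\lambda_j = \min\{1500,\; 30\,e^{E_j}\}$ with
$E_j \sim \mathrm{Exp}(1.35)$, giving a right-skewed $F$ spectrum with
floor 30, mean $\approx 116$, and a tail to 1500 — the strength profile of
a genome-wide-significant autoimmune instrument panel; the true exposure
effect is $b_j = \pm\sqrt{\lambda_j}\,\sigma_{Xj}$. Observed effects are
independent normal draws on both sides (non-overlapping samples), and
p-values are two-sided normal.

Pleiotropy is controlled by three switches. `none` sets all direct effects
to zero. `balanced` draws them from $N(0, \sigma_\alpha)$. `directional`
draws them from $N(\mu_\alpha, \sigma_\alpha)$ *in the exposure-increasing
allele frame* (the sign of $b_j$ maps them onto the arbitrary allele
labels) — without this frame convention, random allele orientation would
average directional pleiotropy away and no estimator could be probed with
it. `inside_violation = TRUE` makes the deterministic component
proportional to $|b_j|$, breaking InSIDE specifically. In the validation
suite the directional regime uses $\mu_\alpha = 0.05$, $\sigma_\alpha =
0.02$ and the balanced regime $\sigma_\alpha = 0.05$: magnitudes
comparable to the outcome-side standard errors (0.06–0.12 at these sample
sizes), i.e. individually invisible but collectively detectable — the
regime a pleiotropy diagnostic exists for.

A configurable fraction of variants (default 5%) receives palindromic
alleles, and the outcome table's orientation is randomly scrambled with
allele swaps and strand complements, so harmonization is exercised on
every run.

What the generator does **not** emulate: LD between instruments (they are
post-clumping by construction; clumping is tested separately on
block-diagonal LD fixtures with known answers), sample overlap, allele
frequency differences between the two studies, population stratification,
and winner's curse in the exposure effects. Passing the simulation suite
therefore validates the estimators and diagnostics under the stated
two-sample assumptions; it does not certify behavior under violations the
generator cannot produce.

# Validation scale and numerical choices

The packaged test-suite checks run at desk scale, chosen so the full suite
completes in well under two minutes: 1000 replicates for parameter
recovery ($|$mean $-$ 0.19$|$ within 3 Monte-Carlo SEs), CI coverage
(93–97%) and null type-I error (3.5–6.5%); 400 replicates per pleiotropy
regime for the Egger intercept comparisons; 200 replicate datasets for the
outlier test's null size; 100 random block-diagonal fixtures (with
exhaustive independent-subset enumeration on instances up to 12 variants)
for clumping; and 100 random instrument sets for the estimator-identity
oracles at $10^{-10}$ relative tolerance.

Degenerate inputs are handled explicitly: a single instrument degenerates
IVW to the Wald ratio with a warning; $\hat\beta_{Xj} = 0$ is a
degenerate-instrument error rather than an infinite ratio; $Q = 0$ yields
$I^2 = 0$; empty selection stages abort the pipeline naming the stage that
emptied the set. Every stochastic routine (weighted-median bootstrap,
outlier simulation, generator) requires an explicit integer seed and
restores the caller's RNG state, and results are invariant to instrument
row order because inputs are canonically sorted internally.

# Reproducing a published analysis

Re-deriving a published instrument list from raw GWAS requires the
original summary files and an external LD reference panel, neither of
which ships with a desk-scale package. The supported route is the
pre-harmonized entry point: export the publication's instrument table
(typically a supplementary file) to the harmonized TSV layout and pass it
as `harmonized_path` — the selection stages are skipped and the estimator
and sensitivity stack runs unchanged. The pipeline test suite verifies
that this path reproduces the direct estimator calls exactly.

# Limitations

Beyond the generator's scope above: no proxy-SNP lookup for instruments
missing from the outcome study, no Steiger directionality filtering, no
mode-based or regularized estimators, no multivariable MR, and no
continuous-outcome power. Binary-trait effects are treated as per-unit
log-odds throughout; published reports sometimes label such effects "per
SD of exposure", which for a binary exposure has no direct SD
interpretation — the package reports per-unit effects and leaves any
rescaling to the caller.
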