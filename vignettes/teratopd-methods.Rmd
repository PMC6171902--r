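---
title: "Methods: quantal potency estimation and tumorigenicity screens"
author: "teratopd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantal potency estimation and tumorigenicity screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teratopd)
options(teratopd.quiet = TRUE)
```

# The assay and its statistics

`teratopd` analyzes in vivo tumorigenicity (teratoma) assays of human
pluripotent stem cell lines. Severely immunodeficient mice are inoculated
subcutaneously with graded cell doses on a 10-fold grid and palpated weekly
over a 16-week horizon; the data per dose group are quantal: the number of
animals inoculated and the number that formed a tumor. The package covers
five analysis layers: potency estimation (TPD50), descriptive summaries
(volume, incidence, latency, tied rank orders), ordinal grade comparison,
a microarray probe-selection screen, and a cancer-gene variant triage, plus
seeded generators that emulate each data layer with known truth.

# Spearman-Kärber TPD50

The 50% tumor-producing dose is the dose at which half the animals develop a
tumor. With doses equally spaced on the log10 scale (spacing $d$), observed
incidences $p_i = k_i/n_i$, and $x_k$ the log10 of the highest dose, the
Spearman-Kärber estimator is

$$ m = x_k + \tfrac{d}{2} - d \sum_i p_i, \qquad
   \mathrm{Var}(m) = d^2 \sum_i \frac{p_i(1-p_i)}{n_i}, $$

with the 95% interval $m \mp 1.96\sqrt{\mathrm{Var}(m)}$ and everything
back-transformed as $10^{(\cdot)}$. The estimator is the area-balancing
(trapezoid) mean of the tolerance distribution, which is why it requires the
incidence to span 0 at the bottom of the range and 1 at the top.

**Dummy-dose extension.** Assay designs frequently stop short of a fully
negative or fully positive group. Following the endpoint-dilution
convention, `extendSeries()` assumes one extra dilution step on the
deficient side: a group at one-tenth the lowest tested dose with 0%
incidence, and/or a group at ten times the highest dose with 100% incidence.
Dummy groups inherit the adjacent group's $n_i$; because their $p_i$ is 0 or
1 they contribute nothing to $\mathrm{Var}(m)$, so this choice affects
neither the point estimate's variance nor the CI and is made purely for
transparency. Exactly one step per side is ever added; a series still not
spanning 0 to 1 afterwards is rejected rather than extended again, since
repeated extrapolation has no support in the design.

**Numerical choices.** The variance divisor is $n_i$, not the jackknife
style $n_i - 1$: on the packaged dose-incidence table the $n_i$ form
reproduces all three published confidence intervals exactly after integer
rounding, while $n_i-1$ does not (it widens the clumps-row CI to
(177, 2617)). $z = 1.96$; using 1.959964 changes no rounded bound. All
computation is in log10; dose-0 control groups are dropped before the grid
is built (their logarithm is undefined and they carry no information about
the median dose). Reported doses are rounded half away from zero for
display; raw values are retained in the `PotencyEstimate` object.

```{r}
series <- readDoseIncidence(system.file(
  "extdata", "table1_dose_incidence.csv", package = "teratopd"))
estimateTPD50(series$hiPSC_clumps)
```

The closed form is tested against an independent trapezoid-rule oracle
(integrating $x\,dP$ over the piecewise-linear incidence curve) on 1000
random extended series, along with scale-equivariance and monotonicity
properties.

# Descriptive layer

Tumor volume uses the modified-ellipsoid caliper formula
$V = \tfrac{1}{2} L W^2$ (mm^3). Incidence is reported as an integer
percent, rounded half away from zero, the convention that reproduces the
published 83/67/17 values from 5/6, 4/6, 1/6. Group latency is the earliest
palpable week over the line's animals (one latency per line; per-animal
weeks are kept in the data model); animals tumor-free at the 16-week horizon
count as negative for incidence. `rankLines()` produces tie classes and
midranks, the exact form the downstream Spearman correlation consumes; rank
direction is explicit and both published orders are ascending.

# Teratoma grades

Specimens are graded 0-3 by the amount of immature neuroepithelium
(0 = fully mature teratoma). `gradeComparison()` delegates to the
tie-corrected Kruskal-Wallis rank-sum test with the chi-square tail
(df = groups - 1), the standard choice at these group sizes; single-specimen
groups are retained (the statistic is defined for $n_j = 1$) and grade-0
specimens are included. A seeded Monte-Carlo permutation p-value is
available as an option. Exhaustive enumeration on three small groups shows
the chi-square tail can deviate from the exact permutation law by up to
about 0.1 with a dozen tied ordinal observations — far from the 0.05
decision boundary in the packaged specimen table (p = 0.75), but worth
remembering for marginal designs; the permutation option exists for exactly
that case.

# Probe selection

The screen is a strict cascade over a probe-by-sample experiment
(10 lines x 3 replicates in the reference design):

1. **Detection calls**: a probe must be called present in *every* sample;
   marginal counts as absent.
2. **ANOVA**: per-probe one-way fixed-effects ANOVA of intensity on line;
   probes with $p \ge 0.05$ are eliminated. The test runs on the scale the
   normalized intensities are provided on (a `log2` option exists but is
   off by default). The F statistics are computed by a vectorized row-wise
   sum-of-squares decomposition, verified against `stats::lm` per probe.
3. **Dual correlation**: each surviving probe's per-line mean (arithmetic
   mean of the replicates; the per-line aggregation matches the per-line
   outcome variables, $n = 10$) is Spearman-correlated, with midranks for
   ties, against tumor-formation latency and against tumor incidence.
   Two-sided p-values come from the t-approximation with $n-2$ df; a probe
   is selected iff **both** p-values fall below 0.01, either sign of rho.

Correlating all 30 samples against repeated per-line values is available
behind a flag but non-default: it pseudo-replicates the outcome variable.
An exact/Monte-Carlo permutation p-value over line-label permutations is
available; with the heavy ties of the incidence variable (four distinct
values across ten lines) the t-approximation is anti-conservative near the
selection boundary, so permutation decisions can be stricter for borderline
probes.

# Variant triage

A variant survives when all of the following hold: variant allele fraction
strictly greater than 0.09 (the reliability bound of the sequencing design;
"more than 9%" is read as strict), read depth at least 40 (inclusive),
predicted impact HIGH or MODERATE (highest-impact transcript annotation when
several exist), gene symbol on the supplied cancer-gene list (case
normalized), and — by default — at least one variant-level COSMIC
identifier. The filter is monotone in every threshold and order-independent;
survivors collapse to sorted unique gene symbols per line, compared across
lines with the Jaccard index (two empty sets are defined to overlap fully,
with a log note). Flat TSV is the canonical input; single-sample annotated
VCFs are ingested through `VariantAnnotation`, with multi-allelic records
expanded to one record per alt allele.

# Synthetic data and what it does (not) show

`simulateDoseResponse()` draws animal outcomes under a one-hit model,
$P(\text{tumor}\mid D) = 1 - e^{-\ln 2\, D/T}$ with $T$ the true TPD50 —
the single-parameter, mechanistically standard choice for clonogenic tumor
initiation (each engrafting cell acts independently). Latency weeks for
tumor-bearing animals are uniform on 4-9, the span of the published per-line
latencies. Note the estimator's target under this design is the
*design-discretized* value: the closed form applied to the expected
incidences of the extended 10-fold grid, which sits about 0.08 log10 units
below $\log_{10} T$ at $T = 631$ — a discretization property of the
estimator, not a bug; recovery tests therefore score against that target
(500 replicates at 200 animals/dose recover it to ~0.002 log10 in median).

`simulateExpression()` plants probes on a latent tumorigenicity score: the
standardized average of the rank-standardized negated latency and the
incidence ranks, so planted probes correlate with both screening variables.
Planted line means are `baseline + effectSize * sigma * score`; noise is
i.i.d. normal, calls are independent Bernoulli. Defaults: 10 lines x 3
replicates, 2000 probes, 100 planted, baseline 500 (the usual array scaling
target), sigma 50, effect size 3, chosen once as a realistic planted-effect
benchmark. What passing tests show is internal consistency of the cascade
and its power against this idealized structure; real arrays add correlated
probes, batch structure and intensity-dependent variance that the generator
deliberately omits, so measured recall here does not transfer to real data.
A measured property of these defaults: because the incidence variable takes
only four distinct values, even a noiseless planted probe's rho against
incidence midranks is capped near 0.81 (p about 0.005), so expected recall
at the dual 0.01 rule plateaus around 0.88-0.89 rather than approaching 1;
raising the effect size to about 4 SD would push it past 0.95, but 3 SD is
kept as the stated benchmark condition.

`simulateVariants()` constructs records arm-by-arm (one arm violating
exactly one filter criterion, one passing all), with VAF from rescaled
Beta(2,5) draws on the required side of the threshold and depth from
truncated Poisson(150); requested pass-all counts (default uniform on
61-77 per line) are exact by construction and verified by brute-force
re-evaluation.

All generators are pure functions of their parameters and a mandatory seed.

# Problem sizes

The default test suite simulates at desk scale chosen for a single CPU:
2000-probe expression benchmarks, 500-record variant tables, 1000 random
dose series for the closed-form/trapezoid identity, and 500 one-hit
replicates at 200 animals/dose for estimator recovery. These sizes give
binomial/Monte-Carlo error comfortably below the asserted tolerances.

# Known limitations

- The Spearman-Kärber point estimate is design-discretized (see above);
  comparisons across different dose grids should use the same grid.
- No probit/logit or Reed-Muench alternatives; no exact quantal CIs.
- Growth-curve hypothesis testing and time-to-tumor survival analysis are
  out of scope; volumes are summarized, not modeled.
- The probe screen assumes a balanced replicate design and performs no
  multiple-testing correction beyond the dual-variable intersection, by
  design of the original procedure.
- Gene-level collapsing requires an externally supplied probe-to-gene map.
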