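---
title: "Stage-wise AD gene screening and process-level network integration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise AD gene screening and process-level network integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adstagenet)
```

# The problem

Alzheimer's disease (AD) progresses through stages in which cognition
(measured by the Mini-Mental Status Examination, MMSE, 0–30, lower = worse)
declines and neurofibrillary tangle (NFT) burden rises. Hippocampal
expression cohorts annotate each donor with a disease stage (early, medium,
late — or control), an MMSE score and an NFT score. `adstagenet` implements a
pipeline that:

1. screens every gene, **within each disease stage separately**, for Pearson
   correlation of its expression with MMSE and with the square root of the
   NFT score;
2. places the resulting AD-related genes on a protein–protein interaction
   (PPI) network and classifies hubs and high-betweenness bottlenecks;
3. scores biological-process over-representation of the up- and
   down-regulated gene lists with the EASE statistic;
4. integrates the retained processes through per-stage "share" coordinates,
   a three-space Euclidean expression distance, and counts of PPIs bridging
   process pairs, assembled into a dual-edge process link graph.

A synthetic-data module generates cohorts, expression matrices, scale-free
PPI networks and gene-set collections with the statistical structure this
analysis assumes, so the whole pipeline is testable offline.

# The correlation screen

Expression values are accepted only for genes detected (`P` or `M` calls) on
at least `min_detected` chips (default 16, matched to a 22-sample disease
arm). Linear-scale intensities are log2-transformed and each gene is
median-centered across samples. Centering does not change any Pearson
correlation (location/scale invariance — property-tested), it only fixes the
reporting scale.

Within each stage $s$ and for each score $v$ (MMSE or $\sqrt{\mathrm{NFT}}$),
the screen computes the product–moment correlation
$r = \frac{\sum_i (x_i - \bar x)(v_i - \bar v)}
          {\sqrt{\sum_i (x_i-\bar x)^2 \sum_i (v_i-\bar v)^2}}$
over that stage's samples only, with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. Genes with zero
within-stage variance yield an explicit undefined-correlation record that is
excluded from multiple testing. Samples with a missing score are dropped
pairwise per score type.

**Two-step calling rule.** Benjamini–Hochberg adjustment is applied *only*
to the records with $R^2$ strictly above `r2_min` (default 0.30), and a
(gene, stage, score) record is flagged when additionally its adjusted p is
strictly below `alpha` (default 0.05). The BH family is each
(stage, score-type) cell of the prefiltered records by default; a
whole-table family is available via `family = "global"`, since the grouping
convention is a genuinely open choice. Note a consequence of prefiltered
adjustment worth knowing: flag counts are **not** guaranteed monotone in
`r2_min`, because raising it shrinks the BH family and therefore the
multiplicity penalty. Counts are monotone in `alpha`.

**Direction of regulation.** MMSE falls and NFT rises as AD worsens, so a
disease-up gene anti-correlates with MMSE and correlates with
$\sqrt{\mathrm{NFT}}$. The default `"clinical"` policy therefore calls a
flagged gene *down* when $r > 0$ against MMSE or $r < 0$ against
$\sqrt{\mathrm{NFT}}$, and *up* otherwise. A raw `"sign"` policy is exposed
for callers who prefer the uninterpreted correlation sign.

**Normality assessment.** The D'Agostino & Pearson omnibus test
($K^2 = Z^2_{\mathrm{skew}} + Z^2_{\mathrm{kurt}}$, $\chi^2_2$ reference) is
provided to justify Pearson correlation and the square-root transform of
NFT. It is advisory: it does not gate the pipeline. The implementation
requires $n \ge 8$ because the Anscombe–Glynn kurtosis transformation is
numerically unreliable below that; per-stage $n \approx 7$ in small cohorts
is below this floor, so normality in practice is assessed on the pooled
scores. For exactly-zero sample skewness the skewness Z is 0, as the
published transformation dictates.

# Network topology

The PPI graph is pruned before any centrality is computed: duplicate pairs
collapsed, self-loops removed, optionally restricted to a tissue-expressed
gene list, and reduced to its largest connected component (an alternative
minimum-component-size rule is exposed, but betweenness requires the
connected default). Degree is the number of distinct neighbors; the
handshake identity $\sum_i k_i = 2|E|$ is asserted in tests. Betweenness is
shortest-path (Brandes) betweenness with endpoints excluded, normalized by
$(n-1)(n-2)/2$ so values lie in $[0,1]$ — the scale on which the bottleneck
threshold $5\times10^{-4}$ is meaningful for networks of several thousand
nodes; raw counts are available with `normalized = FALSE`.

Hubs are nodes with degree **strictly** greater than 50 and bottlenecks have
normalized betweenness strictly greater than $5\times10^{-4}$; both
thresholds are parameters.

The degree–betweenness relationship is summarized by a least-squares
second-degree polynomial fit $b \approx c_0 + c_1 k + c_2 k^2$ ("binomial"
read as *binomial = quadratic*, the natural reading for a centrality that
grows super-linearly in degree on scale-free graphs). The reported $R$ is
the Pearson correlation of observed and fitted betweenness (equivalently
$\sqrt{R^2}$ of the fit); the plain linear Pearson correlation of $k$ and
$b$ is reported alongside because the two differ on heavy-tailed networks.

# Process over-representation

The EASE score is the one-sided hypergeometric upper-tail probability with
the observed overlap **penalized by one**: for an overlap of $k$ genes
between a query list and an annotation set, the reported p is
$P(X \ge k - 1)$; overlaps of 0 or 1 give $p = 1$. This is deliberately
conservative against single-gene coincidences, and is always at least the
classical hypergeometric p (property-tested). The background universe
defaults to the post-detection-filter screened genes intersected with the
annotated genes, and is an explicit argument because enrichment p-values
are very sensitive to it.

A cluster Enrichment Score is the arithmetic mean of $-\log_{10} p$ over the
cluster's terms. Term clustering itself (kappa-similarity fuzzy clustering
as in annotation web tools) is *not* implemented: clusters are caller
input, and a single term degenerates to $\mathrm{ES} = -\log_{10} p$.
Retention uses strict thresholds: $\mathrm{ES} > 2.0$, EASE $p < 0.05$, and
more than 10 member genes.

Per retained process, member genes flagged at each stage are counted (a
gene flagged at several stages counts at each); per-stage totals across the
retained processes are carried as an attribute and re-asserted as column
sums on every run.

# Process integration

For each retained process the stage-share coordinate is
$(x, y, z) = \left(\frac{n_e}{N_e}, \frac{n_m}{N_m}, \frac{n_l}{N_l}\right)$
where $n_\bullet$ are the process's flagged-gene counts and $N_\bullet$ the
per-stage totals over **all retained processes**. This denominator
convention is forced by consistency with reference stage-count tables in
the field (e.g. 40/148 = 27.0%); per-process or per-direction denominators
do not reproduce them. Shares at each stage sum to 1 across processes.

The expression distance between two processes is the Euclidean distance of
their coordinates,
$d = \sqrt{(x_a-x_b)^2 + (y_a-y_b)^2 + (z_a-z_b)^2}$ — a metric
(property-tested), computed on **unrounded** shares; percentages are
displayed at one decimal (round half away from zero), and distances near
the 0.20 boundary can be rounding-sensitive, which is why display rounding
never feeds the distance.

The number of PPIs bridging processes A and B counts each physical edge
with one endpoint annotated to A and the other to B once; an edge with both
endpoints in the shared membership $A \cap B$ is one physical interaction
and is counted once by default (`shared = "drop"` excludes such edges).

The process link graph connects a pair with a *solid* edge when
$d < 0.20$ (strict; coordinated expression trend) and with a *dashed* edge
when the bridging PPI count exceeds 20 (strict; strong functional link);
both edge types may coexist between a pair. Node attributes carry the
up/down direction; `export_graphml()` preserves all attributes.

# The synthetic-data generator

Defaults mirror a small hippocampal cohort: 9 controls plus 22 disease
samples (7 early, 8 medium, 7 late); MMSE drawn truncated-normal on
$[0, 30]$ and rounded to integers, with group means 28.5 / 23.5 / 18 / 10
(sd 1.5 / 3 / 3.5 / 4) decreasing with severity; $\sqrt{\mathrm{NFT}}$
drawn truncated-normal at 0 with means 0.8 / 1.8 / 2.6 / 3.4 (sd ~0.6)
increasing with severity. These values were chosen once as realistic for
the cohort scale the pipeline targets.

Planted genes are linear-in-score with Gaussian noise: within its stage, a
planted gene's expression is
$\sigma\left(\pm\sqrt{R^2_t}\, \tilde v + \sqrt{1 - R^2_t}\,\varepsilon\right)$
with $\tilde v$ the standardized realized score, so the population $R^2$
given the realized scores equals the target. The sign encodes the clinical
direction. Other stages are pure noise; null genes are pure noise
throughout. This is the minimal generative model consistent with a Pearson
screen — it deliberately omits probe effects, batch structure,
heteroscedasticity and gene–gene correlation, so passing recovery tests
demonstrates correctness of the screen's mechanics, not robustness to real
microarray artifacts.

Two interactions are worth knowing. *Integer rounding* of MMSE happens
after the correlation-target calibration; the small attenuation of
empirical $R^2$ it causes is accepted, not corrected. *Truncation skew*:
for group means near the MMSE ceiling (control 28.5, and mildly early
23.5), the $[0,30]$ truncation induces skewness that the omnibus normality
test detects at large $n$; this mirrors the real ceiling effect of MMSE in
controls. Normality property tests therefore use the medium group, whose
mean sits more than 3 sd inside both bounds.

The PPI generator is preferential-attachment (Barabási–Albert) growth with
`m = 6` edges per node — connected, scale-free, hub-dominated, which is the
regime in which a quadratic degree–betweenness fit attains high $R$. Gene
sets are drawn with a configurable fraction of members from a shared core
pool (pairwise overlap), optionally concentrating planted genes into a
designated set to create true enrichment.

Every generator is deterministic given `seed`; the cohort, expression,
network and gene-set generators use seed offsets 0–3 so they can be called
in any combination.

# Numerical and testing choices

- All published-threshold comparisons are **strict** (`> 50`, `> 5e-4`,
  `> 0.30`, `< 0.05`, `> 2.0`, `> 10`, `< 0.20`, `> 20`), and boundary
  cases are unit-tested on exactly-representable values.
- BH adjustment is the standard step-up (ties need no special rule);
  adjusted values are verified against a brute-force implementation of the
  step-up definition.
- Betweenness is verified against an exhaustive shortest-path enumerator on
  200 random connected graphs of up to 8 nodes; EASE against exhaustive
  tail summation for every configuration with background up to 60.
- Statistical calibration runs use 2,000 genes, 40 samples per stage, and
  tens of replicates (100 for the null type-I rate, 20 for recovery) —
  sizes at which binomial error bands are tight while the suite stays
  fast. Recovery tests use n = 40/stage rather than the study-scale 7
  because per-stage n = 7 has little power by construction; the study-scale
  default remains the generator's cohort shape.
- Percentage display uses round-half-away-from-zero at one decimal.

# Known limitations

- Probe-to-gene collapsing is not performed; inputs are assumed
  gene-summarized (a max-mean collapse can be applied upstream). Screens on
  probe-level data will count probes, not genes.
- Term clustering for the Enrichment Score is caller input; the package
  does not reproduce any specific annotation service's clusters, so ES
  values on real annotation databases are not comparable across services.
- The expression distance treats the three stage shares as independent
  coordinates; it is a descriptive similarity, not a calibrated statistic,
  and has no associated p-value.
- With per-stage family BH adjustment, flag counts can change
  non-monotonically as `r2_min` varies (see above); consumers sweeping
  thresholds should sweep `alpha`, not `r2_min`.
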