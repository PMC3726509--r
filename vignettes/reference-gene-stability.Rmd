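---
title: "Selecting stable reference genes for RT-qPCR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable reference genes for RT-qPCR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by RT-qPCR divides every measurement by the signal
of one or more *reference genes*, assumed equally expressed in all samples.
A housekeeping role does not guarantee that assumption: widely used controls
such as *GAPDH* or *ACTB* vary substantially across tissues and disease
states, and a poorly chosen reference injects its own variability into every
normalized quantity. refstab implements a two-stage selection strategy:

1. **Microarray screen.** Rank the probesets of several public expression
   datasets by an outlier-robust variability statistic and keep the genes
   whose probesets are among the top-K most stable in *every* dataset.
2. **RT-qPCR validation.** Measure the shortlisted candidates on the study's
   own samples and score them with four complementary stability measures;
   combine the four rankings (plus an intergroup-variation veto) into a
   final set, and verify that the *set*, collapsed to a single "quasi-gene",
   outperforms every individual candidate.

Everything below states the exact quantities computed, the conventions
fixed, and the design decisions taken where the methods literature is
silent.

## The quantification model

All Ct-based computations use the exponential model

$$A = I / E^{C_t},$$

where $A$ is the expression level, $I$ the fluorescence threshold (one
scalar per table; it cancels in every ratio and defaults to 1), $E$ the
per-gene amplification efficiency (per-cycle amplification factor, 2 =
perfect doubling), and $C_t$ the threshold cycle. Efficiencies are
calibrated from a dilution series by regressing mean Ct on
$\log_{10}$(relative concentration) and converting the slope with
$E = 10^{-1/\mathrm{slope}}$; a valid assay has a negative slope
($\approx -3.32$ for perfect doubling). Replicates are averaged per
dilution before the fit (for balanced replicates only $r^2$ changes, not
the slope). `expression_from_ct()` works in the log domain, so the identity
$E^{-\bar{C_t}} = \mathrm{geomean}(E^{-C_t})$ holds to machine precision;
note that an *arithmetic* mean of expression levels does not commute with
averaging Ct values (AM–GM), which is why each measure declares whether it
consumes mean Ct or per-replicate values.

## The microarray screening statistic

For each probeset the variability characteristic is the ratio
$p_{95}/p_{5}$ of the 95th to the 5th percentile of its log-scale
expression across samples. It plays the role of an interquartile range that
controls 90% rather than 50% of the samples, and as a quantile ratio it is
insensitive to outliers — the reason it is preferred over the SD for public
datasets of heterogeneous provenance. For a stable probeset with
percentiles $m(1 \mp w)$, $0 \le w \ll 1$,

$$\frac{p_{95}}{p_{5}} = \frac{1+w}{1-w} = 1 + 2w + \frac{2w^2}{1-w}
\approx 1 + 2w,$$

so ascending ratio order is ascending relative-spread order. Conventions
the literature leaves open, fixed here and echoed in output headers:

* **Percentile convention**: linear interpolation between order statistics
  (`quantile(type = 7)`), used identically in the screen and in the Haller
  95th percentile.
* **Ties**: broken lexicographically by probeset ID.
* **Symbol mapping**: a gene symbol is "in the top-k" of a dataset if *any*
  of its probesets is (the natural reading of counting unique gene symbols);
  probeset-level intersection is available by omitting the annotation.
* A non-positive 5th percentile is an error, not a fallback: the ordering
  rationale presumes a positive log-expression scale.

## The four stability measures

Conventions fixed across all four: sample SD ($n-1$ denominator); log base
2 for expression ratios (any base gives the same ranking); lower value =
more stable; rankings ascend with ties broken by gene ID.

**Comparative ΔCt** (`delta_ct_stability`). For each ordered gene pair
$(j,k)$ form $\Delta C_{t,jk}(s) = C_{t,j}(s) - C_{t,k}(s)$ per sample
(replicates collapsed to the per-pair mean Ct) and let $SD_{jk}$ be its SD
across samples; then $M_j = \mathrm{mean}_{k \ne j}\, SD_{jk}$. Invariant
to any per-sample additive Ct shift.

**geNorm** (`genorm_m`, `genorm_ranking`). $M_j$ is the mean over partners
of the SD of $\log_2(A_j/A_k)$ across samples. When all $E = 2$ and $I$ is
common, $\log_2(A_j/A_k) = C_{t,k} - C_{t,j}$ and geNorm *equals* the
comparative ΔCt value — the module's strongest cross-check, asserted to
1e-10 in the tests. The stepwise ranking repeatedly removes the
highest-$M$ gene and recomputes until two remain; those two are mutually
each other's only partner, cannot be distinguished, and share rank 1.

**NormFinder-style variance decomposition** (`normfinder_stability`). The
model on log2 expression is

$$x_{igj} = \alpha_i + b_{gj} + d_{ig} + \varepsilon_{igj},
\qquad \varepsilon_{igj} \sim N(0, \sigma^2_{ig}),$$

with gene effects $\alpha_i$, per-sample effects $b_{gj}$, gene-by-group
deviations $d_{ig}$ and gene/group-specific noise. Implementation details
that matter (all consequences of the gene-specific variances):

* The per-sample effect is removed by an **inverse-variance weighted** mean
  over genes, in two passes — first unweighted to estimate variances, then
  reweighted once. An unweighted mean mixes the noisiest genes' scatter
  into every residual and compresses the separation between quiet genes;
  open-ended iteration is avoided because it lets one quiet gene absorb the
  sample effect entirely and zero out its own residuals.
* With groups, **one common weight vector** (from variances pooled across
  groups) is used for every group: different weights would subtract
  different combinations of the (large) gene baselines in each group, and
  the difference would masquerade as a shared group deviation.
* The between-group spread $\gamma^2$ is estimated by marginal maximum
  likelihood under $\hat d_{ig} \sim N(0, \gamma^2 + \mathrm{Var}(\hat
  d_{ig}))$, and each deviation is shrunk by $\gamma^2/(\gamma^2 +
  \mathrm{Var}(\hat d_{ig}))$. A method-of-moments estimate is unusable
  here: the high-variance genes' noisy deviations dominate it and it
  truncates at zero in most datasets, erasing real intergroup signal.
* Stability value: without groups, the residual SD after sample-effect
  removal; with groups, the mean over groups of $|\tilde d_{ig}| +
  \mathrm{SE}(\text{group mean})$. The shrunken deviations are returned
  separately (`extras$intergroup`) because a gene with low intragroup
  scatter but a real group offset tracks group composition rather than
  loading — it may be the *worst* possible normalizer while looking stable
  by every relative measure, and the consensus step vetoes it explicitly.

**Haller equivalence fold change** (`haller_stability`). For each gene and
each unordered sample pair, a two-sided Welch $1-\alpha$ confidence
interval for the mean Ct difference is built from the replicate values and
mapped through the gene's own efficiency to the fold scale
($\delta = E^{-c}$ for a Ct-difference bound $c$). The pair contributes the
larger fold magnitude $\max(\delta, 1/\delta)$ over both endpoints — the
maximum fold change not excluded at level $\alpha$ — and the gene's value
is the 95th percentile of all pair contributions (default $\alpha = 0.05$).
Decisions taken where the formulation is ambiguous:

* Per-pair maxima are the default (the quantity is a *maximum* fold
  change); pooling both endpoints of every pair into one percentile is
  available as `pooled_endpoints = TRUE`.
* All replicates enter as independent observations by default;
  `nested = TRUE` collapses PCR replicates to run means first, respecting
  the run-level correlation at the cost of degrees of freedom. The nominal
  coverage property ($1-\alpha$ of null pairs contain fold 1) holds for
  independent replicates; shared run effects make the flat intervals
  anti-conservative, which is exactly when the nested option is
  appropriate.
* If both samples of a pair have zero replicate variance the interval is
  degenerate and the point fold change $E^{|D|}$ is used.
* The measure is deliberately pessimistic — interval endpoints, not point
  estimates — so its values are bounded below by the point-estimate fold
  percentile (asserted in the tests), and they respond to per-sample
  loading shifts, which the relative measures cancel. It answers a
  different question (worst plausible fold change between two biopsies)
  and is reported on its own scale ($\ge 1$).

## Quasi-genes: scoring a set as one gene

The normalization factor of a set of $n$ reference genes is the geometric
mean of their expression levels, $\tilde A = (\prod_i A_i)^{1/n}$. To score
that factor with the same four measures, the set is collapsed to a
pseudo-gene with efficiency $\tilde E = (\prod_i E_i)^{1/n}$ (geometric
mean, computed in the log domain) and, per replicate slot,

$$\tilde C_t = \frac{1}{n} \sum_i C_{t,i} \log_{\tilde E} E_i,$$

which is the unique Ct value satisfying $I/\tilde E^{\tilde C_t} = \tilde
A$ (asserted to 1e-10 over randomized sets in the tests). When all member
efficiencies are equal the weights are 1 and $\tilde C_t$ is the plain mean
Ct; a singleton quasi-gene reproduces its member bit-for-bit. Replicate
slots are paired positionally by (run, replicate) index across members;
ragged grids are an error, never imputed.

## Consensus selection

The four rankings are combined by mean rank (Borda and median-rank are
options), ascending. Genes whose absolute intergroup variation exceeds a
configurable quantile (default 0.9) of the panel's values are demoted below
all unflagged genes regardless of rank — the veto described above. Ties
break by NormFinder value, then gene ID. The default set size is 5. The
aggregation rule is intentionally simple: the ingredients (four rankings
plus an intergroup veto) are what practitioners report; any monotone
aggregation of them gives similar sets, and the rule is recorded in output
headers so results are reproducible.

## The synthetic-data generator

`generate_ct_dataset()` emulates the structure of a receptor-status
validation study on tumor biopsies. On the log2 expression scale,

$$x_{is} = L_s + d_{i,g(s)} + \beta_{is}, \qquad
\beta_{is} \sim N(0, \sigma_i^2),$$

with a shared per-sample loading shift $L_s$, optional per-gene group
offsets, and gene-specific biological tiers $\sigma_i$. Ct values convert
through each gene's own efficiency ($C_t = b_i - x_{is}\ln 2/\ln E_i$), so
equal expression variance yields different Ct-scale variance across genes —
the coupling the measures must disentangle. Replicates add run-level noise
(shared within a run) and well-level noise. Defaults are the study shape a
practitioner would recognize: 18 genes × 39 samples with a 25/14 group
split, 3 runs × 3 PCR replicates, efficiencies evenly spaced over
1.76–2.10, biological tiers {0.1, 0.5, 1.5} log2 units assigned
cyclically, loading SD 0.5 log2, run/PCR noise 0.15/0.10 Ct, baselines
20–28 Ct. Biological and technical noise are drawn from independent
seeded streams, so either can be zeroed without changing the other's
draws; regeneration under a seed is bit-for-bit. Values outside a
realistic 15–35 Ct range trigger a warning, never silent clipping.

What the generator does **not** emulate — and therefore what passing tests
do not certify about real data: gene–gene co-regulation (which deflates
ΔCt/geNorm values for co-regulated pairs — the reason the independent
measures are in the panel at all), outlier samples and failed reactions,
PCR inhibition and efficiency drift between runs, and non-Gaussian
heavy-tailed biopsy heterogeneity. `generate_microarray_collection()`
similarly plants a shared low-spread probeset core inside independent
Gaussian datasets; it validates list-intersection mechanics, not RMA
preprocessing, and real accession-scale counts are sensitive to the RMA
implementation upstream.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the study's own scale (18
genes × 39 samples × 9 replicates) with 50–100 simulation repetitions per
property and 1000 trials for the algebraic identities, which keeps the full
suite under half a minute. Tolerances: algebraic identities at 1e-10
(relative), closed forms at 1e-12, Monte-Carlo rates at the widths quoted
per test. Degenerate inputs are handled explicitly: zero-variance Haller
pairs return point folds, noise-free NormFinder blocks skip reweighting,
the singleton quasi-gene bypasses the 0/0 weight, and `E \le 1`,
non-positive percentiles, empty matrices and ragged grids are classed
errors, never repairs.

## Known limitations

* Haller values respond to per-sample loading differences by design; do not
  compare them across experiments with different loading discipline.
* The NormFinder-style value is a model-based estimate; with fewer than ~10
  samples per group the shrinkage dominates and intergroup deviations are
  conservative.
* The geNorm final pair is reported tied — the measure cannot rank the last
  two genes.
* The screen's percentile ratio presumes positive log-scale expression
  (RMA-like); matrices containing non-positive values need rescaling before
  screening.
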