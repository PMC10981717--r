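---
title: "Methods: proteome-peptidome network inference with milknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-peptidome network inference with milknet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`milknet` infers a joint association network over proteins and endogenous
peptides measured by label-free LC-MS/MS in human milk, and interrogates
the proteolytic signatures that shape the peptidome. This vignette is the
package's account of the model, its assumptions, the defaults, and the
limits of what the test suite demonstrates.

## The statistical model

### Shrinkage Gaussian graphical model

Let $X$ be the $n \times p$ matrix of log2 intensities after filtering
and imputation (samples in rows; proteins and peptides together in
columns — in milk roughly $n \approx 300$ samples against
$p \approx 1900$ features). We model the columns as jointly Gaussian and
ask for *direct* associations: the partial correlation

$$\rho_{ij} = -\,\frac{\omega_{ij}}{\sqrt{\omega_{ii}\,\omega_{jj}}},
\qquad \Omega = (R^*)^{-1},$$

the correlation between features $i$ and $j$ after removing the linear
effect of all other features. Marginal correlations in omics data are
dominated by shared drivers (lactation stage, secretion pathways); the
partial correlation strips those indirect paths, which is the point of
the whole construction.

With $p > n$ the sample correlation matrix $R$ is singular, so we invert
the shrinkage estimate

$$R^* = \lambda^* I + (1 - \lambda^*) R, \qquad
\lambda^* = \frac{\sum_{i \ne j} \widehat{\mathrm{Var}}(r_{ij})}
                 {\sum_{i \ne j} r_{ij}^2}
  \;\text{clipped to } [0, 1],$$

the analytic-shrinkage intensity toward the identity target, computed
from the moment sums of the products $w_{kij} = x_{ki}x_{kj}$ of the
standardized data. $\lambda^*$ is dimensionless because we shrink the
*correlation* (not covariance) matrix; standardization also makes
$\rho$ invariant to rescaling any raw feature. When noise dominates
($p \gg n$, weak signal) $\lambda^* \to 1$ and all partial correlations
collapse toward zero; tests verify this monotonicity, the $\lambda = 0$
equivalence with direct inversion of $R$, and permutation equivariance.

A note on wording: "pairwise" estimation in the shrinkage-GGM tradition
refers to this estimator's per-pair output, not to literal $2\times 2$
fits; `partial_correlations()` implements the shrinkage-then-invert
estimator, with a Moore-Penrose pseudo-inverse fallback for the
degenerate $\lambda = 0,\ p > n$ corner so parameter sweeps stay total.

### Empirical-Bayes edge calibration

The off-diagonal $\hat\rho_{ij}$ are modelled as a two-group mixture

$$f(r) = \eta_0\, f_0(r;\kappa) + (1 - \eta_0)\, f_A(r), \qquad
f_0(r;\kappa) = \frac{\Gamma(\kappa/2)}
     {\sqrt{\pi}\,\Gamma((\kappa-1)/2)} (1 - r^2)^{(\kappa-3)/2},$$

where $f_0$ is the sampling law of a null partial correlation with
$\kappa$ effective degrees of freedom (equivalently
$r^2 \sim \mathrm{Beta}(\tfrac12, \tfrac{\kappa-1}{2})$). $\kappa$
cannot be set to $n - p + 1$, which is negative here; it is *fitted* by
maximum likelihood on the central body of the distribution ($|r|$ below
its 90th percentile, with the truncation term
$P(|r| \le c;\kappa)$ kept in the likelihood — omitting it biases
$\kappa$ upward by ~60%). $\eta_0$ is the ratio of empirical to null
mass within one null standard deviation ($1/\sqrt{\kappa}$) of zero,
clipped to $[0,1]$. The mixture density $\hat f$ is a Gaussian kernel
estimate with Silverman bandwidth and reflection at $\pm 1$, evaluated
on a grid that tracks the observed range: under strong shrinkage the
whole distribution can sit within $\pm 10^{-3}$, and a fixed grid on
$[-1, 1]$ cannot resolve it (this, and an adaptive upper bound
$\kappa_{\max} \propto 1/\mathrm{var}(r)$ for the likelihood search,
were both necessary for calibration).

The local false discovery rate of an edge,

$$\mathrm{fdr}(r) = \min\!\left(1,\;
  \frac{\eta_0 f_0(r;\kappa)}{\hat f(r)}\right),$$

is post-processed by isotonic least squares to be non-increasing in
$|r|$. An edge is drawn when $\mathrm{fdr} < 0.1$ — strictly, so a value
of exactly 0.1 is not significant — equivalently when its presence
probability $1 - \mathrm{fdr}$ exceeds 0.9. All-zero input (total
shrinkage) is treated as pure null: $\eta_0 = 1$, every fdr 1.

Calibration is checked by simulation: across ten pure-null data sets
($p = 100$, $n = 297$) the mean significant-edge rate stays below 1%,
and with planted $|\rho| = 0.3$ structure the empirical FDR stays below
0.2 at sensitivity above 0.5.

### Community detection

The significant-edge graph is clustered with the Leiden algorithm under
the Constant Potts Model,

$$H = \sum_c \left[ W_c - \gamma\, \frac{n_c (n_c - 1)}{2} \right],$$

with $W_c$ the intra-community edge weight ($|\rho|$ by default; edge
count in unweighted mode) — `leiden_cpm()` delegates the optimization to
`igraph::cluster_leiden()` and the suite verifies its output against an
exhaustive-partition brute-force maximization of `cpm_quality()` on
6-node graphs. $\gamma$ is the density scale a community must beat: two
groups merge only when the weight between them exceeds
$\gamma\,n_1 n_2$. Defaults are $\gamma = 10^{-3}$, refinement
randomness $\beta = 0.01$, an iteration budget of 1000 (igraph stops
earlier when stable), and seeded tie-breaking; communities are
guaranteed connected, and clusters with more than 3 nodes are retained
and labelled mixed / protein-only / peptide-only.

$\gamma = 10^{-3}$ suits a sparse ~1900-node network whose clusters span
tens of nodes. It is *not* appropriate for a compact synthetic network
of a few dozen nodes: with planted blocks of 4, a single spurious
bridge edge ($|\rho| \approx 0.17$) beats the merge penalty
$\gamma \cdot 16 = 0.016$ and fuses two blocks. The end-to-end synthetic
study therefore runs at $\gamma = 0.05$ with $|\rho|$ weights, between
the within-block edge weight (~0.25) and the spurious-bridge density
(~0.01). Whether the original milk analysis used weighted CPM is not
documented; both modes are provided, and count-sensitive checks use the
unweighted mode.

### Overrepresentation

Protein members of each retained cluster are tested against the
background of all identified proteins with the upper hypergeometric
tail; annotations are consumed as a flat, pre-propagated gene-to-term
table (no GO-DAG traversal, keeping the module offline and
deterministic). Benjamini-Hochberg adjustment pools, by default, the
terms tested within one (cluster, GO-domain) pair, mirroring per-domain
reporting; a global pool is one flag away. Significance is strict at
adjusted $p < 0.05$. The exact adjusted p-values of any given annotation
release are not reproduction targets — they depend on the provider's GO
snapshot and the original web tool's internal pooling, which is
undocumented.

### Peptidome analyses

Peptide coordinates are 1-based inclusive on the full precursor, signal
peptide included. Within a (cluster, precursor) group, *ladders* are the
connected components of the interval-overlap graph (intersection of at
least one residue; a sorted sweep finds components in linear time);
components with $\ge 5$ peptides are reported with their union span,
count, and mean length to one decimal. This definition deliberately
allows two disjoint ladders of one precursor inside one cluster.
*Trimming steps* are ordered peptide pairs differing by exactly one
residue at exactly one terminus — the aminopeptidase (N-step) or
carboxypeptidase (C-step) signature. *Cleavage sites* are the bonds
flanking each peptide (protein termini excluded; the mature-protein
start bond counts, since signal peptidase action is a genuine cleavage),
deduplicated by (precursor, bond position) so the reported fractions are
invariant to duplicate peptide rows; a site matches a protease rule when
its P1 residue (and optionally P1') is allowed — plasmin is K/R at P1,
any P1'. Per-terminus counting is available behind a flag but unique
sites are the default, being order-invariant. Precursor contributions
are reported both by peptide count and by summed mean intensity.

## Preprocessing

- **Prevalence filter**: features observed in strictly more than half of
  the samples are kept (the ">150 of 300" rule, generalized to any
  $n$); contaminant and reverse (decoy) rows are dropped first.
- **Sample outliers**: a sample is excluded when its log10 total peptide
  intensity exceeds the median by $\ge 2$ log10 units — an
  operationalization of "several orders of magnitude", configurable.
- **Missingness**: label-free zeros are detection-limit censoring, not
  randomness. `apply_mnar_censoring()` emulates this per feature below a
  quantile threshold (a logistic soft variant exists behind a flag; the
  hard threshold is the testable worst case and the default).
  `impute_mnar()` fills missing cells on the log2 scale: a
  censored-normal (Tobit) fit per feature — using both the observed tail
  and the count of censored cells — initializes draws truncated above at
  the observed minimum, then a fixed number of Gibbs sweeps re-draws
  each incomplete feature from a ridge regression on its 10
  most-correlated features, conditioning on the full current matrix
  (conditioning only on observed rows would regress on a truncated upper
  tail and bias the intercept). Imputed values never exceed the
  feature's observed minimum, and observed cells are preserved
  bit-exactly. This sampler honours the same MNAR/left-censored contract
  as the Gibbs-based imputation package used in the original analysis,
  which is not available here; against the closed-form truncated-normal
  oracle its imputed means are accurate to within 0.15 standard
  deviations.
- **Transform**: all model fitting uses log2 intensities. Gaussian
  modeling of raw LFQ intensities is indefensible (they are log-normal
  over a 2^20-2^30 dynamic range); the transform is surfaced as an
  explicit step, not buried.

## The synthetic-data generator

The generator is first-class, tested code that carries ground truth.

- **Abundances** (`simulate_abundances()`): $n$ draws from the Gaussian
  whose precision matrix plants disjoint *complete blocks* with constant
  partial correlation $\rho$ (positive definite iff
  $|\rho| < 1/(m-1)$; a block of 4 at $\rho = 0.3$ is the default
  study unit, and violating blocks are rejected by index). Latent
  scores map to intensities as $2^{\mu_f + z}$ with per-feature
  baselines $\mu_f \sim U(20, 30)$ on the log2 scale — a realistic LFQ
  dynamic range whose log2 transform restores exact Gaussianity. Truth
  records the planted edges (the non-zero off-diagonal precision
  entries, exactly) and cluster labels.
- **Digestion** (`simulate_digest()`): bonds after K/R are cut
  independently with probability `cleavage_prob`; fragments bounded by
  at least one cut (the intact chain is not a peptide) and 8-25 residues
  long are emitted, each with up to `exo_steps` single-residue N- and
  C-trimmed ladder variants at geometrically decreasing abundance
  (factor 0.5/step). Peptide intensity is precursor intensity x yield
  x decay x $2^\varepsilon$, $\varepsilon \sim N(0, 0.3)$ per cell —
  the magnitude of peptide-precursor coupling in real milk has only been
  described qualitatively, so the yield (0.05), decay (0.5), and noise
  (0.3 log2 units) are this package's own defaults, chosen once as
  realistic free parameters. At these defaults the
  peptide-precursor log-scale correlation exceeds 0.5 by a wide margin.
  Truth records every endoproteolytic site bounding an emitted base
  peptide, which makes "exact site recovery at `exo_steps = 0`"
  well-defined even when a long fragment falls outside the length
  window.
- **Censoring**: as above, with per-feature thresholds recorded.
- All randomness flows from one integer seed through a scoped generator
  that restores the caller's RNG state; identical seeds give
  bit-identical output, and the MaxQuant-dialect writers round-trip
  through the readers exactly (17-digit intensities, zeros for missing).

### What the generator does not emulate

Acquisition artifacts (peak picking, misidentification, run-order
drift), search-engine FDR, shared-peptide protein inference,
between-sample normalization beyond LFQ, and covariate structure
(lactation stage, allergy status). Passing tests therefore demonstrate
the *statistical* machinery under the stated generative assumptions, not
robustness to MS artifacts.

### A finding worth knowing about

Ladder peptides are near-collinear with their precursor and with each
other. A Gaussian graphical model *dilutes* partial correlations across
such a clique: for $k$ peptides coupled to one precursor the
peptide-precursor partial correlation is capped near $1/\sqrt{k}$
regardless of how small the coupling noise is. At $n = 297$, ladders of
a dozen variants can therefore drop below the significance threshold
even though every marginal correlation is above 0.9. This is a genuine
property of the model class, not a bug; it is why the end-to-end
recovery criterion scores the planted *protein* blocks, and it tempers
the interpretation of edge absence between a peptide and its precursor
in real data.

## Problem sizes and numerical choices

The simulation suites run at the study's sample size ($n = 297$)
with $p = 100$ features (null calibration; planted recovery uses 12
blocks of 4) and a 40-protein + 2-precursor end-to-end study — sizes
chosen so the whole suite completes in well under a minute while keeping
$n/p$ in the regime where shrinkage actually matters. Degenerate inputs
are handled explicitly: all-zero partial correlations (pure-null
fallback), constant features (rejected by name), features with no
observed values (rejected), empty graphs (all singletons), zero-edge
networks (density 0). Ties at thresholds are strict everywhere
(lfdr, adjusted p, retention size uses $\ge$ on `min_size = 4`,
equivalent to "more than 3").

## Known limitations

- The headline numbers of the motivating full-scale milk analysis
  (16,961 edges over 1895 nodes, 119 clusters, per-cluster enrichment
  p-values) require the deposited raw spectra and the upstream MaxQuant
  search; they are out of desk scope. The package reproduces the
  arithmetic identities among those counts and the method's statistical
  operating characteristics instead, and reports its own per-stage
  counts without trying to reconcile externally reported ones.
- No reference values of $\kappa$ or $\eta_0$ exist for the real data;
  absolute edge-set reproduction is not a testable target.
- The imputation sampler is a documented stand-in honouring the same
  contract as the original package's algorithm, not a reimplementation
  of its internals.
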