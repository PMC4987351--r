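---
title: "The hub disruption index: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hub disruption index: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubdisrupt)
```

## The question the index answers

Focal brain lesions do not only damage tissue locally: the functional
network of the *other* hemisphere reorganizes. Classical global graph
metrics (mean efficiency, clustering, ...) average over nodes and are often
too blunt to see this. The hub disruption index $\kappa$ asks a sharper
question: *have the network's hubs lost relative importance while peripheral
nodes gained it?*

For a nodal metric $m$ (degree $D$, nodal global efficiency $E_g$,
betweenness $B$, local efficiency $E_l$, clustering $C$), let $\bar m_i$ be
the reference (healthy) group's mean value at node $i$ and $m_i^{(s)}$ the
value for subject $s$. Regressing the difference on the reference,

$$ m_i^{(s)} - \bar m_i \;=\; \beta_0 + \kappa \,\bar m_i + \varepsilon_i, $$

gives $\kappa$ as the fitted slope (ordinary least squares with intercept,
all nodes weighted equally). A subject with normative topology scatters
around a horizontal line ($\kappa \approx 0$); hub-targeted reorganization
— hubs down, periphery up — produces $\kappa < 0$. Useful identities,
verified exactly in the test suite: a subject equal to the reference gives
$\kappa = 0$; a uniformly inflated subject $(1+a)\bar m$ gives
$\kappa = a$; a constant profile gives $\kappa = -1$; and the members of
the reference group always average to $\kappa = 0$.

## From time series to graphs

The pipeline follows the standard wavelet-correlation construction of
functional brain graphs:

1. **Regional series.** Voxel signals are averaged per region, each voxel
   weighted by its gray-matter probability (no hard GM threshold: a zero
   weight simply contributes nothing). Nuisance regressors and flagged
   outlier volumes are removed by least squares; outliers are handled by
   spike (indicator) regression rather than deletion because the wavelet
   transform needs uniformly sampled series. A scan fails motion QC when
   more than 12% of its volumes are flagged.
2. **Wavelet correlation.** Each regional series is decomposed with the
   maximal-overlap discrete wavelet transform (MODWT, Daubechies
   least-asymmetric 8-tap filter by default, circular filtering). Scale $j$
   covers the dyadic band $(f_N/2^j,\, f_N/2^{j-1})$ with
   $f_N = 1/(2\,\mathrm{TR})$; the analysis scale is the smallest one whose
   whole band sits at or below 0.1 Hz, where resting-state connectivity
   lives. For TR = 0.72 s that is scale 4 (0.043–0.087 Hz); for TR = 2 s,
   scale 3 (exact dyadic edges 0.03125–0.0625 Hz; we report exact values
   rather than rounded ones). Pairwise Pearson correlations of the detail
   coefficients form the connectivity matrix; the first
   $(2^j - 1)(L - 1)$ boundary-affected coefficients are excluded to avoid
   wrap-around bias.
3. **Cost-thresholded graphs.** Graphs are compared at fixed *cost* — the
   fraction of realized edges among all $N(N-1)/2$ pairs — so every subject
   has the same edge count $M = \mathrm{round}(\mathrm{cost}\cdot
   N(N-1)/2)$ (banker's rounding; no rounding rule is canonical and this
   one is deterministic). The maximum-$|r|$ spanning tree (Prim, ties broken
   lexicographically) is always included so the graph stays connected; the
   remaining edges are the strongest non-tree $|r|$ values, ties again
   lexicographic. The deterministic tie rules buy two properties the tests
   rely on: bit-reproducibility, and monotonicity of edge sets in cost. The
   tree edges count toward $M$, so the total edge count is exactly $M$.
4. **Hemispheres.** Correlations are computed once over the full region
   set; intra-hemispheric analyses take the principal submatrix of one
   hemisphere (midline regions, e.g. the cerebellar vermis, are dropped,
   which is how an 89-region template yields 44-node hemisphere graphs).

The five nodal metrics use their standard unweighted definitions;
betweenness is the raw (unnormalized) sum over unordered pairs, local
efficiency is computed inside the induced neighbor subgraph, and clustering
and local efficiency are defined as 0 for nodes of degree < 2 (their
denominators vanish; this keeps profiles total). Note the clustering
coefficient enters $\kappa_C$ as the *per-node* quantity
$2t_i/(D_i(D_i-1))$, not its whole-graph average. All five implementations
are checked exactly against brute-force BFS/path-enumeration oracles on
hundreds of random graphs.

## Reliability and inference

**ICC(1,1).** Test-retest reliability across sessions uses the one-way
random-effects intraclass correlation
$\mathrm{ICC} = (s_b - s_w)/(s_b + (k-1)s_w)$, where $s_b$ and $s_w$ are
the between- and within-subject *mean squares* of the one-way ANOVA
decomposition and $k$ is the session count. The mean-square reading (rather
than raw variances) is what reproduces the standard ICC(1,1) estimator; it
forces the textbook cases: identical sessions give 1, and a 2×2 design with
pure within-variability gives −1. Negative values are returned as computed
and flagged non-reliable.

**Permutation p-values.** The no-reliability null reassigns the pooled
observations to subject slots at random. P-values use an open-ended
sequential Monte-Carlo procedure: sampling proceeds in batches, and a
Clopper–Pearson confidence sequence (error budget spent geometrically over
looks, default total risk $10^{-3}$) stops as soon as the interval for $p$
lies entirely on one side of the decision threshold. This bounds the
probability that the accept/reject decision differs from the
infinite-sampling one, while spending only as many permutations as the data
demand. A fixed-budget mode with $p = (b+1)/(B+1)$ is the reference
implementation. The p-value is one-sided (high ICC = reliable). The
permutation unit defaults to full cell reassignment, with
session-column shuffling available behind a flag, since the one-way model
treats sessions as interchangeable replicates.

**Group comparison.** Kappa (and global metrics) are compared between
groups with the two-sided Wilcoxon rank-sum test across a grid of costs;
the z statistic uses the normal approximation with tie correction, and
combined samples of at most 12 are enumerated exhaustively (the enumeration
stays valid under ties). Nodal difference maps use a per-node Wilcoxon test
with the $p < 1/N$ false-positive correction ($1/44 \approx 0.023$ per
hemisphere).

**Bootstrap robustness.** Small groups make single Wilcoxon p-values
fragile, and — more fundamentally — scoring a test group against a *fixed
reference group* absorbs that reference group's sampling fluctuation, so
the comparison is not nominally calibrated even for same-population groups
(see below). `bootstrap_robustness()` therefore rebuilds the whole design
repeatedly on a healthy cohort: disjoint reference and test groups are
drawn, test hemispheres assigned to mimic the clinical arm (11 right + 9
left by default), kappa and the group z recomputed per draw. The observed z
is then located in this empirical null, counting the fraction of null z at
or below it (lower tail, since disruption predicts reduced kappa); the raw
proportion is reported together with the $(b+1)/(B+1)$ convention.

## The synthetic cohort

No imaging data ship with the package; a generator produces cohorts with
known ground truth at every level the pipeline touches.

* **Spatial structure.** A two-level target correlation matrix: a fraction
  of nodes (20% by default) are hubs correlated at `hub_corr = 0.5` with
  every node, against a `base_corr = 0.1` background — magnitudes typical
  of scale-3 wavelet correlations in resting-state data. Infeasible targets
  are repaired to the nearest positive-semi-definite correlation matrix
  (Higham projection, with eigenvalue clipping as fallback), and the repair
  is flagged.
* **Disruption.** Patients' contralesional hemisphere attenuates every
  hub-involved correlation toward the background by factor `gamma`
  (`gamma = 1` erases the hub structure), optionally raising periphery
  correlations — the under/over-connectivity mixture seen after stroke.
* **Individual differences.** Each subject-hemisphere carries a stable
  multiplier on hub strength (SD 0.15, shared across sessions) plus a
  diffuse random-correlation blend (weight 0.2). Without such traits,
  repeated sessions would differ only by sampling noise and the true ICC of
  any derived quantity would be zero; the hub-strength component in
  particular puts trait variance *along the gradient that* $\kappa$
  *measures*, which is what makes test-retest reliability a meaningful
  target. With these defaults the ICC of $\kappa_D$ lands in the
  fair-to-good range.
* **Time series.** Gaussian series with the subject's spatial correlation,
  AR(1) temporal structure (lag-1 autocorrelation 0.3, about right for
  BOLD at TR 2 s) at stationary unit variance, plus white observation
  noise (SD 0.5, attenuating correlations by roughly 20%).
* **Defaults as study conditions.** 20 controls + 20 patients, 44 nodes
  per hemisphere, 512 timepoints at TR 2 s (scale 3 selected
  automatically), two sessions, patients split 11 right / 9 left
  contralesional — a desk-scale replica of a small clinical arm plus a
  two-session reliability arm. Every draw is reproducible from
  `(spec, seed)`.

What the generator does *not* emulate: biophysical BOLD dynamics,
spatially structured noise, lesion geometry, inter-hemispheric coupling,
or registration/segmentation artifacts. Passing tests therefore validate
the statistical machinery and its operating characteristics under the
stated covariance model, not performance on real scanner data.

## Calibration: a subtle point worth stating plainly

Which null calibration can be expected from the kappa comparison depends on
the scoring scheme:

* If *every* subject — both groups pooled — is scored against a reference
  that excludes it (the leave-one-out flag), subjects are exchangeable
  under the null and the Wilcoxon comparison is exactly level. This is the
  scheme the package's null-calibration tests exercise (measured rejection
  ~2–5% at nominal 5% over independent cohorts).
* If an external group is scored against a *fixed* reference group (the
  clinical design), all test subjects share the reference group's sampling
  fluctuation: their kappas co-move, and the nominal Wilcoxon level does
  not hold even for same-population groups once between-subject trait
  variance is realistic. This is not an implementation artifact but a
  property of the design; it is precisely why the bootstrap robustness
  stage exists, and why its empirical null z distribution (not a standard
  normal) is the right yardstick for the clinical comparison.

## Numerical and degenerate-input choices

* Constant reference profiles make the slope undefined: error, not NaN.
* A perfect fit reports $R^2$ as `NA` when the difference vector is
  constant (zero total sum of squares).
* Zero-variance wavelet detail series abort with the offending region
  named; an all-identical ICC matrix returns 1 with a warning.
* Degenerate rank-sum comparisons (all values tied) return $p = 1$.
* MODWT requires the series to cover the filter support at the deepest
  scale and errors with the minimum length otherwise; energy is preserved
  exactly (checked to $10^{-10}$), so the variance decomposition across
  scales is an identity, not an approximation.
* Problem sizes in the test suite: oracle checks run on graphs of up to 12
  nodes (where exhaustive enumeration is feasible); full-pipeline
  statistical checks use the default 20+20-subject, 44-node, 512-timepoint
  cohort with 20 seeded replicates for power and 30 independent cohorts
  for calibration.

## Known limitations

* The variance of the reference group is not propagated into kappa; the
  index treats the reference mean profile as fixed.
* Only ICC(1,1) is implemented (the design is one-way by construction);
  F-distribution confidence intervals are not provided — permutation
  p-values take their place.
* Costs below the spanning-tree floor $(N-1)/\binom{N}{2}$ are rejected
  rather than approximated.
* The per-node results table is the final nodal output; cortical surface
  rendering is left to external tools.
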