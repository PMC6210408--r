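---
title: "Global-to-local association of genetic variants with dense landmark shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global-to-local association of genetic variants with dense landmark shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`segcca` tests single genetic variants against multivariate shape phenotypes
measured as dense 3D landmark configurations, hierarchically — from the whole
configuration down to small spatially contiguous patches — across several
cohorts combined by a projection-based round-robin meta-analysis. This
vignette is the package's account of the model, its assumptions, the knobs
that matter, and the choices made where the design was genuinely open.

## The statistical model

Shape enters the analysis as configurations of $L$ landmarks in
correspondence. After generalized Procrustes superimposition (GPA) and
symmetrization, shape and genotype are both residualized on confounders
(age, age$^2$, sex, weight, height, centroid size, four ancestry axes), so
downstream tests see the "reduced model". The genotype is a single additive
predictor: the count of minor alleles, with the phenotype effect assumed
linear in that count. Dominance, interactions and between-cohort effect
heterogeneity are out of scope; the meta-analysis assumes a common effect
direction and lets evidence accumulate (or cancel) across cohorts.

The association test in a segment is canonical correlation analysis between
the segment's retained PC scores ($n \times p$) and the genotype. With a
univariate genotype the canonical correlation equals the multiple
correlation $r$ of the genotype on the PCs, and Wilks'
$\Lambda = 1 - r^2$ is tested with Rao's F approximation (right tail),
which in this univariate-block case is exactly the overall regression F:

$$F = \frac{1-\Lambda}{\Lambda}\,\frac{n - p - 1 - c}{p}
\sim F_{p,\; n - p - 1 - c} .$$

The $-c$ term (the number of residualized confounders, 10 by default) is the
partial-correlation degrees-of-freedom correction: both blocks were
residualized on $c$ covariates, which removes $c$ dimensions of variation
from each. At epidemiological sample sizes the correction is invisible; at
simulation scale ($n = 300$ per cohort) omitting it inflates the null
type-I error from 0.05 to about 0.067, so the package always applies it.

## Round-robin replication and Stouffer combination

Each cohort serves once as discovery: its CCA defines loadings (the PC
combination maximally correlated with the genotype), the other cohorts'
scores are projected onto those loadings, and the resulting univariate trait
is tested against the genotype by linear regression with a one-sided
p-value. Loadings are sign-oriented so the discovery-cohort regression slope
of projected score on genotype is positive; this makes the one-sided
replication test well-defined and the whole procedure invariant to which
allele is labelled minor (recoding flips the loadings and leaves every
p-value unchanged — a property the test suite checks). Each discovery row's
three p-values come from disjoint cohorts, hence are independent under the
null and are combined with unweighted Stouffer
$Z = \sum_i \Phi^{-1}(1-p_i)/\sqrt{k}$; a sample-size-weighted variant
exists behind the `weights` argument but is off by default. P-values are
clamped to $[10^{-300}, 1 - 10^{-16}]$ before the normal-quantile transform.

The three meta p-values of one (SNP, segment) share all three cohorts'
data and are therefore *not* independent; following the method's design this
column-wise dependence is handled by the $\times 3$ factor in the Bonferroni
threshold, not by modelling it.

## Segmentation choices

Landmark covariation is measured by Escoufier's RV coefficient between the
3-column coordinate blocks of landmark pairs, computed on pooled corrected
data (segmentation is done once on all cohorts combined, which also places
all cohorts in one shape space per segment). The published description —
grouping strongly correlated *and connected* vertices by hierarchical
spectral clustering — leaves the graph construction and spectral variant
open. The package's choices:

* **Graph**: edges only between template-adjacent landmark pairs (k-nearest
  neighbour adjacency), weighted by RV (floored at $10^{-6}$ to keep the
  graph connected when RV vanishes). This enforces spatially contiguous
  segments.
* **Bipartition**: normalized Laplacian $I - D^{-1/2} W D^{-1/2}$; sign
  split of the degree-rescaled Fiedler vector; a seeded 2-means on the 2D
  spectral embedding and a balanced median cut are fall-backs; a
  region-growing split in Fiedler order is the last resort. Children are
  repaired to induce connected subgraphs by reassigning stray components.
* **Feasibility**: a child at level $\ell$ of a depth-$D$ tree must keep at
  least $3 \cdot 2^{D-\ell}$ landmarks (3 is the minimum for per-segment
  GPA), otherwise splitting is refused with advice to lower the depth.

Depth 5 gives the canonical 63 segments (32 leaves); the tree is binary by
construction and children always partition their parent.

## Per-segment PCA and parallel analysis

Each segment is re-superimposed by GPA across the pooled individuals and
summarized by PCA of the flattened aligned coordinates. Components are
retained while the observed eigenvalue exceeds the 95th percentile of
eigenvalues from 100 (default) null replicates obtained by permuting each
column independently. Two practical notes:

* Superimposition and symmetrization leave even pure landmark noise
  correlated (symmetrization averages mirrored coordinates; GPA removes six
  rigid degrees of freedom), so parallel analysis legitimately retains many
  components on large segments. Since every per-cohort CCA needs
  $n \gg p$, `run_pipeline()` additionally caps the retained count at
  `floor(min cohort size / 10)` by default (`max_pc`); the cap keeps the
  leading variance directions and rarely matters at real cohort sizes.
* A segment where nothing survives parallel analysis retains one component
  with a warning rather than dropping out of the analysis.

## Multiple-testing correction

The Li–Ji effective number of tests is computed from the eigenvalues
$\lambda_i$ of the absolute-value correlation matrix as
$M_\mathrm{eff} = \sum_i [\,\mathbb{1}(\lambda_i \ge 1) + (\lambda_i -
\lfloor \lambda_i \rfloor)\,]$: once for segments (pairwise RV between
retained PC score blocks) and once for SNPs (pooled additive-code
correlations). The adjusted threshold is
$\alpha / (M_\mathrm{seg} \cdot M_\mathrm{snp} \cdot 3)$; with the
published effective counts (37 segments, 56 variants) this is
$8.04 \times 10^{-6}$.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not raw surface scans. Defaults are the emulated study conditions: three
cohorts of 2297, 1555 and 3566 individuals, a dense symmetric template
(default $L = 200$, configurable; kept desk-scale so the $L \times L$ RV
matrix and spectral splits stay cheap), unit Gaussian landmark noise
(template units are arbitrary lengths of order 50–80 per axis).

* **Template**: points on a smoothly deformed half-ellipsoid dome mirrored
  across $x = 0$, with an exact left/right pairing, a midline set, and a
  connected k-NN adjacency graph.
* **Covariates**: age uniform over a configurable range, sex
  Bernoulli(0.5), height and weight Gaussian with a sex offset, four
  standard-normal ancestry axes. Their shape effects are fixed smooth fields
  (low-order polynomials in the template coordinates), linear in the
  standardized covariate, so the PLS correction can provably remove them.
* **Genotypes**: additive counts drawn as Binomial(2, $f$) — exact
  Hardy–Weinberg proportions.
* **SNP effects**: per-allele displacement fields exactly supported on the
  SNP's landmark set, drawn once per SNP and then projected orthogonal to
  the template's similarity modes (translation, infinitesimal rotations,
  scale) restricted to that support. Without this projection a localized
  constant-direction field is mostly a restricted translation/size mode,
  which superimposition and the centroid-size covariate rightly absorb —
  the planted effect would be attenuated and distorted before the test ever
  saw it. Fields are normalized to unit RMS per-landmark displacement, so
  `effect_size` is per-allele displacement in landmark-noise SD units.
* **Homogeneity**: cohorts differ only in size and random stream; a
  per-cohort noise multiplier exists to exercise heterogeneity but is off
  by default, since the emulated design reports no between-cohort
  heterogeneity and the meta-analysis does not model it.

What the generator does *not* emulate: registration error, missing-data
artifacts, acquisition-system batch effects, linkage disequilibrium between
SNPs (columns are independent unless duplicated by the user). Passing tests
therefore validate the statistical machinery on clean correspondence data,
not robustness to registration pathology.

## Validation experiments and problem sizes

Two experiment functions back the package's empirical claims; both are run
by the test suite and by `scripts/acceptance.R`.

* `calibration_experiment()`: three null cohorts of 300 individuals,
  $L = 200$, depth 5, 63 null SNPs, 50 parallel-analysis replicates. The
  type-I error at 5% is measured over one meta p-value per (SNP, leaf
  segment) — 2016 tests. Leaves are disjoint and SNPs independent, so the
  binomial reference applies; measured over *all* meta p-values the strong
  dependence between nested segments (and between the three discovery rows
  of a pair) makes the empirical rate fluctuate about three times more than
  a binomial check would allow, which says nothing about calibration. The
  sizes were chosen once to keep the experiment within minutes on one CPU.
* `recovery_experiment()`: 20 runs, three cohorts of 500, $L = 64$,
  depth 3, one SNP displacing a 7-landmark contiguous region by 2 noise-SD
  per allele. Checked: the minimum meta p-value falls in a segment
  overlapping the planted region, and the per-allele direction
  reconstructed on the full configuration from the pooled cohorts (through
  the root segment's PC basis) has high cosine similarity with the planted
  field. Because the analysis is performed on symmetrized configurations,
  the comparison target is the symmetrized image of the planted field,
  expressed in the root segment's Procrustes frame.

## Numerical and degenerate-input conventions

* GPA: mean initialized as the arithmetic mean of centred configurations
  (which keeps a reflection-closed input set on a symmetric trajectory, so
  symmetrized output is reflection-invariant to machine precision);
  convergence at $10^{-10}$ RMS change of the mean, 100 iterations max,
  rotations constrained to determinant $+1$.
* PLS residualization uses SIMPLS with z-scored covariates; at the default
  full component count residuals equal OLS residuals ($<10^{-6}$), so the
  correction has a closed-form meaning. Rank-deficient covariate designs
  are refused naming the collinear columns.
* CCA solves the genotype-on-scores regression by QR; monomorphic SNPs and
  $n \le p + 1 + c$ are errors, perfect fits are clamped at
  $\Lambda = 10^{-15}$.
* Li–Ji eigenvalues are clipped at zero and snapped to integers within
  $10^{-8}$ (exact duplicates otherwise leak $1 - \epsilon$ fractional
  parts through the floor function).
* The quality report computes Mahalanobis distances in the PC space holding
  98% of variance (the dense-landmark covariance is singular otherwise);
  the threshold Z > 2 flags for inspection, nothing is dropped
  automatically. A raw-scan missing-data score has no meaning for
  correspondence-format input; input validation rejects non-finite
  coordinates instead.

## Known limitations

* The spectral variant, graph construction and minimum segment size are
  this package's choices; other reasonable choices yield different (equally
  valid) segmentations, so segment identities should be interpreted
  relative to the fitted tree, not as anatomical constants.
* The F approximation's accuracy degrades when retained PCs approach the
  cohort size; the `max_pc` cap guards this, at the cost of discarding
  trailing variance directions in very large segments at small $n$.
* Meta p-values can underflow to exactly 0 for planted effects far above
  realistic sizes; they are reported as computed.
* No LD modelling: the SNP effective count is meaningful only for the
  genotype panel supplied.
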