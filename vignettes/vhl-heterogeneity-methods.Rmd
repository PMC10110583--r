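---
title: "Methods: quantifying intratumoral VHL heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying intratumoral VHL heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhlhet)
```

Most clear cell renal cell carcinomas (ccRCC) lose function of the VHL tumor
suppressor, but the loss is rarely uniform across a tumor. This package
implements three quantitative procedures for measuring that heterogeneity
from generic tabular inputs: (1) purity/ploidy adjustment of bulk copy-number
ratios and variant allele frequencies with clonality classification, (2) a
signal-to-noise statistic that scores genes and gene sets for expression
changes conserved across several VHL-loss comparisons, and (3) spatial
profiling of marker-labeled cell coordinates relative to inferred region
boundaries. A forward simulator for each input layer provides ground truth
for every stage.

## Purity/ploidy adjustment

A bulk tumor sample is modeled as a mixture of tumor cells (fraction `PT`,
tumor purity) and normal cells assumed diploid. With tumor ploidy `PL`, an
observed log2 copy-number ratio `CNR` at a locus implies the tumor copy
number

$$CN_t = \frac{2^{CNR}\,\bigl(2(1-PT) + PL \cdot PT\bigr) - 2(1-PT)}{PT},
\qquad CNR_{adj} = \log_2(CN_t/2),$$

and an observed variant allele frequency is rescaled to the fraction of
tumor-cell gene copies carrying the variant,

$$AF_{adj} = VAF \cdot \frac{PT \cdot CN_t + 2(1-PT)}{PT \cdot CN_t}.$$

The model is exactly invertible: `adjust_copy_number()` and `adjust_vaf()`
recover the simulator's true `CN_t` and mutant-copy fraction to numerical
precision in the zero-noise limit, and `PT = 1, PL = 2` is the identity.
Observations incompatible with the model — an implied `CN_t <= 0`, or a raw
`AF_adj > 1.1` — are flagged `removed_incompatible` rather than silently
truncated; raw `AF_adj` in `(1, 1.1]` is attributed to measurement noise and
clamped to 1 (recorded in the `clamped` flag; the observed VAF is never
modified). These are the only ways the printed equations can leave their
valid ranges, so incompatibility is defined by exactly these conditions.

Samples enter adjustment only after `consensus_purity_filter()`: consensus
purity strictly above 0.4, and — where both an ABSOLUTE-style and an
ESTIMATE-style purity exist — absolute difference strictly below 0.3. All
threshold wordings ("greater than", "less than", "above") are implemented as
strict inequalities, with equality falling to the lower/removed side. When a
sample fails several checks, one reason is recorded with precedence
incomplete > low_purity > disagreement. Whether "complete data" requires the
two method purities in addition to the consensus value is configurable
(`require_both_methods`, default off); the default reflects that the
consensus value is the one actually consumed.

Clonality calls bin the adjusted values: adjusted VAF above 0.9 is a clonal
mutation with loss of heterozygosity, above 0.4 likely clonal, otherwise
subclonal. Copy-loss calls use two reference lines on `CNR_adj`, by default
-1.1 (two-copy loss) and -0.4 (one-copy loss). These lines are *empirical
display references, not model-derived quantities*: under the adjustment, a
fully clonal one-copy loss lands at exactly -1 and a fully clonal two-copy
loss at $-\infty$, so the lines can only mark ranges on real, noisy,
partially subclonal data. They are therefore configurable parameters with
the conventional defaults.

Variant prefiltering without a matched normal keeps calls that are present
in COSMIC, have VEP impact above LOW, and observed VAF above 0.1; a missing
annotation flag conservatively fails its filter. `coding_change_to_protein()`
maps a CDS substitution to its protein label under the standard genetic code
(codon index `ceiling(pos/3)`, offset `((pos-1) mod 3)+1`, 1-based
throughout); the VHL c.506T>C example lands in codon 169 as L169P.

Cohort-level distributions are summarized by `cohort_density()`, a Gaussian
kernel density on a 512-point grid spanning the data range plus three
bandwidths per side. The bandwidth defaults to Silverman's rule of thumb and
is overridable; the reported mode is the grid argmax, so its resolution is
the grid step.

## Conserved-signature scoring

For each feature measured in all `k` comparisons (inner join; features
missing anywhere are excluded and counted), the concordance score is the
signal-to-noise ratio of its log2 fold changes:
$SNR = \bar{x}^2 / s^2$ with the sample variance (`k - 1` denominator) in
the denominator. The statistic is invariant to comparison order, global sign
flips, and positive rescaling. Zero-variance features are handled with a
variance floor (default `1e-8`) rather than infinities so the ordering stays
total and serializable. Direction is reported separately as the sign of the
mean, since the score itself is direction-blind. Top-`k` selection breaks
ties by larger absolute mean effect, then feature id, making output
deterministic. The identical code path scores gene-level log2FC matrices and
gene-set NES matrices.

Two properties of this statistic deserve explicit statement. First, with
`k = 3` its null distribution is heavy-tailed: for pure-noise features,
$3\,\bar{x}^2/s^2$ is F(1, 2)-distributed, whose survival function decays
only polynomially, so in a large feature set a nontrivial share of null
features always reaches the score range of genuinely concordant features.
On the simulated study the test suite runs (10,000 features, 200 planted
with effect 2, noise sd 0.3, three comparisons), top-200 selection recovers
about 65% of the planted set — and this plateaus rather than approaching
100% as the effect grows. Selection sensitivity does increase monotonically
with effect size (a property the suite checks over an effect grid), but the
statistic's null tail bounds what any top-`k` cut can achieve at `k = 3`
comparisons. Users wanting higher specificity should add comparisons or
combine the score with an effect-size threshold. Second, the heatmap
preparation z-scales columns *before* Ward clustering (scale-then-cluster):
the display scaling and the dissimilarities then agree, at the cost of
clustering being performed on the scaled space. `ward_leaf_order()` uses
Ward's minimum-variance criterion on Euclidean distances; the suite verifies
its leaf order against an exhaustive error-sum-of-squares merge enumeration
at small `n`.

The pre-ranked GSEA metric is `sign(log2FC) * (-log10 p)`, falling back to
the log2 fold change itself where no p-value could be computed (`p = 1` maps
to 0). The sign-from-log2FC convention is the standard pre-ranked practice;
the alternative literal reading (`sign * log10 p`, all-negative magnitudes)
would destroy the ranking's meaning. Single-cell QC keeps cells with total
counts > 2000, expressed genes > 1000 and mitochondrial percentage < 20,
all strict.

## Spatial profiling

Inputs are already-classified cell centroids in micrometers with logical
marker columns — the export of an image-analysis platform, not images. The
pipeline mirrors a HALO-style infiltration analysis whose proprietary
internals are not public; what is implemented is the described logic, not a
pixel-level reproduction.

Marker-positive cells are binned onto a 100 µm grid and smoothed with an
isotropic Gaussian kernel (sd 200 µm, truncated at 4 sd). Region boundaries
are iso-contours of the smoothed density at a configurable fraction of its
maximum (default 0.2); the grid is padded with a zero ring so contours
always close, and components below a minimum area (default one grid cell)
are discarded and counted. Because the kernel spreads mass outward, the
inferred boundary sits slightly outside the true point support — on a
simulated 1800 µm disc the recovered area is high by roughly 15–20%. This
bias shifts signed distances by an approximately constant offset and
therefore cancels in quantities that depend on distance *differences*, such
as the exponential decay length below.

Signed distance to the boundary is the Euclidean distance to the nearest
polygon edge, negative inside the region ("toward the inside" of the
marker-positive area). The infiltration profile counts target-positive
cells in contiguous distance bands (defaults: 500 µm bands from 2000 µm
inside to 4000 µm outside, truncating the outermost band if the width does
not divide the extent) and divides by each band's geometric area. Band
areas are computed by numerical integration — signed distance evaluated at
the centers of a fine grid (default 100 µm) over the analysis window —
rather than polygon buffering, which keeps the area definition exact with
respect to the same distance function the counts use. The analysis window
defaults to the bounding box of all cells expanded by the outer extent; when
the true tissue mask is known (as for simulated tissue) it should be passed
explicitly, because an empty margin in the window deflates outer-band
densities and biases any decay fit. Band counts plus the logged out-of-band
count always equal the number of positive cells, and the profile is
invariant under rigid motions of all coordinates.

On a simulated tissue whose infiltrating phenotype decays as
$\lambda(d) = \lambda_0 e^{-d/\tau}$ outside the region,
`fit_infiltration_decay()` (log-linear least squares on the outside bands)
recovers $\tau = 1000$ µm within a few percent — run
`analysis/04_spatial_profiles.R` for the exact numbers.

Co-exclusion of two phenotypes (conjunctions of marker states, e.g.
VHL+POSTN- vs VHL-POSTN+) is summarized as the Spearman rank correlation of
the two per-band density vectors over the same bands; strongly negative
values mean the phenotypes occupy opposite sides of the interface. Equal-
width distance bands are used (the natural reading of evenly divided areas;
equal-area binning is a possible alternative and the band width is
configurable). One caveat governs interpretation: when the phenotypes are
*perfectly* segregated the vector for each phenotype contains a block of
exactly-zero bands, and tied ranks cap the average-rank Spearman statistic
near -0.85 rather than -1. Graded, interdigitated distributions — the
realistic tissue situation — reach -1. The permutation null
(`co_exclusion_null()`, default 999 relabelings of the pooled cells) should
be read carefully too: random relabeling of a pooled point set produces two
subsamples of the *same* spatial distribution, so the null concentrates
near +1 whenever the pooled density varies across bands, and around 0 only
for spatially uniform phenotypes. A co-excluded pair falls far below the
null range in either case.

## Synthetic data: what it emulates and what it does not

`simulate_tumor_cohort()` draws per-sample purity from a Beta(2, 2)
distribution rescaled to [0.3, 0.9] — mid-heavy, spanning the range where
purity correction matters but samples mostly pass the 0.4 filter — and
ploidy from a normal distribution centered at 2 (sd 0.15, truncated to
[1.5, 3.5]), reflecting the near-diploid character of most ccRCC. The
default clonal architecture is a clonal one-copy VHL loss with the retained
copy mutated in 70% of tumor cells: the copy-number signal is clonal (true
`CNR_adj` exactly -1, between the two reference lines) while the mutation is
subclonal (true adjusted VAF 0.7), matching the qualitative picture of a
wide adjusted-VAF spectrum over a near-universal single-copy loss. Noise is
additive Gaussian on the observed CNR (sd 0.15) and on the observed VAF
(sd 0.03, truncated to [0, 1]); this is the simplest model that supports
recovery testing, not a sequencing error model — read-depth binomial
sampling is the natural extension and deliberately out of scope. Because
`2^noise` enters the copy-number inversion, the adjusted `CN_t` estimator
carries a small Jensen bias at large noise; the suite's unbiasedness check
(mean error within 2 standard errors over 1000 samples) is run at noise sd
0.05 where the bias is negligible.

Cohorts with planted filter violations condition the background purity draw
above the filter thresholds (e.g. range [0.45, 0.9]) so the planted counts
are exact ground truth; the low-purity, disagreement and incompatible-VAF
classes are kept disjoint, and planted incompatible samples get purities in
[0.45, 0.6] so that an observed VAF at most 1 can push the adjusted value
above the 1.1 clamp window.

`simulate_concordance_study()` gives planted features one fixed signed
effect shared across all comparisons plus iid noise; p-values come from the
monotone map `2 * pnorm(-|log2fc| / noise_sd)`, consistent with the noise
model without any fitting. `simulate_tissue()` samples each phenotype as an
inhomogeneous Poisson process by thinning a homogeneous process at the
phenotype's maximum intensity (with a 5% safety factor over a 50 µm grid
bound, so the bound is conservative even between grid points); intensities
are arbitrary functions of the signed distance to disc-shaped regions.

None of the simulators attempt realism beyond these declared features:
there is no segmentation noise or focal-event structure in copy number, no
gene-gene correlation in the expression studies, and no cell-size exclusion
or tissue-boundary effects in the point patterns. Passing tests demonstrate
that the estimators invert their own declared forward models at the stated
noise levels — not that they are robust to artifacts these models omit.

## Problem sizes and determinism

The test suite and analysis scripts use a 459-sample main cohort (matching
the cohort size the adjustment is designed around), a 500-sample planted
cohort, 10,000-feature expression studies, and tissues of roughly 30–60
thousand cells in 8–9 mm windows — sizes at which every stage completes in
seconds while leaving Monte-Carlo fluctuations small relative to the tested
tolerances. All randomness flows through explicit seeds: identical spec and
seed give byte-identical simulator output, and `run_pipeline()` writes a
manifest of input/output MD5 hashes that reproduces exactly under rerun.

## Known limitations

* The copy-loss reference lines are conventions on noisy data; they do not
  follow from the adjustment model (see above) and should not be read as
  estimated breakpoints.
* Boundary inference has a smoothing-scale bias (area overestimated by
  roughly the kernel bandwidth); offset-invariant quantities are unaffected,
  absolute areas and distances are.
* Region polygons are simple closed curves; holes (a negative region inside
  a positive one) are treated as separate polygons by the contour extractor
  and signed distance uses even-odd containment per polygon, so deeply
  nested geometries are not supported.
* The SNR concordance statistic's heavy null tail at small `k` bounds
  top-`k` recovery (see the concordance section); this is a property of the
  statistic, not of the implementation.
* Per-gene copy number assumes one `CN_t` per (sample, gene); overlapping
  segments must be resolved to gene level upstream.
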