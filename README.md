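# vhlhet

Quantifying intratumoral heterogeneity of VHL loss in clear cell renal cell
carcinoma (ccRCC) from three kinds of evidence: bulk genomics, multi-model
expression comparisons, and spatial cell coordinates.

Most ccRCC tumors inactivate the VHL tumor suppressor, but the loss is often
*heterogeneous*: VHL-expressing and VHL-deficient cells coexist within one
tumor, and their interaction — rather than either population alone — drives
metastatic behavior. Detecting that heterogeneity quantitatively requires
three computations that this package implements as tested, reusable
functions:

1. **Purity/ploidy adjustment and clonality calls** (`adjust_copy_number()`,
   `adjust_vaf()`, `classify_*()`). A bulk sample mixes tumor cells
   (purity `PT`, ploidy `PL`) with diploid normal cells. The observed log2
   copy-number ratio `CNR` and variant allele frequency `VAF` are corrected
   to tumor-intrinsic quantities:

   ```
   CN_t    = (2^CNR * (2(1-PT) + PL*PT) - 2(1-PT)) / PT
   CNR_adj = log2(CN_t / 2)
   AF_adj  = VAF * (PT*CN_t + 2(1-PT)) / (PT*CN_t)
   ```

   Adjusted VAF above 0.4 indicates a likely clonal mutation, above 0.9 a
   clonal mutation with loss of heterozygosity; adjusted CNR is read against
   reference lines at -1.1 (two-copy loss) and -0.4 (one-copy loss). Sample
   filters (consensus purity > 0.4, |ABSOLUTE - ESTIMATE| < 0.3), the VAF
   clamp for raw values in (1, 1.1], incompatible-record removal, and
   COSMIC/VEP/VAF variant prefilters are included, as is the codon-level
   mapping of coding changes (VHL c.506T>C -> L169P).

2. **Conserved-signature scoring** (`snr_concordance()`,
   `select_top_concordant()`). Genes (or gene sets) measured across k
   VHL-loss comparisons are ranked by the signal-to-noise ratio of their
   log2 fold changes — squared mean over sample variance — selecting effects
   that are reproducibly consistent across models. Helpers prepare the
   display matrix (column z-scaling, Ward minimum-variance leaf order) and
   a signed -log10(p) pre-ranked GSEA metric.

3. **Spatial infiltration and co-exclusion** (`infer_region_boundary()`,
   `infiltration_profile()`, `co_exclusion_profile()`). From marker-labeled
   cell centroids (µm), the package infers marker-positive region boundaries
   as iso-contours of a Gaussian-smoothed density, bins cells by signed
   distance to the boundary (negative = inside), area-normalizes the counts,
   and scores two-phenotype co-exclusion as the Spearman correlation of
   their band-density profiles (with a permutation null).

A fourth module simulates all three input layers with known ground truth
(`simulate_tumor_cohort()`, `simulate_concordance_study()`,
`simulate_tissue()`), so every estimator can be checked against the
parameters that generated its input.

## Worked example

A sample with 65% tumor purity, ploidy 2.1, an observed VHL log2 CNR of
-0.32 and an observed VAF of 0.38:

```r
library(vhlhet)

adjust_copy_number(cnr = -0.32, purity = 0.65, ploidy = 2.1)
#>       cn_t   cnr_adj status
#> 1 1.468014 -0.446134     ok

adjust_vaf(vaf = 0.38, purity = 0.65, cn_t = 1.468014)
#>      af_adj clamped status
#> 1 0.6587649   FALSE     ok
```

The observed ratio -0.32 looks like a shallow loss, but after removing the
diploid normal signal the tumor carries about 1.47 copies of VHL
(`CNR_adj = -0.45`, in the one-copy-loss range: a subclonal single-copy
loss), and the mutation sits on about 66% of tumor gene copies
(`classify_variant_clonality(0.6587649)` -> `likely_clonal`, i.e. clonal in
a majority subpopulation but not with LOH).

The analysis scripts chain these steps on simulated cohorts; running

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_adjust_and_classify.R
Rscript analysis/03_signature_concordance.R
Rscript analysis/04_spatial_profiles.R
```

prints, among other things:

```
adjusted-CNR density peak: -1.009 (reference lines: -1.1 two-copy, -0.4 one-copy loss)
VHL c.506T>C maps to codon 169: L169P
planted cohort removals: low_purity=37 disagreement=12 incompatible_vaf=5
top-200 selection recovers 64.5% of the 200 planted genes
infiltration decay: tau = 1013 um (true 1000, error 1.3%)
co-exclusion overlap statistic (Spearman over 9 bands): -0.983
```

i.e. a 459-sample cohort with a planted clonal one-copy VHL loss peaks
between the two reference lines after adjustment; filter bookkeeping on a
planted cohort is exact; the infiltration decay length and the co-exclusion
signal are recovered from simulated tissue; and conserved-signature recovery
is bounded by the heavy null tail of the three-comparison SNR statistic
(see the methods vignette, `vignettes/vhl-heterogeneity-methods.Rmd`).

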