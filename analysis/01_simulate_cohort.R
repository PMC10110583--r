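#!/usr/bin/env Rscript
# Simulates the two synthetic cohorts used by the downstream analyses and
# writes their input tables under results/cohort/:
#   - a TCGA-KIRC-sized cohort (459 samples) carrying a clonal one-copy VHL
#     loss with a subclonal point mutation on the retained copy;
#   - a 500-sample cohort with planted filter violations (37 low-purity,
#     12 purity-method disagreement, 5 incompatible adjusted VAF) for
#     bookkeeping checks.

library(vhlhet)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

main <- simulate_tumor_cohort(cohort_spec(seed = 459))
write_tsv(main$purity, file.path(out, "main_purity.tsv"))
write_tsv(main$copy_number, file.path(out, "main_copy_number.tsv"))
write_tsv(main$variants, file.path(out, "main_variants.tsv"))
write_tsv(main$truth, file.path(out, "main_truth.tsv"))
cat(sprintf("main cohort: %d samples, true CN_t = %.2f, true AF = %.2f\n",
            nrow(main$purity), main$truth$cn_t[1], main$truth$af_true[1]))

planted <- simulate_tumor_cohort(cohort_spec(
  n_samples = 500, purity_range = c(0.45, 0.9),
  clones = data.frame(fraction = 1, copies_lost = 0,
                      mutation_present = TRUE, mutant_copies = 1),
  n_low_purity = 37, n_disagreement = 12, n_incompatible = 5, seed = 500))
write_tsv(planted$purity, file.path(out, "planted_purity.tsv"))
write_tsv(planted$copy_number, file.path(out, "planted_copy_number.tsv"))
write_tsv(planted$variants, file.path(out, "planted_variants.tsv"))
write_tsv(planted$truth, file.path(out, "planted_truth.tsv"))
cat(sprintf("planted cohort: %d samples (%d low purity, %d disagreement, %d incompatible VAF)\n",
            nrow(planted$purity),
            sum(planted$truth$planted == "low_purity"),
            sum(planted$truth$planted == "disagreement"),
            sum(planted$truth$planted == "incompatible_vaf")))
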