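test_that("purity filter keeps and removes samples with the right reasons", {
  purity <- data.frame(
    sample_id = c("low", "disagree", "ok", "incomplete"),
    purity_absolute = c(0.5, 0.8, 0.62, 0.7),
    purity_estimate = c(0.5, 0.45, 0.58, 0.7),
    purity_consensus = c(0.35, 0.6, 0.6, NA),
    ploidy = 2)
  res <- consensus_purity_filter(purity)
  expect_equal(res$kept$sample_id, "ok")
  expect_equal(res$removed$reason[res$removed$sample_id == "low"],
               "low_purity")
  expect_equal(res$removed$reason[res$removed$sample_id == "disagree"],
               "disagreement")
  expect_equal(res$removed$reason[res$removed$sample_id == "incomplete"],
               "incomplete")
})

test_that("purity filter thresholds are strict and inputs validated", {
  at_threshold <- data.frame(sample_id = c("a", "b"),
                             purity_absolute = c(0.5, 0.8),
                             purity_estimate = c(0.5, 0.5),
                             purity_consensus = c(0.4, 0.6), ploidy = 2)
  res <- consensus_purity_filter(at_threshold)
  # purity exactly at 0.4 is not "greater than 0.4"; diff exactly 0.3 is not
  # "less than 0.3"
  expect_setequal(res$removed$sample_id, c("a", "b"))
  expect_error(consensus_purity_filter(
    data.frame(sample_id = "x", purity_consensus = NaN, ploidy = 2)),
    "non-finite")
  expect_error(consensus_purity_filter(
    data.frame(sample_id = "x", purity_consensus = 1.2, ploidy = 2)),
    "outside")
  # missing method columns: only consensus is required by default
  res2 <- consensus_purity_filter(
    data.frame(sample_id = "x", purity_consensus = 0.6, ploidy = 2))
  expect_equal(nrow(res2$kept), 1)
  res3 <- consensus_purity_filter(
    data.frame(sample_id = "x", purity_consensus = 0.6, ploidy = 2),
    require_both_methods = TRUE)
  expect_equal(res3$removed$reason, "incomplete")
})

test_that("copy-number adjustment matches the forward-model oracle", {
  # copy-neutral diploid is a fixed point
  r <- adjust_copy_number(0, 0.7, 2)
  expect_equal(r$cn_t, 2)
  expect_equal(r$cnr_adj, 0)
  # frozen values from inverting the forward model at CN_t = 1 and 2
  r <- adjust_copy_number(-0.415037, 0.5, 2)
  expect_equal(r$cn_t, 1, tolerance = 1e-5)
  expect_equal(r$cnr_adj, -1, tolerance = 1e-5)
  r <- adjust_copy_number(-0.378512, 0.6, 3)
  expect_equal(r$cn_t, 2, tolerance = 1e-5)
  expect_equal(r$cnr_adj, 0, tolerance = 1e-5)
  # recompute the same cases live from the oracle
  for (case in list(c(1, 0.5, 2), c(2, 0.6, 3), c(3, 0.8, 2.5))) {
    r <- adjust_copy_number(forward_cnr(case[1], case[2], case[3]),
                            case[2], case[3])
    expect_equal(r$cn_t, case[1], tolerance = 1e-9)
  }
  # implied negative tumor copy number is incompatible
  r <- adjust_copy_number(-4, 0.9, 2)
  expect_true(r$cn_t < 0)
  expect_equal(r$status, "removed_incompatible")
  expect_true(is.na(r$cnr_adj))
  expect_error(adjust_copy_number(0, 0, 2), "purity")
})

test_that("VAF adjustment scales, clamps and removes as specified", {
  expect_equal(adjust_vaf(0.37, 1, 2)$af_adj, 0.37)   # pure tumor identity
  expect_equal(adjust_vaf(0.25, 0.5, 2)$af_adj, 0.5)
  r <- adjust_vaf(0.525, 0.5, 2)                      # raw 1.05 -> clamp
  expect_equal(r$af_adj, 1)
  expect_true(r$clamped)
  expect_equal(r$status, "ok")
  r <- adjust_vaf(0.6, 0.5, 2)                        # raw 1.2 -> removed
  expect_true(is.na(r$af_adj))
  expect_equal(r$status, "removed_incompatible")
  expect_error(adjust_vaf(0.5, 0.5, 0), "cn_t")
  expect_error(adjust_vaf(1.2, 0.5, 2), "vaf")
})

test_that("adjustment round-trips the forward model and preserves order", {
  set.seed(42)
  n <- 500
  pt <- runif(n, 0.05, 1)
  pl <- runif(n, 1, 6)
  cn <- runif(n, 0.1, 8)
  af <- runif(n)
  adj <- adjust_copy_number(forward_cnr(cn, pt, pl), pt, pl)
  expect_true(all(abs(adj$cn_t - cn) < 1e-9))
  v <- adjust_vaf(forward_vaf(af, pt, cn), pt, cn)
  expect_true(all(abs(v$af_adj - af) < 1e-9))
  # identity limits: PT = 1, PL = 2 leaves both observations unchanged
  # (up to one ulp through the 2^x / log2 round trip)
  cnr <- runif(20, -2, 2)
  expect_lt(max(abs(adjust_copy_number(cnr, 1, 2)$cnr_adj - cnr)), 1e-12)
  vaf <- runif(20)
  expect_identical(adjust_vaf(vaf, 1, 2)$af_adj, vaf)
  # monotonicity in the observation at fixed purity/ploidy
  grid <- seq(-1, 1, length.out = 50)
  expect_true(all(diff(adjust_copy_number(grid, 0.6, 2.4)$cn_t) > 0))
  vgrid <- seq(0, 0.4, length.out = 50)
  expect_true(all(diff(adjust_vaf(vgrid, 0.6, 2)$af_adj) > 0))
  # a clonal heterozygous mutation reads out at 0.5 regardless of purity
  for (pt1 in c(0.2, 0.5, 0.9, 1))
    expect_equal(adjust_vaf(forward_vaf(0.5, pt1, 2), pt1, 2)$af_adj, 0.5,
                 tolerance = 1e-9)
})

test_that("clonality calls partition their domains with strict thresholds", {
  expect_equal(as.character(classify_variant_clonality(0.95)),
               "clonal_with_LOH")
  expect_equal(as.character(classify_variant_clonality(0.5)),
               "likely_clonal")
  expect_equal(as.character(classify_variant_clonality(0.35)), "subclonal")
  # equality at a threshold goes to the lower category
  expect_equal(as.character(classify_variant_clonality(c(0.4, 0.9))),
               c("subclonal", "likely_clonal"))
  expect_error(classify_variant_clonality(1.2), "af_adj")
  calls <- classify_variant_clonality(seq(0, 1, by = 0.01))
  expect_false(any(is.na(calls)))     # every value gets exactly one class

  expect_equal(as.character(classify_copy_loss(c(-1.2, -0.7, 0))),
               c("two_copy_loss_range", "one_copy_loss_range",
                 "neutral_or_gain"))
  expect_equal(as.character(classify_copy_loss(c(-1.1, -0.4))),
               c("two_copy_loss_range", "one_copy_loss_range"))
  loss <- classify_copy_loss(seq(-3, 2, by = 0.05))
  expect_false(any(is.na(loss)))
  expect_error(classify_copy_loss(NA_real_), "finite")
  expect_error(classify_copy_loss(0, two_copy_line = -0.2,
                                  one_copy_line = -0.4), "below")
})

test_that("annotation filter requires COSMIC, impact above LOW and VAF", {
  v <- data.frame(
    id = 1:6,
    in_cosmic = c(FALSE, TRUE, TRUE, TRUE, NA, TRUE),
    vep_impact = c("HIGH", "LOW", "MODERATE", "HIGH", "HIGH", NA),
    vaf = c(0.3, 0.3, 0.3, 0.05, 0.3, 0.3))
  res <- filter_annotated_variants(v)
  expect_equal(res$kept$id, 3)
  reasons <- res$dropped$reason[order(res$dropped$id)]
  expect_equal(reasons, c("not_in_cosmic", "low_impact", "low_vaf",
                          "not_in_cosmic", "low_impact"))
  # VAF exactly at the threshold fails ("greater than 0.1")
  res <- filter_annotated_variants(
    data.frame(in_cosmic = TRUE, vep_impact = "HIGH", vaf = 0.1))
  expect_equal(nrow(res$kept), 0)
  expect_error(filter_annotated_variants(
    data.frame(in_cosmic = TRUE, vep_impact = "SEVERE", vaf = 0.3)),
    "vep_impact")
})

test_that("coding changes map to protein substitutions", {
  r <- coding_change_to_protein(506, "T", "C", "CTG")
  expect_equal(r$codon_index, 169)
  expect_equal(r$label, "L169P")
  r <- coding_change_to_protein(3, "G", "A", "ATG")
  expect_equal(r$codon_index, 1)
  expect_equal(r$label, "M1I")
  # synonymous: CTA and CTG are both leucine
  r <- coding_change_to_protein(6, "A", "G", "CTA")
  expect_equal(r$codon_index, 2)
  expect_equal(r$label, "L2=")
  expect_error(coding_change_to_protein(506, "G", "C", "CTG"),
               "coordinate inconsistency")
  expect_error(coding_change_to_protein(0, "T", "C", "CTG"), "positive")
})

test_that("cohort density peaks, integrates and locates modes correctly", {
  d <- cohort_density(rep(-0.7, 10), bandwidth = 0.1)
  grid_step <- diff(d$grid$x[1:2])
  expect_lt(abs(d$peak - -0.7), grid_step)
  set.seed(1)
  vals <- rnorm(500)
  vals <- c(vals, -vals)              # exactly symmetric about 0
  d <- cohort_density(vals)
  expect_equal(d$peak, 0, tolerance = 0.15)
  # trapezoid integral within 1e-3 of 1
  integral <- sum(diff(d$grid$x) *
                    (head(d$grid$density, -1) + tail(d$grid$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  set.seed(99)
  d <- cohort_density(rnorm(1000, -0.7, 0.1))
  expect_gt(d$peak, -0.75)
  expect_lt(d$peak, -0.65)
  expect_error(cohort_density(1), "at least 2")
})
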