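#' Filter a cohort on consensus purity and purity-method agreement
#'
#' Samples enter downstream purity/ploidy adjustment only when their purity is
#' known with some confidence. A sample is kept when (i) its consensus purity
#' and ploidy are present and finite, (ii) consensus purity exceeds
#' \code{min_purity}, and (iii) where both an ABSOLUTE-style and an
#' ESTIMATE-style purity are available, the two agree to within
#' \code{max_disagreement}. All inequalities are strict.
#'
#' @param purity data.frame with columns \code{sample_id},
#'   \code{purity_consensus}, \code{ploidy} and optionally
#'   \code{purity_absolute}, \code{purity_estimate}. Purities are fractions in
#'   \[0, 1\]; missing values are allowed in the two method columns.
#' @param min_purity minimum consensus purity (default 0.4); samples at or
#'   below this value are removed.
#' @param max_disagreement maximum allowed |purity_absolute - purity_estimate|
#'   (default 0.3); the check applies only when both values are present.
#' @param require_both_methods if \code{TRUE}, samples missing either method
#'   purity are removed as incomplete (default \code{FALSE}: only the consensus
#'   value and ploidy are required).
#'
#' @return list with elements \code{kept} (data.frame of passing samples) and
#'   \code{removed} (data.frame of failing samples with a \code{reason} column:
#'   \code{"incomplete"}, \code{"low_purity"} or \code{"disagreement"}; when a
#'   sample fails several checks the first in that order is recorded).
#' @export
consensus_purity_filter <- function(purity, min_purity = 0.4,
                                    max_disagreement = 0.3,
                                    require_both_methods = FALSE) {
  purity <- as.data.frame(purity)
  need <- c("sample_id", "purity_consensus", "ploidy")
  miss <- setdiff(need, names(purity))
  if (length(miss))
    stop("purity table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"purity_absolute" %in% names(purity)) purity$purity_absolute <- NA_real_
  if (!"purity_estimate" %in% names(purity)) purity$purity_estimate <- NA_real_

  for (col in c("purity_consensus", "purity_absolute", "purity_estimate")) {
    v <- purity[[col]]
    if (any(is.nan(v) | is.infinite(v)))
      stop("non-finite values in column '", col, "'")
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("purity values in '", col, "' outside [0, 1]")
  }
  if (any(is.nan(purity$ploidy) | is.infinite(purity$ploidy)))
    stop("non-finite values in column 'ploidy'")
  if (any(purity$ploidy <= 0, na.rm = TRUE))
    stop("ploidy must be positive")

  incomplete <- is.na(purity$purity_consensus) | is.na(purity$ploidy)
  if (require_both_methods)
    incomplete <- incomplete | is.na(purity$purity_absolute) |
      is.na(purity$purity_estimate)
  low <- !is.na(purity$purity_consensus) &
    purity$purity_consensus <= min_purity
  both <- !is.na(purity$purity_absolute) & !is.na(purity$purity_estimate)
  disagree <- both &
    abs(purity$purity_absolute - purity$purity_estimate) >= max_disagreement

  reason <- rep(NA_character_, nrow(purity))
  reason[disagree] <- "disagreement"
  reason[low] <- "low_purity"           # higher precedence overwrites
  reason[incomplete] <- "incomplete"
  removed <- purity[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(kept = purity[is.na(reason), , drop = FALSE], removed = removed)
}

#' Adjust observed copy-number ratios for tumor purity and ploidy
#'
#' Converts observed log2 copy-number ratios (tumor vs. diploid reference,
#' measured on a purity/ploidy-confounded bulk) into tumor copy numbers under
#' the assumption that the contaminating normal cells are diploid:
#' \deqn{CN_t = \frac{2^{CNR}(2(1-PT) + PL \cdot PT) - 2(1-PT)}{PT}}
#' \deqn{CNR_{adj} = \log_2(CN_t / 2)}
#' where \eqn{PT} is tumor purity and \eqn{PL} tumor ploidy. Observations whose
#' implied tumor copy number is non-positive cannot arise under the model and
#' are flagged \code{removed_incompatible}.
#'
#' @param cnr numeric vector of observed log2 copy-number ratios.
#' @param purity tumor purity in (0, 1], recycled against \code{cnr}.
#' @param ploidy tumor ploidy (> 0), recycled.
#'
#' @return data.frame with columns \code{cn_t}, \code{cnr_adj} (NA when
#'   \code{cn_t <= 0}) and \code{status} (\code{"ok"} or
#'   \code{"removed_incompatible"}).
#' @export
adjust_copy_number <- function(cnr, purity, ploidy) {
  if (any(!is.finite(cnr))) stop("cnr must be finite")
  if (any(!is.finite(purity)) || any(purity <= 0) || any(purity > 1))
    stop("purity must be in (0, 1]")
  if (any(!is.finite(ploidy)) || any(ploidy <= 0))
    stop("ploidy must be > 0")
  n <- max(length(cnr), length(purity), length(ploidy))
  cnr <- rep_len(cnr, n); purity <- rep_len(purity, n)
  ploidy <- rep_len(ploidy, n)

  cn_t <- (2^cnr * (2 * (1 - purity) + ploidy * purity) - 2 * (1 - purity)) /
    purity
  ok <- cn_t > 0
  cnr_adj <- ifelse(ok, log2(cn_t / 2), NA_real_)
  data.frame(cn_t = cn_t, cnr_adj = cnr_adj,
             status = ifelse(ok, "ok", "removed_incompatible"),
             stringsAsFactors = FALSE)
}

#' Adjust observed variant allele frequencies for purity and local copy number
#'
#' Rescales an observed VAF to the fraction of tumor-cell gene copies carrying
#' the variant, given tumor purity and the (already purity/ploidy-adjusted)
#' tumor copy number at the locus:
#' \deqn{AF_{adj} = VAF \cdot \frac{PT \cdot CN_t + 2(1-PT)}{PT \cdot CN_t}}
#' Adjusted values landing just above 1 (in (1, 1.1\]) are attributed to
#' measurement noise and clamped to 1; values above 1.1 are incompatible with
#' the model and flagged for removal. The observed VAF is never modified.
#'
#' @param vaf numeric vector of observed variant allele frequencies in \[0, 1\].
#' @param purity tumor purity in (0, 1], recycled.
#' @param cn_t tumor copy number at the locus (> 0), recycled.
#' @param clamp_max upper end of the clamp window (default 1.1).
#'
#' @return data.frame with columns \code{af_adj} (NA when removed),
#'   \code{clamped} (logical) and \code{status}.
#' @export
adjust_vaf <- function(vaf, purity, cn_t, clamp_max = 1.1) {
  if (any(!is.finite(vaf)) || any(vaf < 0) || any(vaf > 1))
    stop("vaf must be in [0, 1]")
  if (any(!is.finite(purity)) || any(purity <= 0) || any(purity > 1))
    stop("purity must be in (0, 1]")
  if (any(!is.finite(cn_t)) || any(cn_t <= 0))
    stop("cn_t must be > 0 (incompatible copy-number records must be removed first)")
  n <- max(length(vaf), length(purity), length(cn_t))
  vaf <- rep_len(vaf, n); purity <- rep_len(purity, n)
  cn_t <- rep_len(cn_t, n)

  raw <- vaf * (purity * cn_t + (1 - purity) * 2) / (purity * cn_t)
  clamped <- raw > 1 & raw <= clamp_max
  removed <- raw > clamp_max
  af_adj <- ifelse(removed, NA_real_, ifelse(clamped, 1, raw))
  data.frame(af_adj = af_adj, clamped = clamped,
             status = ifelse(removed, "removed_incompatible", "ok"),
             stringsAsFactors = FALSE)
}

#' Classify variant clonality from adjusted allele frequency
#'
#' Bins the purity/ploidy-adjusted allele frequency into the three clonality
#' classes used for driver-mutation interpretation: values above 0.9 indicate a
#' clonal mutation combined with loss of heterozygosity, values above 0.4 a
#' likely clonal mutation, anything else a subclonal mutation. Thresholds are
#' strict ("above"), so equality falls into the lower category.
#'
#' @param af_adj adjusted allele frequencies in \[0, 1\].
#' @param likely_clonal_min threshold for likely clonal calls (default 0.4).
#' @param loh_min threshold for clonal-with-LOH calls (default 0.9).
#'
#' @return factor with levels \code{subclonal}, \code{likely_clonal},
#'   \code{clonal_with_LOH}.
#' @export
classify_variant_clonality <- function(af_adj, likely_clonal_min = 0.4,
                                       loh_min = 0.9) {
  if (any(!is.finite(af_adj)) || any(af_adj < 0) || any(af_adj > 1))
    stop("af_adj must be in [0, 1]")
  out <- ifelse(af_adj > loh_min, "clonal_with_LOH",
                ifelse(af_adj > likely_clonal_min, "likely_clonal",
                       "subclonal"))
  factor(out, levels = c("subclonal", "likely_clonal", "clonal_with_LOH"))
}

#' Classify copy-loss status from adjusted copy-number ratio
#'
#' Bins adjusted log2 copy-number ratios against two empirical reference lines:
#' values at or below \code{two_copy_line} fall in the two-copy-loss range,
#' values between the two lines in the one-copy-loss range, and the rest are
#' copy-neutral or gained. The default lines (-1.1, -0.4) are the reference
#' values used for the VHL locus; they are display/interpretation conventions,
#' not quantities derived from the adjustment model (a fully clonal one-copy
#' loss adjusts to exactly -1, a fully clonal two-copy loss to -Inf).
#'
#' @param cnr_adj adjusted log2 copy-number ratios (finite).
#' @param two_copy_line reference line for two-copy loss (default -1.1).
#' @param one_copy_line reference line for one-copy loss (default -0.4).
#'
#' @return factor with levels \code{two_copy_loss_range},
#'   \code{one_copy_loss_range}, \code{neutral_or_gain}.
#' @export
classify_copy_loss <- function(cnr_adj, two_copy_line = -1.1,
                               one_copy_line = -0.4) {
  if (any(!is.finite(cnr_adj))) stop("cnr_adj must be finite")
  if (two_copy_line >= one_copy_line)
    stop("two_copy_line must lie below one_copy_line")
  out <- ifelse(cnr_adj <= two_copy_line, "two_copy_loss_range",
                ifelse(cnr_adj <= one_copy_line, "one_copy_loss_range",
                       "neutral_or_gain"))
  factor(out, levels = c("two_copy_loss_range", "one_copy_loss_range",
                         "neutral_or_gain"))
}

#' Filter annotated variants on database membership, impact and VAF
#'
#' Without a matched normal, somatic calls are restricted to mutations present
#' in COSMIC, with a VEP impact above LOW (i.e. MODERATE or HIGH), and with an
#' observed VAF above \code{min_vaf}. Missing annotation is treated
#' conservatively: a variant without the flag fails that filter.
#'
#' @param variants data.frame with columns \code{vaf} and optionally
#'   \code{in_cosmic} (logical) and \code{vep_impact} (one of MODIFIER, LOW,
#'   MODERATE, HIGH).
#' @param min_vaf minimum observed VAF (default 0.1, strict).
#'
#' @return list with \code{kept} and \code{dropped} data.frames; \code{dropped}
#'   gains a \code{reason} column (first failing filter among
#'   \code{not_in_cosmic}, \code{low_impact}, \code{low_vaf}).
#' @export
filter_annotated_variants <- function(variants, min_vaf = 0.1) {
  variants <- as.data.frame(variants)
  if (!"vaf" %in% names(variants)) stop("variants need a 'vaf' column")
  if (!"in_cosmic" %in% names(variants)) variants$in_cosmic <- NA
  if (!"vep_impact" %in% names(variants)) variants$vep_impact <- NA_character_
  bad_imp <- !is.na(variants$vep_impact) &
    !variants$vep_impact %in% c("MODIFIER", "LOW", "MODERATE", "HIGH")
  if (any(bad_imp))
    stop("unknown vep_impact value(s): ",
         paste(unique(variants$vep_impact[bad_imp]), collapse = ", "))

  cosmic_ok <- !is.na(variants$in_cosmic) & variants$in_cosmic
  impact_ok <- !is.na(variants$vep_impact) &
    variants$vep_impact %in% c("MODERATE", "HIGH")
  vaf_ok <- !is.na(variants$vaf) & variants$vaf > min_vaf

  reason <- rep(NA_character_, nrow(variants))
  reason[!vaf_ok] <- "low_vaf"
  reason[!impact_ok] <- "low_impact"
  reason[!cosmic_ok] <- "not_in_cosmic"
  dropped <- variants[!is.na(reason), , drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  list(kept = variants[is.na(reason), , drop = FALSE], dropped = dropped)
}

#' Map a coding nucleotide change to its protein-level substitution
#'
#' Given a 1-based CDS position, the reference and alternate bases, and the
#' reference codon at that position, returns the codon index and the standard
#' one-letter amino-acid substitution label (e.g. the VHL c.506T>C transition
#' in codon 169, CTG -> CCG, labeled "L169P"). Synonymous changes are labeled
#' with an "=" suffix (e.g. "L2=").
#'
#' @param cds_position 1-based position of the changed base in the CDS.
#' @param ref_base,alt_base single reference/alternate nucleotides (A/C/G/T).
#' @param reference_codon 3-letter reference codon covering the position; its
#'   base at the within-codon offset must equal \code{ref_base}.
#'
#' @return list with \code{codon_index}, \code{ref_aa}, \code{alt_aa} and
#'   \code{label}.
#' @export
coding_change_to_protein <- function(cds_position, ref_base, alt_base,
                                     reference_codon) {
  if (length(cds_position) != 1 || !is.finite(cds_position) ||
      cds_position < 1 || cds_position != round(cds_position))
    stop("cds_position must be a positive integer")
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  codon <- strsplit(toupper(reference_codon), "")[[1]]
  if (length(codon) != 3 || !all(codon %in% c("A", "C", "G", "T")))
    stop("reference_codon must be a 3-mer over ACGT")
  if (!ref_base %in% c("A", "C", "G", "T") ||
      !alt_base %in% c("A", "C", "G", "T"))
    stop("ref_base and alt_base must be single nucleotides")

  codon_index <- ceiling(cds_position / 3)
  offset <- ((cds_position - 1) %% 3) + 1
  if (codon[offset] != ref_base)
    stop("reference codon has '", codon[offset], "' at CDS position ",
         cds_position, " but ref_base is '", ref_base,
         "': coordinate inconsistency")
  alt_codon <- codon
  alt_codon[offset] <- alt_base
  ref_aa <- seqinr::translate(codon)
  alt_aa <- seqinr::translate(alt_codon)
  label <- if (ref_aa == alt_aa) paste0(ref_aa, codon_index, "=") else
    paste0(ref_aa, codon_index, alt_aa)
  list(codon_index = codon_index, ref_aa = ref_aa, alt_aa = alt_aa,
       label = label)
}

#' Gaussian kernel density of a cohort-level statistic
#'
#' Density summary used to display the cohort-wide distribution of adjusted
#' copy-number ratios or allele frequencies, with the grid peak reported as the
#' cohort mode. The estimate uses a Gaussian kernel on an evenly spaced grid
#' spanning the data range plus three bandwidths on each side.
#'
#' @param values numeric vector (at least two finite values).
#' @param bandwidth kernel bandwidth; \code{"silverman"} (default) uses
#'   Silverman's rule of thumb (\code{stats::bw.nrd0}).
#' @param n_grid number of grid points (default 512).
#'
#' @return list with \code{grid} (data.frame of \code{x}, \code{density}),
#'   \code{peak} (grid argmax) and \code{bandwidth}.
#' @export
cohort_density <- function(values, bandwidth = "silverman", n_grid = 512) {
  values <- values[!is.na(values)]
  if (length(values) < 2 || any(!is.finite(values)))
    stop("need at least 2 finite values")
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(values)
        else as.numeric(bandwidth)
  if (!is.finite(bw) || bw <= 0) stop("bandwidth must be positive")
  d <- withCallingHandlers(
    stats::density(values, bw = bw, kernel = "gaussian", n = n_grid,
                   cut = 3),
    # tied values are legitimate input (e.g. a noiseless cohort); the
    # interpolation step's tie note is not actionable for the caller
    warning = function(w) {
      if (grepl("collapsing to unique", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(grid = data.frame(x = d$x, density = d$y),
       peak = d$x[which.max(d$y)], bandwidth = bw)
}
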