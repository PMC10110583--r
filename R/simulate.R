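# Forward simulators with known ground truth for the three input layers:
# purity/ploidy-confounded tumor cohorts, multi-comparison differential-
# expression studies with a planted concordant subset, and two-region tissues
# with distance-dependent phenotype intensities.

#' Specification of a synthetic tumor-admixture cohort
#'
#' Describes a cohort of bulk samples, each a mixture of diploid normal cells
#' and tumor cells whose clonal architecture determines the true gene copy
#' number and mutant-copy fraction at a single locus (default: VHL). Defaults
#' model a TCGA-KIRC-like cohort: 459 samples, purity Beta(2,2) rescaled to
#' \[0.3, 0.9\], near-diploid ploidy, and a fully clonal one-copy VHL loss
#' carrying a mutation on the retained copy.
#'
#' @param n_samples number of samples (default 459).
#' @param purity_shape shape parameters of the Beta draw for purity
#'   (default c(2, 2)).
#' @param purity_range range the Beta draw is rescaled to (default
#'   c(0.3, 0.9)).
#' @param ploidy_mean,ploidy_sd normal draw for tumor ploidy, truncated to
#'   \code{ploidy_range} (defaults 2, 0.15, c(1.5, 3.5)).
#' @param ploidy_range truncation bounds for ploidy.
#' @param clones data.frame describing the clonal architecture with columns
#'   \code{fraction} (sums to 1), \code{copies_lost} (0, 1 or 2 of the two
#'   starting copies), \code{mutation_present} (logical) and
#'   \code{mutant_copies} (<= copies retained). Default: a clonal one-copy
#'   loss with the retained copy mutated in 70% of tumor cells, giving a
#'   subclonal mutation (true mutant-copy fraction 0.7) on a clonal loss.
#' @param cnr_noise_sd additive Gaussian noise on the observed log2 CNR
#'   (default 0.15).
#' @param vaf_noise_sd additive Gaussian noise on the observed VAF, after
#'   which values are truncated to \[0, 1\] (default 0.03).
#' @param method_noise_sd noise linking the ABSOLUTE-/ESTIMATE-style purity
#'   columns to the consensus value (default 0.05; differences are capped
#'   below the 0.3 agreement filter so only planted samples violate it).
#' @param gene locus name (default "VHL").
#' @param n_low_purity,n_disagreement,n_incompatible numbers of samples
#'   planted to violate, respectively, the consensus-purity filter, the
#'   purity-agreement filter, and the adjusted-VAF upper bound (default 0).
#'   Planted classes are disjoint; when planting, keep \code{purity_range}
#'   above the purity filter so background samples cannot collide with the
#'   planted counts.
#' @param seed RNG seed.
#'
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_samples = 459,
                        purity_shape = c(2, 2),
                        purity_range = c(0.3, 0.9),
                        ploidy_mean = 2, ploidy_sd = 0.15,
                        ploidy_range = c(1.5, 3.5),
                        clones = data.frame(fraction = c(0.7, 0.3),
                                            copies_lost = 1,
                                            mutation_present = c(TRUE, FALSE),
                                            mutant_copies = c(1, 0)),
                        cnr_noise_sd = 0.15, vaf_noise_sd = 0.03,
                        method_noise_sd = 0.05,
                        gene = "VHL",
                        n_low_purity = 0, n_disagreement = 0,
                        n_incompatible = 0,
                        seed = 1) {
  if (abs(sum(clones$fraction) - 1) > 1e-9)
    stop("clone fractions must sum to 1")
  if (any(clones$copies_lost < 0 | clones$copies_lost > 2))
    stop("copies_lost must be 0, 1 or 2")
  copies <- 2 - clones$copies_lost
  if (any(clones$mutant_copies > copies))
    stop("mutant_copies exceeds per-clone gene copies")
  cn_t <- sum(clones$fraction * copies)
  if (cn_t == 0 && any(clones$mutation_present))
    stop("architecture has CN_t = 0 with a mutation present")
  if (n_low_purity + n_disagreement + n_incompatible > n_samples)
    stop("more planted violations than samples")
  structure(list(n_samples = n_samples, purity_shape = purity_shape,
                 purity_range = purity_range, ploidy_mean = ploidy_mean,
                 ploidy_sd = ploidy_sd, ploidy_range = ploidy_range,
                 clones = clones, cnr_noise_sd = cnr_noise_sd,
                 vaf_noise_sd = vaf_noise_sd,
                 method_noise_sd = method_noise_sd, gene = gene,
                 n_low_purity = n_low_purity,
                 n_disagreement = n_disagreement,
                 n_incompatible = n_incompatible, seed = seed),
            class = "cohort_spec")
}

#' Simulate a purity/ploidy-confounded tumor cohort
#'
#' Forward model: per-sample purity PT and ploidy PL are drawn from the spec's
#' distributions; the clonal architecture fixes the true tumor copy number
#' \eqn{CN_t = \sum_i f_i \cdot copies_i} and true mutant-copy fraction
#' \eqn{AF_{true} = \sum_i f_i \cdot mutant_i / CN_t}. Observations are
#' \deqn{CNR = \log_2\frac{PT \cdot CN_t + 2(1-PT)}{PT \cdot PL + 2(1-PT)}
#'   + N(0, \sigma_{CNR})}
#' \deqn{VAF = AF_{true}\frac{PT \cdot CN_t}{PT \cdot CN_t + 2(1-PT)}
#'   + N(0, \sigma_{VAF}) \textrm{, truncated to } [0,1]}
#' which the purity/ploidy adjustment inverts exactly in the zero-noise limit.
#' Planted violations (low purity, purity-method disagreement, adjusted VAF
#' above 1.1) are recorded in the truth table.
#'
#' @param spec a [cohort_spec()].
#'
#' @return list with \code{purity} (sample_id, purity_absolute,
#'   purity_estimate, purity_consensus, ploidy), \code{copy_number}
#'   (sample_id, gene, cnr), \code{variants} (sample_id, gene, vaf) and
#'   \code{truth} (per-sample PT, PL, CN_t, AF_true, noiseless CNR/VAF,
#'   planted violation class).
#' @export
simulate_tumor_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  sample_id <- sprintf("S%04d", seq_len(n))

  pt <- spec$purity_range[1] + diff(spec$purity_range) *
    stats::rbeta(n, spec$purity_shape[1], spec$purity_shape[2])
  pl <- pmin(spec$ploidy_range[2],
             pmax(spec$ploidy_range[1],
                  stats::rnorm(n, spec$ploidy_mean, spec$ploidy_sd)))

  # disjoint planted-violation assignment
  planted <- rep("none", n)
  idx <- seq_len(n)
  pick <- function(k) { s <- idx[seq_len(k)]; idx <<- idx[-seq_len(k)]; s }
  i_low <- pick(spec$n_low_purity)
  i_dis <- pick(spec$n_disagreement)
  i_inc <- pick(spec$n_incompatible)
  planted[i_low] <- "low_purity"
  planted[i_dis] <- "disagreement"
  planted[i_inc] <- "incompatible_vaf"

  pt[i_low] <- stats::runif(length(i_low), 0.05, 0.38)
  # incompatible-VAF plants need enough normal contamination for the adjusted
  # value to be pushable above the clamp window with an observed VAF <= 1
  pt[i_inc] <- stats::runif(length(i_inc), 0.45, 0.6)

  dev <- stats::rnorm(n, 0, spec$method_noise_sd)
  dev <- pmin(0.12, pmax(-0.12, dev))   # keeps |abs - est| < 0.3 background
  purity_absolute <- pmin(1, pmax(0, pt + dev))
  purity_estimate <- pmin(1, pmax(0, pt - dev))
  gap <- stats::runif(length(i_dis), 0.35, 0.6)
  purity_absolute[i_dis] <- pmin(1, pt[i_dis] + gap / 2)
  purity_estimate[i_dis] <- pmax(0, purity_absolute[i_dis] - gap)

  copies <- 2 - spec$clones$copies_lost
  cn_t <- sum(spec$clones$fraction * copies)
  af_true <- if (cn_t > 0)
    sum(spec$clones$fraction * spec$clones$mutant_copies *
          spec$clones$mutation_present) / cn_t else 0

  cnr_true <- log2((pt * cn_t + 2 * (1 - pt)) / (pt * pl + 2 * (1 - pt)))
  cnr_obs <- cnr_true + stats::rnorm(n, 0, spec$cnr_noise_sd)
  vaf_true <- af_true * pt * cn_t / (pt * cn_t + 2 * (1 - pt))
  vaf_obs <- pmin(1, pmax(0, vaf_true + stats::rnorm(n, 0,
                                                     spec$vaf_noise_sd)))
  # planted incompatible: choose the observed VAF so the adjusted value lands
  # above the clamp window (raw adjusted VAF in [1.2, 1.5])
  if (length(i_inc)) {
    fac <- (pt[i_inc] * cn_t + 2 * (1 - pt[i_inc])) / (pt[i_inc] * cn_t)
    target <- stats::runif(length(i_inc), 1.2, pmin(1.5, fac))
    vaf_obs[i_inc] <- target / fac
  }

  list(
    purity = data.frame(sample_id = sample_id,
                        purity_absolute = purity_absolute,
                        purity_estimate = purity_estimate,
                        purity_consensus = pt, ploidy = pl,
                        stringsAsFactors = FALSE),
    copy_number = data.frame(sample_id = sample_id, gene = spec$gene,
                             cnr = cnr_obs, stringsAsFactors = FALSE),
    variants = data.frame(sample_id = sample_id, gene = spec$gene,
                          vaf = vaf_obs, stringsAsFactors = FALSE),
    truth = data.frame(sample_id = sample_id, purity = pt, ploidy = pl,
                       cn_t = cn_t, af_true = af_true,
                       cnr_noiseless = cnr_true, vaf_noiseless = vaf_true,
                       planted = planted, stringsAsFactors = FALSE))
}

#' Simulate a multi-comparison differential-expression study
#'
#' Generates k comparison tables over the same features. A planted subset
#' shares a fixed signed effect across all comparisons (sign drawn once per
#' feature) plus iid Gaussian noise; null features are pure noise. P-values
#' come from a monotone map of the standardized effect
#' (\code{2 * pnorm(-|log2fc| / noise_sd)}), so they are consistent with the
#' noise model without fitting anything.
#'
#' @param n_features total number of features (default 10000).
#' @param k number of comparisons (default 3).
#' @param n_planted number of concordant features (default 200).
#' @param effect absolute planted effect on the log2FC scale (default 2).
#' @param noise_sd iid noise standard deviation (default 0.3).
#' @param seed RNG seed.
#'
#' @return list with \code{tables} (named list of k data.frames:
#'   feature_id, log2fc, p_value) and \code{truth} (data.frame: feature_id,
#'   planted, effect).
#' @export
simulate_concordance_study <- function(n_features = 10000, k = 3,
                                       n_planted = 200, effect = 2,
                                       noise_sd = 0.3, seed = 1) {
  if (n_planted > n_features) stop("n_planted exceeds n_features")
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  feature_id <- sprintf("gene%05d", seq_len(n_features))
  planted <- seq_len(n_features) <= n_planted
  sgn <- ifelse(stats::runif(n_features) < 0.5, -1, 1)
  mu <- ifelse(planted, sgn * effect, 0)
  tables <- lapply(seq_len(k), function(j) {
    l2fc <- mu + stats::rnorm(n_features, 0, noise_sd)
    data.frame(feature_id = feature_id, log2fc = l2fc,
               p_value = pmax(2 * stats::pnorm(-abs(l2fc) / noise_sd),
                              .Machine$double.xmin),
               stringsAsFactors = FALSE)
  })
  names(tables) <- sprintf("comparison_%d", seq_len(k))
  list(tables = tables,
       truth = data.frame(feature_id = feature_id, planted = planted,
                          effect = mu, stringsAsFactors = FALSE))
}

#' Specification of a synthetic two-region tissue
#'
#' Describes a rectangular tissue window, one or more disc-shaped
#' marker-positive regions, and per-phenotype intensity functions of the
#' signed distance to the region boundary (negative = inside).
#'
#' @param window \code{c(xmin, xmax, ymin, ymax)} in µm.
#' @param discs data.frame with columns \code{cx}, \code{cy}, \code{r} (µm)
#'   describing the marker-positive regions.
#' @param phenotypes named list; each element is a list with \code{markers}
#'   (named logical vector of the marker states this phenotype carries) and
#'   \code{intensity} (function of signed distance d in µm returning a
#'   non-negative intensity in cells/µm²).
#' @param seed RNG seed.
#'
#' @return list of class \code{tissue_spec}.
#' @export
tissue_spec <- function(window, discs, phenotypes, seed = 1) {
  if (length(window) != 4 || window[2] <= window[1] || window[4] <= window[3])
    stop("window must be c(xmin, xmax, ymin, ymax)")
  if (!all(c("cx", "cy", "r") %in% names(discs)) || any(discs$r <= 0))
    stop("discs need positive-radius cx/cy/r rows")
  if (is.null(names(phenotypes)))
    stop("phenotypes must be a named list")
  structure(list(window = window, discs = discs, phenotypes = phenotypes,
                 seed = seed), class = "tissue_spec")
}

# signed distance to the union of discs (negative inside)
.disc_signed_distance <- function(x, y, discs) {
  d <- rep(Inf, length(x))
  for (i in seq_len(nrow(discs)))
    d <- pmin(d, sqrt((x - discs$cx[i])^2 + (y - discs$cy[i])^2) -
                discs$r[i])
  d
}

#' Simulate a marker-labeled tissue by inhomogeneous Poisson thinning
#'
#' For each phenotype, draws a homogeneous Poisson point process at the
#' phenotype's maximum intensity over the window and thins each point with
#' probability \eqn{\lambda(d)/\lambda_{max}}, where d is the signed distance
#' of the point to the disc-region boundary. Produces one cell table with the
#' union of all marker columns.
#'
#' @param spec a [tissue_spec()].
#' @param lambda_grid grid step (µm) used to bound each phenotype's maximum
#'   intensity over the window (default 50).
#'
#' @return list with \code{cells} (data.frame: x_um, y_um, one logical column
#'   per marker, phenotype label) and \code{truth} (the spec plus per-
#'   phenotype expected counts).
#' @export
simulate_tissue <- function(spec, lambda_grid = 50) {
  stopifnot(inherits(spec, "tissue_spec"))
  set.seed(spec$seed)
  w <- spec$window
  area <- (w[2] - w[1]) * (w[4] - w[3])
  gx <- seq(w[1], w[2], by = lambda_grid)
  gy <- seq(w[3], w[4], by = lambda_grid)
  grid <- expand.grid(x = gx, y = gy)
  dgrid <- .disc_signed_distance(grid$x, grid$y, spec$discs)

  markers <- unique(unlist(lapply(spec$phenotypes,
                                  function(p) names(p$markers))))
  rows <- list()
  expected <- numeric(length(spec$phenotypes))
  names(expected) <- names(spec$phenotypes)
  for (nm in names(spec$phenotypes)) {
    ph <- spec$phenotypes[[nm]]
    lam <- ph$intensity(dgrid)
    if (any(lam < 0)) stop("negative intensity for phenotype ", nm)
    lam_max <- max(lam) * 1.05        # safety factor over the grid bound
    expected[nm] <- mean(lam) * area
    if (lam_max == 0) next
    n <- stats::rpois(1, lam_max * area)
    if (n == 0) next
    x <- stats::runif(n, w[1], w[2]); y <- stats::runif(n, w[3], w[4])
    keep <- stats::runif(n) < ph$intensity(
      .disc_signed_distance(x, y, spec$discs)) / lam_max
    if (!any(keep)) next
    df <- data.frame(x_um = x[keep], y_um = y[keep])
    for (m in markers)
      df[[m]] <- if (m %in% names(ph$markers)) ph$markers[[m]] else FALSE
    df$phenotype <- nm
    rows[[nm]] <- df
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    stop("no cells generated: all intensities are zero")
  rownames(cells) <- NULL
  list(cells = cells,
       truth = list(spec = spec, expected_counts = expected))
}
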