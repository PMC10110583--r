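# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data files.

# Forward model linking true tumor copy number to the observed log2 CNR,
# written independently of the package's inversion.
forward_cnr <- function(cn_t, pt, pl) {
  log2((pt * cn_t + 2 * (1 - pt)) / (pt * pl + 2 * (1 - pt)))
}

# Forward model for the observed VAF of a mutation at mutant-copy fraction
# af_true on a locus with tumor copy number cn_t.
forward_vaf <- function(af_true, pt, cn_t) {
  af_true * pt * cn_t / (pt * cn_t + 2 * (1 - pt))
}

# Brute-force per-feature SNR: explicit loop, independent of the vectorized
# implementation.
brute_snr <- function(mat, variance_floor = 1e-8) {
  out <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    m <- sum(x) / length(x)
    v <- sum((x - m)^2) / (length(x) - 1)
    out[i] <- m^2 / max(v, variance_floor)
  }
  out
}

# Exhaustive greedy Ward merges: at every step evaluates the error-sum-of-
# squares increase of *every* cluster pair directly from the member rows and
# merges the minimum. Returns the list of merged member sets, in merge order.
ward_merges_oracle <- function(mat) {
  ess <- function(rows) {
    if (length(rows) == 1) return(0)
    sub <- mat[rows, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- as.list(seq_len(nrow(mat)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        cost <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# TRUE when every member set appears as a contiguous block of the leaf order.
clusters_contiguous <- function(merges, leaf_order) {
  all(vapply(merges, function(s) {
    pos <- match(s, leaf_order)
    max(pos) - min(pos) + 1 == length(s)
  }, logical(1)))
}

# Disc-region tissue with an infiltrating phenotype decaying outside the
# boundary; used by spatial and simulator tests.
make_infiltration_spec <- function(tau = 1000, lambda0 = 0.002, seed = 7) {
  tissue_spec(
    window = c(0, 9000, 0, 9000),
    discs = data.frame(cx = 4500, cy = 4500, r = 1800),
    phenotypes = list(
      region = list(markers = c(VHL = TRUE),
                    intensity = function(d) ifelse(d <= 0, lambda0, 0)),
      infiltrate = list(
        markers = c(Ki67 = TRUE),
        intensity = function(d) ifelse(d > 0, lambda0 * exp(-d / tau),
                                       lambda0 / 4))),
    seed = seed)
}

# Two phenotypes on opposite sides of a disc boundary, strictly disjoint.
make_disjoint_spec <- function(seed = 11) {
  tissue_spec(
    window = c(0, 8000, 0, 8000),
    discs = data.frame(cx = 4000, cy = 4000, r = 1800),
    phenotypes = list(
      a = list(markers = c(VHL = TRUE, POSTN = FALSE),
               intensity = function(d) ifelse(d <= 0, 0.0015, 0)),
      b = list(markers = c(VHL = FALSE, POSTN = TRUE),
               intensity = function(d) ifelse(d > 0, 0.0015, 0))),
    seed = seed)
}

# Two phenotypes with opposing exponential gradients across the interface:
# the co-exclusion scenario with graded, interdigitated territory.
make_coexclusion_spec <- function(seed = 11) {
  tissue_spec(
    window = c(0, 8000, 0, 8000),
    discs = data.frame(cx = 4000, cy = 4000, r = 1800),
    phenotypes = list(
      a = list(markers = c(VHL = TRUE, POSTN = FALSE),
               intensity = function(d) 0.0015 * exp(-pmax(d + 1500, 0) / 700)),
      b = list(markers = c(VHL = FALSE, POSTN = TRUE),
               intensity = function(d) 0.0015 * exp(-pmax(1500 - d, 0) / 700))),
    seed = seed)
}

# Writes a cohort simulation to TSV files under dir; returns the paths.
write_cohort_files <- function(sim, dir) {
  paths <- list(cn = file.path(dir, "copy_number.tsv"),
                variants = file.path(dir, "variants.tsv"),
                purity = file.path(dir, "purity.tsv"))
  write_tsv(sim$copy_number, paths$cn)
  write_tsv(sim$variants, paths$variants)
  write_tsv(sim$purity, paths$purity)
  paths
}
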