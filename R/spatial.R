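# Spatial profiling of marker-labeled cell coordinates: density grids,
# marker-region boundaries, boundary-relative infiltration histograms and
# two-phenotype co-exclusion profiles. Inputs are tables of already-classified
# cell centroids (x_um, y_um plus one logical column per marker), i.e. the
# output of an image-analysis cell classifier, not images.

.marker_positive <- function(cells, marker) {
  if (!marker %in% names(cells))
    stop("cells table has no marker column '", marker, "'")
  v <- cells[[marker]]
  if (!is.logical(v)) v <- as.logical(v)
  if (any(is.na(v))) stop("marker column '", marker, "' has missing values")
  v
}

#' Evaluate a cell-phenotype definition
#'
#' A phenotype is a conjunction of marker states, e.g.
#' \code{c(VHL = TRUE, POSTN = FALSE)} for VHL-positive POSTN-negative cells.
#'
#' @param cells cell table with logical marker columns.
#' @param phenotype named logical vector of required marker states.
#' @return logical vector, one entry per cell.
#' @export
phenotype_mask <- function(cells, phenotype) {
  if (is.null(names(phenotype)) || any(!nzchar(names(phenotype))))
    stop("phenotype must be a named logical vector")
  mask <- rep(TRUE, nrow(cells))
  for (m in names(phenotype))
    mask <- mask & (.marker_positive(cells, m) == phenotype[[m]])
  mask
}

#' Gaussian-smoothed density grid of marker-positive cells
#'
#' Bins marker-positive cells onto a regular grid and smooths the counts with
#' an isotropic Gaussian kernel — the density heatmap underlying boundary
#' inference. The unsmoothed bin counts sum exactly to the number of positive
#' cells.
#'
#' @param cells data.frame with \code{x_um}, \code{y_um} and logical marker
#'   columns.
#' @param marker name of the marker column defining positivity.
#' @param cell_size grid cell edge in µm (default 100).
#' @param bandwidth Gaussian kernel standard deviation in µm (default 200).
#'
#' @return object of class \code{density_grid}: list with \code{x}, \code{y}
#'   (cell-center coordinates), \code{counts} and \code{smooth} matrices
#'   (rows = x, cols = y), \code{cell_size}, \code{bandwidth}.
#' @export
density_grid <- function(cells, marker, cell_size = 100, bandwidth = 200) {
  pos <- .marker_positive(cells, marker)
  if (!any(pos)) stop("no '", marker, "'-positive cells")
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um)))
    stop("cell coordinates must be finite")
  px <- cells$x_um[pos]; py <- cells$y_um[pos]

  # grid over the bounding box of *all* cells, padded by one kernel sd
  pad <- bandwidth
  x0 <- min(cells$x_um) - pad; x1 <- max(cells$x_um) + pad
  y0 <- min(cells$y_um) - pad; y1 <- max(cells$y_um) + pad
  xb <- seq(x0, x1 + cell_size, by = cell_size)
  yb <- seq(y0, y1 + cell_size, by = cell_size)
  ix <- findInterval(px, xb, rightmost.closed = TRUE)
  iy <- findInterval(py, yb, rightmost.closed = TRUE)
  counts <- matrix(0, length(xb) - 1, length(yb) - 1)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1

  # separable Gaussian smoothing, kernel truncated at 4 sd
  sd_cells <- bandwidth / cell_size
  r <- max(1L, ceiling(4 * sd_cells))
  kern <- stats::dnorm(seq(-r, r), sd = sd_cells)
  kern <- kern / sum(kern)
  smooth1 <- function(m) {             # smooth along rows (first margin)
    n <- nrow(m)
    padm <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- matrix(0, n, ncol(m))
    for (k in seq_along(kern))
      out <- out + kern[k] * padm[seq_len(n) + (k - 1), , drop = FALSE]
    out
  }
  smooth <- t(smooth1(t(smooth1(counts))))
  structure(list(x = (xb[-length(xb)] + xb[-1]) / 2,
                 y = (yb[-length(yb)] + yb[-1]) / 2,
                 counts = counts, smooth = smooth,
                 cell_size = cell_size, bandwidth = bandwidth),
            class = "density_grid")
}

#' Infer marker-positive region boundaries from a smoothed density
#'
#' Draws iso-contours of the Gaussian-smoothed positive-cell density at a
#' fraction of its maximum and returns the resulting closed polygons as the
#' region boundary. Components smaller than \code{min_area} are discarded
#' (and counted in the \code{n_discarded} attribute).
#'
#' @param cells cell table (see [density_grid()]).
#' @param marker marker defining the region (e.g. \code{"VHL"}).
#' @param density_threshold contour level as a fraction of the smoothed
#'   maximum, in (0, 1) (default 0.2).
#' @param cell_size,bandwidth passed to [density_grid()].
#' @param min_area minimum polygon area in µm² (default one grid cell).
#'
#' @return object of class \code{region_boundary}: list with \code{polygons}
#'   (list of data.frames with x/y vertices), \code{grid_resolution},
#'   \code{threshold_level} and \code{n_discarded}.
#' @export
infer_region_boundary <- function(cells, marker, density_threshold = 0.2,
                                  cell_size = 100, bandwidth = 200,
                                  min_area = cell_size^2) {
  if (density_threshold <= 0 || density_threshold >= 1)
    stop("density_threshold must be in (0, 1)")
  g <- density_grid(cells, marker, cell_size = cell_size,
                    bandwidth = bandwidth)
  level <- density_threshold * max(g$smooth)
  # pad the grid with a zero ring so every contour closes
  nx <- length(g$x); ny <- length(g$y)
  z <- matrix(0, nx + 2, ny + 2)
  z[2:(nx + 1), 2:(ny + 1)] <- g$smooth
  xs <- c(g$x[1] - cell_size, g$x, g$x[nx] + cell_size)
  ys <- c(g$y[1] - cell_size, g$y, g$y[ny] + cell_size)
  cl <- grDevices::contourLines(xs, ys, z, levels = level)
  if (!length(cl))
    stop("no region found: smoothed density never reaches ",
         signif(level, 4), " (threshold ", density_threshold, " of max)")
  polys <- lapply(cl, function(p) data.frame(x = p$x, y = p$y))
  areas <- vapply(polys, polygon_area, numeric(1))
  small <- areas < min_area
  polys <- polys[!small]
  if (!length(polys))
    stop("all candidate regions fall below min_area = ", min_area, " um^2")
  structure(list(polygons = polys, grid_resolution = cell_size,
                 threshold_level = level, n_discarded = sum(small)),
            class = "region_boundary")
}

# Distance bands on the signed distance axis: negative = inside the region.
.distance_bands <- function(inner_extent, outer_extent, band_width) {
  if (inner_extent <= 0 || outer_extent <= 0 || band_width <= 0)
    stop("extents and band_width must be positive")
  # bands anchored at the boundary (0); a non-dividing band_width truncates
  # the outermost band on each side
  sort(unique(c(-seq(0, inner_extent, by = band_width), -inner_extent,
                seq(0, outer_extent, by = band_width), outer_extent)))
}

# Band areas by numerical integration: signed distance evaluated at the
# centers of a fine grid over the analysis window; each center contributes
# resolution^2 to its band's area.
.band_areas <- function(boundary, breaks, window, resolution) {
  gx <- seq(window[1] + resolution / 2, window[2], by = resolution)
  gy <- seq(window[3] + resolution / 2, window[4], by = resolution)
  pts <- expand.grid(x = gx, y = gy)
  d <- signed_distance_to_boundary(pts$x, pts$y, boundary)
  band <- cut(d, breaks = breaks, include.lowest = TRUE)
  as.numeric(table(band)) * resolution^2
}

#' Boundary-relative infiltration profile of marker-positive cells
#'
#' Counts target-marker-positive cells in contiguous bands of signed distance
#' to a region boundary (negative distances = inside the region), normalizes
#' each count by the band's geometric area within the analysis window, and
#' reports the per-band density — the histogram used to quantify infiltration
#' of e.g. proliferating cells across a tumor-region edge.
#'
#' @param cells cell table with \code{x_um}, \code{y_um} and marker columns.
#' @param target_marker marker whose positive cells are profiled.
#' @param boundary \code{region_boundary} the distances refer to.
#' @param inner_extent how far inside the region the bands extend, µm
#'   (default 2000).
#' @param outer_extent how far outside, µm (default 4000).
#' @param band_width band width in µm (default 500); if it does not divide an
#'   extent the last band is truncated, with a warning.
#' @param window analysis window \code{c(xmin, xmax, ymin, ymax)} in µm;
#'   default: bounding box of all cells expanded by \code{outer_extent}.
#' @param area_resolution grid step in µm for numerical band-area integration
#'   (default 100).
#'
#' @return data.frame of class \code{infiltration_profile} with one row per
#'   band: \code{band}, \code{d_lo}, \code{d_hi}, \code{count},
#'   \code{area_um2}, \code{density}; attribute \code{n_out_of_band} counts
#'   positive cells outside all bands.
#' @export
infiltration_profile <- function(cells, target_marker, boundary,
                                 inner_extent = 2000, outer_extent = 4000,
                                 band_width = 500, window = NULL,
                                 area_resolution = 100) {
  if (inner_extent %% band_width != 0 || outer_extent %% band_width != 0)
    warning("band_width does not divide the extents; last band truncated")
  breaks <- .distance_bands(inner_extent, outer_extent, band_width)
  if (is.null(window))
    window <- c(min(cells$x_um) - outer_extent,
                max(cells$x_um) + outer_extent,
                min(cells$y_um) - outer_extent,
                max(cells$y_um) + outer_extent)

  pos <- .marker_positive(cells, target_marker)
  d <- signed_distance_to_boundary(cells$x_um[pos], cells$y_um[pos], boundary)
  band <- cut(d, breaks = breaks, include.lowest = TRUE)
  counts <- as.numeric(table(band))
  areas <- .band_areas(boundary, breaks, window, area_resolution)
  zero <- areas == 0
  if (any(zero & counts > 0))
    warning("band with cells but zero integrated area; density undefined")
  out <- data.frame(
    band = seq_len(length(breaks) - 1),
    d_lo = breaks[-length(breaks)],
    d_hi = breaks[-1],
    count = counts,
    area_um2 = areas,
    density = ifelse(zero, NA_real_, counts / areas))
  attr(out, "n_out_of_band") <- sum(is.na(band))
  class(out) <- c("infiltration_profile", "data.frame")
  out
}

#' Fraction of target-positive cells per labeled region
#'
#' Assigns every cell to the first region whose boundary contains it (cells in
#' no region are labeled \code{"neither"}) and reports, per region, the
#' fraction of cells positive for the target marker — e.g. Ki-67 positivity
#' inside vs. outside VHL-positive areas.
#'
#' @param cells cell table.
#' @param target_marker marker whose positivity fraction is reported.
#' @param regions named list of \code{region_boundary} objects.
#'
#' @return data.frame with \code{region}, \code{n_cells}, \code{n_positive},
#'   \code{fraction} (NA, with a warning, for empty regions); includes a
#'   \code{"neither"} row for unassigned cells.
#' @export
positivity_fraction_by_region <- function(cells, target_marker, regions) {
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be a named list")
  pos <- .marker_positive(cells, target_marker)
  label <- rep("neither", nrow(cells))
  for (nm in rev(names(regions))) {
    b <- regions[[nm]]
    inside <- signed_distance_to_boundary(cells$x_um, cells$y_um, b) <= 0
    label[inside] <- nm               # earlier regions win via rev() order
  }
  levs <- c(names(regions), "neither")
  n_cells <- as.numeric(table(factor(label, levels = levs)))
  n_pos <- as.numeric(tapply(pos, factor(label, levels = levs), sum,
                             default = 0))
  if (any(n_cells == 0))
    warning("region(s) with zero cells: fraction undefined")
  data.frame(region = levs, n_cells = n_cells, n_positive = n_pos,
             fraction = ifelse(n_cells == 0, NA_real_, n_pos / n_cells))
}

#' Co-exclusion profile of two cell phenotypes across a region boundary
#'
#' Computes boundary-relative, area-normalized density profiles for two
#' mutually exclusive phenotypes (e.g. VHL+POSTN- vs. VHL-POSTN+) over the
#' same distance bands, and summarizes their spatial relationship as the
#' Spearman rank correlation of the two per-band density vectors: strongly
#' negative values indicate the phenotypes occupy disjoint territory
#' (co-exclusion).
#'
#' @param cells cell table.
#' @param phenotype_a,phenotype_b named logical vectors of marker states (see
#'   [phenotype_mask()]).
#' @param boundary \code{region_boundary} of the phenotype-A region.
#' @param inner_extent,outer_extent,band_width,window,area_resolution as in
#'   [infiltration_profile()].
#'
#' @return list with \code{profile} (data.frame: band, d_lo, d_hi, count_a,
#'   count_b, area_um2, density_a, density_b), \code{spearman} (the overlap
#'   statistic; NA with a warning when fewer than 3 usable bands) and
#'   \code{n_usable_bands}.
#' @export
co_exclusion_profile <- function(cells, phenotype_a, phenotype_b, boundary,
                                 inner_extent = 2000, outer_extent = 4000,
                                 band_width = 500, window = NULL,
                                 area_resolution = 100) {
  ma <- phenotype_mask(cells, phenotype_a)
  mb <- phenotype_mask(cells, phenotype_b)
  tmp <- cells
  tmp$.pheno_a <- ma
  tmp$.pheno_b <- mb
  pa <- infiltration_profile(tmp, ".pheno_a", boundary, inner_extent,
                             outer_extent, band_width, window,
                             area_resolution)
  pb <- infiltration_profile(tmp, ".pheno_b", boundary, inner_extent,
                             outer_extent, band_width, window,
                             area_resolution)
  usable <- !is.na(pa$density) & !is.na(pb$density)
  rho <- if (sum(usable) < 3) {
    warning("fewer than 3 usable bands; overlap statistic undefined")
    NA_real_
  } else {
    stats::cor(pa$density[usable], pb$density[usable], method = "spearman")
  }
  list(profile = data.frame(band = pa$band, d_lo = pa$d_lo, d_hi = pa$d_hi,
                            count_a = pa$count, count_b = pb$count,
                            area_um2 = pa$area_um2,
                            density_a = pa$density, density_b = pb$density),
       spearman = rho, n_usable_bands = sum(usable))
}

#' Permutation null for the co-exclusion statistic
#'
#' Re-labels the pooled phenotype-A/phenotype-B cells at random (keeping the
#' group sizes), recomputes the per-band Spearman statistic for each
#' permutation, and returns the null distribution. Under no spatial
#' segregation the observed statistic should fall within these values.
#'
#' @inheritParams co_exclusion_profile
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#'
#' @return numeric vector of \code{n_perm} permuted Spearman statistics.
#' @export
co_exclusion_null <- function(cells, phenotype_a, phenotype_b, boundary,
                              inner_extent = 2000, outer_extent = 4000,
                              band_width = 500, window = NULL,
                              area_resolution = 100, n_perm = 999,
                              seed = 1) {
  ma <- phenotype_mask(cells, phenotype_a)
  mb <- phenotype_mask(cells, phenotype_b)
  if (any(ma & mb)) stop("phenotypes overlap: not mutually exclusive")
  pool <- which(ma | mb)
  n_a <- sum(ma)
  breaks <- .distance_bands(inner_extent, outer_extent, band_width)
  if (is.null(window))
    window <- c(min(cells$x_um) - outer_extent,
                max(cells$x_um) + outer_extent,
                min(cells$y_um) - outer_extent,
                max(cells$y_um) + outer_extent)
  d <- signed_distance_to_boundary(cells$x_um[pool], cells$y_um[pool],
                                   boundary)
  band <- cut(d, breaks = breaks, include.lowest = TRUE)
  areas <- .band_areas(boundary, breaks, window, area_resolution)
  usable <- areas > 0
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  vapply(seq_len(n_perm), function(i) {
    lab_a <- seq_along(pool) %in% sample(seq_along(pool), n_a)
    ca <- as.numeric(table(band[lab_a]))
    cb <- as.numeric(table(band[!lab_a]))
    stats::cor((ca / areas)[usable], (cb / areas)[usable],
               method = "spearman")
  }, numeric(1))
}

#' Fit an exponential decay to the outside arm of an infiltration profile
#'
#' Log-linear least squares on the positive-density bands outside the region
#' (d >= 0): \eqn{\lambda(d) = \lambda_0 e^{-d/\tau}}. Useful to summarize how
#' quickly an infiltrating population falls off with distance from the
#' boundary.
#'
#' @param profile an [infiltration_profile()] result.
#' @return list with \code{lambda0} (density at the boundary, cells/µm²),
#'   \code{tau} (decay length, µm) and \code{n_bands} used.
#' @export
fit_infiltration_decay <- function(profile) {
  out <- profile[profile$d_lo >= 0 & !is.na(profile$density) &
                   profile$density > 0, , drop = FALSE]
  if (nrow(out) < 3) stop("need at least 3 positive outside bands")
  mid <- (out$d_lo + out$d_hi) / 2
  fit <- stats::lm(log(out$density) ~ mid)
  list(lambda0 = exp(unname(stats::coef(fit)[1])),
       tau = -1 / unname(stats::coef(fit)[2]),
       n_bands = nrow(out))
}
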