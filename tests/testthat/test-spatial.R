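test_that("density grid conserves counts and locates mass", {
  set.seed(1)
  cells <- data.frame(x_um = runif(100, 0, 2000), y_um = runif(100, 0, 2000),
                      M = TRUE)
  g <- density_grid(cells, "M")
  expect_equal(sum(g$counts), 100)
  # all positives at one location: smoothed argmax lands on that cell
  one <- data.frame(x_um = c(rep(500, 30), 0, 1000),
                    y_um = c(rep(700, 30), 0, 1000),
                    M = c(rep(TRUE, 30), FALSE, FALSE))
  g1 <- density_grid(one, "M")
  peak <- which(g1$smooth == max(g1$smooth), arr.ind = TRUE)
  expect_lt(abs(g1$x[peak[1]] - 500), g1$cell_size)
  expect_lt(abs(g1$y[peak[2]] - 700), g1$cell_size)
  expect_error(density_grid(one, "absent"), "marker")
  expect_error(density_grid(data.frame(x_um = 1, y_um = 1, M = FALSE), "M"),
               "positive")
})

test_that("region boundaries recover disc geometry", {
  sim <- simulate_tissue(make_disjoint_spec(seed = 2))
  b <- infer_region_boundary(sim$cells, "VHL")
  area <- sum(vapply(b$polygons, polygon_area, numeric(1)))
  expect_lt(abs(area - pi * 1800^2) / (pi * 1800^2), 0.25)
  # two well-separated discs give two polygons
  spec2 <- tissue_spec(
    window = c(0, 10000, 0, 6000),
    discs = data.frame(cx = c(2500, 7500), cy = 3000, r = 1200),
    phenotypes = list(
      r = list(markers = c(VHL = TRUE),
               intensity = function(d) ifelse(d <= 0, 0.002, 0))),
    seed = 3)
  sim2 <- simulate_tissue(spec2)
  b2 <- infer_region_boundary(sim2$cells, "VHL")
  expect_equal(length(b2$polygons), 2)
  expect_error(infer_region_boundary(sim$cells, "VHL",
                                     density_threshold = 1.2), "threshold")
})

test_that("signed distances are zero on vertices, negative inside", {
  sq <- list(polygons = list(data.frame(x = c(0, 1, 1, 0),
                                        y = c(0, 0, 1, 1))))
  expect_equal(signed_distance_to_boundary(0, 0, sq), 0)
  expect_equal(signed_distance_to_boundary(1.5, 0.5, sq), 0.5)  # outside edge
  expect_equal(signed_distance_to_boundary(0.5, 0.5, sq), -0.5) # center
  theta <- seq(0, 2 * pi, length.out = 257)[-257]
  circ <- list(polygons = list(data.frame(x = 300 * cos(theta),
                                          y = 300 * sin(theta))))
  expect_equal(signed_distance_to_boundary(0, 0, circ), -300, tolerance = 1e-3)
  # continuity across the boundary: straddling points straddle zero
  d <- signed_distance_to_boundary(c(0.999, 1.001), c(0.5, 0.5), sq)
  expect_lt(d[1], 0); expect_gt(d[2], 0)
  expect_lt(abs(d[1]) + abs(d[2]), 0.01)
})

test_that("infiltration profiles conserve counts and respect rigid motions", {
  sim <- simulate_tissue(make_infiltration_spec(seed = 4))
  b <- infer_region_boundary(sim$cells, "VHL")
  p <- infiltration_profile(sim$cells, "Ki67", b, inner_extent = 1500,
                            outer_extent = 4000, band_width = 500,
                            window = make_infiltration_spec()$window)
  expect_equal(sum(p$count) + attr(p, "n_out_of_band"),
               sum(sim$cells$Ki67))
  # rotate and translate everything: same counts and areas
  ang <- pi / 7; dx <- 1234; dy <- -567
  rot <- function(x, y) list(x = cos(ang) * x - sin(ang) * y + dx,
                             y = sin(ang) * x + cos(ang) * y + dy)
  cells2 <- sim$cells
  xy <- rot(cells2$x_um, cells2$y_um)
  cells2$x_um <- xy$x; cells2$y_um <- xy$y
  b2 <- b
  b2$polygons <- lapply(b$polygons, function(pp) {
    q <- rot(pp$x, pp$y); data.frame(x = q$x, y = q$y)
  })
  w <- make_infiltration_spec()$window
  corners <- rot(c(w[1], w[2], w[1], w[2]), c(w[3], w[3], w[4], w[4]))
  p2 <- infiltration_profile(cells2, "Ki67", b2, 1500, 4000, 500,
                             window = c(min(corners$x), max(corners$x),
                                        min(corners$y), max(corners$y)))
  expect_equal(p2$count, p$count)
  # doubling every cell doubles counts and leaves density ratios unchanged
  pd <- infiltration_profile(rbind(sim$cells, sim$cells), "Ki67", b,
                             1500, 4000, 500,
                             window = make_infiltration_spec()$window)
  expect_equal(pd$count, 2 * p$count)
  nz <- p$density > 0 & !is.na(p$density)
  expect_equal(pd$density[nz] / p$density[nz], rep(2, sum(nz)))
})

test_that("band densities track a homogeneous Poisson intensity", {
  spec <- tissue_spec(
    window = c(0, 8000, 0, 8000),
    discs = data.frame(cx = 4000, cy = 4000, r = 1500),
    phenotypes = list(
      r = list(markers = c(VHL = TRUE),
               intensity = function(d) ifelse(d <= 0, 0.002, 0)),
      u = list(markers = c(U = TRUE),
               intensity = function(d) rep(0.001, length(d)))),
    seed = 6)
  sim <- simulate_tissue(spec)
  theta <- seq(0, 2 * pi, length.out = 129)[-129]
  b <- list(polygons = list(data.frame(x = 4000 + 1500 * cos(theta),
                                       y = 4000 + 1500 * sin(theta))))
  p <- infiltration_profile(sim$cells, "U", b, inner_extent = 1000,
                            outer_extent = 2000, band_width = 500,
                            window = spec$window)
  lambda <- 0.001
  for (i in seq_len(nrow(p))) {
    expected <- lambda * p$area_um2[i]
    expect_lt(abs(p$count[i] - expected), 3 * sqrt(expected) + 3)
  }
})

test_that("exponential infiltration decay is recovered from the profile", {
  spec <- make_infiltration_spec(tau = 1000, seed = 7)
  sim <- simulate_tissue(spec)
  b <- infer_region_boundary(sim$cells, "VHL")
  p <- infiltration_profile(sim$cells, "Ki67", b, inner_extent = 1500,
                            outer_extent = 4000, band_width = 500,
                            window = spec$window)
  fit <- fit_infiltration_decay(p)
  expect_lt(abs(fit$tau - 1000) / 1000, 0.2)
})

test_that("positivity fractions per region are exact on constructed data", {
  sq <- function(x0, y0, s) list(polygons = list(
    data.frame(x = c(x0, x0 + s, x0 + s, x0), y = c(y0, y0, y0 + s, y0 + s))))
  regions <- list(A = sq(0, 0, 100), B = sq(200, 0, 100))
  cells <- data.frame(
    x_um = c(runif(40, 10, 90), runif(20, 210, 290), 150),
    y_um = c(runif(40, 10, 90), runif(20, 10, 90), 50),
    K = c(rep(TRUE, 10), rep(FALSE, 30), rep(TRUE, 20), FALSE))
  res <- positivity_fraction_by_region(cells, "K", regions)
  expect_equal(res$fraction[res$region == "A"], 0.25)
  expect_equal(res$fraction[res$region == "B"], 1.0)
  expect_equal(res$n_cells[res$region == "neither"], 1)
  # planted fractions recovered within binomial bounds
  spec <- tissue_spec(
    window = c(0, 8000, 0, 4000),
    discs = data.frame(cx = 2000, cy = 2000, r = 1200),
    phenotypes = list(
      inA  = list(markers = c(VHL = TRUE, K = FALSE),
                  intensity = function(d) ifelse(d <= 0, 0.0014, 0)),
      inAK = list(markers = c(VHL = TRUE, K = TRUE),
                  intensity = function(d) ifelse(d <= 0, 0.0006, 0))),
    seed = 8)
  sim <- simulate_tissue(spec)
  theta <- seq(0, 2 * pi, length.out = 129)[-129]
  disc <- list(polygons = list(data.frame(x = 2000 + 1200 * cos(theta),
                                          y = 2000 + 1200 * sin(theta))))
  res <- positivity_fraction_by_region(sim$cells, "K", list(A = disc))
  p_true <- 0.0006 / 0.002
  n <- res$n_cells[res$region == "A"]
  expect_lt(abs(res$fraction[res$region == "A"] - p_true),
            2 * sqrt(p_true * (1 - p_true) / n))
})

test_that("co-exclusion statistic separates segregated from uniform tissue", {
  sim <- simulate_tissue(make_disjoint_spec(seed = 11))
  b <- infer_region_boundary(sim$cells, "VHL")
  co <- co_exclusion_profile(sim$cells, c(VHL = TRUE, POSTN = FALSE),
                             c(VHL = FALSE, POSTN = TRUE), b,
                             inner_extent = 1500, outer_extent = 3000,
                             band_width = 500,
                             window = make_disjoint_spec()$window)
  expect_lt(co$spearman, -0.8)
  # perfectly opposite monotone band densities give Spearman exactly -1
  sim2 <- simulate_tissue(make_coexclusion_spec(seed = 1))
  b2 <- infer_region_boundary(sim2$cells, "VHL")
  co2 <- co_exclusion_profile(sim2$cells, c(VHL = TRUE, POSTN = FALSE),
                              c(VHL = FALSE, POSTN = TRUE), b2,
                              1500, 3000, 500,
                              window = make_coexclusion_spec()$window)
  expect_lt(co2$spearman, -0.9)
  # uniform phenotypes stay within the permutation null
  spec <- tissue_spec(
    window = c(0, 8000, 0, 8000),
    discs = data.frame(cx = 4000, cy = 4000, r = 1800),
    phenotypes = list(
      r = list(markers = c(VHL = TRUE),
               intensity = function(d) ifelse(d <= 0, 0.0015, 0)),
      a = list(markers = c(A = TRUE),
               intensity = function(d) rep(5e-4, length(d))),
      b = list(markers = c(B = TRUE),
               intensity = function(d) rep(5e-4, length(d)))),
    seed = 12)
  simu <- simulate_tissue(spec)
  bu <- infer_region_boundary(simu$cells, "VHL")
  cou <- co_exclusion_profile(simu$cells, c(A = TRUE), c(B = TRUE), bu,
                              1500, 3000, 500, window = spec$window)
  null <- co_exclusion_null(simu$cells, c(A = TRUE), c(B = TRUE), bu,
                            1500, 3000, 500, window = spec$window,
                            n_perm = 199, seed = 5)
  expect_gte(cou$spearman, min(null))
  expect_lte(cou$spearman, max(null))
  expect_error(co_exclusion_null(simu$cells, c(A = TRUE), c(A = TRUE), bu,
                                 window = spec$window), "overlap")
})
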