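# independent raster oracle: nearest-site pixel counting on a fine grid
raster_cell_areas <- function(x, y, w, h, res = 800) {
  gx <- (seq_len(res) - 0.5) * w / res
  gy <- (seq_len(res) - 0.5) * h / res
  counts <- numeric(length(x))
  for (iy in seq_len(res)) {
    d2 <- outer(gx, x, function(g, p) (g - p)^2) +
      matrix(rep((gy[iy] - y)^2, each = res), res, length(x))
    nearest <- max.col(-d2, ties.method = "first")
    tab <- tabulate(nearest, nbins = length(x))
    counts <- counts + tab
  }
  counts * (w / res) * (h / res)
}

test_that("a lone emitter claims the whole rectangle (degenerate path)", {
  em <- emitter_set(100, 80, pixel_size = 1, width_px = 300, height_px = 200)
  vr <- voronoi_radii(em, c(300, 200))
  expect_equal(vr$cell_area_nm2, 300 * 200)
  expect_equal(vr$delta_r_nm, sqrt(300 * 200 / pi))
})

test_that("a regular square grid of emitters yields cells of area s^2", {
  s <- 50
  centers <- (seq_len(10) - 0.5) * s
  g <- expand.grid(x = centers, y = centers)
  em <- emitter_set(g$x, g$y, pixel_size = 1, width_px = 500, height_px = 500)
  vr <- voronoi_radii(em, c(500, 500))
  expect_equal(vr$cell_area_nm2, rep(s^2, 100), tolerance = 1e-9)
  expect_equal(vr$delta_r_nm, rep(s / sqrt(pi), 100), tolerance = 1e-9)
})

test_that("clipped cell areas partition the rectangle exactly", {
  withr::with_seed(13, {
    em <- emitter_set(runif(2000, 0, 640), runif(2000, 0, 480),
                      pixel_size = 1, width_px = 640, height_px = 480)
  })
  vr <- voronoi_radii(em, c(640, 480))
  expect_equal(attr(vr, "total_area_nm2"), 640 * 480, tolerance = 1e-6)
  expect_true(all(vr$cell_area_nm2 >= 0))
})

test_that("cell areas agree with an independent raster nearest-site oracle", {
  withr::with_seed(17, {
    em <- emitter_set(runif(12, 10, 190), runif(12, 10, 190),
                      pixel_size = 1, width_px = 200, height_px = 200)
  })
  vr <- voronoi_radii(em, c(200, 200))
  oracle <- raster_cell_areas(em$x_nm, em$y_nm, 200, 200)
  expect_equal(vr$cell_area_nm2, oracle, tolerance = 0.02)
})

test_that("limiting precision combines sampling and localization in quadrature", {
  expect_identical(limiting_precision(3, 4), 5)
  expect_identical(limiting_precision(7.5, 0), 7.5)
  expect_identical(limiting_precision(0, 0), 0)
  expect_equal(limiting_precision(c(3, 0), 4), c(5, 4))
  expect_error(limiting_precision(-1, 2), class = "smlm_parameter_error")
})

test_that("coordinate scaling scales every sampling radius by the same factor", {
  withr::with_seed(19, {
    x <- runif(200, 0, 100); y <- runif(200, 0, 100)
  })
  v1 <- voronoi_radii(emitter_set(x, y), c(100, 100))
  v3 <- voronoi_radii(emitter_set(3 * x, 3 * y), c(300, 300))
  expect_equal(v3$delta_r_nm, 3 * v1$delta_r_nm, tolerance = 1e-9)
})

test_that("mean sampling radius matches 1/sqrt(pi * rho) for uniform emitters", {
  n <- 1e4
  withr::with_seed(23, {
    em <- emitter_set(runif(n, 0, 1000), runif(n, 0, 1000))
  })
  vr <- voronoi_radii(em, c(1000, 1000))
  rho <- n / 1e6
  expect_equal(mean(vr$delta_r_nm), 1 / sqrt(pi * rho), tolerance = 0.05)
})

test_that("duplicate emitter positions are separated deterministically", {
  em <- emitter_set(c(50, 50, 50, 120), c(60, 60, 60, 30),
                    pixel_size = 1, width_px = 200, height_px = 100)
  v1 <- voronoi_radii(em, c(200, 100))
  v2 <- voronoi_radii(em, c(200, 100))
  expect_identical(v1$cell_area_nm2, v2$cell_area_nm2)
  expect_true(all(v1$cell_area_nm2 > 0))
  expect_equal(attr(v1, "total_area_nm2"), 200 * 100, tolerance = 1e-6)
})

test_that("sampling summary reports the box-plot statistics and limiting scales", {
  st <- summarize_sampling(rep(7, 50), delta_g = 0)
  s <- st$summary
  expect_equal(unlist(s[c("mean_r_nm", "p05_r_nm", "median_r_nm", "p95_r_nm")]),
               c(mean_r_nm = 7, p05_r_nm = 7, median_r_nm = 7, p95_r_nm = 7))
  expect_equal(s$limiting_period_median_nm, 14)
  expect_equal(s$limiting_freq_median, 1 / 14)

  st2 <- summarize_sampling(3, delta_g = 4)
  expect_equal(st2$delta_l, 5)

  withr::with_seed(29, r <- runif(1e4))
  s3 <- summarize_sampling(r, delta_g = 0)$summary
  expect_equal(s3$median_r_nm, 0.5, tolerance = 0.03)
  expect_equal(s3$p05_r_nm, 0.05, tolerance = 0.1)
  expect_equal(s3$p95_r_nm, 0.95, tolerance = 0.02)
  expect_error(summarize_sampling(numeric(0)), class = "smlm_parameter_error")
})

test_that("worst-case sampling predicts the frequency cutoff better than the mean", {
  # nucleus-like structure: dense blobs are finely sampled, the background is
  # not; the recoverable frequency band should track the sparse (p95) radius
  ph <- make_nucleus_phantom(256, 256, 6.4, n_blobs = 3, blob_radius = 250, seed = 8)
  em <- sample_emitters(ph, 2e4, kappa = 0, seed = 9)
  rec <- render(em, ph, kernel = "square", d = 6.4)
  fs <- q_freq(ph, rec, k = 32)
  below <- which(fs$q < 0.5)
  cutoff <- fs$f_cycles_per_nm[min(below)]
  vr <- voronoi_radii(em, ph)
  s <- summarize_sampling(vr, delta_g = 0)$summary
  f_mean <- 1 / (2 * s$mean_r_nm)
  f_p95 <- 1 / (2 * s$p95_r_nm)
  expect_lt(abs(cutoff - f_p95), abs(cutoff - f_mean))
})

test_that("sampling statistics export to CSV and JSON", {
  st <- summarize_sampling(c(3, 4, 5, 6), delta_g = 4)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_sampling_stats(st, csv_path = csv, json_path = js)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_named(back, c("delta_r_nm", "delta_l_nm"))
  expect_equal(back$delta_l_nm[1], 5)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$n, 4)
  expect_length(meta$whiskers, 2)
})
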