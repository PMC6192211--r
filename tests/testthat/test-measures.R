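test_that("Pearson measure: self-correlation, affine invariance, hand-computed case", {
  m <- random_image(16, 1)
  expect_equal(q_pearson(m, m), 1)
  expect_equal(q_pearson(m, 2.5 * m + 3), 1)
  # reversed 2x2 ramp: rec = 3 - ref, perfectly anti-correlated
  ref <- matrix(c(0, 2, 1, 3), 2, 2)
  rec <- matrix(c(3, 1, 2, 0), 2, 2)
  expect_equal(q_pearson(ref, rec), -1)
  expect_error(q_pearson(m, matrix(1, 16, 16)), class = "smlm_degenerate_error")
  expect_error(q_pearson(m, random_image(8)), class = "smlm_parameter_error")
})

test_that("Otsu threshold separates modes and scales with intensity", {
  m <- matrix(c(rep(0, 128), rep(1, 128)), 16, 16)
  t1 <- otsu_threshold(m)
  expect_gt(t1, 0); expect_lt(t1, 1)
  expect_equal(otsu_threshold(m * 10), t1 * 10)
  expect_error(otsu_threshold(matrix(0.3, 8, 8)), class = "smlm_degenerate_error")
})

test_that("Otsu threshold misclassifies under 1% of two well-separated clusters", {
  withr::with_seed(42, {
    lo <- rnorm(5000, 0.2, 0.05)
    hi <- rnorm(5000, 0.8, 0.05)
  })
  img <- matrix(c(lo, hi), 100, 100)
  thr <- otsu_threshold(img)
  truth <- matrix(rep(c(FALSE, TRUE), each = 5000), 100, 100)
  expect_lt(mean((img > thr) != truth), 0.01)
})

test_that("binarized overlap agreement follows its defining substitution", {
  # reference: 100 foreground pixels in a 32x32 image
  ref <- matrix(0, 32, 32); ref[1:100] <- 1
  expect_equal(q_binarized(ref, ref), 1)
  # rec keeps all 100 and adds 50 false positives: 1 - 50/100
  rec <- ref; rec[101:150] <- 1
  expect_equal(q_binarized(ref, rec), 0.5)
  # rec keeps 50, misses 50, adds 50 elsewhere: 1 - 100/100 = 0
  rec2 <- matrix(0, 32, 32); rec2[1:50] <- 1; rec2[201:250] <- 1
  expect_equal(q_binarized(ref, rec2), 0)
  # disjoint foregrounds of equal size: negative, returned unclamped
  rec3 <- matrix(0, 32, 32); rec3[301:400] <- 1
  expect_equal(q_binarized(ref, rec3), -1)
})

test_that("normalized squared L2: zero at agreement, 2 at orthogonality, range [0, 4]", {
  m <- random_image(24, 3)
  expect_equal(q_l2(m, m), 0)
  expect_equal(q_l2(m, 0.7 * m + 0.1), 0, tolerance = 1e-12)
  # orthogonalized pair: expand the norm as 2 - 2 <u, v> = 2
  u <- as.vector(scale(as.vector(random_image(24, 4)), scale = FALSE))
  v <- as.vector(scale(as.vector(random_image(24, 5)), scale = FALSE))
  v <- v - sum(u * v) / sum(u * u) * u
  expect_equal(q_l2(matrix(u, 24, 24), matrix(v, 24, 24)), 2, tolerance = 1e-10)
  expect_equal(q_l2(m, -m), 4)
  expect_error(q_l2(m, matrix(5, 24, 24)), class = "smlm_degenerate_error")
})

test_that("L2 measure equals 2 * (1 - Pearson) on random pairs to 1e-10", {
  for (s in 1:100) {
    a <- random_image(16, s)
    b <- random_image(16, s + 1000)
    expect_equal(q_l2(a, b), 2 * (1 - q_pearson(a, b)), tolerance = 1e-10)
  }
})

test_that("phase-agreement spectrum is 1 on every ring for identical images", {
  ph <- make_filament_phantom(128, 128, 6.4, n_filaments = 4, thickness = 40, seed = 2)
  fs <- q_freq(ph, ph, k = 16)
  expect_s3_class(fs, "freq_similarity")
  expect_equal(nrow(fs), 16)
  expect_true(all(abs(fs$q[fs$n_samples > 0] - 1) < 1e-12))
  # ring centers increase and the last ring edge is the Nyquist frequency
  expect_true(all(diff(fs$f_cycles_per_nm) > 0))
  expect_equal(attr(fs, "f_max"), 1 / (2 * 6.4))
  expect_equal(attr(fs, "delta_f") * 16, attr(fs, "f_max"))
})

test_that("phase-agreement spectrum ignores Fourier amplitudes", {
  a <- random_image(64, 10); b <- random_image(64, 11)
  expect_equal(q_freq(a, b, k = 8)$q, q_freq(a, 37.5 * b, k = 8)$q, tolerance = 1e-12)
})

test_that("independent white-noise images have near-zero phase agreement on all rings", {
  for (s in c(21, 22, 23)) {
    a <- random_image(256, s)
    b <- random_image(256, s + 500)
    fs <- q_freq(a, b, k = 32)
    expect_true(all(abs(fs$q) < 4 / sqrt(fs$n_samples)))
  }
})

test_that("blur plus noise degrades high frequencies first", {
  ph <- make_filament_phantom(256, 256, 6.4, n_filaments = 6, thickness = 50, seed = 4)
  blurred <- smlmetrics:::gaussian_blur_fft(unclass(ph), sigma = 4)
  withr::with_seed(9, noisy <- blurred + matrix(rnorm(256^2, 0, 0.05), 256, 256))
  fs <- q_freq(ph, noisy, k = 32)
  expect_gt(fs$q[1], 0.8)
  expect_lt(mean(fs$q[28:32]), 0.3)
  expect_gt(mean(fs$q[1:3]), mean(fs$q[30:32]))
})

test_that("a one-pixel shift degrades high-frequency rings before low-frequency rings", {
  ph <- make_filament_phantom(128, 128, 6.4, n_filaments = 5, thickness = 40, seed = 6)
  shifted <- unclass(ph)[, c(128, 1:127)]
  fs <- q_freq(ph, shifted, k = 16)
  expect_gt(mean(fs$q[1:5]), mean(fs$q[12:16]))
  expect_gt(fs$q[1], 0.9)
})

test_that("similarity measures are symmetric in their arguments", {
  a <- random_image(32, 31); b <- random_image(32, 32)
  expect_equal(q_pearson(a, b), q_pearson(b, a))
  expect_equal(q_l2(a, b), q_l2(b, a))
  expect_equal(q_freq(a, b, k = 8)$q, q_freq(b, a, k = 8)$q)
})

test_that("ring count is validated against resolvable rings", {
  a <- random_image(32, 1)
  expect_error(q_freq(a, a, k = 17), class = "smlm_parameter_error")
  expect_error(q_freq(a, a, k = 1), class = "smlm_parameter_error")
  expect_silent(q_freq(a, a, k = 16))
})

test_that("spectra serialize to CSV and JSON", {
  a <- random_image(32, 2); b <- random_image(32, 3)
  fs <- q_freq(a, b, k = 8, pixel_size = 6.4)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_freq_similarity(fs, csv, "csv")
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_named(back, c("f_cycles_per_nm", "q"))
  expect_equal(back$q, fs$q)
  js <- withr::local_tempfile(fileext = ".json")
  write_freq_similarity(fs, js, "json")
  expect_equal(jsonlite::read_json(js)$k, 8)
})
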