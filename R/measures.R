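#' Pearson correlation between reference and reconstruction
#'
#' The most common scale-free image similarity measure: the Pearson correlation
#' coefficient of the two pixel-intensity vectors. Insensitive to affine
#' intensity transforms of either image, which matters because a rendered SMLM
#' reconstruction has no natural overall intensity scale.
#'
#' @param ref,rec Same-shape numeric image matrices (any `smlm_image` or plain
#'   matrix); both must be non-constant.
#' @return A number in \[-1, 1\].
#' @export
q_pearson <- function(ref, rec) {
  check_image_pair(ref, rec)
  if (is_constant(ref) || is_constant(rec)) {
    abort("Pearson correlation is undefined for a constant image.",
          class = "smlm_degenerate_error")
  }
  cor(as.vector(unclass(ref)), as.vector(unclass(rec)))
}

#' Otsu intensity threshold
#'
#' Histogram-based automatic threshold maximizing the between-class variance,
#' computed on 256 bins spanning the image's own \[min, max\] range. Foreground
#' is `img > threshold`.
#'
#' @param img Numeric image matrix with at least two distinct values.
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(img) {
  rng <- range(img)
  if (rng[1] == rng[2]) {
    abort("Otsu threshold is undefined for a constant image.",
          class = "smlm_degenerate_error")
  }
  EBImage::otsu(unclass(img), range = rng, levels = 256L)
}

#' Overlap agreement between Otsu-binarized images
#'
#' Both images are thresholded independently by the Otsu method; the agreement
#' is `1 - sum(|B0 - Brec|) / sum(B0)` where `B0`, `Brec` are the binary masks
#' of the reference and reconstruction. The value is 1 for identical masks and
#' decreases by one unit of reference-foreground area per misclassified pixel;
#' it can be negative when the false-positive area exceeds the reference
#' foreground, and is returned unclamped.
#'
#' @inheritParams q_pearson
#' @return A number <= 1 (possibly negative).
#' @export
q_binarized <- function(ref, rec) {
  check_image_pair(ref, rec)
  b0 <- unclass(ref) > otsu_threshold(ref)
  br <- unclass(rec) > otsu_threshold(rec)
  f <- sum(b0)
  if (f == 0) {
    abort("Reference binarizes to empty foreground; overlap agreement undefined.",
          class = "smlm_degenerate_error")
  }
  1 - sum(abs(b0 - br)) / f
}

#' Normalized squared L2 distance
#'
#' Each image is mean-centered and scaled to unit L2 norm; the measure is the
#' sum of squared differences of the two normalized images. Zero for perfect
#' agreement (up to any positive affine intensity transform), and emphasizes
#' large local intensity differences. Algebraically equal to
#' `2 * (1 - q_pearson)`, with range \[0, 4\].
#'
#' @inheritParams q_pearson
#' @return A non-negative number.
#' @export
q_l2 <- function(ref, rec) {
  check_image_pair(ref, rec)
  u <- as.vector(unclass(ref)); v <- as.vector(unclass(rec))
  u <- u - mean(u); v <- v - mean(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort("Normalized L2 distance is undefined for a constant image (zero norm).",
          class = "smlm_degenerate_error")
  }
  sum((u / nu - v / nv)^2)
}

#' Phase-agreement similarity spectrum in frequency space
#'
#' A frequency-resolved similarity measure mathematically similar to Fourier
#' Ring Correlation, computed against a ground-truth reference. Both images are
#' Fourier transformed and each spectrum is decomposed into amplitude and pure
#' phase factors; for each ring of radial frequency `]f, f + delta_f]` (with
#' `delta_f = f_max / k` and `f_max` the Nyquist frequency of the pixel grid)
#' the measure is the ring average of the real part of the product of the two
#' unit phase factors, `cos(eta_ref - eta_rec)`. It equals 1 on every ring when
#' the images agree perfectly at that frequency and 0 in expectation when they
#' are uncorrelated. Amplitudes are discarded entirely, so rescaling either
#' spectrum leaves the measure unchanged.
#'
#' The DC sample is excluded (its phase carries no structural information for
#' non-negative images), as are samples beyond the Nyquist ring (grid corners)
#' and samples where either amplitude is exactly zero (undefined phase). A
#' ring with no valid samples is reported as `NA`.
#'
#' @inheritParams q_pearson
#' @param k Number of frequency rings (>= 2, at most `min(dim) / 2`).
#' @param pixel_size Physical pixel size in nm; defaults to the `ref`
#'   attribute (1 if absent). Only scales the reported frequencies.
#' @param window `"none"` (default) or `"tukey"`: optionally taper both images
#'   with a separable Tukey (alpha = 0.5) window to reduce spectral leakage on
#'   non-periodic real images.
#' @return A `freq_similarity` tibble with columns `ring`, `f_cycles_per_nm`
#'   (ring-center frequency), `q`, `n_samples`, and attributes `k`, `delta_f`,
#'   `f_max`.
#' @export
q_freq <- function(ref, rec, k = 64L, pixel_size = NULL, window = c("none", "tukey")) {
  check_image_pair(ref, rec)
  window <- match.arg(window)
  nr <- nrow(ref); nc <- ncol(ref)
  k <- as.integer(k)
  if (k < 2L) abort("`k` must be >= 2.", class = "smlm_parameter_error")
  if (k > min(nr, nc) %/% 2L) {
    abort(sprintf("`k` = %d exceeds the number of resolvable rings (%d).",
                  k, min(nr, nc) %/% 2L),
          class = "smlm_parameter_error")
  }
  ps <- if (is.null(pixel_size)) pixel_size(ref) else pixel_size
  a <- unclass(ref); b <- unclass(rec)
  if (window == "tukey") {
    w <- outer(tukey_window(nr), tukey_window(nc))
    a <- a * w; b <- b * w
  }
  fa <- fft(a); fb <- fft(b)

  # radial frequency of every sample, normalized to the Nyquist frequency
  fi <- fft_freqs(nr); fj <- fft_freqs(nc)
  rnorm2 <- outer(fi^2, fj^2, "+") * 4  # (f / f_max)^2 since f_max = 1/2 cycles/px
  ring <- ceiling(sqrt(rnorm2) * k)     # half-open rings ](r-1) df, r df]

  ma <- Mod(fa); mb <- Mod(fb)
  valid <- ring >= 1L & ring <= k & ma > 0 & mb > 0
  # cos(eta_ref - eta_rec) = Re(Fa * Conj(Fb)) / (|Fa| |Fb|)
  agree <- Re(fa * Conj(fb))[valid] / (ma[valid] * mb[valid])
  ring_v <- ring[valid]
  sums <- vapply(split(agree, factor(ring_v, levels = seq_len(k))), sum, numeric(1))
  counts <- tabulate(ring_v, nbins = k)
  q <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)

  f_max <- 1 / (2 * ps)
  delta_f <- f_max / k
  structure(tibble(ring = seq_len(k),
                   f_cycles_per_nm = (seq_len(k) - 0.5) * delta_f,
                   q = as.numeric(q),
                   n_samples = counts),
            k = k, delta_f = delta_f, f_max = f_max, pixel_size = ps,
            class = c("freq_similarity", class(tibble())))
}

# DFT sample frequencies in cycles/pixel (unshifted order)
fft_freqs <- function(n) {
  i <- seq_len(n) - 1L
  ifelse(i <= n %/% 2, i, i - n) / n
}

tukey_window <- function(n, alpha = 0.5) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

is_constant <- function(img) {
  rng <- range(img)
  rng[1] == rng[2]
}

#' Serialize a frequency-similarity spectrum
#'
#' @param fs A `freq_similarity` object.
#' @param path Output path.
#' @param format `"csv"` (columns `f_cycles_per_nm`, `q`) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_freq_similarity <- function(fs, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(tibble(f_cycles_per_nm = fs$f_cycles_per_nm, q = fs$q), path)
  } else {
    jsonlite::write_json(list(k = attr(fs, "k"), delta_f = attr(fs, "delta_f"),
                              f_max = attr(fs, "f_max"),
                              f_cycles_per_nm = fs$f_cycles_per_nm, q = fs$q),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Plot a frequency-similarity spectrum
#'
#' @param object A `freq_similarity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.freq_similarity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f_cycles_per_nm, y = .data$q)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", color = "grey50") +
    ggplot2::geom_area(alpha = 0.3, fill = "seagreen") +
    ggplot2::geom_line(color = "seagreen") +
    ggplot2::labs(x = "spatial frequency (cycles/nm)", y = "phase agreement") +
    ggplot2::theme_minimal()
}
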