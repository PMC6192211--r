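#' Filament phantom: repetitive curvilinear structures
#'
#' Generates a synthetic density map emulating filament-like biological
#' structures (e.g. lipid membranes in neuronal tissue): several smooth,
#' roughly uniformly distributed curvilinear ridges of a given thickness on a
#' near-zero background. Each filament is a random cubic Bezier curve spanning
#' the image; the rasterized curves are blurred with a Gaussian whose full
#' width at half maximum equals `thickness`, so Otsu binarization recovers
#' ridges of approximately the requested width.
#'
#' @param width,height Image size in pixels (>= 8).
#' @param pixel_size Pixel side in nm.
#' @param n_filaments Number of filaments (>= 1).
#' @param thickness Ridge thickness (FWHM) in nm; at least one pixel.
#' @param seed Integer seed; the phantom is bit-reproducible for a fixed seed.
#' @return A [density_image()] with values spanning \[0, 1\].
#' @examples
#' ph <- make_filament_phantom(128, 128, 6.4, n_filaments = 4, thickness = 50, seed = 1)
#' @export
make_filament_phantom <- function(width, height, pixel_size, n_filaments = 6L,
                                  thickness = 50, seed = 1L) {
  check_phantom_dims(width, height, pixel_size)
  if (!is.numeric(n_filaments) || n_filaments < 1) {
    abort("`n_filaments` must be >= 1.", class = "smlm_parameter_error")
  }
  if (thickness < pixel_size) {
    abort("`thickness` must be at least one pixel equivalent.", class = "smlm_parameter_error")
  }
  withr::local_seed(as.integer(seed))
  canvas <- matrix(0, nrow = height, ncol = width)
  n_samp <- 4L * max(width, height)
  tt <- seq(0, 1, length.out = n_samp)
  for (f in seq_len(n_filaments)) {
    # endpoints on two random (distinct) borders, control points interior
    ends <- random_border_points(width, height)
    cx <- c(ends$x[1], runif(2, 0.1 * width, 0.9 * width), ends$x[2])
    cy <- c(ends$y[1], runif(2, 0.1 * height, 0.9 * height), ends$y[2])
    bx <- bezier_eval(cx, tt)
    by <- bezier_eval(cy, tt)
    j <- pmin(pmax(ceiling(bx), 1L), width)
    i <- pmin(pmax(ceiling(by), 1L), height)
    canvas[cbind(i, j)] <- 1
  }
  sigma_px <- (thickness / pixel_size) / (2 * sqrt(2 * log(2)))
  out <- gaussian_blur_fft(canvas, sigma_px)
  out <- pmax(out, 0)
  out <- out / max(out)
  img <- density_image(out, pixel_size)
  attr(img, "generator") <- list(type = "filament", n_filaments = n_filaments,
                                 thickness_nm = thickness, seed = as.integer(seed))
  img
}

#' Nucleus phantom: few dense blobs over a sparse background
#'
#' Generates a synthetic density map emulating a nucleus-like structure: a few
#' compact high-density regions (concentrated chromatin) occupying a small
#' fraction of the image area, over a sparse, weakly textured background. Each
#' blob has a Gaussian radial profile whose density falls to 0.5 at about
#' 0.59 x `blob_radius` and is negligible beyond the radius.
#'
#' @inheritParams make_filament_phantom
#' @param n_blobs Number of dense regions (>= 1).
#' @param blob_radius Blob radius in nm; blobs must fit inside the image.
#' @return A [density_image()].
#' @export
make_nucleus_phantom <- function(width, height, pixel_size, n_blobs = 3L,
                                 blob_radius = 400, seed = 1L) {
  check_phantom_dims(width, height, pixel_size)
  if (!is.numeric(n_blobs) || n_blobs < 1) {
    abort("`n_blobs` must be >= 1.", class = "smlm_parameter_error")
  }
  r_px <- blob_radius / pixel_size
  if (2 * r_px > min(width, height)) {
    abort("`blob_radius` too large: a blob must fit inside the image.",
          class = "smlm_parameter_error")
  }
  withr::local_seed(as.integer(seed))
  # sparse background: low constant level plus smooth texture
  bg <- gaussian_blur_fft(matrix(runif(height * width), height, width), 8)
  bg <- 0.03 + 0.07 * (bg - min(bg)) / (max(bg) - min(bg))
  canvas <- bg
  sigma_b <- r_px / 2
  jc <- runif(n_blobs, r_px, width - r_px)
  ic <- runif(n_blobs, r_px, height - r_px)
  jj <- matrix(rep(seq_len(width) - 0.5, each = height), height, width)
  ii <- matrix(rep(seq_len(height) - 0.5, times = width), height, width)
  for (b in seq_len(n_blobs)) {
    r2 <- (jj - jc[b])^2 + (ii - ic[b])^2
    canvas <- pmax(canvas, exp(-r2 / (2 * sigma_b^2)))
  }
  img <- density_image(pmin(canvas, 1), pixel_size)
  attr(img, "generator") <- list(type = "nucleus", n_blobs = n_blobs,
                                 blob_radius_nm = blob_radius, seed = as.integer(seed))
  img
}

check_phantom_dims <- function(width, height, pixel_size) {
  if (!is.numeric(width) || !is.numeric(height) || width < 8 || height < 8) {
    abort("`width` and `height` must be >= 8 pixels.", class = "smlm_parameter_error")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be positive.", class = "smlm_parameter_error")
  }
  invisible(NULL)
}

# two points on distinct random borders of a width x height image (px units)
random_border_points <- function(width, height) {
  sides <- sample(4L, 2L)
  pt <- function(side) {
    switch(side,
           c(runif(1, 0, width), 0),          # top
           c(width, runif(1, 0, height)),     # right
           c(runif(1, 0, width), height),     # bottom
           c(0, runif(1, 0, height)))         # left
  }
  p1 <- pt(sides[1]); p2 <- pt(sides[2])
  list(x = c(p1[1], p2[1]), y = c(p1[2], p2[2]))
}

# cubic Bezier through 4 control values
bezier_eval <- function(p, t) {
  (1 - t)^3 * p[1] + 3 * (1 - t)^2 * t * p[2] + 3 * (1 - t) * t^2 * p[3] + t^3 * p[4]
}

# periodic Gaussian blur via FFT; sigma in pixels
gaussian_blur_fft <- function(m, sigma) {
  if (sigma <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  gi <- circular_gaussian(nr, sigma)
  gj <- circular_gaussian(nc, sigma)
  kern <- outer(gi, gj)
  kern <- kern / sum(kern)
  Re(fft(fft(m) * fft(kern), inverse = TRUE)) / (nr * nc)
}

circular_gaussian <- function(n, sigma) {
  d <- c(0:(n %/% 2), rev(seq_len(n - n %/% 2 - 1)))
  exp(-d^2 / (2 * sigma^2))
}
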