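#' Construct a density image
#'
#' A `density_image` is a numeric matrix of relative emitter density together
#' with the physical pixel size. Values are dimensionless and must lie in
#' \[0, 1\]; the map doubles as the ground-truth reference when scoring a
#' reconstruction.
#'
#' The coordinate convention used throughout the package is: origin at the
#' top-left corner of the image, x increasing rightward (along columns),
#' y increasing downward (along rows). The continuous coordinate of the center
#' of the pixel in row `i`, column `j` (1-based) is
#' `((j - 0.5) * pixel_size, (i - 0.5) * pixel_size)` in nanometres.
#'
#' @param values Numeric matrix of relative densities in \[0, 1\]. Rows map to
#'   image height, columns to width.
#' @param pixel_size Physical side length of one pixel, in nanometres.
#' @return A `density_image` object (a matrix with `pixel_size` attribute).
#' @export
density_image <- function(values, pixel_size) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "smlm_parameter_error")
  }
  if (nrow(values) < 8L || ncol(values) < 8L) {
    abort("Density images must be at least 8x8 pixels.", class = "smlm_parameter_error")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (nm).", class = "smlm_parameter_error")
  }
  if (anyNA(values) || min(values) < 0 || max(values) > 1) {
    abort("Density values must be finite and lie in [0, 1].", class = "smlm_parameter_error")
  }
  structure(values,
            pixel_size = as.numeric(pixel_size),
            class = c("density_image", "smlm_image", "matrix", "array"))
}

#' @export
print.density_image <- function(x, ...) {
  cat(sprintf("<density_image> %d x %d px @ %g nm/px (%.1f x %.1f nm)\n",
              ncol(x), nrow(x), pixel_size(x),
              ncol(x) * pixel_size(x), nrow(x) * pixel_size(x)))
  cat(sprintf("  density range [%.4g, %.4g], mean %.4g\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image> %d x %d px @ %g nm/px | kernel %s, d = %g nm, %d emitters\n",
              ncol(x), nrow(x), pixel_size(x), attr(x, "kernel"), attr(x, "d"),
              attr(x, "n_rendered")))
  cat(sprintf("  intensity range [%.4g, %.4g], total %.6g\n",
              min(x), max(x), sum(x)))
  invisible(x)
}

#' Physical pixel size of an image
#'
#' @param img A `density_image`, `rendered_image`, or plain matrix.
#' @return Pixel side length in nm (1 for a plain matrix with no attribute).
#' @export
pixel_size <- function(img) {
  ps <- attr(img, "pixel_size")
  if (is.null(ps)) 1 else ps
}

#' Physical extent of an image
#'
#' @inheritParams pixel_size
#' @return Named numeric vector with `width_nm` and `height_nm`.
#' @export
image_extent <- function(img) {
  ps <- pixel_size(img)
  c(width_nm = ncol(img) * ps, height_nm = nrow(img) * ps)
}

#' Load a grayscale reference image as a density map
#'
#' Reads a single-channel 8- or 16-bit grayscale TIFF and linearly rescales its
#' intensities so that the minimum maps to 0 and the maximum to 1. The rescaled
#' image is interpreted as a relative emitter (labeling) density; intensity is
#' assumed to map linearly to density.
#'
#' @param path Path to a grayscale TIFF file.
#' @param pixel_size Physical pixel size in nm (e.g. 6.4 for the SEM reference
#'   geometry of a 2048x2048 frame).
#' @return A [density_image()].
#' @export
load_reference <- function(path, pixel_size) {
  if (!file.exists(path)) {
    abort(sprintf("Reference image not found: %s", path), class = "smlm_io_error")
  }
  img <- tryCatch(tiff::readTIFF(path, as.is = FALSE),
                  error = function(e) {
                    abort(sprintf("Failed to read TIFF '%s': %s", path, conditionMessage(e)),
                          class = "smlm_io_error")
                  })
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L) {
      abort("Multi-channel (RGB/RGBA) TIFFs are not supported; supply a grayscale image.",
            class = "smlm_format_error")
    }
    img <- img[, , 1L]
  }
  rng <- range(img)
  if (rng[1] == rng[2]) {
    abort("Reference image is constant (zero dynamic range); cannot be used as a density map.",
          class = "smlm_degenerate_error")
  }
  density_image((img - rng[1]) / (rng[2] - rng[1]), pixel_size)
}

#' Write a density map or rendered image as a 16-bit TIFF
#'
#' Intensities are linearly rescaled to the full 16-bit range; the scale and
#' the physical pixel size are recorded in a sidecar JSON file (`<path>.json`)
#' so the image can be reloaded without loss of physical meaning.
#'
#' @param img A `density_image` or `rendered_image`.
#' @param path Output TIFF path.
#' @param sidecar Write the sidecar JSON (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, sidecar = TRUE) {
  rng <- range(img)
  scaled <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  tiff::writeTIFF(unclass(scaled), path, bits.per.sample = 16L)
  if (isTRUE(sidecar)) {
    meta <- list(pixel_size_nm = pixel_size(img),
                 intensity_min = rng[1], intensity_max = rng[2],
                 width_px = ncol(img), height_px = nrow(img))
    for (a in c("kernel", "d", "sigma", "n_rendered", "generator")) {
      if (!is.null(attr(img, a))) meta[[a]] <- attr(img, a)
    }
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# internal: validate a pair of same-shape images for the similarity measures
check_image_pair <- function(ref, rec) {
  if (!all(dim(ref) == dim(rec))) {
    abort("Reference and reconstruction must have identical dimensions.",
          class = "smlm_parameter_error")
  }
  invisible(NULL)
}
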