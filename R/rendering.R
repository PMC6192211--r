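#' Render localized emitters into a reconstructed image
#'
#' Deposits a kernel at each localized emitter position and accumulates
#' additively (overlapping kernels sum). Two kernels are supported:
#'
#' * `"square"`: an axis-aligned `d` x `d` nm square of constant amplitude 1,
#'   rasterized over all pixels whose centers fall inside it. A pixel center
#'   exactly on the square boundary is included on the low-coordinate side.
#' * `"gaussian"`: an isotropic Gaussian of peak amplitude 1, sampled at pixel
#'   centers and truncated at 3 standard deviations per axis. The deviation is
#'   `d / 2` by default (`sigma_convention = "half_d"`, i.e. `2 * sigma = d`,
#'   the convention that makes square and Gaussian renderings of width `d`
#'   comparable); `sigma_convention = "d"` selects `sigma = d`.
#'
#' Kernel footprints are clipped at image borders; emitters whose footprint
#' falls entirely outside contribute nothing but still count toward
#' `n_rendered`. Per-emitter amplitude is constant (not unit mass): all four
#' similarity measures are invariant to a global intensity scale, so amplitude
#' normalization would only rescale the image.
#'
#' @param emitters An `emitter_set` (non-empty).
#' @param geometry Image geometry: a `density_image` (or any image with a
#'   `pixel_size` attribute), or a list with `width_px`, `height_px`,
#'   `pixel_size`. Defaults to the geometry recorded in `emitters`.
#' @param kernel `"square"` or `"gaussian"`.
#' @param d Kernel size in nm (> 0): square side, or Gaussian width parameter.
#' @param sigma_convention For the Gaussian kernel, `"half_d"` (default,
#'   `sigma = d/2`) or `"d"` (`sigma = d`). Recorded in the output.
#' @return A `rendered_image`: intensity matrix with attributes `pixel_size`,
#'   `kernel`, `d`, `sigma`, `sigma_convention`, `n_rendered`.
#' @export
render <- function(emitters, geometry = NULL, kernel = c("square", "gaussian"),
                   d = 32, sigma_convention = c("half_d", "d")) {
  kernel <- match.arg(kernel)
  sigma_convention <- match.arg(sigma_convention)
  geo <- as_geometry(geometry, emitters)
  if (NROW(emitters) < 1) {
    abort("Emitter set is empty.", class = "smlm_parameter_error")
  }
  if (!is.numeric(d) || d <= 0) {
    abort("`d` must be positive (nm).", class = "smlm_parameter_error")
  }
  if (d < geo$pixel_size / 2) {
    warn(sprintf("d = %g nm is below half a pixel (%g nm); emitters deposit on single pixels.",
                 d, geo$pixel_size))
  }
  sigma <- if (sigma_convention == "half_d") d / 2 else d
  vals <- if (kernel == "square") {
    render_square_cpp(emitters$x_nm, emitters$y_nm, geo$height_px, geo$width_px,
                      geo$pixel_size, d)
  } else {
    render_gaussian_cpp(emitters$x_nm, emitters$y_nm, geo$height_px, geo$width_px,
                        geo$pixel_size, sigma)
  }
  new_rendered_image(vals, geo$pixel_size, kernel, d,
                     if (kernel == "gaussian") sigma else NA_real_,
                     sigma_convention, NROW(emitters))
}

new_rendered_image <- function(vals, pixel_size, kernel, d, sigma, sigma_convention,
                               n_rendered) {
  structure(vals, pixel_size = pixel_size, kernel = kernel, d = d, sigma = sigma,
            sigma_convention = sigma_convention, n_rendered = as.integer(n_rendered),
            class = c("rendered_image", "smlm_image", "matrix", "array"))
}

#' Incremental (frame-by-frame) rendering
#'
#' Emulates the acquisition-order reconstruction: at each step `n_f` emitters
#' are selected at random without replacement from the remaining list and
#' deposited onto the running image; the procedure continues until all emitters
#' are used. Frame `t` therefore contains `t * n_f` emitters (the last frame
#' all of them), and the final frame equals the one-shot [render()] of the full
#' set (bit-identical for the square kernel, whose deposits are exact
#' integers; for the Gaussian kernel equal up to floating-point summation
#' order).
#'
#' @inheritParams render
#' @param n_f Emitters selected per step (1 <= `n_f` <= number of emitters).
#' @param seed Integer seed for the random selection order.
#' @return A list of `rendered_image` frames (cumulative), length
#'   `ceiling(n / n_f)`.
#' @export
incremental_render <- function(emitters, geometry = NULL,
                               kernel = c("square", "gaussian"), d = 32, n_f,
                               seed = 1L, sigma_convention = c("half_d", "d")) {
  kernel <- match.arg(kernel)
  sigma_convention <- match.arg(sigma_convention)
  n <- NROW(emitters)
  if (n < 1) abort("Emitter set is empty.", class = "smlm_parameter_error")
  if (!is.numeric(n_f) || n_f < 1 || n_f > n) {
    abort("`n_f` must satisfy 1 <= n_f <= number of emitters.",
          class = "smlm_parameter_error")
  }
  geo <- as_geometry(geometry, emitters)
  withr::local_seed(as.integer(seed))
  ord <- sample.int(n)
  n_f <- as.integer(n_f)
  n_frames <- ceiling(n / n_f)
  frames <- vector("list", n_frames)
  acc <- NULL
  sigma <- if (sigma_convention == "half_d") d / 2 else d
  for (t in seq_len(n_frames)) {
    idx <- ord[(((t - 1L) * n_f) + 1L):min(t * n_f, n)]
    step <- if (kernel == "square") {
      render_square_cpp(emitters$x_nm[idx], emitters$y_nm[idx],
                        geo$height_px, geo$width_px, geo$pixel_size, d)
    } else {
      render_gaussian_cpp(emitters$x_nm[idx], emitters$y_nm[idx],
                          geo$height_px, geo$width_px, geo$pixel_size, sigma)
    }
    acc <- if (is.null(acc)) step else acc + step
    frames[[t]] <- new_rendered_image(acc, geo$pixel_size, kernel, d,
                                      if (kernel == "gaussian") sigma else NA_real_,
                                      sigma_convention, min(t * n_f, n))
  }
  frames
}

# resolve the target raster geometry from an image, a list, or emitter metadata
as_geometry <- function(geometry, emitters = NULL) {
  if (inherits(geometry, "smlm_image") || (is.matrix(geometry) && !is.null(attr(geometry, "pixel_size")))) {
    return(list(width_px = ncol(geometry), height_px = nrow(geometry),
                pixel_size = pixel_size(geometry)))
  }
  if (is.list(geometry) && all(c("width_px", "height_px", "pixel_size") %in% names(geometry))) {
    return(geometry[c("width_px", "height_px", "pixel_size")])
  }
  if (is.null(geometry) && !is.null(emitters)) {
    g <- list(width_px = attr(emitters, "width_px"),
              height_px = attr(emitters, "height_px"),
              pixel_size = attr(emitters, "pixel_size"))
    if (!anyNA(unlist(g))) return(g)
  }
  abort("Supply `geometry` (an image, or list(width_px, height_px, pixel_size)).",
        class = "smlm_parameter_error")
}
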