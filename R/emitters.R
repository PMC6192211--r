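#' Simulate detected emitters from a density map
#'
#' Draws emitter positions by rejection sampling against the relative density
#' map and perturbs each accepted position with independent Gaussian
#' localization error in x and y. This emulates the STORM/PALM detection
#' pipeline: the structure is labeled in proportion to the local density
#' `rho(x, y)` and each detection is localized with finite accuracy `kappa`.
#'
#' Candidate coordinates are continuous-uniform over the image rectangle; a
#' candidate at `(x, y)` is accepted when an independent uniform `p <= rho(x, y)`,
#' with `rho` evaluated at the containing pixel (or bilinearly, see `interp`).
#' Sampling proceeds until exactly `n_max` emitters are accepted; accepted
#' positions are then perturbed by `N(0, kappa^2)` offsets. All draws come from
#' one seeded stream in a fixed order (candidate x, y, p per batch, then the x
#' offsets, then the y offsets), so runs are bit-reproducible. Perturbed
#' emitters may fall slightly outside the image; they are kept (rendering clips
#' their footprint).
#'
#' @param density A [density_image()]; must contain at least one positive pixel.
#' @param n_max Number of emitters to accept (>= 1).
#' @param kappa Localization accuracy in nm (standard deviation of the Gaussian
#'   localization error; >= 0). A single `kappa` applies to all emitters.
#' @param seed Integer seed.
#' @param interp Density lookup: `"nearest"` (containing pixel, default) or
#'   `"bilinear"`.
#' @return An `emitter_set`: a tibble with columns `x_nm`, `y_nm` (localized
#'   positions), `x_true_nm`, `y_true_nm` (accepted positions before
#'   localization error), and attributes `kappa`, `seed`, `pixel_size`,
#'   `width_px`, `height_px`, `n_candidates`.
#' @export
sample_emitters <- function(density, n_max, kappa, seed, interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  if (!inherits(density, "density_image")) {
    abort("`density` must be a density_image.", class = "smlm_parameter_error")
  }
  if (!is.numeric(n_max) || n_max < 1) {
    abort("`n_max` must be >= 1.", class = "smlm_parameter_error")
  }
  if (!is.numeric(kappa) || kappa < 0) {
    abort("`kappa` must be >= 0.", class = "smlm_parameter_error")
  }
  if (max(density) <= 0) {
    abort("Density map is identically zero: rejection sampling cannot terminate.",
          class = "smlm_degenerate_error")
  }
  n_max <- as.integer(n_max)
  ps <- pixel_size(density)
  w_nm <- ncol(density) * ps
  h_nm <- nrow(density) * ps
  pbar <- mean(density)

  withr::local_seed(as.integer(seed))
  xs <- numeric(0); ys <- numeric(0)
  n_candidates <- 0L
  while (length(xs) < n_max) {
    m <- ceiling(1.5 * (n_max - length(xs)) / pbar)
    m <- min(max(m, 1000L), 5e6)
    cx <- runif(m, 0, w_nm)
    cy <- runif(m, 0, h_nm)
    p <- runif(m)
    rho <- lookup_density(density, cx, cy, interp)
    acc <- which(p <= rho)
    needed <- n_max - length(xs)
    if (length(acc) >= needed) {
      # the sequential procedure stops at the n_max-th acceptance; candidates
      # drawn after it in this batch are not counted
      acc <- acc[seq_len(needed)]
      n_candidates <- n_candidates + acc[needed]
    } else {
      n_candidates <- n_candidates + m
    }
    xs <- c(xs, cx[acc])
    ys <- c(ys, cy[acc])
  }
  dx <- if (kappa > 0) rnorm(n_max, 0, kappa) else numeric(n_max)
  dy <- if (kappa > 0) rnorm(n_max, 0, kappa) else numeric(n_max)

  new_emitter_set(tibble(x_nm = xs + dx, y_nm = ys + dy, x_true_nm = xs, y_true_nm = ys),
                  kappa = kappa, seed = as.integer(seed), pixel_size = ps,
                  width_px = ncol(density), height_px = nrow(density),
                  n_candidates = n_candidates)
}

new_emitter_set <- function(df, kappa = NA_real_, seed = NA_integer_, pixel_size = NA_real_,
                            width_px = NA_integer_, height_px = NA_integer_,
                            n_candidates = NA_integer_) {
  structure(df,
            kappa = kappa, seed = seed, pixel_size = pixel_size,
            width_px = width_px, height_px = height_px, n_candidates = n_candidates,
            class = c("emitter_set", class(tibble())))
}

#' Build an emitter set from coordinates
#'
#' Wraps raw localized coordinates (nm) into the `emitter_set` container used
#' by the rendering and sampling-density modules.
#'
#' @param x_nm,y_nm Numeric coordinate vectors (nm), equal length.
#' @param kappa Localization accuracy in nm associated with the set (optional).
#' @param pixel_size,width_px,height_px Reference geometry (optional; required
#'   by operations that need image bounds unless supplied there).
#' @return An `emitter_set` tibble.
#' @export
emitter_set <- function(x_nm, y_nm, kappa = NA_real_, pixel_size = NA_real_,
                        width_px = NA_integer_, height_px = NA_integer_) {
  stopifnot(length(x_nm) == length(y_nm))
  new_emitter_set(tibble(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                         x_true_nm = as.numeric(x_nm), y_true_nm = as.numeric(y_nm)),
                  kappa = kappa, pixel_size = pixel_size,
                  width_px = width_px, height_px = height_px)
}

# density lookup at continuous coordinates (nm); nearest containing pixel or bilinear
lookup_density <- function(density, x, y, interp = "nearest") {
  ps <- pixel_size(density)
  nr <- nrow(density); nc <- ncol(density)
  if (interp == "nearest") {
    j <- pmin(pmax(floor(x / ps) + 1L, 1L), nc)
    i <- pmin(pmax(floor(y / ps) + 1L, 1L), nr)
    density[cbind(i, j)]
  } else {
    # bilinear between the 4 surrounding pixel centers, edge-clamped
    u <- x / ps - 0.5
    v <- y / ps - 0.5
    j0 <- pmin(pmax(floor(u), 0), nc - 1); i0 <- pmin(pmax(floor(v), 0), nr - 1)
    j1 <- pmin(j0 + 1, nc - 1); i1 <- pmin(i0 + 1, nr - 1)
    fu <- pmin(pmax(u - j0, 0), 1); fv <- pmin(pmax(v - i0, 0), 1)
    d00 <- density[cbind(i0 + 1, j0 + 1)]; d01 <- density[cbind(i0 + 1, j1 + 1)]
    d10 <- density[cbind(i1 + 1, j0 + 1)]; d11 <- density[cbind(i1 + 1, j1 + 1)]
    (1 - fv) * ((1 - fu) * d00 + fu * d01) + fv * ((1 - fu) * d10 + fu * d11)
  }
}

#' Emitter density per square micrometre
#'
#' Converts an emitter count over a given image geometry to the areal density
#' conventionally reported for SMLM data.
#'
#' @param n Emitter count (>= 0).
#' @param width,height Image size in pixels.
#' @param pixel_size Pixel side in nm.
#' @return Density in emitters per um^2.
#' @examples
#' emitter_density_per_um2(50e3, 2048, 2048, 6.4) # ~291 per um^2
#' @export
emitter_density_per_um2 <- function(n, width, height, pixel_size) {
  if (any(c(width, height, pixel_size) <= 0)) {
    abort("Image geometry must be positive (non-zero area).", class = "smlm_parameter_error")
  }
  if (any(n < 0)) abort("`n` must be >= 0.", class = "smlm_parameter_error")
  n / (width * height * pixel_size^2 * 1e-6)
}

#' Write / read a localization table
#'
#' Emitter sets round-trip through a plain CSV with columns `x_nm`, `y_nm`
#' (one row per localization), the common interchange convention for SMLM
#' localization tables.
#'
#' @param emitters An `emitter_set`.
#' @param path CSV path.
#' @return `path` invisibly (write); an `emitter_set` (read).
#' @export
write_localizations <- function(emitters, path) {
  readr::write_csv(tibble(x_nm = emitters$x_nm, y_nm = emitters$y_nm), path)
  invisible(path)
}

#' @rdname write_localizations
#' @param kappa,pixel_size,width_px,height_px Optional metadata to attach on read.
#' @export
read_localizations <- function(path, kappa = NA_real_, pixel_size = NA_real_,
                               width_px = NA_integer_, height_px = NA_integer_) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x_nm", "y_nm") %in% names(df))) {
    abort("Localization table must have columns x_nm, y_nm.", class = "smlm_format_error")
  }
  emitter_set(df$x_nm, df$y_nm, kappa = kappa, pixel_size = pixel_size,
              width_px = width_px, height_px = height_px)
}

#' @export
print.emitter_set <- function(x, ...) {
  cat(sprintf("<emitter_set> %d localizations | kappa = %s nm\n",
              nrow(x), format(attr(x, "kappa"))))
  NextMethod()
}
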