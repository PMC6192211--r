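#' Equivalent-circle sampling radii from Voronoi tessellation
#'
#' Quantifies the local sampling density of a localization data set: each
#' emitter is assigned the area of its Voronoi cell, clipped to the image
#' rectangle (infinite boundary cells are clipped, which keeps the total area
#' exactly conserved), and the local sampling interval is the radius
#' `delta_r = sqrt(area / pi)` of the circle with the same area.
#'
#' Exact duplicate positions (possible after pixel snapping) are separated by
#' a deterministic jitter of `1e-6` pixel before tessellation. A single emitter
#' is a documented degenerate path: its cell is the whole rectangle. Emitters
#' outside the rectangle participate in the tessellation (their cells may
#' still claim area inside) but are flagged, so radii are reported per emitter
#' inside bounds.
#'
#' @param emitters An `emitter_set`, or any data frame with `x_nm`, `y_nm`.
#' @param bounds Image rectangle: a `density_image`, or a numeric
#'   `c(width_nm, height_nm)` (origin at 0). Defaults to the geometry recorded
#'   in `emitters`.
#' @return A tibble with one row per emitter: `x_nm`, `y_nm`, `cell_area_nm2`,
#'   `delta_r_nm` (`NA` for a zero-area cell), `inside`; attribute
#'   `total_area_nm2` (sum of all clipped cells, equal to the rectangle area).
#' @export
voronoi_radii <- function(emitters, bounds = NULL) {
  x <- emitters$x_nm; y <- emitters$y_nm
  n <- length(x)
  if (n < 1) abort("Need at least one emitter.", class = "smlm_parameter_error")
  wh <- resolve_bounds(bounds, emitters)
  ps <- attr(emitters, "pixel_size")
  if (is.null(ps) || is.na(ps)) ps <- 1
  # deterministic separation of exact duplicates: 1e-6 px steps along +x, +y
  key <- paste(x, y)
  dup_rank <- stats::ave(seq_along(key), key, FUN = seq_along) - 1L
  if (any(dup_rank > 0)) {
    x <- x + dup_rank * 1e-6 * ps
    y <- y + dup_rank * 1e-6 * ps
  }
  areas <- voronoi_areas_cpp(x, y, 0, wh[1], 0, wh[2])
  inside <- x >= 0 & x <= wh[1] & y >= 0 & y <= wh[2]
  out <- tibble(x_nm = emitters$x_nm, y_nm = emitters$y_nm,
                cell_area_nm2 = areas,
                delta_r_nm = ifelse(areas > 0, sqrt(areas / pi), NA_real_),
                inside = inside)
  attr(out, "total_area_nm2") <- sum(areas)
  attr(out, "bounds_nm") <- wh
  out
}

resolve_bounds <- function(bounds, emitters) {
  if (inherits(bounds, "smlm_image")) {
    ex <- image_extent(bounds)
    return(c(ex[["width_nm"]], ex[["height_nm"]]))
  }
  if (is.numeric(bounds) && length(bounds) == 2L) {
    if (any(bounds <= 0)) abort("`bounds` must be positive.", class = "smlm_parameter_error")
    return(as.numeric(bounds))
  }
  if (is.null(bounds)) {
    w <- attr(emitters, "width_px"); h <- attr(emitters, "height_px")
    ps <- attr(emitters, "pixel_size")
    if (!is.null(w) && !anyNA(c(w, h, ps))) return(c(w * ps, h * ps))
  }
  abort("Supply `bounds`: a density_image or c(width_nm, height_nm).",
        class = "smlm_parameter_error")
}

#' Limiting precision from sampling interval and localization accuracy
#'
#' The smallest length scale recoverable at an emitter combines the local
#' sampling interval `delta_r` and the localization precision `delta_g` in
#' quadrature: `delta_l = sqrt(delta_r^2 + delta_g^2)`.
#'
#' @param delta_r Sampling radius/radii in nm (>= 0).
#' @param delta_g Localization precision in nm (>= 0); identified with the
#'   localization accuracy `kappa` of the run.
#' @return `sqrt(delta_r^2 + delta_g^2)`, vectorized over `delta_r`.
#' @examples
#' limiting_precision(3, 4) # 5
#' @export
limiting_precision <- function(delta_r, delta_g) {
  if (any(delta_r < 0, na.rm = TRUE) || any(delta_g < 0)) {
    abort("`delta_r` and `delta_g` must be >= 0.", class = "smlm_parameter_error")
  }
  sqrt(delta_r^2 + delta_g^2)
}

#' Summarize the sampling-density distribution
#'
#' Computes the box-plot summary of the per-emitter sampling radii (mean,
#' median, 25/75th and 5/95th percentiles), combines each radius with the
#' localization precision into a limiting precision via
#' [limiting_precision()], and reports the limiting spatial scale two ways:
#' as the limiting period `2 * delta_l` (Nyquist: two samples per recovered
#' period) and as the limiting frequency `1 / (2 * delta_l)` in cycles/nm.
#' Because the maximal recoverable frequency is restricted by the worst, not
#' the average, sampling, both the median and the 95th-percentile `delta_l`
#' variants are reported.
#'
#' @param radii Numeric vector of sampling radii (nm), or the tibble returned
#'   by [voronoi_radii()] (rows outside bounds and zero-area cells dropped).
#' @param delta_g Localization precision in nm.
#' @return A `sampling_stats` object: list with `radii`, `delta_g`, `delta_l`
#'   (elementwise), and `summary` (a one-row tibble).
#' @export
summarize_sampling <- function(radii, delta_g = 0) {
  if (is.data.frame(radii)) {
    r <- radii$delta_r_nm[radii$inside & !is.na(radii$delta_r_nm)]
  } else {
    r <- radii[!is.na(radii)]
  }
  if (length(r) == 0) abort("No radii to summarize.", class = "smlm_parameter_error")
  dl <- limiting_precision(r, delta_g)
  qs <- quantile(r, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  dl_med <- stats::median(dl)
  dl_p95 <- quantile(dl, 0.95, names = FALSE)
  summary <- tibble(
    n = length(r), mean_r_nm = mean(r),
    p05_r_nm = qs[1], p25_r_nm = qs[2], median_r_nm = qs[3],
    p75_r_nm = qs[4], p95_r_nm = qs[5],
    delta_g_nm = delta_g,
    median_l_nm = dl_med, p95_l_nm = dl_p95,
    limiting_period_median_nm = 2 * dl_med,
    limiting_freq_median = 1 / (2 * dl_med),
    limiting_period_p95_nm = 2 * dl_p95,
    limiting_freq_p95 = 1 / (2 * dl_p95))
  structure(list(radii = r, delta_g = delta_g, delta_l = dl, summary = summary),
            class = "sampling_stats")
}

#' @export
print.sampling_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sampling_stats> n = %d | delta_r median %.1f nm [5-95%%: %.1f-%.1f] | delta_g %.1f nm\n",
              s$n, s$median_r_nm, s$p05_r_nm, s$p95_r_nm, s$delta_g_nm))
  cat(sprintf("  limiting period 2*delta_l: median %.1f nm, p95 %.1f nm\n",
              s$limiting_period_median_nm, s$limiting_period_p95_nm))
  invisible(x)
}

#' @rdname summarize_sampling
#' @param x A `sampling_stats` object.
#' @param ... Unused.
#' @export
tidy.sampling_stats <- function(x, ...) {
  tibble(delta_r_nm = x$radii, delta_l_nm = x$delta_l)
}

#' @rdname summarize_sampling
#' @export
glance.sampling_stats <- function(x, ...) {
  x$summary
}

#' Export sampling statistics
#'
#' Writes the per-emitter radii to CSV and/or the box-plot summary (5/25/50/75/95
#' percentiles plus mean, whisker convention of the distribution plots) to JSON.
#'
#' @param stats A `sampling_stats` object.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the paths written.
#' @export
write_sampling_stats <- function(stats, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(tidy(stats), csv_path)
  if (!is.null(json_path)) {
    s <- stats$summary
    jsonlite::write_json(list(
      n = s$n, mean = s$mean_r_nm,
      whiskers = c(s$p05_r_nm, s$p95_r_nm),
      box = c(s$p25_r_nm, s$p75_r_nm),
      median = s$median_r_nm,
      delta_g = s$delta_g_nm,
      limiting_period_median_nm = s$limiting_period_median_nm,
      limiting_freq_median = s$limiting_freq_median,
      limiting_period_p95_nm = s$limiting_period_p95_nm,
      limiting_freq_p95 = s$limiting_freq_p95), json_path,
      auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}

#' Box plot of the sampling-radius distribution
#'
#' @param object A `sampling_stats` object.
#' @param ... Unused.
#' @return A ggplot object using the 5/25/50/75/95 whisker convention, with
#'   the mean marked as a diamond.
#' @export
autoplot.sampling_stats <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s) +
    ggplot2::geom_boxplot(ggplot2::aes(x = "", ymin = .data$p05_r_nm,
                                       lower = .data$p25_r_nm, middle = .data$median_r_nm,
                                       upper = .data$p75_r_nm, ymax = .data$p95_r_nm),
                          stat = "identity", width = 0.4, fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(x = "", y = .data$mean_r_nm),
                        shape = 18, size = 3, color = "darkgreen") +
    ggplot2::labs(x = NULL, y = "sampling radius delta_r (nm)") +
    ggplot2::theme_minimal()
}
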