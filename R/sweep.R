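#' Configure a reconstruction-fidelity sweep
#'
#' Defines the simulation campaign: for every combination of localization
#' accuracy `kappa` and kernel size `d` (and replicate seed), one emitter set
#' of size `max(n_grid)` is sampled from the reference, rendered incrementally
#' in acquisition order, and all four similarity measures are recorded at every
#' intermediate frame whose cumulative emitter count hits a value of `n_grid`.
#'
#' @param reference A [density_image()] (load one with [load_reference()] or
#'   generate a phantom).
#' @param n_grid Emitter counts at which measures are read off (positive,
#'   deduplicated and sorted; `max(n_grid)` sets the emitter-set size).
#' @param kappa_grid Localization accuracies in nm (>= 0).
#' @param d_grid Kernel sizes in nm (> 0).
#' @param kernel `"square"` or `"gaussian"`.
#' @param sigma_convention Gaussian width convention, see [render()].
#' @param k_rings Ring count for the frequency spectrum.
#' @param replicates Independent replicate simulations per cell (default 3),
#'   used to quantify Monte-Carlo spread.
#' @param seed Base integer seed; per-cell seeds are derived deterministically.
#' @param n_f Optional per-step emitter count for frame accumulation. When
#'   `NULL` (default) frames are accumulated directly between consecutive
#'   `n_grid` readout points; when given, every value of `n_grid` must be a
#'   multiple of `n_f` (or equal to `max(n_grid)`).
#' @param interp Density lookup mode for the sampler.
#' @param output_dir Optional directory: records CSV, spectra CSV and config
#'   JSON are written there by [run_sweep()].
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(reference, n_grid, kappa_grid, d_grid,
                         kernel = c("square", "gaussian"),
                         sigma_convention = c("half_d", "d"),
                         k_rings = 64L, replicates = 3L, seed = 1L,
                         n_f = NULL, interp = "nearest", output_dir = NULL) {
  kernel <- match.arg(kernel)
  sigma_convention <- match.arg(sigma_convention)
  if (!inherits(reference, "density_image")) {
    abort("`reference` must be a density_image.", class = "smlm_parameter_error")
  }
  n_grid <- sort(unique(as.integer(n_grid)))
  if (length(n_grid) < 1 || any(n_grid < 1)) {
    abort("`n_grid` must contain positive emitter counts.", class = "smlm_parameter_error")
  }
  if (length(kappa_grid) < 1 || any(kappa_grid < 0)) {
    abort("`kappa_grid` must contain non-negative accuracies.", class = "smlm_parameter_error")
  }
  if (length(d_grid) < 1 || any(d_grid <= 0)) {
    abort("`d_grid` must contain positive kernel sizes.", class = "smlm_parameter_error")
  }
  if (!is.null(n_f)) {
    n_f <- as.integer(n_f)
    if (n_f < 1 || n_f > max(n_grid)) {
      abort("`n_f` must satisfy 1 <= n_f <= max(n_grid).", class = "smlm_parameter_error")
    }
    bad <- n_grid[n_grid %% n_f != 0 & n_grid != max(n_grid)]
    if (length(bad)) {
      abort(sprintf("n_grid values not aligned with n_f = %d: %s", n_f,
                    paste(bad, collapse = ", ")), class = "smlm_parameter_error")
    }
  }
  structure(list(reference = reference, n_grid = n_grid,
                 kappa_grid = as.numeric(kappa_grid), d_grid = as.numeric(d_grid),
                 kernel = kernel, sigma_convention = sigma_convention,
                 k_rings = as.integer(k_rings), replicates = as.integer(replicates),
                 seed = as.integer(seed), n_f = n_f, interp = interp,
                 output_dir = output_dir),
            class = "sweep_config")
}

#' Run a reconstruction-fidelity sweep
#'
#' Executes the campaign defined by [sweep_config()]. For each
#' (replicate, kappa, d) cell, one emitter set of size `max(n_grid)` is drawn
#' with that `kappa`, a random acquisition order is fixed, and the image is
#' accumulated incrementally; at every readout count the reconstruction is
#' scored against the reference with [q_pearson()], [q_binarized()], [q_l2()]
#' and [q_freq()]. The run is deterministic for a fixed base seed.
#'
#' @param config A `sweep_config`.
#' @param verbose Print one progress line per (replicate, kappa, d) cell.
#' @return An `smlm_sweep` tibble: one row per readout with columns
#'   `replicate`, `kappa`, `d`, `kernel`, `n`, `density_um2`, `q_pearson`,
#'   `q_binarized`, `q_l2` and a list-column `spectrum` of `freq_similarity`
#'   tibbles. `q_binarized` is `NA` when a frame cannot be binarized.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  ref <- config$reference
  n_grid <- config$n_grid
  n_max <- max(n_grid)
  cells <- tidyr::expand_grid(replicate = seq_len(config$replicates),
                              kappa = config$kappa_grid, d = config$d_grid)
  # readout boundaries; with n_f set, frames advance in n_f steps between them
  steps <- if (is.null(config$n_f)) n_grid else {
    sort(unique(c(seq(config$n_f, n_max, by = config$n_f), n_max)))
  }
  cells$cell <- seq_len(nrow(cells))
  records <- purrr::pmap(cells, function(replicate, kappa, d, cell) {
    cell_seed <- derive_seed(config$seed, cell)
    if (verbose) {
      message(sprintf("sweep cell: replicate %d, kappa = %g nm, d = %g nm (seed %d)",
                      replicate, kappa, d, cell_seed))
    }
    em <- sample_emitters(ref, n_max, kappa, cell_seed, interp = config$interp)
    withr::local_seed(derive_seed(cell_seed, 1L))
    ord <- sample.int(n_max)
    acc <- NULL
    prev <- 0L
    out <- vector("list", length(n_grid))
    oi <- 1L
    for (s in steps) {
      idx <- ord[(prev + 1L):s]
      step_img <- if (config$kernel == "square") {
        render_square_cpp(em$x_nm[idx], em$y_nm[idx], nrow(ref), ncol(ref),
                          pixel_size(ref), d)
      } else {
        render_gaussian_cpp(em$x_nm[idx], em$y_nm[idx], nrow(ref), ncol(ref),
                            pixel_size(ref), if (config$sigma_convention == "half_d") d / 2 else d)
      }
      acc <- if (is.null(acc)) step_img else acc + step_img
      prev <- s
      if (!(s %in% n_grid)) next
      qp <- q_pearson(ref, acc)
      qb <- tryCatch(q_binarized(ref, acc), error = function(e) NA_real_)
      ql <- q_l2(ref, acc)
      fs <- q_freq(ref, acc, k = config$k_rings, pixel_size = pixel_size(ref))
      out[[oi]] <- tibble(replicate = replicate, kappa = kappa, d = d,
                          kernel = config$kernel, n = s,
                          density_um2 = emitter_density_per_um2(
                            s, ncol(ref), nrow(ref), pixel_size(ref)),
                          q_pearson = qp, q_binarized = qb, q_l2 = ql,
                          spectrum = list(fs))
      oi <- oi + 1L
    }
    dplyr::bind_rows(out)
  })
  res <- structure(dplyr::bind_rows(records),
                   config = config,
                   class = c("smlm_sweep", class(tibble())))
  if (!is.null(config$output_dir)) write_sweep(res, config$output_dir)
  res
}

# deterministic per-cell seed derivation, kept within 32-bit integer range
derive_seed <- function(base, index) {
  as.integer((as.numeric(base) * 48271 + as.numeric(index) * 7919) %% 2147483629 + 1)
}

#' Write sweep results to disk
#'
#' Records go to `records.csv` (flat, no spectra), spectra to `spectra.csv`
#' (long format keyed by replicate/kappa/d/n), the configuration to
#' `config.json`.
#'
#' @param sweep An `smlm_sweep`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(sweep), file.path(dir, "records.csv"))
  spectra <- sweep |>
    dplyr::mutate(spectrum = purrr::map(.data$spectrum, as_tibble)) |>
    dplyr::select("replicate", "kappa", "d", "kernel", "n", "spectrum") |>
    tidyr::unnest("spectrum")
  readr::write_csv(spectra, file.path(dir, "spectra.csv"))
  cfg <- attr(sweep, "config")
  jsonlite::write_json(
    list(n_grid = cfg$n_grid, kappa_grid = cfg$kappa_grid, d_grid = cfg$d_grid,
         kernel = cfg$kernel, sigma_convention = cfg$sigma_convention,
         k_rings = cfg$k_rings, replicates = cfg$replicates, seed = cfg$seed,
         n_f = cfg$n_f, interp = cfg$interp,
         reference = list(width_px = ncol(cfg$reference),
                          height_px = nrow(cfg$reference),
                          pixel_size_nm = pixel_size(cfg$reference),
                          generator = attr(cfg$reference, "generator"))),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname run_sweep
#' @param x An `smlm_sweep`.
#' @param ... Unused.
#' @export
tidy.smlm_sweep <- function(x, ...) {
  dplyr::select(as_tibble(x), -dplyr::any_of("spectrum"))
}

#' @rdname run_sweep
#' @export
glance.smlm_sweep <- function(x, ...) {
  tibble(n_records = nrow(x),
         n_cells = nrow(dplyr::distinct(as_tibble(x), .data$replicate, .data$kappa, .data$d)),
         replicates = length(unique(x$replicate)),
         n_max = max(x$n), kernel = x$kernel[1])
}

#' Optimal kernel size at a given density and accuracy
#'
#' Selects, among the swept kernel sizes, the `d` maximizing the Pearson
#' correlation at the queried emitter count and localization accuracy
#' (averaging over replicates). Ties break toward the smaller `d` (finer
#' rendering preferred). The `interior` flag reports whether the maximum sits
#' strictly inside the swept `d` range, i.e. whether an optimum (rather than a
#' range endpoint) was actually resolved.
#'
#' @param records An `smlm_sweep` or its [tidy()] data frame.
#' @param n Emitter count to query (must be a readout value).
#' @param kappa Localization accuracy to query.
#' @return One-row tibble: `n`, `kappa`, `d_opt`, `q_pearson`, `interior`.
#' @export
optimal_d <- function(records, n, kappa) {
  df <- as_tibble(records) |>
    dplyr::filter(.data$n == !!n, .data$kappa == !!kappa)
  if (nrow(df) == 0) {
    abort(sprintf("No sweep records at n = %g, kappa = %g.", n, kappa),
          class = "smlm_lookup_error")
  }
  by_d <- df |>
    dplyr::group_by(d = .data$d) |>
    dplyr::summarise(q_pearson = mean(.data$q_pearson), .groups = "drop") |>
    dplyr::arrange(.data$d)
  if (nrow(by_d) < 3) {
    abort("Need >= 3 distinct d values to locate an optimum.", class = "smlm_lookup_error")
  }
  best <- which(by_d$q_pearson == max(by_d$q_pearson))[1]  # tie -> smaller d
  tibble(n = n, kappa = kappa, d_opt = by_d$d[best],
         q_pearson = by_d$q_pearson[best],
         interior = best > 1 && best < nrow(by_d))
}

#' Plot sweep results
#'
#' Pearson correlation versus emitter density (log axis), one curve per kernel
#' size, faceted by localization accuracy; replicates are averaged with the
#' spread shown as a ribbon.
#'
#' @param object An `smlm_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.smlm_sweep <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$kappa, .data$d, .data$n, .data$density_um2) |>
    dplyr::summarise(q_mean = mean(.data$q_pearson),
                     q_sd = sd(.data$q_pearson), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density_um2, y = .data$q_mean,
                                   color = factor(.data$d), group = factor(.data$d))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q_mean - .data$q_sd,
                                      ymax = .data$q_mean + .data$q_sd,
                                      fill = factor(.data$d)),
                         alpha = 0.15, color = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$kappa), labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression("emitter density (" * mu * m^-2 * ")"),
                  y = "Pearson correlation", color = "d (nm)", fill = "d (nm)") +
    ggplot2::theme_minimal()
}
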