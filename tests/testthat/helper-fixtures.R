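# Shared fixtures, all generated in code.

# uniform density over an n x n grid
uniform_density <- function(n = 64, pixel_size = 6.4, value = 1) {
  density_image(matrix(value, n, n), pixel_size)
}

# density 1 on the left half of the image, 0 on the right
half_plane_density <- function(n = 64, pixel_size = 6.4) {
  m <- matrix(0, n, n)
  m[, seq_len(n %/% 2)] <- 1
  density_image(m, pixel_size)
}

# smooth non-uniform density with full support (for goodness-of-fit tests)
smooth_density <- function(n = 64, pixel_size = 6.4) {
  i <- seq_len(n) / n
  m <- 0.1 + 0.9 * outer(sin(pi * i)^2, cos(pi * i / 2)^2)
  density_image(m / max(m), pixel_size)
}

random_image <- function(n = 32, seed = 1) {
  withr::with_seed(seed, matrix(runif(n * n), n, n))
}

# bare numeric matrix: drop class and metadata attributes, keep dim
mat <- function(img) {
  a <- unclass(img)
  attributes(a) <- list(dim = dim(a))
  a
}

# the scaled-down study sweep shared by experiment and acceptance tests:
# filament phantom 512 px @ 6.4 nm, emitter counts up to 5e5 over 3 decades,
# the 5-size kernel ladder at kappa = 25 nm plus a kappa ladder at d = 32 nm,
# 3 replicate seeds. Computed once per session and reused.
study_sweep_cache <- new.env(parent = emptyenv())

study_phantom <- function() {
  if (is.null(study_sweep_cache$phantom)) {
    study_sweep_cache$phantom <-
      make_filament_phantom(512, 512, 6.4, n_filaments = 8, thickness = 50, seed = 421)
  }
  study_sweep_cache$phantom
}

study_d_sweep <- function() {
  if (is.null(study_sweep_cache$d_sweep)) {
    cfg <- sweep_config(study_phantom(),
                        n_grid = c(5e2, 5e3, 5e4, 5e5),
                        kappa_grid = 25,
                        d_grid = c(6.4, 32, 57.6, 108.8, 211.2),
                        kernel = "square", k_rings = 32,
                        replicates = 3, seed = 99)
    study_sweep_cache$d_sweep <- run_sweep(cfg)
  }
  study_sweep_cache$d_sweep
}

study_kappa_sweep <- function() {
  if (is.null(study_sweep_cache$kappa_sweep)) {
    cfg <- sweep_config(study_phantom(),
                        n_grid = c(5e2, 5e3, 5e4, 5e5),
                        kappa_grid = c(6.4, 25, 100),
                        d_grid = 32,
                        kernel = "square", k_rings = 32,
                        replicates = 3, seed = 177)
    study_sweep_cache$kappa_sweep <- run_sweep(cfg)
  }
  study_sweep_cache$kappa_sweep
}
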