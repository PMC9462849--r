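# Shared fixtures and independent oracles for the test suite.

# A small disc configuration that keeps per-test runtime low.
small_config <- function(...) {
  disc_config(nx = 60L, nz = 40L, ap_boundary_x = 41L,
              region_widths = c(ci_a = 8L, ci_f = 12L), thickness = 24L,
              ...)
}

# Noise-free generator settings: expectations only, no offsets.
noiseless <- function(cfg_fun = small_config, ...) {
  cfg_fun(expectation_mode = TRUE, read_noise_sd = 0, background = 0, ...)
}

run_cfg <- function(...) {
  apbaquant:::validate_run_config(
    modifyList(apbaquant:::default_run_config(), list(...)))
}

# Run config matched to small_config() geometry.
small_run_cfg <- function(...) {
  run_cfg(ap_boundary_x = 41L,
          classification = list(background_quantile = 0.5, low_frac = 0.2,
                                high_frac = 0.6, min_region_width = 3L,
                                fallback_widths = list(ci_a = 8L,
                                                       ci_f = 12L)),
          ...)
}

# Build a disc_mask by hand (flat or arbitrary extents).
manual_mask <- function(nz, nx, z_top, z_bottom) {
  z_top <- rep_len(z_top, nx)
  z_bottom <- rep_len(z_bottom, nx)
  mask <- matrix(FALSE, nz, nx)
  for (x in seq_len(nx)) mask[z_top[x]:z_bottom[x], x] <- TRUE
  structure(list(mask = mask, z_top = as.integer(z_top),
                 z_bottom = as.integer(z_bottom),
                 valid = (z_bottom - z_top + 1L) >= 3L, h_min = 3L,
                 threshold = NA_real_),
            class = "disc_mask")
}

manual_profile <- function(values) {
  structure(data.frame(x = seq_along(values), ci = values),
            class = c("ci_profile", "data.frame"), smooth_window = 1L)
}

# Literal enumeration oracle for the Wilcoxon signed-rank two-sided
# p-value: every one of the 2^n sign assignments, no generating functions.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-12)
  p_ge <- mean(Ws >= W - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Literal enumeration oracle for the Mann-Whitney two-sided p-value over
# all choose(n1 + n2, n1) rank assignments (untied data).
brute_mann_whitney_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  Us <- apply(sets, 2, sum) - n1 * (n1 + 1) / 2
  p_le <- mean(Us <= U + 1e-12)
  p_ge <- mean(Us >= U - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Pixel-pooling oracle: per-(region, subregion) sums via an explicit
# double loop over member pixels.
brute_pool <- function(projection, columns, regions, spec) {
  px <- unclass(projection)
  acc <- list()
  for (i in seq_len(nrow(columns))) {
    col <- columns[i, ]
    parts <- partition_column(col, spec)
    parts$column <- list(x_start = col$x_start, x_end = col$x_end,
                         z_top = col$z_top, z_bottom = col$z_bottom)
    for (s in names(parts)) {
      roi <- parts[[s]]
      tot <- 0; npx <- 0
      for (x in roi$x_start:roi$x_end)
        for (z in roi$z_top:roi$z_bottom) {
          tot <- tot + px[z, x]; npx <- npx + 1
        }
      key <- paste(regions[i], s)
      old <- acc[[key]] %||% c(0, 0)
      acc[[key]] <- old + c(tot, npx)
    }
  }
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
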