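#' Configuration for the synthetic disc generator
#'
#' Builds and validates the parameter set that defines a synthetic
#' antero-posterior XZ stack of a columnar epithelium: its geometry, the
#' four-region layout of the Hedgehog gradient along the AP axis, the
#' expected receptor intensity of each region and how that intensity is
#' apportioned between the apical, lateral, and basal thirds of the tissue,
#' the CI-like marker levels used for region classification, and the noise
#' model.
#'
#' The defaults describe the imaging conditions the package emulates: a
#' columnar epithelium of constant thickness imaged in XZ view (apical up,
#' anterior left), eight optical sections 1 um apart, an anterior CI-A band
#' of 12 pixel columns (one pixel column per cell row of the Hedgehog
#' gradient), receptor levels rising 1.7-fold from the far-anterior CI-R
#' region to the posterior compartment, and a basal intensity fraction that
#' rises from 0.10 (CI-R) to 0.25 (P).
#'
#' @param nx AP extent in pixels.
#' @param nz apico-basal extent in pixels per section (row 1 = apical).
#' @param n_sections number of XZ sections in the stack.
#' @param z_spacing_um axial spacing between sections, micrometres.
#' @param pixel_size_um lateral pixel size, micrometres.
#' @param ap_boundary_x first pixel column of the posterior compartment
#'   (1-based); everything at `x >= ap_boundary_x` is posterior.
#' @param region_widths named vector with elements `ci_a` and `ci_f`: pixel
#'   widths of the CI-A and CI-F intervals. CI-R fills the remaining
#'   anterior extent, P the posterior extent.
#' @param thickness tissue thickness in pixels at the disc centre.
#' @param bow_amplitude amplitude (pixels) of a smooth parabolic thinning
#'   toward the AP edges; 0 gives a constant thickness profile.
#' @param smo_levels named vector (one entry per AP region) of expected
#'   column-summed receptor intensity, photon units.
#' @param smo_fractions 4 x 3 matrix (rows = AP regions, columns
#'   apical/lateral/basal) of the fraction of each region's column intensity
#'   allotted to each depth band; rows must sum to 1.
#' @param ci_levels named vector of expected column-summed CI-channel
#'   intensity per AP region (background in P and CI-R, high in CI-F, low in
#'   CI-A).
#' @param background additive intensity offset applied everywhere.
#' @param poisson_scale photons per intensity unit for shot-noise sampling.
#' @param read_noise_sd standard deviation of additive Gaussian read noise.
#' @param expectation_mode if `TRUE` the generator emits noiseless expected
#'   intensities (no sampling); used for exact recovery checks.
#' @param subregion_fractions named vector `c(apical=, basal=)` of the
#'   thickness fractions defining the depth bands; kept equal to the
#'   analysis defaults (0.15 / 0.10) so generator fractions are directly
#'   recoverable.
#'
#' @return An object of class `disc_config`.
#' @export
disc_config <- function(nx = 200L,
                        nz = 80L,
                        n_sections = 8L,
                        z_spacing_um = 1.0,
                        pixel_size_um = 0.4,
                        ap_boundary_x = 141L,
                        region_widths = c(ci_a = 12L, ci_f = 20L),
                        thickness = 60L,
                        bow_amplitude = 0,
                        smo_levels = c("CI-R" = 2000, "CI-F" = 2600,
                                       "CI-A" = 3100, "P" = 3400),
                        smo_fractions = default_smo_fractions(),
                        ci_levels = c("CI-R" = 0, "CI-F" = 3000,
                                      "CI-A" = 1200, "P" = 0),
                        background = 0,
                        poisson_scale = 1,
                        read_noise_sd = 1,
                        expectation_mode = FALSE,
                        subregion_fractions = c(apical = 0.15, basal = 0.10)) {
  cfg <- list(nx = as.integer(nx), nz = as.integer(nz),
              n_sections = as.integer(n_sections),
              z_spacing_um = z_spacing_um, pixel_size_um = pixel_size_um,
              ap_boundary_x = as.integer(ap_boundary_x),
              region_widths = region_widths,
              thickness = as.integer(thickness),
              bow_amplitude = bow_amplitude,
              smo_levels = smo_levels, smo_fractions = smo_fractions,
              ci_levels = ci_levels, background = background,
              poisson_scale = poisson_scale, read_noise_sd = read_noise_sd,
              expectation_mode = isTRUE(expectation_mode),
              subregion_fractions = subregion_fractions)
  class(cfg) <- "disc_config"
  validate_disc_config(cfg)
}

#' Default apico-basal intensity fractions per AP region
#'
#' Encodes the qualitative pattern the pipeline is built to detect: the
#' apical fraction of cell-surface receptor falls, and the basal fraction
#' rises, from the far-anterior CI-R region toward the posterior
#' compartment.
#'
#' @return A 4 x 3 numeric matrix, rows `CI-R`, `CI-F`, `CI-A`, `P` and
#'   columns `apical`, `lateral`, `basal`; each row sums to 1.
#' @export
default_smo_fractions <- function() {
  m <- rbind("CI-R" = c(0.25, 0.65, 0.10),
             "CI-F" = c(0.22, 0.64, 0.14),
             "CI-A" = c(0.18, 0.64, 0.18),
             "P"    = c(0.15, 0.60, 0.25))
  colnames(m) <- SUBREGIONS
  m
}

#' Default pulse-chase retention factors
#'
#' Region x subregion fraction of surface-labelled receptor remaining after
#' the chase. Far-anterior and posterior values correspond to measured
#' subregion reductions of 47/44/28 percent (no Hedgehog) and 38/28/4
#' percent (high Hedgehog); the two intermediate regions are linear
#' interpolations, as no measured values exist for them.
#'
#' @return A 4 x 3 numeric matrix in `[0, 1]`, rows = AP regions, columns =
#'   subregions.
#' @export
default_retention <- function() {
  m <- rbind("CI-R" = c(0.53, 0.56, 0.72),
             "CI-F" = c(0.56, 0.61, 0.80),
             "CI-A" = c(0.59, 0.67, 0.88),
             "P"    = c(0.62, 0.72, 0.96))
  colnames(m) <- SUBREGIONS
  m
}

validate_disc_config <- function(cfg) {
  with(cfg, {
    if (nx < 1L || nz < 1L || n_sections < 1L)
      stop_quant("nx, nz and n_sections must all be >= 1")
    if (z_spacing_um <= 0 || pixel_size_um <= 0)
      stop_quant("pixel spacings must be positive")
    if (ap_boundary_x < 1L || ap_boundary_x > nx)
      stop_quant("ap_boundary_x must lie inside [1, nx]")
    if (!all(c("ci_a", "ci_f") %in% names(region_widths)))
      stop_quant("region_widths needs named elements 'ci_a' and 'ci_f'")
    if (any(region_widths < 0))
      stop_quant("region widths must be nonnegative")
    if (sum(region_widths) > ap_boundary_x - 1L)
      stop_quant("region widths (ci_a + ci_f = ", sum(region_widths),
                 ") exceed the anterior extent of ", ap_boundary_x - 1L,
                 " pixels")
    if (thickness < H_MIN)
      stop_quant("thickness must be at least ", H_MIN,
                 " pixels (minimum partitionable column)")
    if (bow_amplitude < 0 || thickness - bow_amplitude < H_MIN)
      stop_quant("bow_amplitude must be in [0, thickness - ", H_MIN, "]")
    if (thickness > nz)
      stop_quant("thickness exceeds nz")
    for (v in list(smo_levels, ci_levels))
      if (!identical(sort(names(v)), sort(AP_REGIONS)) || any(v < 0))
        stop_quant("smo_levels/ci_levels must be nonnegative and named ",
                   paste(AP_REGIONS, collapse = ", "))
    if (!is.matrix(smo_fractions) ||
        !identical(rownames(smo_fractions), AP_REGIONS) ||
        !identical(colnames(smo_fractions), SUBREGIONS))
      stop_quant("smo_fractions must be a matrix with rows ",
                 paste(AP_REGIONS, collapse = ", "), " and columns ",
                 paste(SUBREGIONS, collapse = ", "))
    if (any(smo_fractions < 0) ||
        any(abs(rowSums(smo_fractions) - 1) > 1e-9))
      stop_quant("each row of smo_fractions must be nonnegative and sum to 1")
    if (background < 0 || poisson_scale < 0 || read_noise_sd < 0)
      stop_quant("background, poisson_scale and read_noise_sd must be >= 0")
    f <- subregion_fractions
    if (f[["apical"]] <= 0 || f[["basal"]] <= 0 ||
        f[["apical"]] + f[["basal"]] >= 1)
      stop_quant("subregion_fractions must satisfy 0 < apical, basal and ",
                 "apical + basal < 1")
  })
  cfg
}

#' @export
print.disc_config <- function(x, ...) {
  cat("<disc_config> ", x$nx, " x ", x$nz, " px, ", x$n_sections,
      " sections (dz = ", x$z_spacing_um, " um)\n", sep = "")
  cat("  AP boundary at x =", x$ap_boundary_x, "| region widths:",
      paste(names(x$region_widths), x$region_widths, sep = "=",
            collapse = ", "), "\n")
  cat("  thickness", x$thickness, "px (bow", x$bow_amplitude, "px),",
      if (x$expectation_mode) "expectation mode" else
        paste0("poisson_scale=", x$poisson_scale,
               ", read_noise_sd=", x$read_noise_sd,
               ", background=", x$background), "\n")
  invisible(x)
}

# AP-region label for every pixel column (1-based x).
region_labels <- function(cfg) {
  lab <- rep("CI-R", cfg$nx)
  b <- cfg$ap_boundary_x
  wa <- cfg$region_widths[["ci_a"]]
  wf <- cfg$region_widths[["ci_f"]]
  if (b <= cfg$nx) lab[seq(b, cfg$nx)] <- "P"
  if (wa > 0) lab[seq(b - wa, b - 1L)] <- "CI-A"
  if (wf > 0) lab[seq(b - wa - wf, b - wa - 1L)] <- "CI-F"
  lab
}

# Tissue thickness per AP position: constant, or thinned parabolically
# toward both AP edges by up to bow_amplitude pixels.
thickness_profile <- function(cfg) {
  x <- seq_len(cfg$nx)
  t <- 2 * (x - 0.5) / cfg$nx - 1
  h <- as.integer(round_half_up(cfg$thickness - cfg$bow_amplitude * t^2))
  pmax(h, H_MIN)
}

# Noise-free expected intensity images (one section's worth; all sections
# share the same expectation). Returns nz x nx matrices for both channels
# plus the realized geometry.
expectation_images <- function(cfg, retention = NULL) {
  nz <- cfg$nz; nx <- cfg$nx
  lab <- region_labels(cfg)
  h <- thickness_profile(cfg)
  z_top <- pmax(1L, (nz - h) %/% 2L + 1L)
  smo <- matrix(0, nz, nx)
  ci <- matrix(0, nz, nx)
  f_ap <- cfg$subregion_fractions[["apical"]]
  f_ba <- cfg$subregion_fractions[["basal"]]
  for (x in seq_len(nx)) {
    hx <- h[x]; zt <- z_top[x]
    bands <- partition_heights(hx, f_ap, f_ba)
    r <- lab[x]
    ret <- if (is.null(retention)) c(1, 1, 1) else retention[r, ]
    lv <- cfg$smo_levels[[r]] * cfg$smo_fractions[r, ] * ret
    rows_ap <- seq(zt, zt + bands[["apical"]] - 1L)
    rows_la <- seq(zt + bands[["apical"]],
                   zt + bands[["apical"]] + bands[["lateral"]] - 1L)
    rows_ba <- seq(zt + hx - bands[["basal"]], zt + hx - 1L)
    smo[rows_ap, x] <- lv[["apical"]] / bands[["apical"]]
    smo[rows_la, x] <- lv[["lateral"]] / bands[["lateral"]]
    smo[rows_ba, x] <- lv[["basal"]] / bands[["basal"]]
    ci[c(rows_ap, rows_la, rows_ba), x] <- cfg$ci_levels[[r]] / hx
  }
  list(smo = smo, ci = ci, labels = lab, thickness = h, z_top = z_top)
}

new_disc_stack <- function(voxels, channel_names, z_spacing_um,
                           pixel_size_um) {
  if (any(voxels < 0)) stop_quant("voxel intensities must be nonnegative")
  if (anyDuplicated(channel_names))
    stop_quant("channel names must be unique")
  dimnames(voxels) <- list(channel = channel_names, section = NULL,
                           z = NULL, x = NULL)
  structure(list(voxels = voxels, channel_names = channel_names,
                 z_spacing_um = z_spacing_um, pixel_size_um = pixel_size_um),
            class = "disc_stack")
}

#' @export
print.disc_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<disc_stack> ", d[1], " channel(s) [",
      paste(x$channel_names, collapse = ", "), "], ", d[2],
      " sections of ", d[3], " x ", d[4], " px, dz = ", x$z_spacing_um,
      " um\n", sep = "")
  invisible(x)
}

#' Generate one synthetic disc stack with ground truth
#'
#' Renders a two-channel XZ stack of a columnar epithelium: channel
#' `surface_receptor` carries the region- and depth-structured receptor
#' signal, channel `ci_marker` the CI-like regional marker. Tissue pixels
#' carry their expected intensity (region level apportioned over the
#' apical/lateral/basal bands by the configured fractions); outside the
#' tissue only background and noise remain. Unless
#' `config$expectation_mode` is set, every pixel of every section is
#' sampled as `Poisson(E * poisson_scale) / poisson_scale +
#' Normal(0, read_noise_sd) + background`, clamped at zero. The same
#' `(config, seed)` pair reproduces the stack bit for bit.
#'
#' @param config a [disc_config()].
#' @param seed integer RNG seed for this disc.
#' @param retention optional 4 x 3 region-by-subregion matrix of retention
#'   factors in `[0, 1]` multiplying the expected intensities (used for
#'   chase time points; `NULL` means no chase, factors 1).
#' @return A list with elements `stack` (a `disc_stack`) and `truth` (a
#'   `disc_truth` recording region labels per x, thickness per x, true
#'   fractions, true levels, and retention factors).
#' @export
make_disc <- function(config, seed = 1L, retention = NULL) {
  validate_disc_config(config)
  if (!is.null(retention)) {
    if (!is.matrix(retention) ||
        !identical(rownames(retention), AP_REGIONS) ||
        !identical(colnames(retention), SUBREGIONS) ||
        any(retention < 0) || any(retention > 1))
      stop_quant("retention must be a 4 x 3 region-by-subregion matrix ",
                 "with values in [0, 1]")
  }
  exp_img <- expectation_images(config, retention)
  nz <- config$nz; nx <- config$nx; ns <- config$n_sections
  channels <- c("surface_receptor", "ci_marker")
  voxels <- array(0, dim = c(2L, ns, nz, nx))
  if (config$expectation_mode) {
    for (s in seq_len(ns)) {
      voxels[1L, s, , ] <- exp_img$smo + config$background
      voxels[2L, s, , ] <- exp_img$ci + config$background
    }
  } else {
    withr::with_seed(as.integer(seed), {
      for (ci in 1:2) {
        e <- if (ci == 1L) exp_img$smo else exp_img$ci
        for (s in seq_len(ns)) {
          v <- if (config$poisson_scale > 0)
            rpois(length(e), e * config$poisson_scale) / config$poisson_scale
          else as.numeric(e)
          v <- v + rnorm(length(e), 0, config$read_noise_sd) +
            config$background
          voxels[ci, s, , ] <- pmax(matrix(v, nz, nx), 0)
        }
      }
    })
  }
  ret <- if (is.null(retention)) {
    m <- matrix(1, 4, 3, dimnames = list(AP_REGIONS, SUBREGIONS))
    m
  } else retention
  truth <- structure(list(
    region_label_per_x = exp_img$labels,
    thickness_per_x = exp_img$thickness,
    z_top_per_x = exp_img$z_top,
    true_fractions = config$smo_fractions,
    true_levels = config$smo_levels,
    ci_levels = config$ci_levels,
    retention = ret,
    seed = as.integer(seed),
    expectation_mode = config$expectation_mode), class = "disc_truth")
  stopifnot(abs(rowSums(truth$true_fractions) - 1) < 1e-9)
  list(stack = new_disc_stack(voxels, channels, config$z_spacing_um,
                              config$pixel_size_um),
       truth = truth)
}

#' Generate a pulse-chase pair of disc stacks
#'
#' Emulates a surface-labelling pulse followed by a chase: the first disc
#' carries the configured expected intensities (time 0), the second the
#' same intensities multiplied, per region and subregion, by the retention
#' factors. Both ground truths record the factors.
#'
#' @inheritParams make_disc
#' @param retention 4 x 3 region-by-subregion retention matrix in `[0, 1]`;
#'   defaults to [default_retention()].
#' @return A list with elements `t0` and `chase`, each a
#'   `list(stack, truth)` as returned by [make_disc()].
#' @export
make_pulse_chase <- function(config, retention = default_retention(),
                             seed = 1L) {
  t0 <- make_disc(config, seed = seed)
  chase <- make_disc(config, seed = as.integer(seed) + 1L,
                     retention = retention)
  t0$truth$retention[] <- 1
  list(t0 = t0, chase = chase)
}

#' Generate a cohort of independent synthetic discs
#'
#' @inheritParams make_disc
#' @param n number of discs.
#' @param seed base seed; disc `i` uses `seed + i`.
#' @return A list of `n` elements, each a `list(stack, truth)`.
#' @export
simulate_cohort <- function(config, n, seed = 1L, retention = NULL) {
  lapply(seq_len(n), function(i)
    make_disc(config, seed = as.integer(seed) + i, retention = retention))
}

#' Write / read a disc stack as multi-page TIFF with a YAML sidecar
#'
#' Pages are stored channel-major (all sections of channel 1, then channel
#' 2, ...) as 32-bit float samples, rescaled to `[0, 1]` by a global factor
#' recorded, together with channel names and pixel spacings, in a sidecar
#' `<path>.yaml`. The round trip is lossless at 32-bit float precision.
#'
#' @param disc a `disc_stack`.
#' @param path output TIFF path (`.tif`/`.tiff`).
#' @return `write_stack` returns `path` invisibly; `read_stack` returns a
#'   `disc_stack`.
#' @export
write_stack <- function(disc, path) {
  stopifnot(inherits(disc, "disc_stack"))
  d <- dim(disc$voxels)
  scale <- max(disc$voxels, 1)
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (ch in seq_len(d[1])) for (s in seq_len(d[2])) {
    k <- k + 1L
    pages[[k]] <- matrix(disc$voxels[ch, s, , ] / scale, d[3], d[4])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channel_names = as.list(disc$channel_names),
               n_sections = d[2], nz = d[3], nx = d[4],
               z_spacing_um = disc$z_spacing_um,
               pixel_size_um = disc$pixel_size_um,
               intensity_scale = scale)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' @rdname write_stack
#' @param require_channels character vector of channel names that must be
#'   present; a descriptive error is raised for any that are missing.
#' @export
read_stack <- function(path, require_channels = NULL) {
  if (!file.exists(path)) stop_quant("stack file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop_quant("metadata sidecar not found: ", sp)
  meta <- yaml::read_yaml(sp)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop_quant("unreadable TIFF '", path, "': ",
                                 conditionMessage(e)))
  channels <- unlist(meta$channel_names)
  n_expected <- length(channels) * meta$n_sections
  if (length(pages) != n_expected)
    stop_quant("inconsistent stack: ", length(pages), " pages on disk but ",
               "metadata declares ", n_expected,
               " (", length(channels), " channels x ", meta$n_sections,
               " sections); file may be truncated")
  if (!all(vapply(pages, function(p)
    identical(dim(p), c(meta$nz, meta$nx)), logical(1))))
    stop_quant("inconsistent page dimensions in ", path)
  if (!is.null(require_channels)) {
    missing <- setdiff(require_channels, channels)
    if (length(missing))
      stop_quant("missing channel(s) in ", path, ": ",
                 paste(missing, collapse = ", "))
  }
  voxels <- array(0, dim = c(length(channels), meta$n_sections,
                             meta$nz, meta$nx))
  k <- 0L
  for (ch in seq_along(channels)) for (s in seq_len(meta$n_sections)) {
    k <- k + 1L
    voxels[ch, s, , ] <- pages[[k]] * meta$intensity_scale
  }
  new_disc_stack(voxels, channels, meta$z_spacing_um, meta$pixel_size_um)
}

#' Write generator ground truth as CSV
#'
#' One row per (region, subregion) with the expected column-summed level,
#' the apico-basal fraction, and the retention factor.
#'
#' @param truth a `disc_truth` from [make_disc()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "disc_truth"))
  rows <- expand.grid(subregion = SUBREGIONS, region = AP_REGIONS,
                      stringsAsFactors = FALSE)[, 2:1]
  rows$level <- truth$true_levels[rows$region]
  rows$fraction <- truth$true_fractions[cbind(rows$region, rows$subregion)]
  rows$retention <- truth$retention[cbind(rows$region, rows$subregion)]
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
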