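#' Mean CI-channel profile along the AP axis
#'
#' Per AP column, the mean CI-marker intensity over the tissue pixels of
#' the mask, smoothed by a centred moving average. Invalid mask columns
#' yield `NA`.
#'
#' @param projection_ci `projection_image` of the CI-like channel.
#' @param mask a `disc_mask`.
#' @param smooth_window moving-average window in columns (odd; 1 =
#'   unsmoothed).
#' @return A data frame with columns `x` and `ci` (class `ci_profile`,
#'   attribute `smooth_window`).
#' @export
ci_profile <- function(projection_ci, mask, smooth_window = 5L) {
  stopifnot(inherits(mask, "disc_mask"))
  if (!any(mask$valid)) stop_quant("mask has no valid columns")
  px <- unclass(projection_ci)
  nx <- ncol(px)
  raw <- rep(NA_real_, nx)
  for (x in which(mask$valid))
    raw[x] <- mean(px[mask$z_top[x]:mask$z_bottom[x], x])
  w <- as.integer(smooth_window)
  if (w < 1L || w %% 2L == 0L)
    stop_quant("smooth_window must be a positive odd integer")
  sm <- raw
  if (w > 1L) {
    half <- w %/% 2L
    for (x in which(!is.na(raw))) {
      win <- raw[max(1L, x - half):min(nx, x + half)]
      sm[x] <- mean(win, na.rm = TRUE)
    }
  }
  structure(data.frame(x = seq_len(nx), ci = sm),
            class = c("ci_profile", "data.frame"), smooth_window = w)
}

#' Classify AP positions into the four Hedgehog-gradient regions
#'
#' Splits the valid AP extent into the posterior compartment (P, everything
#' at or posterior of the user-supplied A/P boundary) and three anterior
#' regions read off the CI profile: walking anterior from the boundary,
#' CI-A is the contiguous dip where the profile sits between the low and
#' high thresholds, CI-F the following plateau at or above the high
#' threshold (held, by hysteresis, until the profile falls below the low
#' threshold), and CI-R the remaining anterior extent. Thresholds are
#' defined relative to the posterior background level and the robust
#' anterior maximum, which makes the classification invariant to positive
#' affine rescaling of the CI channel.
#'
#' If no plateau reaches the high threshold the classifier falls back to
#' fixed region widths (provenance `fixed-width fallback`); if the profile
#' is at plateau level immediately anterior of the boundary (no dip), CI-A
#' gets width zero and CI-F abuts the boundary (provenance `no-dip`).
#'
#' @param profile a [ci_profile()].
#' @param ap_boundary_x first pixel column of the posterior side (1-based).
#' @param background_quantile quantile of the posterior profile used as
#'   background level.
#' @param low_frac,high_frac thresholds as fractions of the
#'   background-to-maximum span.
#' @param min_region_width regions narrower than this are merged into
#'   their anterior neighbour.
#' @param fallback_widths named vector `c(ci_a=, ci_f=)` of region widths
#'   used by the fixed-width fallback.
#' @return A data frame (class `ap_region_map`) with one row per region
#'   (`CI-R`, `CI-F`, `CI-A`, `P`): `x_start`, `x_end` (inclusive; empty
#'   regions have `width` 0), `width`, `provenance`.
#' @export
classify_regions <- function(profile, ap_boundary_x,
                             background_quantile = 0.5,
                             low_frac = 0.2, high_frac = 0.6,
                             min_region_width = 3L,
                             fallback_widths = c(ci_a = 12L, ci_f = 20L)) {
  stopifnot(inherits(profile, "ci_profile"))
  ok <- !is.na(profile$ci)
  if (!any(ok)) stop_quant("profile has no defined values")
  xs <- profile$x[ok]
  xmin <- min(xs); xmax <- max(xs)
  b <- as.integer(ap_boundary_x)
  if (b <= xmin || b > xmax)
    stop_quant("A/P boundary x=", b, " outside the profile domain (",
               xmin, ", ", xmax, "]")
  v <- profile$ci
  post <- v[profile$x >= b & ok]
  ant_x <- sort(xs[xs < b], decreasing = TRUE)   # boundary -> anterior
  if (!length(post) || !length(ant_x))
    stop_quant("need profile values on both sides of the boundary")
  bg <- quantile(post, background_quantile, names = FALSE, na.rm = TRUE)
  m <- quantile(v[profile$x < b & ok], 0.98, names = FALSE, na.rm = TRUE)
  t_low <- bg + low_frac * (m - bg)
  t_high <- bg + high_frac * (m - bg)
  widths <- NULL
  provenance <- "classified"
  if (!(m > bg) || !any(v[profile$x < b & ok] >= t_high)) {
    widths <- fallback_region_widths(fallback_widths, b, xmin)
    provenance <- "fixed-width fallback"
  } else {
    i <- 1L; n_ant <- length(ant_x)
    ca <- 0L
    while (i <= n_ant && v[ant_x[i]] > t_low && v[ant_x[i]] < t_high) {
      ca <- ca + 1L; i <- i + 1L
    }
    if (i > n_ant || v[ant_x[i]] < t_high) {
      # dip never reaches a plateau adjacent to it
      widths <- fallback_region_widths(fallback_widths, b, xmin)
      provenance <- "fixed-width fallback"
    } else {
      cf <- 0L
      while (i <= n_ant && v[ant_x[i]] >= t_low) {
        cf <- cf + 1L; i <- i + 1L
      }
      if (ca == 0L) provenance <- "no-dip"
      if (ca > 0L && ca < min_region_width) {     # merge CI-A into CI-F
        cf <- cf + ca; ca <- 0L
        provenance <- paste0(provenance, "; narrow CI-A merged")
      }
      if (cf > 0L && cf < min_region_width) {     # merge CI-F into CI-R
        cf <- 0L
        provenance <- paste0(provenance, "; narrow CI-F merged")
      }
      widths <- c(ci_a = ca, ci_f = cf)
    }
  }
  ca <- widths[["ci_a"]]; cf <- widths[["ci_f"]]
  map <- data.frame(
    region = AP_REGIONS,
    x_start = c(xmin, b - ca - cf, b - ca, b),
    x_end = c(b - ca - cf - 1L, b - ca - 1L, b - 1L, xmax))
  map$width <- pmax(0L, map$x_end - map$x_start + 1L)
  map$provenance <- provenance
  structure(map, class = c("ap_region_map", "data.frame"),
            thresholds = c(background = bg, low = t_low, high = t_high))
}

fallback_region_widths <- function(fallback_widths, b, xmin) {
  avail <- b - xmin
  ca <- min(as.integer(fallback_widths[["ci_a"]]), avail)
  cf <- min(as.integer(fallback_widths[["ci_f"]]), avail - ca)
  c(ci_a = ca, ci_f = cf)
}

#' Estimate the A/P boundary from the CI profile
#'
#' Helper returning the posterior-most crossing of the low threshold (the
#' CI signal vanishes in the posterior compartment). A user-supplied
#' boundary always takes precedence in the pipeline.
#'
#' @inheritParams classify_regions
#' @return Estimated boundary x (1-based), or `NA` if no crossing exists.
#' @export
estimate_ap_boundary <- function(profile, background_quantile = 0.1,
                                 low_frac = 0.2) {
  ok <- !is.na(profile$ci)
  v <- profile$ci[ok]; xs <- profile$x[ok]
  bg <- quantile(v, background_quantile, names = FALSE)
  m <- quantile(v, 0.98, names = FALSE)
  t_low <- bg + low_frac * (m - bg)
  above <- which(v >= t_low)
  if (!length(above) || max(above) == length(v)) return(NA_integer_)
  xs[max(above)] + 1L
}

#' Assign tiled columns to AP regions
#'
#' A column belongs to the region containing its midpoint pixel.
#'
#' @param columns data frame from [make_columns()].
#' @param region_map an `ap_region_map` from [classify_regions()].
#' @return Character vector of region labels (`NA` when the midpoint falls
#'   outside every region), one per column.
#' @export
assign_columns <- function(columns, region_map) {
  mids <- (columns$x_start + columns$x_end) %/% 2L
  vapply(mids, function(m) {
    hit <- region_map$width > 0 & region_map$x_start <= m &
      region_map$x_end >= m
    if (any(hit)) region_map$region[which(hit)[1L]] else NA_character_
  }, character(1))
}
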