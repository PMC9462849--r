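#' Subregion partition specification
#'
#' Thickness fractions that split an apical-to-basal column into the
#' apical/subapical, lateral, and basal subregions. The defaults are 15%
#' apical (the depth of the septate junctions) and 10% basal; the lateral
#' band takes the remainder.
#'
#' @param f_ap apical fraction of the column thickness.
#' @param f_ba basal fraction of the column thickness.
#' @return An object of class `subregion_spec`.
#' @export
subregion_spec <- function(f_ap = 0.15, f_ba = 0.10) {
  if (f_ap <= 0 || f_ba <= 0 || f_ap + f_ba >= 1)
    stop_quant("need 0 < f_ap, 0 < f_ba and f_ap + f_ba < 1")
  structure(list(f_ap = f_ap, f_ba = f_ba,
                 rounding = "half-away-from-zero, floor 1 row"),
            class = "subregion_spec")
}

# Integer band heights for a column of thickness h. Rounds f*h half away
# from zero with a floor of one row per band; the lateral band takes the
# remainder, so the three bands always cover h exactly.
partition_heights <- function(h, f_ap = 0.15, f_ba = 0.10) {
  h <- as.integer(h)
  if (h < H_MIN)
    stop_quant("column thickness ", h, " below minimum of ", H_MIN)
  n_ap <- max(1L, as.integer(round_half_up(f_ap * h)))
  n_ba <- max(1L, as.integer(round_half_up(f_ba * h)))
  n_lat <- h - n_ap - n_ba
  if (n_lat < 1L)
    stop_quant("thickness ", h, " leaves no lateral band for fractions ",
               f_ap, "/", f_ba)
  c(apical = n_ap, lateral = n_lat, basal = n_ba)
}

#' Partition a column into apical, lateral, and basal subregions
#'
#' Splits the depth range of one column into three disjoint bands covering
#' it exactly: the apical/subapical band is `round(f_ap * h)` rows from the
#' top (minimum 1), the basal band `round(f_ba * h)` rows from the bottom
#' (minimum 1), the lateral band the remainder.
#'
#' @param col a list or one-row data frame with `x_start`, `x_end`,
#'   `z_top`, `z_bottom` (inclusive pixel ranges).
#' @param spec a [subregion_spec()].
#' @return A named list of three ROIs (`apical`, `lateral`, `basal`), each
#'   with `x_start`, `x_end`, `z_top`, `z_bottom`.
#' @export
partition_column <- function(col, spec = subregion_spec()) {
  h <- col$z_bottom - col$z_top + 1L
  bands <- partition_heights(h, spec$f_ap, spec$f_ba)
  roi <- function(zt, zb) list(x_start = col$x_start, x_end = col$x_end,
                               z_top = zt, z_bottom = zb)
  list(
    apical = roi(col$z_top, col$z_top + bands[["apical"]] - 1L),
    lateral = roi(col$z_top + bands[["apical"]],
                  col$z_bottom - bands[["basal"]]),
    basal = roi(col$z_bottom - bands[["basal"]] + 1L, col$z_bottom))
}

#' Measure a rectangular ROI on a projection
#'
#' The three atomic statistics of the pipeline: pixel count, integrated
#' density (sum of pixel values), and mean intensity (integrated density
#' over pixel count).
#'
#' @param projection a `projection_image` (or plain matrix).
#' @param roi list with `x_start`, `x_end`, `z_top`, `z_bottom`.
#' @return A list `(n_pixels, integrated_density, mean_intensity)`.
#' @export
measure_roi <- function(projection, roi) {
  px <- unclass(projection)
  if (roi$x_start > roi$x_end || roi$z_top > roi$z_bottom)
    stop_quant("empty ROI")
  if (roi$x_start < 1L || roi$z_top < 1L ||
      roi$x_end > ncol(px) || roi$z_bottom > nrow(px))
    stop_quant("ROI out of image bounds")
  block <- px[roi$z_top:roi$z_bottom, roi$x_start:roi$x_end, drop = FALSE]
  n <- length(block)
  s <- sum(block)
  list(n_pixels = n, integrated_density = s, mean_intensity = s / n)
}

#' Relative intensity of a subregion within its column
#'
#' Ratio of the subregion's integrated density over the integrated density
#' of the full-thickness column that contains it.
#'
#' @param sub subregion measurement from [measure_roi()].
#' @param column whole-column measurement from [measure_roi()].
#' @return The ratio, or `NA` (with a warning) if the column density is
#'   not positive.
#' @export
relative_intensity <- function(sub, column) {
  if (!is.finite(column$integrated_density) ||
      column$integrated_density <= 0) {
    warning("column integrated density is not positive; ",
            "relative intensity undefined", call. = FALSE)
    return(NA_real_)
  }
  sub$integrated_density / column$integrated_density
}

#' Quantify columns and aggregate per AP region
#'
#' Partitions every column into its three subregions, measures each, and
#' pools pixels per (AP region x subregion): region-level integrated
#' density and pixel counts are sums over member columns, the region mean
#' intensity is pooled sum over pooled count, and the region relative
#' intensity is the pooled subregion density over the pooled column
#' density. A `column` row per region carries the whole-column pooled
#' statistics. Pooling pixels (rather than averaging per-column ratios)
#' matches region-level integrated-density measurement and is robust to
#' thickness variation across columns.
#'
#' @param projection a `projection_image` of the signal channel.
#' @param columns data frame from [make_columns()].
#' @param region_per_column character vector, one AP region label per row
#'   of `columns` (`NA` columns are dropped).
#' @param spec a [subregion_spec()].
#' @return A data frame with columns `region`, `subregion` (apical,
#'   lateral, basal, column), `n_pixels`, `integrated_density`,
#'   `mean_intensity`, `relative_intensity`. Regions with no valid column
#'   get `NA` statistics with a warning.
#' @export
aggregate_region <- function(projection, columns, region_per_column,
                             spec = subregion_spec()) {
  stopifnot(nrow(columns) == length(region_per_column))
  keep <- !is.na(region_per_column)
  columns <- columns[keep, , drop = FALSE]
  region_per_column <- region_per_column[keep]
  acc <- list()
  for (i in seq_len(nrow(columns))) {
    col <- columns[i, ]
    if (col$height < H_MIN) {
      warning("column at x=", col$x_start, " thinner than ", H_MIN,
              " px; excluded", call. = FALSE)
      next
    }
    parts <- partition_column(col, spec)
    whole <- measure_roi(projection, list(
      x_start = col$x_start, x_end = col$x_end,
      z_top = col$z_top, z_bottom = col$z_bottom))
    r <- region_per_column[i]
    for (s in SUBREGIONS) {
      m <- measure_roi(projection, parts[[s]])
      key <- paste(r, s, sep = "\r")
      acc[[key]] <- add_measure(acc[[key]], m)
    }
    key <- paste(r, "column", sep = "\r")
    acc[[key]] <- add_measure(acc[[key]], whole)
  }
  out <- expand.grid(subregion = c(SUBREGIONS, "column"),
                     region = AP_REGIONS,
                     stringsAsFactors = FALSE)[, 2:1]
  out$n_pixels <- NA_real_
  out$integrated_density <- NA_real_
  out$mean_intensity <- NA_real_
  out$relative_intensity <- NA_real_
  for (i in seq_len(nrow(out))) {
    key <- paste(out$region[i], out$subregion[i], sep = "\r")
    m <- acc[[key]]
    if (is.null(m)) next
    out$n_pixels[i] <- m$n_pixels
    out$integrated_density[i] <- m$integrated_density
    out$mean_intensity[i] <- m$integrated_density / m$n_pixels
  }
  for (r in unique(out$region)) {
    rows <- out$region == r
    if (all(is.na(out$n_pixels[rows]))) {
      if (r %in% region_per_column)
        warning("region ", r, " has no valid columns", call. = FALSE)
      next
    }
    coldens <- out$integrated_density[rows & out$subregion == "column"]
    for (s in SUBREGIONS) {
      i <- which(rows & out$subregion == s)
      out$relative_intensity[i] <-
        if (is.finite(coldens) && coldens > 0)
          out$integrated_density[i] / coldens else NA_real_
    }
    out$relative_intensity[rows & out$subregion == "column"] <- 1
  }
  out
}

add_measure <- function(acc, m) {
  if (is.null(acc))
    list(n_pixels = m$n_pixels, integrated_density = m$integrated_density)
  else
    list(n_pixels = acc$n_pixels + m$n_pixels,
         integrated_density = acc$integrated_density + m$integrated_density)
}
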