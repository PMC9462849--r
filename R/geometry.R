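#' Average-intensity XZ projection of a stack
#'
#' Collapses a window of consecutive optical sections of one channel into a
#' single XZ image by per-pixel arithmetic mean, the projection on which
#' all quantification is performed. Eight sections are averaged by
#' default; the window is centred in the stack when `z_start` is not
#' given.
#'
#' @param stack a `disc_stack`.
#' @param channel channel name to project.
#' @param z_start first section of the window (1-based); default centres
#'   the window.
#' @param n number of sections to average.
#' @return A `projection_image`: an `nz x nx` matrix (row 1 = apical) with
#'   attributes `channel`, `n_sections_used`, and `pixel_size_um`.
#' @export
average_projection <- function(stack, channel = "surface_receptor",
                               z_start = NULL, n = 8L) {
  stopifnot(inherits(stack, "disc_stack"))
  ch <- match(channel, stack$channel_names)
  if (is.na(ch))
    stop_quant("channel '", channel, "' not in stack (has: ",
               paste(stack$channel_names, collapse = ", "), ")")
  ns <- dim(stack$voxels)[2]
  n <- as.integer(n)
  if (n < 1L) stop_quant("n must be >= 1")
  if (is.null(z_start)) z_start <- max(1L, (ns - n) %/% 2L + 1L)
  z_start <- as.integer(z_start)
  if (z_start < 1L || z_start + n - 1L > ns)
    stop_quant("projection window [", z_start, ", ", z_start + n - 1L,
               "] out of range: stack has ", ns, " sections")
  sub <- stack$voxels[ch, z_start:(z_start + n - 1L), , , drop = FALSE]
  px <- apply(sub, c(3, 4), mean)
  new_projection(px, channel, n, stack$pixel_size_um)
}

new_projection <- function(pixels, channel, n_used, pixel_size_um) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), all(pixels >= 0))
  structure(pixels, class = c("projection_image", "matrix", "array"),
            channel = channel, n_sections_used = as.integer(n_used),
            pixel_size_um = pixel_size_um)
}

#' @export
print.projection_image <- function(x, ...) {
  cat("<projection_image> ", nrow(x), " x ", ncol(x), " px, channel '",
      attr(x, "channel"), "', mean of ", attr(x, "n_sections_used"),
      " sections\n", sep = "")
  invisible(x)
}

#' Detect the tissue footprint on a projection
#'
#' Determines the shape and limits of the disc on an XZ projection:
#' Gaussian smoothing, automatic (Otsu) or fixed thresholding, largest
#' connected foreground component, morphological hole filling, and finally
#' per-column refinement of the apical and basal edges to the half-maximum
#' crossing of the smoothed depth profile (which localizes a blurred step
#' edge to the pixel regardless of the global threshold). Columns whose
#' tissue span is below the minimum partitionable thickness are flagged
#' invalid.
#'
#' @param projection a `projection_image`.
#' @param smoothing_sigma Gaussian smoothing sigma in pixels.
#' @param min_area minimum pixel area of the detected component; smaller
#'   detections raise "no tissue detected".
#' @param threshold optional fixed intensity threshold replacing Otsu.
#' @param refine_edges refine per-column extents by half-maximum edge
#'   localization (default `TRUE`).
#' @return A `disc_mask`: list with the logical `mask`, integer vectors
#'   `z_top` / `z_bottom` (inclusive row extents per AP column, `NA` where
#'   invalid), and logical `valid`.
#' @export
detect_disc <- function(projection, smoothing_sigma = 2, min_area = 50L,
                        threshold = NULL, refine_edges = TRUE) {
  px <- unclass(projection)
  if (length(px) == 0L) stop_quant("empty projection")
  sm <- if (smoothing_sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(px),
                                      sigma = smoothing_sigma))
  else px
  thr <- if (is.null(threshold)) {
    # Otsu on the log-compressed image: regional intensity differences
    # within the tissue (several-fold in a morphogen gradient) otherwise
    # pull the global threshold between tissue modes instead of between
    # background and tissue.
    lg <- log1p(sm)
    rng <- range(lg)
    if (diff(rng) <= 0) stop_quant("no tissue detected: flat image")
    expm1(EBImage::otsu(EBImage::Image(lg), range = rng))
  } else threshold
  fg <- sm > thr
  if (!any(fg)) stop_quant("no tissue detected: nothing above threshold")
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  sizes <- tabulate(as.integer(lab))
  if (!length(sizes) || max(sizes) < min_area)
    stop_quant("no tissue detected: largest component has ",
               if (length(sizes)) max(sizes) else 0,
               " px (min_area = ", min_area, ")")
  keep <- which.max(sizes)
  comp <- EBImage::Image(as.integer(lab) == keep, dim = dim(px))
  comp <- EBImage::imageData(EBImage::fillHull(comp)) > 0
  dim(comp) <- dim(px)
  nz <- nrow(px); nx <- ncol(px)
  z_top <- rep(NA_integer_, nx)
  z_bottom <- rep(NA_integer_, nx)
  for (x in seq_len(nx)) {
    rows <- which(comp[, x])
    if (!length(rows)) next
    zt <- rows[1L]; zb <- rows[length(rows)]
    if (refine_edges) {
      e <- refine_column_edges(px[, x], zt, zb)
      zt <- e[1L]; zb <- e[2L]
    }
    z_top[x] <- zt; z_bottom[x] <- zb
    comp[, x] <- FALSE
    comp[zt:zb, x] <- TRUE
  }
  valid <- !is.na(z_top) & (z_bottom - z_top + 1L) >= H_MIN
  structure(list(mask = comp, z_top = z_top, z_bottom = z_bottom,
                 valid = valid, h_min = H_MIN,
                 threshold = as.numeric(thr)),
            class = "disc_mask")
}

# Half-maximum refinement of one column's tissue extent on the raw
# (unsmoothed) projection profile, where a tissue edge is a sharp step:
# the interior level at each edge is the maximum of the profile within 6
# rows inside the thresholded extent, and the edge row is the outermost
# row still at >= half that level, searched within +/-3 px of the
# thresholded extent. Smoothing-independent, so thin bright basal bands
# do not bleed outward.
refine_column_edges <- function(p, zt, zb, halo = 3L) {
  n <- length(p)
  a_top <- max(p[seq(zt, min(zb, zt + halo + 3L))])
  zt2 <- NA_integer_
  for (cand in seq(max(1L, zt - halo), zb)) {
    if (p[cand] >= a_top / 2) { zt2 <- cand; break }
  }
  a_bot <- max(p[seq(max(zt, zb - halo - 3L), zb)])
  zb2 <- NA_integer_
  for (cand in seq(min(n, zb + halo), zt)) {
    if (p[cand] >= a_bot / 2) { zb2 <- cand; break }
  }
  if (is.na(zt2) || is.na(zb2) || zt2 > zb2) c(zt, zb)
  else c(zt2, zb2)
}

#' @export
print.disc_mask <- function(x, ...) {
  cat("<disc_mask> ", nrow(x$mask), " x ", ncol(x$mask), " px, ",
      sum(x$valid), " valid AP columns, thickness ",
      if (any(x$valid)) paste0(min(x$z_bottom - x$z_top + 1L,
                                   na.rm = TRUE), "-",
                               max(x$z_bottom - x$z_top + 1L,
                                   na.rm = TRUE)) else "-",
      " px\n", sep = "")
  invisible(x)
}

#' Write a disc mask as single-channel TIFF (for inspection)
#' @param mask a `disc_mask`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask$mask * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' Tile fixed-width apical-to-basal columns across the disc
#'
#' Starting at the user-supplied A/P boundary, rectangular columns of
#' identical width are tiled outward in both directions across the mask's
#' valid AP extent. Each column's depth range is the union extent (minimum
#' apical, maximum basal row) of its valid member mask columns; columns
#' with no valid member, and partial-width columns at the image border, are
#' dropped. Columns are tagged `anterior` or `posterior` by their side of
#' the boundary.
#'
#' @param mask a `disc_mask`.
#' @param ap_boundary_x first pixel column of the posterior side (1-based).
#' @param width column width in pixels.
#' @return A data frame with one row per column: `x_start`, `x_end`,
#'   `z_top`, `z_bottom` (all inclusive), `height`, `side`, ordered
#'   anterior to posterior.
#' @export
make_columns <- function(mask, ap_boundary_x, width = 4L) {
  stopifnot(inherits(mask, "disc_mask"))
  width <- as.integer(width)
  if (width < 1L) stop_quant("width must be >= 1")
  vx <- which(mask$valid)
  if (!length(vx)) stop_quant("mask has no valid columns")
  b <- as.integer(ap_boundary_x)
  if (b < min(vx) || b > max(vx))
    stop_quant("A/P boundary x=", b, " lies outside the tissue extent [",
               min(vx), ", ", max(vx), "]")
  nx <- ncol(mask$mask)
  starts_post <- seq(b, nx - width + 1L, by = width)
  starts_ant <- rev(seq(b - width, 1L, by = -width))
  starts <- c(starts_ant, starts_post)
  out <- lapply(starts, function(x0) {
    x1 <- x0 + width - 1L
    members <- x0:x1
    ok <- members[mask$valid[members]]
    if (!length(ok)) return(NULL)
    data.frame(x_start = x0, x_end = x1,
               z_top = min(mask$z_top[ok]),
               z_bottom = max(mask$z_bottom[ok]),
               side = if (x1 < b) "anterior" else "posterior")
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop_quant("no valid columns to tile")
  out$height <- out$z_bottom - out$z_top + 1L
  out[, c("x_start", "x_end", "z_top", "z_bottom", "height", "side")]
}
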