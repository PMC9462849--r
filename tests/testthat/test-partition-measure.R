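test_that("band heights reproduce the 15/75/10 partition rule", {
  expect_equal(apbaquant:::partition_heights(200),
               c(apical = 30L, lateral = 150L, basal = 20L))
  expect_equal(apbaquant:::partition_heights(100),
               c(apical = 15L, lateral = 75L, basal = 10L))
  expect_equal(apbaquant:::partition_heights(7),
               c(apical = 1L, lateral = 5L, basal = 1L))
})

test_that("bands cover every thickness from 3 to 50 exactly", {
  for (h in 3:50) {
    bands <- apbaquant:::partition_heights(h)
    expect_true(all(bands >= 1L))
    expect_equal(sum(bands), h)
    # reconstruct the row sets and verify the disjoint exact cover
    col <- list(x_start = 1L, x_end = 1L, z_top = 10L,
                z_bottom = 10L + h - 1L)
    parts <- partition_column(col)
    rows <- unname(unlist(lapply(parts, function(r) r$z_top:r$z_bottom)))
    expect_equal(sort(rows), 10:(10 + h - 1))
    expect_false(any(duplicated(rows)))
  }
  expect_error(apbaquant:::partition_heights(2), "below minimum")
})

test_that("measure_roi computes count, sum, and mean", {
  px <- matrix(c(1, 3, 2, 4), 2, 2)   # values 1..4 in a 2x2 block
  proj <- apbaquant:::new_projection(px, "surface_receptor", 1L, 1)
  m <- measure_roi(proj, list(x_start = 1, x_end = 2, z_top = 1,
                              z_bottom = 2))
  expect_equal(m$integrated_density, 10)
  expect_equal(m$mean_intensity, 2.5)
  expect_equal(m$n_pixels, 4)

  zero <- apbaquant:::new_projection(matrix(0, 3, 3), "x", 1L, 1)
  mz <- measure_roi(zero, list(x_start = 1, x_end = 3, z_top = 1,
                               z_bottom = 3))
  expect_equal(mz$integrated_density, 0)
  expect_equal(mz$mean_intensity, 0)

  set.seed(7)
  big <- apbaquant:::new_projection(matrix(runif(600), 20, 30), "x", 1L, 1)
  roi <- list(x_start = 4, x_end = 17, z_top = 3, z_bottom = 15)
  mb <- measure_roi(big, roi)
  acc <- 0; n <- 0
  for (x in roi$x_start:roi$x_end) for (z in roi$z_top:roi$z_bottom) {
    acc <- acc + unclass(big)[z, x]; n <- n + 1
  }
  expect_equal(mb$integrated_density, acc)
  expect_equal(mb$n_pixels, n)

  expect_error(measure_roi(big, list(x_start = 5, x_end = 4, z_top = 1,
                                     z_bottom = 2)), "empty ROI")
  expect_error(measure_roi(big, list(x_start = 1, x_end = 40, z_top = 1,
                                     z_bottom = 2)), "out of image")
})

test_that("relative intensity behaves on uniform columns and degenerate input", {
  px <- matrix(5, 100, 4)
  proj <- apbaquant:::new_projection(px, "x", 1L, 1)
  col <- list(x_start = 1L, x_end = 4L, z_top = 1L, z_bottom = 100L)
  parts <- partition_column(col)
  whole <- measure_roi(proj, col)
  ratios <- vapply(parts, function(r)
    relative_intensity(measure_roi(proj, r), whole), numeric(1))
  expect_equal(unname(ratios), c(0.15, 0.75, 0.10), tolerance = 1e-12)
  expect_equal(relative_intensity(whole, whole), 1)

  zero <- list(n_pixels = 4, integrated_density = 0, mean_intensity = 0)
  expect_warning(ri <- relative_intensity(zero, zero), "not positive")
  expect_true(is.na(ri))
})

test_that("region aggregation pools pixels, not per-column ratios", {
  set.seed(41)
  px <- matrix(rexp(40 * 60, rate = 0.1), 40, 60)
  proj <- apbaquant:::new_projection(px, "x", 1L, 1)
  columns <- data.frame(
    x_start = c(1L, 9L, 17L, 25L), x_end = c(8L, 16L, 24L, 32L),
    z_top = c(5L, 5L, 8L, 3L), z_bottom = c(30L, 36L, 27L, 38L),
    height = c(26L, 32L, 20L, 36L), side = "anterior")
  regions <- c("CI-R", "CI-R", "P", "P")
  spec <- subregion_spec()
  agg <- aggregate_region(proj, columns, regions, spec)
  oracle <- brute_pool(proj, columns, regions, spec)
  for (r in c("CI-R", "P")) for (s in c("apical", "lateral", "basal",
                                        "column")) {
    row <- agg[agg$region == r & agg$subregion == s, ]
    expect_equal(row$integrated_density, oracle[[paste(r, s)]][1])
    expect_equal(row$n_pixels, oracle[[paste(r, s)]][2])
    expect_equal(row$mean_intensity,
                 oracle[[paste(r, s)]][1] / oracle[[paste(r, s)]][2])
  }
  # pooling differs from the mean of per-column ratios for unequal columns
  sub1 <- measure_roi(proj, partition_column(columns[1, ], spec)$basal)
  sub2 <- measure_roi(proj, partition_column(columns[2, ], spec)$basal)
  w1 <- measure_roi(proj, as.list(columns[1, 1:4]))
  w2 <- measure_roi(proj, as.list(columns[2, 1:4]))
  naive <- mean(c(sub1$integrated_density / w1$integrated_density,
                  sub2$integrated_density / w2$integrated_density))
  pooled <- agg$relative_intensity[agg$region == "CI-R" &
                                     agg$subregion == "basal"]
  expect_false(isTRUE(all.equal(naive, pooled)))
})

test_that("aggregation of identical duplicate columns equals the single column", {
  d <- make_disc(noiseless(), seed = 1)
  proj <- average_projection(d$stack)
  col <- data.frame(x_start = 9L, x_end = 12L, z_top = 9L, z_bottom = 32L,
                    height = 24L, side = "anterior")
  spec <- subregion_spec()
  one <- aggregate_region(proj, col, "CI-R", spec)
  two <- aggregate_region(proj, rbind(col, col), c("CI-R", "CI-R"), spec)
  keep <- !is.na(one$n_pixels)
  expect_equal(two$mean_intensity[keep], one$mean_intensity[keep])
  expect_equal(two$relative_intensity[keep], one$relative_intensity[keep])
  expect_equal(two$n_pixels[keep], 2 * one$n_pixels[keep])
})

test_that("subregion densities conserve the column density exactly", {
  d <- make_disc(small_config(), seed = 44)
  q <- quantify_stack(d$stack, config = small_run_cfg())
  r <- q$records[!is.na(q$records$n_pixels), ]
  for (reg in unique(r$region)) {
    sub <- r[r$region == reg, ]
    expect_equal(
      sum(sub$integrated_density[sub$subregion != "column"]),
      sub$integrated_density[sub$subregion == "column"],
      tolerance = 1e-12)
    expect_equal(sum(sub$relative_intensity[sub$subregion != "column"]),
                 1, tolerance = 1e-9)
  }
})

test_that("relative intensities are scale invariant, means scale linearly", {
  d <- make_disc(small_config(), seed = 45)
  q1 <- quantify_stack(d$stack, config = small_run_cfg())
  scaled <- d$stack
  scaled$voxels[1, , , ] <- scaled$voxels[1, , , ] * 3.7
  q2 <- quantify_stack(scaled, config = small_run_cfg())
  keep <- !is.na(q1$records$n_pixels)
  expect_equal(q2$records$relative_intensity[keep],
               q1$records$relative_intensity[keep], tolerance = 1e-9)
  expect_equal(q2$records$mean_intensity[keep],
               3.7 * q1$records$mean_intensity[keep], tolerance = 1e-9)
})

test_that("noise-free recovery of configured fractions is within 0.02", {
  frac <- default_smo_fractions()
  frac[] <- rep(c(0.2, 0.4, 0.4), each = 4)
  cfg <- noiseless(smo_fractions = frac)
  d <- make_disc(cfg, seed = 1)
  q <- quantify_stack(d$stack, config = small_run_cfg())
  r <- q$records[!is.na(q$records$n_pixels) &
                   q$records$subregion != "column", ]
  err <- r$relative_intensity -
    frac[cbind(r$region, r$subregion)]
  expect_lt(max(abs(err)), 0.02)
})

test_that("measured basal fraction responds monotonically to generator f_ba", {
  got <- vapply(c(0.10, 0.20, 0.30), function(fb) {
    frac <- default_smo_fractions()
    frac["P", ] <- c(0.15, 0.85 - fb, fb)
    d <- make_disc(noiseless(smo_fractions = frac), seed = 1)
    q <- quantify_stack(d$stack, config = small_run_cfg())
    q$records$relative_intensity[q$records$region == "P" &
                                   q$records$subregion == "basal"]
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})
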