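# Disc-level effect estimates and tabular reporting on the records data
# frame produced by quantification (columns: disc_id, condition, region,
# subregion, n_pixels, integrated_density, mean_intensity,
# relative_intensity).

records_value <- function(records, region, subregion,
                          measure = "mean_intensity") {
  rows <- records$region == region & records$subregion == subregion
  v <- records[[measure]][rows]
  names(v) <- records$disc_id[rows]
  v[!is.na(v)]
}

#' Fold change of mean intensity between two AP regions
#'
#' Ratio of the across-disc averages of the per-disc region mean
#' intensities.
#'
#' @param records records data frame.
#' @param region_a,region_b AP region labels (numerator, denominator).
#' @param subregion subregion to compare (default whole `column`).
#' @return The fold change, or `NA` (with a warning) if the denominator
#'   mean is not positive.
#' @export
fold_change <- function(records, region_a, region_b,
                        subregion = "column") {
  a <- records_value(records, region_a, subregion)
  b <- records_value(records, region_b, subregion)
  if (!length(a) || !length(b))
    stop_quant("both regions must be present in the records")
  mb <- mean(b)
  if (!is.finite(mb) || mb <= 0) {
    warning("denominator region mean is not positive", call. = FALSE)
    return(NA_real_)
  }
  mean(a) / mb
}

#' Percent reduction between two cohorts (pulse-chase)
#'
#' `100 * (1 - mean_chase / mean_t0)` on the cohort means of the per-disc
#' mean intensities of one (region, subregion) cell, the decay readout of
#' a surface-labelling pulse-chase.
#'
#' @param records_t0,records_chase records data frames for the two time
#'   points (independent disc cohorts).
#' @param region AP region label.
#' @param subregion subregion label (`apical`, `lateral`, `basal`, or
#'   `column`).
#' @return Percentage reduction (negative = increase), or `NA` with a
#'   warning if the time-0 mean is not positive.
#' @export
percent_reduction <- function(records_t0, records_chase, region,
                              subregion = "column") {
  a <- records_value(records_t0, region, subregion)
  b <- records_value(records_chase, region, subregion)
  if (!length(a) || !length(b))
    stop_quant("region/subregion must be present in both cohorts")
  m0 <- mean(a)
  if (!is.finite(m0) || m0 <= 0) {
    warning("time-0 mean is not positive", call. = FALSE)
    return(NA_real_)
  }
  100 * (1 - mean(b) / m0)
}

#' Within-disc region comparisons
#'
#' Compares two AP regions across the discs of one cohort, pairing by
#' disc: a paired t-test on the mean intensities and a Wilcoxon
#' signed-rank test on the relative intensities, for each requested
#' subregion.
#'
#' @param records records data frame (one cohort).
#' @param region_a,region_b AP regions to compare.
#' @param subregions subregion labels to iterate over.
#' @return A data frame of comparison rows.
#' @export
compare_regions_paired <- function(records, region_a, region_b,
                                   subregions = SUBREGIONS) {
  out <- list()
  for (s in subregions) {
    mi_a <- records_value(records, region_a, s, "mean_intensity")
    mi_b <- records_value(records, region_b, s, "mean_intensity")
    ids <- intersect(names(mi_a), names(mi_b))
    row_t <- as.data.frame(paired_t(mi_a[ids], mi_b[ids]))
    row_t$measure <- "mean_intensity"
    rows <- row_t
    if (s != "column") {
      ri_a <- records_value(records, region_a, s, "relative_intensity")
      ri_b <- records_value(records, region_b, s, "relative_intensity")
      row_w <- as.data.frame(wilcoxon_signed_rank(ri_a[ids], ri_b[ids]))
      row_w$measure <- "relative_intensity"
      rows <- rbind(rows, row_w)
    }
    rows$group_a <- region_a; rows$group_b <- region_b; rows$subregion <- s
    out[[s]] <- rows
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Between-cohort comparisons
#'
#' Mann-Whitney tests between two independent disc cohorts for each
#' (region, subregion, measure) cell.
#'
#' @param records_a,records_b records data frames of the two cohorts.
#' @param regions,subregions labels to iterate over.
#' @param measure `"mean_intensity"` or `"relative_intensity"`.
#' @return A data frame of comparison rows.
#' @export
compare_cohorts <- function(records_a, records_b,
                            regions = AP_REGIONS,
                            subregions = c(SUBREGIONS, "column"),
                            measure = "mean_intensity") {
  out <- list()
  for (r in regions) for (s in subregions) {
    va <- records_value(records_a, r, s, measure)
    vb <- records_value(records_b, r, s, measure)
    if (!length(va) || !length(vb)) next
    row <- as.data.frame(mann_whitney(va, vb))
    row$measure <- measure
    row$group_a <- r; row$group_b <- r; row$subregion <- s
    out[[paste(r, s)]] <- row
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write records and comparison tables to disk
#'
#' Deterministic CSV outputs plus a plain-text log recording, for every
#' test, its sample sizes and whether the exact or approximate path was
#' taken. No multiple-testing correction is applied (noted in the log).
#'
#' @param records records data frame.
#' @param comparisons data frame of comparison rows (possibly empty or
#'   `NULL`).
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
report_results <- function(records, comparisons, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(records = file.path(out_dir, "records.csv"))
  write.csv(records, files[["records"]], row.names = FALSE)
  log_lines <- c("apbaquant report",
                 paste0("records: ", length(unique(records$disc_id)),
                        " disc(s), ", nrow(records), " rows"),
                 "p-values are two-sided; no multiple-testing correction")
  if (!is.null(comparisons) && nrow(comparisons)) {
    files[["comparisons"]] <- file.path(out_dir, "comparisons.csv")
    write.csv(comparisons, files[["comparisons"]], row.names = FALSE)
    log_lines <- c(log_lines, apply(comparisons, 1, function(row)
      paste0(row[["test"]], " ", row[["group_a"]], " vs ", row[["group_b"]],
             " [", row[["subregion"]], ", ", row[["measure"]], "]: p=",
             row[["p_value"]], ", n=", row[["n"]], ", path=",
             row[["method_path"]])))
  }
  files[["log"]] <- file.path(out_dir, "report.log")
  writeLines(log_lines, files[["log"]])
  invisible(files)
}
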