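# Pipeline orchestration: run configuration, per-disc quantification, and
# the simulate / quantify / compare / recover commands that the CLI script
# wraps.

default_run_config <- function() {
  list(
    channels = list(signal = "surface_receptor", region = "ci_marker"),
    n_sections = 8L,
    z_start = NULL,                 # NULL = centred window
    column_width = 4L,
    subregion_fractions = list(apical = 0.15, basal = 0.10),
    detection = list(smoothing_sigma = 2, min_area = 50L),
    classification = list(background_quantile = 0.5, low_frac = 0.2,
                          high_frac = 0.6, min_region_width = 3L,
                          fallback_widths = list(ci_a = 12L, ci_f = 20L)),
    ap_boundary_x = 141L,
    seed = 1L,
    n_discs = 20L,
    n_chase = 23L,
    condition = "ctr",
    generator = list(),             # overrides for disc_config()
    input_dir = NULL,
    out_dir = "apbaquant-out")
}

#' Read and validate a pipeline run configuration
#'
#' Loads a YAML configuration, fills unset keys with package defaults, and
#' validates it; validation failures name the offending key.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list merged on top (e.g. command-line values).
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_quant("config file not found: ", path)
    yaml::read_yaml(path) %||% list()
  }
  cfg <- modifyList(cfg, user)
  cfg <- modifyList(cfg, overrides)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  need <- function(test, key, what)
    if (!test) stop_quant("invalid run config key '", key, "': ", what)
  need(is.list(cfg$channels) &&
         all(c("signal", "region") %in% names(cfg$channels)),
       "channels", "must name 'signal' and 'region' channels")
  need(all(nzchar(unlist(cfg$channels))), "channels",
       "channel names must be non-empty")
  need(cfg$n_sections >= 1, "n_sections", "must be >= 1")
  need(cfg$column_width >= 1, "column_width", "must be >= 1")
  f <- cfg$subregion_fractions
  need(f$apical > 0 && f$basal > 0 && f$apical + f$basal < 1,
       "subregion_fractions", "need 0 < apical, basal, apical + basal < 1")
  need(cfg$ap_boundary_x >= 1, "ap_boundary_x", "must be >= 1")
  need(cfg$n_discs >= 1, "n_discs", "must be >= 1")
  if (!is.null(cfg$input_dir))
    need(dir.exists(cfg$input_dir), "input_dir",
         paste0("directory does not exist: ", cfg$input_dir))
  structure(cfg, class = "run_config")
}

generator_config_from <- function(cfg) {
  args <- cfg$generator
  if (!is.null(args$smo_fractions) && !is.matrix(args$smo_fractions)) {
    m <- do.call(rbind, args$smo_fractions)
    dimnames(m) <- list(AP_REGIONS, SUBREGIONS)
    args$smo_fractions <- m
  }
  if (!is.null(args$region_widths))
    args$region_widths <- unlist(args$region_widths)
  for (k in c("smo_levels", "ci_levels"))
    if (!is.null(args[[k]])) args[[k]] <- unlist(args[[k]])
  if (is.null(args$ap_boundary_x)) args$ap_boundary_x <- cfg$ap_boundary_x
  if (is.null(args$n_sections)) args$n_sections <- cfg$n_sections
  do.call(disc_config, args)
}

#' Quantify one disc stack end to end
#'
#' Projects the signal and region-marker channels, detects the tissue
#' footprint, tiles apical-to-basal columns from the A/P boundary,
#' classifies AP regions from the marker profile, and aggregates the
#' subregion measurements per region.
#'
#' @param stack a `disc_stack`.
#' @param ap_boundary_x A/P boundary pixel column (1-based).
#' @param config a `run_config` (defaults apply when `NULL`).
#' @return A list: `records` (per-region/subregion measurements),
#'   `region_map`, `columns`, `mask`, `projection` (signal channel).
#' @export
quantify_stack <- function(stack, ap_boundary_x = NULL, config = NULL) {
  cfg <- if (is.null(config)) validate_run_config(default_run_config())
         else config
  b <- ap_boundary_x %||% cfg$ap_boundary_x
  proj_sig <- average_projection(stack, cfg$channels$signal,
                                 z_start = cfg$z_start,
                                 n = cfg$n_sections)
  proj_reg <- average_projection(stack, cfg$channels$region,
                                 z_start = cfg$z_start,
                                 n = cfg$n_sections)
  mask <- detect_disc(proj_sig,
                      smoothing_sigma = cfg$detection$smoothing_sigma,
                      min_area = cfg$detection$min_area)
  columns <- make_columns(mask, b, width = cfg$column_width)
  profile <- ci_profile(proj_reg, mask)
  cl <- cfg$classification
  region_map <- classify_regions(
    profile, b,
    background_quantile = cl$background_quantile,
    low_frac = cl$low_frac, high_frac = cl$high_frac,
    min_region_width = cl$min_region_width,
    fallback_widths = unlist(cl$fallback_widths))
  assignment <- assign_columns(columns, region_map)
  spec <- subregion_spec(cfg$subregion_fractions$apical,
                         cfg$subregion_fractions$basal)
  records <- aggregate_region(proj_sig, columns, assignment, spec)
  list(records = records, region_map = region_map, columns = columns,
       mask = mask, projection = proj_sig)
}

quantify_cohort <- function(discs, config, condition = "ctr") {
  recs <- lapply(seq_along(discs), function(i) {
    q <- quantify_stack(discs[[i]]$stack, config = config)
    r <- q$records
    r$disc_id <- sprintf("%s_disc%03d", condition, i)
    r$condition <- condition
    r
  })
  out <- do.call(rbind, recs)
  out[!is.na(out$n_pixels), ]
}

#' Pipeline command: simulate a cohort of synthetic discs
#'
#' Writes `n_discs` stacks (and, when retention factors are configured
#' under `generator$retention` or `pulse_chase = TRUE`, a chase cohort of
#' `n_chase` stacks) plus per-disc ground-truth CSVs into `out_dir`.
#'
#' @param config a `run_config`.
#' @param pulse_chase also simulate a chase cohort with
#'   [default_retention()] factors.
#' @return Character vector of stack files written, invisibly.
#' @export
cmd_simulate <- function(config, pulse_chase = FALSE) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generator_config_from(cfg)
  files <- character(0)
  write_one <- function(d, name) {
    f <- file.path(cfg$out_dir, paste0(name, ".tif"))
    write_stack(d$stack, f)
    write_truth(d$truth, file.path(cfg$out_dir, paste0(name, "_truth.csv")))
    f
  }
  for (i in seq_len(cfg$n_discs))
    files <- c(files, write_one(make_disc(gen, seed = cfg$seed + i),
                                sprintf("t0_disc%03d", i)))
  if (isTRUE(pulse_chase)) {
    ret <- default_retention()
    for (i in seq_len(cfg$n_chase))
      files <- c(files, write_one(
        make_disc(gen, seed = cfg$seed + 1000L + i, retention = ret),
        sprintf("chase_disc%03d", i)))
  }
  invisible(files)
}

#' Pipeline command: quantify a directory of disc stacks
#'
#' Reads every `*.tif` stack in `config$input_dir`, quantifies it, and
#' writes `records.csv`, `region_maps.csv`, and per-disc mask TIFFs into
#' `out_dir`.
#'
#' @param config a `run_config` with `input_dir` set.
#' @return The records data frame, invisibly.
#' @export
cmd_quantify <- function(config) {
  cfg <- config
  if (is.null(cfg$input_dir))
    stop_quant("invalid run config key 'input_dir': required for quantify")
  paths <- sort(list.files(cfg$input_dir, pattern = "\\.tiff?$",
                           full.names = TRUE))
  if (!length(paths)) stop_quant("no TIFF stacks in ", cfg$input_dir)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  all_records <- list(); all_maps <- list()
  for (p in paths) {
    stack <- read_stack(p, require_channels = unlist(cfg$channels))
    q <- quantify_stack(stack, config = cfg)
    id <- tools::file_path_sans_ext(basename(p))
    r <- q$records
    r$disc_id <- id
    r$condition <- cfg$condition
    all_records[[id]] <- r[!is.na(r$n_pixels), ]
    m <- q$region_map
    m$disc_id <- id
    all_maps[[id]] <- m
    write_mask(q$mask, file.path(cfg$out_dir, paste0(id, "_mask.tif")))
  }
  records <- do.call(rbind, c(all_records, list(make.row.names = FALSE)))
  write.csv(records, file.path(cfg$out_dir, "records.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, c(all_maps, list(make.row.names = FALSE))),
            file.path(cfg$out_dir, "region_maps.csv"), row.names = FALSE)
  invisible(records)
}

#' Pipeline command: compare two record sets
#'
#' Runs the standard battery: within-cohort paired comparisons of the
#' extreme regions (CI-R vs P) and, when a second record set is given,
#' between-cohort Mann-Whitney tests plus percent reductions per region.
#'
#' @param records_a records data frame (or CSV path).
#' @param records_b optional second cohort (or CSV path).
#' @param out_dir output directory for `comparisons.csv` and the log.
#' @return The comparisons data frame, invisibly.
#' @export
cmd_compare <- function(records_a, records_b = NULL,
                        out_dir = "apbaquant-out") {
  load_rec <- function(x) if (is.character(x)) read.csv(x) else x
  ra <- load_rec(records_a)
  comparisons <- compare_regions_paired(ra, "CI-R", "P",
                                        subregions = c(SUBREGIONS, "column"))
  if (!is.null(records_b)) {
    rb <- load_rec(records_b)
    comparisons <- rbind(comparisons,
                         compare_cohorts(ra, rb),
                         make.row.names = FALSE)
  }
  report_results(ra, comparisons, out_dir)
  invisible(comparisons)
}

#' Pipeline command: end-to-end parameter recovery on synthetic cohorts
#'
#' Generates a time-0 cohort (and a chase cohort under the configured
#' retention factors), pushes every disc through the full quantification
#' pipeline, and compares what comes out against the generator's ground
#' truth: apico-basal fractions per region, the P vs CI-R fold change,
#' AP-region label accuracy, and retention-derived percent reductions.
#'
#' @param config a `run_config`; `generator` overrides apply.
#' @param retention region-by-subregion retention matrix for the chase
#'   cohort.
#' @param write if `TRUE`, write `recovery_report.csv` and a JSON sidecar
#'   of every parameter used into `config$out_dir`.
#' @return A list: `report` (data frame: quantity, recovered, truth,
#'   abs_error), `records_t0`, `records_chase`, `label_accuracy`.
#' @export
cmd_recover <- function(config = NULL, retention = default_retention(),
                        write = FALSE) {
  cfg <- if (is.null(config)) validate_run_config(default_run_config())
         else config
  gen <- generator_config_from(cfg)
  t0 <- simulate_cohort(gen, cfg$n_discs, seed = cfg$seed)
  chase <- simulate_cohort(gen, cfg$n_chase, seed = cfg$seed + 1000L,
                           retention = retention)
  rec_t0 <- quantify_cohort(t0, cfg, condition = "t0")
  rec_ch <- quantify_cohort(chase, cfg, condition = "chase")
  truth <- t0[[1]]$truth

  rows <- list()
  addrow <- function(quantity, recovered, expected)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, recovered = recovered, truth = expected,
      abs_error = abs(recovered - expected))
  # apico-basal fraction recovery (cohort mean of per-disc relative
  # intensities vs generator fractions)
  for (r in AP_REGIONS) for (s in SUBREGIONS) {
    v <- records_value(rec_t0, r, s, "relative_intensity")
    addrow(paste0("fraction_", r, "_", s), mean(v),
           truth$true_fractions[r, s])
  }
  lv <- truth$true_levels
  addrow("fold_change_P_vs_CI-R", fold_change(rec_t0, "P", "CI-R"),
         unname(lv[["P"]] / lv[["CI-R"]]))
  # retention-derived percent reductions
  fr <- truth$true_fractions
  for (r in AP_REGIONS) {
    for (s in SUBREGIONS)
      addrow(paste0("pct_reduction_", r, "_", s),
             percent_reduction(rec_t0, rec_ch, r, s),
             100 * (1 - retention[r, s]))
    addrow(paste0("pct_reduction_", r, "_column"),
           percent_reduction(rec_t0, rec_ch, r, "column"),
           100 * (1 - sum(fr[r, ] * retention[r, ])))
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  # AP label accuracy of one quantified disc against generator labels
  q1 <- quantify_stack(t0[[1]]$stack, config = cfg)
  label_accuracy <- region_label_accuracy(q1$region_map, truth)

  if (isTRUE(write)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(report, file.path(cfg$out_dir, "recovery_report.csv"),
              row.names = FALSE)
    pars <- cfg
    pars$generator_realized <- unclass(gen)
    jsonlite::write_json(pars,
                         file.path(cfg$out_dir, "recovery_params.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
  }
  list(report = report, records_t0 = rec_t0, records_chase = rec_ch,
       label_accuracy = label_accuracy)
}

# Fraction of AP pixel columns whose classified region matches the
# generator label, over the classified extent.
region_label_accuracy <- function(region_map, truth) {
  labels <- rep(NA_character_, length(truth$region_label_per_x))
  for (i in seq_len(nrow(region_map))) {
    if (region_map$width[i] <= 0) next
    labels[region_map$x_start[i]:region_map$x_end[i]] <-
      region_map$region[i]
  }
  ok <- !is.na(labels)
  mean(labels[ok] == truth$region_label_per_x[ok])
}
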