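#' Build and validate an end-to-end run configuration
#'
#' One config drives the whole workflow: simulate virtual slides,
#' segment, quantify, simulate and score the chromogenic cohort, and
#' run the group statistics. The single `seed` fans out to fixed
#' per-stage offsets so individual stages can be rerun reproducibly.
#'
#' @param out_dir Output directory for images and result files.
#' @param seed Master seed (integer).
#' @param cases_per_group,images_per_case Layout of the simulated
#'   fluorescence collection.
#' @param n_cells Cells per simulated image.
#' @param image_size Length-2 (height, width) in pixels.
#' @param min_area_px,connectivity,threshold,merge_rule Segmentation
#'   parameters (see [extract_objects()], [threshold_mask()],
#'   [merge_to_gray()]); `threshold` is `"otsu"` or an integer.
#' @param chr_ranges Per-group case-mean ranges for the chromogenic
#'   simulation (default [chr_group_ranges()]).
#' @param chr_cases_per_group,chr_neurons_per_case Chromogenic cohort
#'   layout.
#' @param fdl Further arguments for [fdl_sim_config()] as a named list
#'   (optional overrides, e.g. `list(noise_sd = 0)`).
#' @return Object of class `fdl_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       cases_per_group = 2L, images_per_case = 2L,
                       n_cells = 12L, image_size = c(384L, 384L),
                       min_area_px = 400L, connectivity = 8L,
                       threshold = "otsu", merge_rule = "mean2",
                       chr_ranges = chr_group_ranges(),
                       chr_cases_per_group = 5L,
                       chr_neurons_per_case = 300L,
                       fdl = list()) {
  if (!is.character(out_dir) || length(out_dir) != 1L)
    stop_fq("'out_dir' must be a single path")
  seed <- check_count(seed, "seed")
  if (!identical(threshold, "otsu"))
    threshold <- check_count(threshold, "threshold", 0L)
  if (!connectivity %in% c(4L, 8L)) stop_fq("'connectivity' must be 4 or 8")
  image_size <- c(check_count(image_size[1], "image_size[1]", 8L),
                  check_count(image_size[2], "image_size[2]", 8L))
  stopifnot(is.list(fdl))
  structure(list(
    out_dir = out_dir, seed = seed,
    cases_per_group = check_count(cases_per_group, "cases_per_group", 1L),
    images_per_case = check_count(images_per_case, "images_per_case", 1L),
    n_cells = check_count(n_cells, "n_cells", 0L),
    image_size = image_size,
    min_area_px = check_count(min_area_px, "min_area_px", 0L),
    connectivity = as.integer(connectivity),
    threshold = threshold, merge_rule = merge_rule,
    chr_ranges = chr_ranges,
    chr_cases_per_group = check_count(chr_cases_per_group,
                                      "chr_cases_per_group", 2L),
    chr_neurons_per_case = check_count(chr_neurons_per_case,
                                       "chr_neurons_per_case", 1L),
    fdl = fdl),
    class = "fdl_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [run_config()].
#' @return An `fdl_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$chr_ranges)) vals$chr_ranges <-
      as.data.frame(vals$chr_ranges, stringsAsFactors = FALSE)
  if (!is.null(vals$image_size)) vals$image_size <- unlist(vals$image_size)
  do.call(run_config, vals)
}

# per-stage child seeds, fixed offsets from the master seed
stage_seeds <- function(seed) {
  list(fdl = seed + 101L, chr = seed + 211L)
}

#' Run the full pipeline
#'
#' Simulate -> segment -> quantify -> score -> statistics. Writes
#' `signals.csv` (per-ROI), `case_summaries.csv`, `group_stats.csv`,
#' `scores.csv` (per-neuron chromogenic), `chr_cases.csv`,
#' `stats.json` and `run.log` into `config$out_dir`, and returns the
#' same results in memory. Deterministic given the config (including
#' its seed). If the area filter removes every object, an empty signal
#' table and a "no objects" note are produced instead of an error.
#'
#' @param config An [run_config()] object.
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return List: `signals`, `case_summaries`, `group_stats`,
#'   `chr_scores`, `chr_cases`, `chr_ttests`, `ancova`, `stats`
#'   (the JSON-ready report), `paths`.
#' @export
run_all <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "fdl_run_config"))
  seeds <- stage_seeds(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- c(
    sprintf("fdlquant %s", as.character(packageVersion("fdlquant"))),
    sprintf("R %s", getRversion()),
    sprintf("master seed %d (fdl %d, chr %d)", config$seed,
            seeds$fdl, seeds$chr))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_fq(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e))))
  }

  # --- simulate fluorescence slides ---
  img_dir <- file.path(config$out_dir, "images")
  manifest <- stage("simulate", {
    cfgs <- do.call(fdl_group_configs, c(
      list(seed = seeds$fdl, n_cells = config$n_cells,
           image_height_px = config$image_size[1],
           image_width_px = config$image_size[2]),
      config$fdl))
    generate_fdl_group_set(cfgs, img_dir,
                           cases_per_group = config$cases_per_group,
                           images_per_case = config$images_per_case)
  })
  log_lines <- c(log_lines, sprintf("simulated %d images", nrow(manifest)))

  # --- segment + quantify ---
  signals <- stage("quantify", quantify_manifest(
    manifest, min_area_px = config$min_area_px,
    connectivity = config$connectivity, threshold = config$threshold,
    merge_rule = config$merge_rule))
  thr <- attr(signals, "thresholds")
  log_lines <- c(log_lines,
                 sprintf("threshold[%s] = %s", thr$image, thr$threshold),
                 sprintf("%d ROIs measured (%d flagged)", nrow(signals),
                         sum(signals$flagged)))

  no_objects <- nrow(signals) == 0
  if (no_objects)
    log_lines <- c(log_lines,
                   "no objects passed the area filter; group statistics skipped")

  case_summaries <- if (no_objects) data.frame() else stage("aggregate", {
    do.call(rbind, lapply(split(signals, signals$case_id), function(d)
      cbind(aggregate_case(d, d$case_id[1]),
            data.frame(group = d$group[1]))))
  })
  group_stats <- if (no_objects) data.frame() else stage("aggregate", {
    do.call(rbind, lapply(split(signals, signals$group), function(d)
      suppressMessages(aggregate_group(d, d$group[1]))))
  })

  # normality gate on the pooled proportions: expected to fail for the
  # bounded, skewed R column -> rank-based correlation path
  fdl_shapiro <- if (no_objects || nrow(signals) < 3 ||
                     diff(range(signals$R, na.rm = TRUE)) == 0) NULL else
    stage("stats", {
      r <- signals$R[!signals$flagged]
      shapiro_gate(r[seq_len(min(length(r), 5000L))])
    })

  # --- chromogenic arm ---
  chr <- stage("score", generate_chr_group_cohort(
    ranges = config$chr_ranges,
    n_cases_per_group = config$chr_cases_per_group,
    neurons_per_case = config$chr_neurons_per_case,
    seed = seeds$chr))
  chr_case_means <- stage("score", {
    cm <- case_mean_scores(chr$scores)
    merge(cm, chr$cases[c("case_id", "group", "stage", "region")],
          by = "case_id", sort = FALSE)
  })
  chr_shapiro <- stage("stats",
                       shapiro_gate(chr_case_means$mean_score))
  chr_ttests <- stage("stats", pairwise_ttests(chr_case_means))
  group_means <- vapply(.group_levels, function(g)
    group_mean_score(chr_case_means, g), numeric(1))

  # ANCOVA on a synthetic clinical table: covariates drawn around the
  # cohort's demographics, independent of score (null covariates)
  ancova_res <- stage("stats", {
    meta <- with_preserved_rng(seeds$chr + 1L, {
      n <- nrow(chr_case_means)
      data.frame(case_id = chr_case_means$case_id,
                 age = round(runif(n, 55, 85)),
                 final_mmse = round(runif(n, 0, 26)),
                 apoe_e4 = sample(0:2, n, replace = TRUE,
                                  prob = c(0.5, 0.4, 0.1)))
    })
    ancova_covariates(merge(chr_case_means, meta, by = "case_id",
                            sort = FALSE))
  })

  stats_report <- list(
    fdl = list(
      shapiro = fdl_shapiro,
      group_stats = if (no_objects) NULL else group_stats,
      note = if (no_objects) "no objects passed the area filter" else NULL),
    chr = list(shapiro = chr_shapiro, group_means = as.list(group_means),
               ttests = chr_ttests, ancova = ancova_res$table))

  paths <- list(signals = file.path(config$out_dir, "signals.csv"),
                case_summaries = file.path(config$out_dir,
                                           "case_summaries.csv"),
                group_stats = file.path(config$out_dir, "group_stats.csv"),
                scores = file.path(config$out_dir, "scores.csv"),
                chr_cases = file.path(config$out_dir, "chr_cases.csv"),
                stats = file.path(config$out_dir, "stats.json"),
                log = log_path)
  write_table(signals, paths$signals)
  if (!no_objects) {
    write_table(case_summaries, paths$case_summaries)
    write_table(group_stats, paths$group_stats)
  }
  write_table(chr$scores, paths$scores)
  write_table(chr_case_means, paths$chr_cases)
  jsonlite::write_json(stats_report, paths$stats, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  writeLines(log_lines, log_path)
  if (!quiet) message(sprintf("run_all: results in %s", config$out_dir))

  list(signals = signals, case_summaries = case_summaries,
       group_stats = group_stats, chr_scores = chr$scores,
       chr_cases = chr_case_means, chr_ttests = chr_ttests,
       ancova = ancova_res, stats = stats_report, paths = paths)
}
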