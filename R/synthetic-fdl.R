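#' Configuration for a synthetic two-channel slide
#'
#' Describes one virtual fluorescence field: bright, roughly circular
#' neuron-scale objects on a dark background. Each cell is a filled
#' disk with a per-cell red-signal fraction drawn from a truncated
#' normal on \[0, 1\] whose *mean* is `mean_red_fraction` (the location
#' parameter is solved for, so truncation does not bias the mean); the
#' green fraction is its complement, encoding the modelling assumption
#' that the summed red + green signal per cell is invariant. In-disk
#' pixel values are `background + fraction * total` (red) and
#' `background + (1 - fraction) * total` (green), plus optional
#' Gaussian read noise, rounded and clipped to the 8-bit range.
#'
#' Defaults emulate one 200x field: a 512 x 512 px frame with 40
#' non-overlapping somata of radius 12-20 px (area 450-1300 px, safely
#' above the 400 px object filter), near-saturating total intensity
#' (180-240 counts) and mild read noise over a near-black background
#' (2 counts, as after autofluorescence quenching). The background
#' matters: downstream densitometry deliberately performs no
#' background subtraction, so a bright pedestal would bias measured
#' fractions toward 0.5; at the default levels the bias is below
#' 0.01.
#'
#' @param mean_red_fraction Mean per-cell red fraction in \[0, 1\]; the
#'   group-level parameter (e.g. 0.946 for the NFT-spared control
#'   group, 0.215 for the most affected group).
#' @param image_height_px,image_width_px Frame size in pixels.
#' @param n_cells Number of cells to place.
#' @param cell_radius_px_range Length-2 integer range of disk radii
#'   (min >= 1).
#' @param red_fraction_sd SD (>= 0) of the per-cell red fraction before
#'   truncation to \[0, 1\].
#' @param total_intensity_range Length-2 integer range of per-cell
#'   total signal (red + green above background), in 8-bit counts.
#' @param background_level Background intensity, 8-bit counts.
#' @param noise_sd Gaussian pixel noise SD, 8-bit counts (0 disables).
#' @param min_gap_px Minimum empty margin between disk rims, pixels;
#'   keeps neighbouring cells from fusing into one connected component.
#' @param seed Integer RNG seed; the generator is deterministic given
#'   the full config.
#' @return An object of class `fdl_sim_config` (validated list).
#' @seealso [generate_fdl_image()], [fdl_group_configs()]
#' @export
fdl_sim_config <- function(mean_red_fraction,
                           image_height_px = 512L,
                           image_width_px = 512L,
                           n_cells = 40L,
                           cell_radius_px_range = c(12L, 20L),
                           red_fraction_sd = 0.1,
                           total_intensity_range = c(180L, 240L),
                           background_level = 2L,
                           noise_sd = 2,
                           min_gap_px = 3L,
                           seed = 1L) {
  cfg <- list(
    image_height_px = check_count(image_height_px, "image_height_px", 8L),
    image_width_px = check_count(image_width_px, "image_width_px", 8L),
    n_cells = check_count(n_cells, "n_cells", 0L),
    cell_radius_px_range = check_range(cell_radius_px_range,
                                       "cell_radius_px_range", 1L),
    mean_red_fraction = check_scalar_number(mean_red_fraction,
                                            "mean_red_fraction", 0, 1),
    red_fraction_sd = check_scalar_number(red_fraction_sd,
                                          "red_fraction_sd", 0),
    total_intensity_range = check_range(total_intensity_range,
                                        "total_intensity_range", 1L, 255L),
    background_level = check_count(background_level, "background_level", 0L),
    noise_sd = check_scalar_number(noise_sd, "noise_sd", 0),
    min_gap_px = check_count(min_gap_px, "min_gap_px", 0L),
    seed = check_count(seed, "seed"))
  if (cfg$background_level > 255L)
    stop_fq("'background_level' exceeds the 8-bit range")
  rmax <- cfg$cell_radius_px_range[2]
  if (2 * rmax + 2 > min(cfg$image_height_px, cfg$image_width_px))
    stop_fq("largest cell does not fit in the image")
  structure(cfg, class = "fdl_sim_config")
}

check_range <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2])
    stop_fq(sprintf("'%s' must be c(min, max) with min <= max", name))
  if (x[1] < lo || x[2] > hi)
    stop_fq(sprintf("'%s' must lie within [%s, %s]", name, lo, hi))
  as.integer(x)
}

# Mean of N(mu, sd) truncated to [0, 1]. For locations so far outside
# the interval that the truncation mass underflows, the mean tends to
# the near boundary; returning it keeps the root-finder's objective
# finite and monotone.
truncnorm_mean <- function(mu, sd) {
  a <- (0 - mu) / sd
  b <- (1 - mu) / sd
  z <- pnorm(b) - pnorm(a)
  if (!is.finite(z) || z < 1e-12) return(if (mu < 0.5) 0 else 1)
  m <- mu + sd * (dnorm(a) - dnorm(b)) / z
  min(max(m, 0), 1)
}

# Location parameter such that the [0,1]-truncated normal with the
# given sd has the requested mean. The truncated mean is increasing in
# mu and spans (0, 1) over the bracket below, so uniroot always has a
# sign change.
truncnorm_location <- function(target_mean, sd) {
  if (sd == 0) return(target_mean)
  eps <- 1e-9
  if (target_mean < eps || target_mean > 1 - eps)
    stop_fq("mean_red_fraction must be strictly inside (0, 1) when red_fraction_sd > 0")
  lo <- min(target_mean, 0) - 12 * sd
  hi <- max(target_mean, 1) + 12 * sd
  uniroot(function(mu) truncnorm_mean(mu, sd) - target_mean,
          interval = c(lo, hi), tol = 1e-12)$root
}

# Inverse-CDF sampling of the [0,1]-truncated normal: exact, no
# rejection loop.
rtruncnorm01 <- function(n, target_mean, sd) {
  if (sd == 0) return(rep(target_mean, n))
  mu <- truncnorm_location(target_mean, sd)
  lo <- pnorm((0 - mu) / sd)
  hi <- pnorm((1 - mu) / sd)
  mu + sd * qnorm(runif(n, lo, hi))
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate one synthetic two-channel slide with ground truth
#'
#' Places `n_cells` non-overlapping filled disks by rejection sampling
#' (at most 1000 attempts per cell), draws each cell's red fraction and
#' total intensity, renders both channels and returns the image
#' together with a per-cell ground-truth table — the oracle for
#' parameter-recovery benchmarks.
#'
#' @param config An [fdl_sim_config()].
#' @return A list with elements `image` (a [two_channel_image()]) and
#'   `ground_truth` (data frame: `cell`, `center_row`, `center_col`
#'   (1-based pixel coordinates), `radius_px`, `true_red_fraction`,
#'   `true_total_intensity`, `area_px`).
#' @examples
#' sim <- generate_fdl_image(fdl_sim_config(0.9, n_cells = 3, seed = 42))
#' sim$ground_truth
#' @export
generate_fdl_image <- function(config) {
  stopifnot(inherits(config, "fdl_sim_config"))
  with_preserved_rng(config$seed, generate_fdl_image_impl(config))
}

generate_fdl_image_impl <- function(config) {
  h <- config$image_height_px
  w <- config$image_width_px
  n <- config$n_cells
  bg <- config$background_level

  red <- matrix(as.numeric(bg), h, w)
  green <- matrix(as.numeric(bg), h, w)

  gt <- data.frame(cell = integer(0), center_row = integer(0),
                   center_col = integer(0), radius_px = integer(0),
                   true_red_fraction = numeric(0),
                   true_total_intensity = integer(0), area_px = integer(0))

  if (n > 0) {
    rr <- config$cell_radius_px_range
    radii <- if (rr[1] == rr[2]) rep(rr[1], n) else
      sample(rr[1]:rr[2], n, replace = TRUE)
    placed_r <- integer(0); placed_c <- integer(0); placed_rad <- integer(0)
    for (i in seq_len(n)) {
      r <- radii[i]
      ok <- FALSE
      for (try in seq_len(1000L)) {
        ci <- sample((r + 1L):(h - r), 1L)
        cj <- sample((r + 1L):(w - r), 1L)
        if (length(placed_r) == 0L ||
            all((placed_r - ci)^2 + (placed_c - cj)^2 >
                (placed_rad + r + config$min_gap_px)^2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop_fq(sprintf(
          "image too crowded: could not place cell %d of %d after 1000 attempts",
          i, n))
      placed_r <- c(placed_r, ci)
      placed_c <- c(placed_c, cj)
      placed_rad <- c(placed_rad, r)
    }

    fracs <- rtruncnorm01(n, config$mean_red_fraction, config$red_fraction_sd)
    tr <- config$total_intensity_range
    totals <- if (tr[1] == tr[2]) rep(tr[1], n) else
      sample(tr[1]:tr[2], n, replace = TRUE)

    areas <- integer(n)
    for (i in seq_len(n)) {
      px <- disk_pixels(placed_r[i], placed_c[i], placed_rad[i], h, w)
      areas[i] <- nrow(px)
      red[px] <- bg + fracs[i] * totals[i]
      green[px] <- bg + (1 - fracs[i]) * totals[i]
    }
    gt <- data.frame(cell = seq_len(n), center_row = placed_r,
                     center_col = placed_c, radius_px = placed_rad,
                     true_red_fraction = fracs,
                     true_total_intensity = totals, area_px = areas)
  }

  if (config$noise_sd > 0) {
    red <- red + rnorm(length(red), 0, config$noise_sd)
    green <- green + rnorm(length(green), 0, config$noise_sd)
  }
  red <- pmin(pmax(round(red), 0), 255)
  green <- pmin(pmax(round(green), 0), 255)
  storage.mode(red) <- "integer"
  storage.mode(green) <- "integer"
  list(image = two_channel_image(red, green), ground_truth = gt)
}

# (row, col) index matrix of the filled disk (ci, cj, radius r).
disk_pixels <- function(ci, cj, r, h, w) {
  ri <- max(1L, ci - r):min(h, ci + r)
  cjs <- max(1L, cj - r):min(w, cj + r)
  grid <- expand.grid(row = ri, col = cjs)
  keep <- (grid$row - ci)^2 + (grid$col - cj)^2 <= r^2
  as.matrix(grid[keep, , drop = FALSE])
}

#' Study-condition configs for the four experimental groups
#'
#' Returns one [fdl_sim_config()] per group with the group mean red
#' fractions 0.946 / 0.349 / 0.273 / 0.215 (early MFG, early aHPC,
#' late MFG, late aHPC) and the matching per-ROI red-fraction SDs
#' 0.087 / 0.233 / 0.237 / 0.159. Early-stage MFG is the NFT-spared
#' endogenous control, hence its near-pure red signal.
#'
#' @param seed Base seed; each group gets a distinct fixed offset.
#' @param ... Further arguments passed to [fdl_sim_config()] (e.g.
#'   `n_cells`, image size).
#' @return Named list of four `fdl_sim_config` objects, names from
#'   [group_levels()].
#' @export
fdl_group_configs <- function(seed = 1L, ...) {
  means <- c(early_MFG = 0.946, early_aHPC = 0.349,
             late_MFG = 0.273, late_aHPC = 0.215)
  sds <- c(early_MFG = 0.087, early_aHPC = 0.233,
           late_MFG = 0.237, late_aHPC = 0.159)
  cfgs <- lapply(seq_along(means), function(k) {
    fdl_sim_config(mean_red_fraction = means[[k]],
                   red_fraction_sd = sds[[k]],
                   seed = seed + 97L * k, ...)
  })
  names(cfgs) <- names(means)
  cfgs
}

#' Write a collection of synthetic slides to disk
#'
#' Renders `cases_per_group * images_per_case` slides for each group
#' config, writes the TIFFs (default as `_red.tif`/`_green.tif` pairs),
#' a pooled `ground_truth.csv` and a `manifest.csv` linking every image
#' to its case and group. Per-image seeds are derived from each group
#' config's seed by fixed offsets, so the collection is reproducible
#' and a same-seed rerun is byte-identical.
#'
#' @param configs Named list of [fdl_sim_config()] objects; names must
#'   be `stage_region` labels as in [group_levels()].
#' @param out_dir Output directory (created if needed).
#' @param cases_per_group,images_per_case Collection layout.
#' @param layout TIFF layout, `"pair"` (default) or `"stack"`.
#' @return Invisibly, the manifest data frame (with absolute paths
#'   resolved).
#' @export
generate_fdl_group_set <- function(configs, out_dir,
                                   cases_per_group = 1L,
                                   images_per_case = 1L,
                                   layout = c("pair", "stack")) {
  layout <- match.arg(layout)
  if (is.null(names(configs)) || !all(names(configs) %in% .group_levels))
    stop_fq("'configs' must be named with stage_region group labels")
  cases_per_group <- check_count(cases_per_group, "cases_per_group", 1L)
  images_per_case <- check_count(images_per_case, "images_per_case", 1L)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_fq(sprintf("cannot create output directory '%s'", out_dir))

  man <- list(); gts <- list(); k <- 0L
  for (g in names(configs)) {
    cfg <- configs[[g]]
    stopifnot(inherits(cfg, "fdl_sim_config"))
    parts <- strsplit(g, "_", fixed = TRUE)[[1]]
    for (case in seq_len(cases_per_group)) {
      case_id <- sprintf("%s_case%02d", g, case)
      for (im in seq_len(images_per_case)) {
        k <- k + 1L
        icfg <- cfg
        icfg$seed <- cfg$seed + 1009L * (case - 1L) + 31L * (im - 1L)
        sim <- generate_fdl_image(icfg)
        stem <- sprintf("%s_img%02d", case_id, im)
        if (layout == "stack") {
          fname <- paste0(stem, ".tif")
          write_two_channel(sim$image, file.path(out_dir, fname),
                            layout = "stack")
        } else {
          fname <- stem
          write_two_channel(sim$image, file.path(out_dir, stem),
                            layout = "pair")
        }
        man[[k]] <- data.frame(image_path = fname, case_id = case_id,
                               region = parts[2], stage = parts[1])
        if (nrow(sim$ground_truth)) {
          gt <- sim$ground_truth
          gt <- cbind(data.frame(image_path = fname, case_id = case_id,
                                 group = g), gt)
          gts[[length(gts) + 1L]] <- gt
        }
      }
    }
  }
  manifest <- do.call(rbind, man)
  write_table(manifest, file.path(out_dir, "manifest.csv"))
  gt_all <- if (length(gts)) do.call(rbind, gts) else
    data.frame(image_path = character(0), case_id = character(0),
               group = character(0), cell = integer(0))
  write_table(gt_all, file.path(out_dir, "ground_truth.csv"))
  invisible(read_manifest(file.path(out_dir, "manifest.csv")))
}
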