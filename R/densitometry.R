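#' Redirected raw integrated density of one ROI
#'
#' The object was segmented on the merged gray image; its intensity is
#' measured back on the original channel rasters ("redirected"
#' measurement): the raw integrated density of a channel is the sum of
#' that channel's pixel counts over the ROI's pixel set (equivalently
#' area times mean intensity).
#'
#' @param obj One ROI from [extract_objects()].
#' @param img The source [two_channel_image()].
#' @return One-row data frame: `label_id`, `area_px`, `rid_red`,
#'   `rid_green`.
#' @export
measure_roi <- function(obj, img) {
  stopifnot(is_two_channel_image(img))
  px <- obj$pixels
  if (any(px[, 1] < 1L | px[, 1] > nrow(img$red) |
          px[, 2] < 1L | px[, 2] > ncol(img$red)))
    stop_fq("ROI pixel outside image bounds")
  data.frame(label_id = obj$label_id, area_px = obj$area_px,
             rid_red = sum(as.numeric(img$red[px])),
             rid_green = sum(as.numeric(img$green[px])))
}

#' Measure every ROI of an image
#'
#' @param objs ROI list from [extract_objects()].
#' @param img The source [two_channel_image()].
#' @return Data frame, one row per ROI (empty with the right columns
#'   when no objects pass the filter).
#' @export
measure_objects <- function(objs, img) {
  if (length(objs) == 0)
    return(data.frame(label_id = integer(0), area_px = integer(0),
                      rid_red = numeric(0), rid_green = numeric(0)))
  do.call(rbind, lapply(objs, measure_roi, img = img))
}

#' Percentage-of-sum signals per ROI
#'
#' Expresses each ROI's two raw integrated densities as proportions of
#' their sum: `R = red / (red + green)`, `G = green / (red + green)`,
#' so `R + G = 1` — the construction under which the red and green
#' columns of any group are exact complements. ROIs with zero summed
#' density have no defined proportion; they are flagged (not silently
#' dropped) and excluded from statistics downstream.
#'
#' @param measurements Data frame from [measure_objects()] (columns
#'   `rid_red`, `rid_green`).
#' @return The input with columns `R`, `G`, `X` (see [x_transform()])
#'   and logical `flagged` appended; `R`, `G`, `X` are `NA` for
#'   flagged rows.
#' @export
percent_of_sum <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("rid_red", "rid_green") %in% names(measurements)))
  s <- measurements$rid_red + measurements$rid_green
  flagged <- s == 0
  R <- ifelse(flagged, NA_real_, measurements$rid_red / s)
  G <- ifelse(flagged, NA_real_, measurements$rid_green / s)
  out <- measurements
  out$R <- R
  out$G <- G
  out$X <- ifelse(flagged, NA_real_, (R - G) / (R + G))
  out$flagged <- flagged
  if (any(flagged))
    message(sprintf("percent_of_sum: %d ROI(s) with zero summed density flagged",
                    sum(flagged)))
  out
}

#' Normalized difference index X
#'
#' `X = (R - G) / (R + G)`, mapping the red/green balance onto
#' \[-1, +1\]: +1 means 100% red (LMTK2) signal, -1 means 100% green
#' (phospho-tau) signal, 0 an even split. When `R` and `G` are already
#' proportions of their sum (`R + G = 1`) this reduces to `R - G`.
#'
#' @param R,G Nonnegative signal values (vectorized).
#' @return `X` in \[-1, +1\].
#' @examples
#' x_transform(0.946, 0.054)  # 0.892, red-dominated control group
#' x_transform(0.215, 0.785)  # -0.570, phospho-tau-dominated group
#' @export
x_transform <- function(R, G) {
  if (length(R) != length(G)) stop_fq("'R' and 'G' lengths differ")
  if (anyNA(R) || anyNA(G)) stop_fq("'R'/'G' must not contain NA")
  if (any(R < 0) || any(G < 0)) stop_fq("'R' and 'G' must be nonnegative")
  if (any(R + G == 0)) stop_fq("X undefined where R + G = 0")
  (R - G) / (R + G)
}

#' Case-level aggregation of ROI signals
#'
#' Arithmetic means of the unflagged per-ROI signals of one case.
#'
#' @param signals Data frame with columns `R`, `G`, `X`, `flagged`.
#' @param case_id Case identifier (for reporting).
#' @return One-row data frame: `case_id`, `mean_R`, `mean_G`,
#'   `mean_X`, `n_rois`.
#' @export
aggregate_case <- function(signals, case_id) {
  ok <- signals[!signals$flagged, , drop = FALSE]
  if (nrow(ok) == 0)
    stop_fq(sprintf("case '%s' has no measurable (unflagged) ROI", case_id))
  data.frame(case_id = case_id, mean_R = mean(ok$R), mean_G = mean(ok$G),
             mean_X = mean(ok$X), n_rois = nrow(ok))
}

#' Group-level aggregation and correlation
#'
#' Pools the per-ROI signals of one experimental group: Spearman rank
#' correlation (midranks) between the R and G columns via
#' [spearman_cor()], means and SDs of R, G and X, and the standard
#' error `sd_R / sqrt(n_pairs)`. Because `G = 1 - R` for every
#' unflagged ROI, the correlation is -1 by construction whenever at
#' least two distinct R values are present — a property of the
#' percentage-of-sum transform, not an empirical finding.
#'
#' @param signals Data frame of per-ROI signals (columns `R`, `G`,
#'   `X`, `flagged`) for one group.
#' @param group Group label.
#' @return One-row data frame: `group`, `spearman_rho`, `spearman_p`,
#'   `mean_R`, `mean_G`, `mean_X`, `sd_R`, `sd_G`, `sd_X`, `se_R`,
#'   `n_pairs`. With fewer than 2 ROIs or all R identical the
#'   correlation is degenerate and reported as `NA` (with a message).
#' @export
aggregate_group <- function(signals, group) {
  ok <- signals[!signals$flagged, , drop = FALSE]
  n <- nrow(ok)
  rho <- NA_real_; pval <- NA_real_
  if (n >= 2 && length(unique(ok$R)) >= 2) {
    ct <- spearman_cor(ok$R, ok$G)
    rho <- ct$rho
    pval <- ct$p_value
  } else {
    message(sprintf(
      "group '%s': correlation undefined (%d ROIs, %d distinct R values)",
      group, n, length(unique(ok$R))))
  }
  data.frame(group = group, spearman_rho = rho, spearman_p = pval,
             mean_R = if (n) mean(ok$R) else NA_real_,
             mean_G = if (n) mean(ok$G) else NA_real_,
             mean_X = if (n) mean(ok$X) else NA_real_,
             sd_R = if (n > 1) sd(ok$R) else NA_real_,
             sd_G = if (n > 1) sd(ok$G) else NA_real_,
             sd_X = if (n > 1) sd(ok$X) else NA_real_,
             se_R = if (n > 1) sd(ok$R) / sqrt(n) else NA_real_,
             n_pairs = n)
}

#' Quantify all images of a manifest
#'
#' Runs merge, threshold, object extraction and redirected densitometry
#' over every image of a slide collection, producing the per-ROI signal
#' table that feeds case- and group-level analysis.
#'
#' @param manifest Data frame from [read_manifest()].
#' @param min_area_px Strict area filter (default 400).
#' @param connectivity 4 or 8 (default 8).
#' @param threshold `"otsu"` or a fixed integer threshold in 0:255.
#' @param merge_rule Passed to [merge_to_gray()].
#' @return Data frame with one row per ROI: `image`, `case_id`,
#'   `group`, `label_id`, `area_px`, `rid_red`, `rid_green`, `R`, `G`,
#'   `X`, `flagged`, plus attribute `thresholds` (data frame of the
#'   threshold chosen per image).
#' @export
quantify_manifest <- function(manifest, min_area_px = 400L,
                              connectivity = 8L, threshold = "otsu",
                              merge_rule = "mean2") {
  rows <- list(); thrs <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- load_manifest_image(row)
    gray <- merge_to_gray(img, rule = merge_rule)
    mask <- if (identical(threshold, "otsu"))
      threshold_mask(gray, "otsu")
    else
      threshold_mask(gray, "fixed", fixed_value = threshold)
    thrs[i] <- attr(mask, "threshold")
    objs <- extract_objects(mask, min_area_px = min_area_px,
                            connectivity = connectivity)
    meas <- measure_objects(objs, img)
    sig <- suppressMessages(percent_of_sum(meas))
    if (nrow(sig))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(image = row$image_path, case_id = row$case_id,
                   group = row$group), sig)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image = character(0), case_id = character(0),
               group = character(0), label_id = integer(0),
               area_px = integer(0), rid_red = numeric(0),
               rid_green = numeric(0), R = numeric(0), G = numeric(0),
               X = numeric(0), flagged = logical(0))
  attr(out, "thresholds") <- data.frame(image = manifest$image_path,
                                        threshold = thrs)
  out
}
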