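#' Merge the two channels into an 8-bit gray image
#'
#' Segmentation operates on a single merged intensity image while
#' densitometry is later redirected to the original channels. The
#' default rule is the unweighted mean of the two channels,
#' `round((red + green) / 2)` with half-up rounding, which keeps the
#' merged scale comparable to a single channel. `"mean3"` instead
#' divides by 3, mimicking an RGB-to-gray average in which the absent
#' blue channel contributes zero.
#'
#' @param img A [two_channel_image()].
#' @param rule `"mean2"` (default) or `"mean3"`.
#' @return Integer matrix in \[0, 255\].
#' @export
merge_to_gray <- function(img, rule = c("mean2", "mean3")) {
  stopifnot(is_two_channel_image(img))
  rule <- match.arg(rule)
  den <- if (rule == "mean2") 2 else 3
  g <- floor((as.numeric(img$red) + as.numeric(img$green)) / den + 0.5)
  g <- pmin(pmax(g, 0), 255)
  gray <- matrix(as.integer(g), nrow(img$red), ncol(img$red))
  gray
}

#' Otsu's automatic threshold
#'
#' Exhaustive maximization of the between-class variance over all 255
#' candidate cut points of the 8-bit histogram; the lowest maximizer is
#' returned on ties. Pixels strictly above the returned value are
#' foreground.
#'
#' @param gray Integer matrix in \[0, 255\].
#' @return The threshold value (integer in 0:254).
#' @export
otsu_threshold <- function(gray) {
  check_gray(gray)
  if (min(gray) == max(gray))
    stop_fq("degenerate image: all pixels equal, Otsu threshold undefined")
  counts <- tabulate(as.vector(gray) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)[1:255]               # P(class <= t), t = 0..254
  mu0 <- cumsum(p * levels)[1:255]     # first moment up to t
  mu_t <- sum(p * levels)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  which.max(bcv) - 1L
}

check_gray <- function(gray) {
  if (!is.matrix(gray) || !is.numeric(gray) || anyNA(gray) ||
      any(gray < 0 | gray > 255) || any(gray != round(gray)))
    stop_fq("gray image must be an integer matrix in [0, 255]")
  invisible(gray)
}

#' Threshold a gray image into a binary mask
#'
#' @param gray Integer matrix in \[0, 255\].
#' @param method `"otsu"` (automatic, see [otsu_threshold()]) or
#'   `"fixed"`.
#' @param fixed_value Threshold in 0:255; required iff
#'   `method = "fixed"`. Pixels strictly above it are foreground.
#' @return Logical matrix with attribute `threshold`, the value used
#'   (so the choice can be logged alongside results).
#' @export
threshold_mask <- function(gray, method = c("otsu", "fixed"),
                           fixed_value = NULL) {
  check_gray(gray)
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_value))
      stop_fq("'fixed_value' is required when method = \"fixed\"")
    thr <- check_count(fixed_value, "fixed_value", 0L)
    if (thr > 255L) stop_fq("'fixed_value' must be in 0:255")
  } else {
    if (!is.null(fixed_value))
      stop_fq("'fixed_value' is only meaningful with method = \"fixed\"")
    thr <- otsu_threshold(gray)
  }
  mask <- gray > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Extract size-filtered connected components
#'
#' Labels the foreground of a binary mask (4- or 8-connectivity) and
#' keeps only components whose pixel area is *strictly greater* than
#' `min_area_px` — the particle filter applied to neuron-scale objects.
#' Component labels follow the row-major scan order of each
#' component's first pixel.
#'
#' @param mask Logical matrix (e.g. from [threshold_mask()]).
#' @param min_area_px Strict lower area bound in pixels (default 400).
#' @param connectivity 4 or 8 (default 8).
#' @return List of ROI objects, each a list with `label_id`, `area_px`
#'   and `pixels` (two-column `[row, col]` index matrix, 1-based). The
#'   full label raster (all components, before the area filter) is
#'   attached as attribute `labels`, and the number of discarded
#'   small components as attribute `n_discarded`.
#' @export
extract_objects <- function(mask, min_area_px = 400L, connectivity = 8L) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_fq("'mask' must be a logical matrix")
  if (anyNA(mask)) stop_fq("'mask' contains NA")
  min_area_px <- check_count(min_area_px, "min_area_px", 0L)
  if (!connectivity %in% c(4L, 8L))
    stop_fq("'connectivity' must be 4 or 8")
  labels <- label_components_cpp(mask, as.integer(connectivity))
  n_comp <- max(labels)
  objs <- list()
  if (n_comp > 0) {
    areas <- tabulate(labels[labels > 0L], nbins = n_comp)
    keep <- which(areas > min_area_px)
    # one pass over foreground pixels, grouped by label
    idx <- which(labels > 0L)
    by_label <- split(idx, labels[idx])
    nr <- nrow(mask)
    new_id <- 0L
    for (lab in keep) {
      new_id <- new_id + 1L
      lin <- by_label[[as.character(lab)]]
      px <- cbind(row = ((lin - 1L) %% nr) + 1L,
                  col = ((lin - 1L) %/% nr) + 1L)
      objs[[new_id]] <- list(label_id = new_id, area_px = areas[lab],
                             pixels = px)
    }
    attr(objs, "n_discarded") <- n_comp - length(keep)
  } else {
    attr(objs, "n_discarded") <- 0L
  }
  attr(objs, "labels") <- labels
  objs
}
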