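#' Read a two-channel image from TIFF
#'
#' Accepts either a single planar multi-sample TIFF or a pair of
#' single-channel files. Inputs must be 8- or 16-bit integer TIFFs;
#' 16-bit data are rescaled to 8-bit by integer division by 257
#' (full-range linear mapping, the behavior of common viewers).
#' Channel order is never guessed from content: for a single file the
#' `channel_order` argument states which sample is which, and a file
#' with more than two samples requires explicit `channels` indices.
#'
#' @param path Path to a multi-sample TIFF, or (with `green` given) to
#'   the red-channel file of a pair.
#' @param green Optional path to the green-channel file when channels
#'   are stored as separate single-channel TIFFs.
#' @param channel_order For single-file input: character vector naming
#'   the first and second retained sample; default `c("red", "green")`,
#'   the order written by [write_two_channel()].
#' @param channels For files with more than two samples: integer vector
#'   of length 2 selecting the samples to use (in `channel_order`
#'   order). Mandatory in that case.
#' @return A [two_channel_image()].
#' @export
read_two_channel <- function(path, green = NULL,
                             channel_order = c("red", "green"),
                             channels = NULL) {
  if (!identical(sort(channel_order), c("green", "red")))
    stop_fq("'channel_order' must be a permutation of c(\"red\", \"green\")")
  if (!is.null(green)) {
    red_m <- read_channel_tiff(path)
    green_m <- read_channel_tiff(green)
    if (!identical(dim(red_m), dim(green_m)))
      stop_fq(sprintf(
        "shape mismatch between pair members: %s is %dx%d, %s is %dx%d",
        path, nrow(red_m), ncol(red_m), green, nrow(green_m), ncol(green_m)))
    return(two_channel_image(red_m, green_m))
  }
  arr <- read_raw_tiff(path)
  if (length(dim(arr)) == 2L)
    stop_fq(sprintf("'%s' has a single channel; supply the pair via 'green='",
                    path))
  nch <- dim(arr)[3]
  if (nch > 2L) {
    if (is.null(channels))
      stop_fq(sprintf(
        "'%s' has %d channels; select two with 'channels = c(i, j)'",
        path, nch))
    if (length(channels) != 2L || any(channels < 1L | channels > nch))
      stop_fq("'channels' must be two valid sample indices")
    arr <- arr[, , channels, drop = FALSE]
  }
  chans <- list(arr[, , 1L], arr[, , 2L])
  names(chans) <- channel_order
  two_channel_image(chans$red, chans$green)
}

read_channel_tiff <- function(path) {
  arr <- read_raw_tiff(path)
  if (length(dim(arr)) != 2L)
    stop_fq(sprintf("'%s' is not single-channel", path))
  arr
}

# Decode one TIFF to integer 8-bit counts, preserving array layout.
read_raw_tiff <- function(path) {
  if (!file.exists(path)) stop_fq(sprintf("file not found: %s", path))
  arr <- suppressWarnings(tiff::readTIFF(path, info = TRUE))
  bits <- attr(arr, "bits.per.sample")
  if (!bits %in% c(8L, 16L))
    stop_fq(sprintf("'%s' is %d-bit; only 8- and 16-bit TIFF supported",
                    path, bits))
  counts <- round(arr * (2^bits - 1))
  if (bits == 16L) counts <- counts %/% 257
  storage.mode(counts) <- "integer"
  attributes(counts) <- list(dim = dim(arr))
  counts
}

#' Write a two-channel image to TIFF
#'
#' @param img A [two_channel_image()].
#' @param path Output path. With `layout = "pair"` this is a stem: the
#'   files written are `<stem>_red.tif` and `<stem>_green.tif` (any
#'   `.tif`/`.tiff` extension on `path` is stripped first). With
#'   `layout = "stack"` a single planar two-sample file is written with
#'   red as sample 1 and green as sample 2.
#' @param layout `"pair"` (default) or `"stack"`.
#' @return Invisibly, the paths written.
#' @export
write_two_channel <- function(img, path, layout = c("pair", "stack")) {
  stopifnot(is_two_channel_image(img))
  layout <- match.arg(layout)
  if (layout == "stack") {
    arr <- array(0, dim = c(dim(img$red), 2L))
    arr[, , 1] <- img$red
    arr[, , 2] <- img$green
    tiff::writeTIFF(arr / 255, path, bits.per.sample = 8L,
                    compression = "none")
    return(invisible(path))
  }
  stem <- sub("\\.tiff?$", "", path)
  paths <- pair_paths(stem)
  tiff::writeTIFF(img$red / 255, paths[1], bits.per.sample = 8L,
                  compression = "none")
  tiff::writeTIFF(img$green / 255, paths[2], bits.per.sample = 8L,
                  compression = "none")
  invisible(paths)
}

pair_paths <- function(stem) {
  c(paste0(stem, "_red.tif"), paste0(stem, "_green.tif"))
}

#' Write a results table as CSV
#'
#' UTF-8 CSV with a header row and `.` as decimal separator; floats
#' survive a round-trip to at least 12 significant digits. An empty
#' data frame yields a header-only file.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  con <- tryCatch(file(path, open = "wb", encoding = "UTF-8"),
                  error = function(e)
                    stop_fq(sprintf("cannot write '%s': %s", path,
                                    conditionMessage(e))))
  on.exit(close(con))
  write.csv(rows, con, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a results table written by [write_table()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop_fq(sprintf("file not found: %s", path))
  read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Read and validate a slide manifest
#'
#' A manifest links each image to its case and experimental group. It
#' is a CSV with columns `image_path`, `case_id`, `region` (`MFG` or
#' `aHPC`) and `stage` (`early` or `late`); `(region, stage)` defines
#' the four groups of the study design. `image_path` is either a file
#' (planar two-channel TIFF) or a stem whose `_red.tif`/`_green.tif`
#' pair exists; paths are resolved relative to the manifest's
#' directory.
#'
#' @param path Manifest CSV path.
#' @param check_paths Verify that every referenced image exists
#'   (default `TRUE`).
#' @return Data frame with the manifest columns plus `group`
#'   (stage_region label) and `layout` (`"stack"` or `"pair"`).
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  man <- read_table(path)
  need <- c("image_path", "case_id", "region", "stage")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop_fq(sprintf("manifest lacks column(s): %s",
                    paste(miss, collapse = ", ")))
  if (!all(man$region %in% c("MFG", "aHPC")))
    stop_fq("manifest 'region' values must be 'MFG' or 'aHPC'")
  if (!all(man$stage %in% c("early", "late")))
    stop_fq("manifest 'stage' values must be 'early' or 'late'")
  man$group <- group_label(man$stage, man$region)
  base <- dirname(path)
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", man$image_path), man$image_path,
                file.path(base, man$image_path))
  man$resolved_path <- abs
  man$layout <- ifelse(file.exists(abs), "stack", "pair")
  if (check_paths) {
    ok <- file.exists(abs) |
      (file.exists(pair_paths(abs)[1]) & file.exists(pair_paths(abs)[2]))
    if (!all(ok))
      stop_fq(sprintf("manifest references missing image(s): %s",
                      paste(man$image_path[!ok], collapse = ", ")))
  }
  man
}

# Load the image behind one manifest row.
load_manifest_image <- function(row) {
  if (row$layout == "stack") {
    read_two_channel(row$resolved_path)
  } else {
    p <- pair_paths(row$resolved_path)
    read_two_channel(p[1], green = p[2])
  }
}
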