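#' Two-channel fluorescence image
#'
#' Container for a pair of equally shaped 8-bit intensity rasters: the
#' red channel carries the LMTK2 immunolabelling signal, the green
#' channel the phospho-tau (AT8) signal. Pixel values are integer counts
#' in \[0, 255\]; matrices are indexed `[row, col]` starting at 1, as
#' usual in R.
#'
#' @param red,green Integer matrices of identical dimensions with values
#'   in \[0, 255\].
#' @return An object of class `two_channel_image`: a list with elements
#'   `red` and `green`.
#' @examples
#' img <- two_channel_image(matrix(200L, 4, 4), matrix(20L, 4, 4))
#' dim(img$red)
#' @export
two_channel_image <- function(red, green) {
  red <- check_channel(red, "red")
  green <- check_channel(green, "green")
  if (!identical(dim(red), dim(green)))
    stop_fq(sprintf("channel shapes differ: red %dx%d vs green %dx%d",
                    nrow(red), ncol(red), nrow(green), ncol(green)))
  structure(list(red = red, green = green), class = "two_channel_image")
}

check_channel <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_fq(sprintf("'%s' must be a numeric matrix", name))
  if (anyNA(x)) stop_fq(sprintf("'%s' contains NA", name))
  if (any(x < 0 | x > 255))
    stop_fq(sprintf("'%s' has values outside [0, 255]", name))
  if (any(x != round(x)))
    stop_fq(sprintf("'%s' must hold integer counts", name))
  storage.mode(x) <- "integer"
  x
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat(sprintf("<two_channel_image> %d x %d px, 8-bit\n",
              nrow(x$red), ncol(x$red)))
  cat(sprintf("  red:   range [%d, %d]\n", min(x$red), max(x$red)))
  cat(sprintf("  green: range [%d, %d]\n", min(x$green), max(x$green)))
  invisible(x)
}

#' @export
dim.two_channel_image <- function(x) dim(x$red)

is_two_channel_image <- function(x) inherits(x, "two_channel_image")
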