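#' Single-channel intensity image
#'
#' The basic container of the package: an H x W matrix of intensities on
#' \[0, 1\] plus the gray-level count used by the histogram metrics and a
#' modality tag. CT and MR slices, and the fused results, are all carried
#' in this form; the network normalizes nothing further.
#'
#' @param pixels Numeric matrix, all values finite and in \[0, 1\],
#'   at least 8 x 8.
#' @param levels Integer number of gray levels assumed by the histogram
#'   metrics (256 for 8-bit sources, 65536 for 16-bit).
#' @param source_tag One of `"CT"`, `"MR"`, `"FUSED"`, `"OTHER"`.
#'
#' @return An object of class `fusion_image`: the pixel matrix with
#'   `levels` and `source_tag` attributes.
#' @examples
#' img <- fusion_image(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
fusion_image <- function(pixels, levels = 256L,
                         source_tag = c("OTHER", "CT", "MR", "FUSED")) {
  source_tag <- match.arg(source_tag)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  img <- structure(pixels,
                   levels = as.integer(levels),
                   source_tag = source_tag,
                   class = c("fusion_image", "matrix", "array"))
  validate_image(img)
  img
}

#' Validate the intensity-image invariants
#'
#' Checks finiteness, the \[0, 1\] intensity range and the minimum 8 x 8
#' size. Called by every operation that consumes an image.
#'
#' @param img A `fusion_image` or plain numeric matrix.
#' @return `img`, invisibly; errors if any invariant fails.
#' @export
validate_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix")
  if (!all(is.finite(img)))
    stop("image contains non-finite pixels")
  if (min(img) < 0 || max(img) > 1)
    stop("image intensities must lie in [0, 1]")
  if (nrow(img) < 8 || ncol(img) < 8)
    stop("image must be at least 8 x 8")
  invisible(img)
}

# Coerce matrices / fusion_images to a bare double matrix.
as_pixel_matrix <- function(img) {
  x <- unclass(img)
  attr(x, "levels") <- NULL
  attr(x, "source_tag") <- NULL
  as.matrix(x)
}

image_levels <- function(img) attr(img, "levels") %||% 256L

#' @export
print.fusion_image <- function(x, ...) {
  cat(sprintf("<fusion_image %dx%d, %s, %d gray levels, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), attr(x, "source_tag") %||% "OTHER",
              image_levels(x), min(x), max(x)))
  invisible(x)
}
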