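# Readers and writers for the grayscale formats the tool consumes:
# PNG and TIFF (8/16-bit) plus single-slice access into NIfTI volumes,
# and the CSV manifest tying CT/MR(/fused) files together.

#' Read a grayscale image
#'
#' Supports 8/16-bit grayscale PNG and TIFF and NIfTI volumes with a
#' slice selector (`"vol.nii.gz#12"` reads axial slice 12). Intensities
#' are scaled to \[0, 1\] by the format maximum (NIfTI slices, which have
#' no format maximum, are min-max scaled); the source bit depth is
#' recorded in the `levels` attribute. RGB inputs are converted to
#' luminance with a warning.
#'
#' @param path File path, optionally with a `#z` NIfTI slice suffix.
#' @param source_tag Modality tag stored on the result.
#' @return A `fusion_image`.
#' @export
read_image <- function(path, source_tag = "OTHER") {
  slice <- NULL
  if (grepl("#[0-9]+$", path)) {
    slice <- as.integer(sub(".*#", "", path))
    path <- sub("#[0-9]+$", "", path)
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    depth <- attr(x, "info")$bit.depth %||% 8L
    x <- collapse_rgb(x, path)
    fusion_image(x, levels = 2L^depth, source_tag = source_tag)
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(x, "bits.per.sample") %||% 8L
    x <- collapse_rgb(x, path)
    fusion_image(x, levels = 2L^depth, source_tag = source_tag)
  } else if (ext == "nii") {
    if (is.null(slice))
      stop(sprintf("NIfTI input needs a slice selector, e.g. %s#1", path))
    vol <- RNifti::readNifti(path)
    if (length(dim(vol)) < 3) stop(sprintf("not a 3-d NIfTI volume: %s", path))
    if (slice < 1 || slice > dim(vol)[3])
      stop(sprintf("slice %d out of range for %s", slice, path))
    x <- vol[, , slice]
    rng <- range(x)
    x <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x * 0
    fusion_image(x, levels = 256L, source_tag = source_tag)
  } else {
    stop(sprintf("unsupported image format: %s", path))
  }
}

collapse_rgb <- function(x, path) {
  if (length(dim(x)) == 3) {
    if (dim(x)[3] >= 3) {
      warning(sprintf("RGB input %s converted to luminance", path))
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    } else x <- x[, , 1]
  }
  x
}

#' Write a grayscale image
#'
#' Quantizes \[0, 1\] intensities to the target integer range by
#' round-half-away-from-zero and writes a lossless file: PNG at 8 bits,
#' TIFF at 8 or 16 bits (chosen by extension and `bit_depth`).
#'
#' @param img `fusion_image` or matrix in \[0, 1\].
#' @param path Destination ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth 8 or 16 (16 requires TIFF).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 8L) {
  x <- as_pixel_matrix_or_array(img)
  stopifnot(bit_depth %in% c(8L, 16L))
  maxv <- 2^bit_depth - 1
  q <- floor(pmin(pmax(x, 0), 1) * maxv + 0.5)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    if (bit_depth != 8L) stop("PNG output is written at 8 bits; use TIFF for 16")
    png::writePNG(q / maxv, path)
  } else if (ext %in% c("tif", "tiff")) {
    ok <- tiff::writeTIFF(q / maxv, path, bits.per.sample = bit_depth,
                          compression = "none")
    if (!ok) stop(sprintf("failed to write %s", path))
  } else {
    stop(sprintf("unsupported output format: %s", path))
  }
  invisible(path)
}

#' Read a fusion manifest
#'
#' A manifest is a CSV with columns `ct_path`, `mr_path` and optionally
#' `fused_path` and `label_path`; relative paths are resolved against the
#' manifest's directory.
#'
#' @param path Manifest CSV.
#' @return Data frame with resolved paths; class `fusion_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ct_path", "mr_path") %in% names(df)))
    stop("manifest must have ct_path and mr_path columns")
  root <- dirname(normalizePath(path))
  for (col in intersect(c("ct_path", "mr_path", "fused_path", "label_path"),
                        names(df))) {
    rel <- !grepl("^(/|[A-Za-z]:)", df[[col]]) & nzchar(df[[col]])
    df[[col]][rel] <- file.path(root, df[[col]][rel])
  }
  structure(df, class = c("fusion_manifest", "data.frame"), root = root)
}

#' Validate a manifest
#'
#' Checks that every referenced file exists and that the images of each
#' row share dimensions.
#'
#' @param manifest From [read_manifest()].
#' @return The manifest, invisibly; errors on the first violation.
#' @export
validate_manifest <- function(manifest) {
  for (r in seq_len(nrow(manifest))) {
    paths <- c(manifest$ct_path[r], manifest$mr_path[r],
               manifest$fused_path[r])
    paths <- paths[!is.na(paths) & nzchar(paths)]
    for (p in paths)
      if (!file.exists(sub("#[0-9]+$", "", p)))
        stop(sprintf("manifest row %d: missing file %s", r, p))
    dims <- lapply(paths, function(p) dim(read_image(p)))
    if (length(unique(dims)) > 1)
      stop(sprintf("manifest row %d: image dimensions differ", r))
  }
  invisible(manifest)
}

#' Merge run settings from defaults, a config file and CLI flags
#'
#' Later sources win: package defaults, then a YAML `key: value` file,
#' then explicit flags. Each setting's provenance (`default`, `file` or
#' `flag`) is recorded in the `provenance` attribute.
#'
#' @param file Optional YAML config path.
#' @param flags Named list of explicit overrides.
#' @return Named list of settings, class `run_config`.
#' @export
run_config <- function(file = NULL, flags = list()) {
  defaults <- list(strategy = "mean_attention", weight_mode = "l1",
                   local_window = NULL, psnr_peak = "fused_max",
                   mi_mode = "fusion_standard", levels = 256L, seed = 0L)
  prov <- stats::setNames(rep("default", length(defaults)), names(defaults))
  cfg <- defaults
  if (!is.null(file)) {
    if (!file.exists(file)) stop(sprintf("config file not found: %s", file))
    fv <- yaml::read_yaml(file)
    for (nm in names(fv)) { cfg[[nm]] <- fv[[nm]]; prov[nm] <- "file" }
  }
  for (nm in names(flags)) {
    if (!is.null(flags[[nm]])) { cfg[[nm]] <- flags[[nm]]; prov[nm] <- "flag" }
  }
  structure(cfg, provenance = prov, class = "run_config")
}
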