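#' RGB image container
#'
#' Wraps an H x W x 3 array of 8-bit channel intensities together with its
#' provenance: a sample identifier, the cultivar it came from, and its class
#' label (`"malting"`, `"naked"`, or `NA` for unlabelled images).
#'
#' @param pixels numeric or integer array of dimension H x W x 3 with values
#'   in `[0, 255]`. Images smaller than 8 x 8 are rejected: they cannot
#'   survive two rounds of quartering into meaningful tiles.
#' @param sample_id character scalar identifying the sample.
#' @param cultivar_id character scalar identifying the cultivar (subject).
#' @param label class label, one of `"malting"`, `"naked"` or `NA`.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, sample_id = "sample", cultivar_id = NA_character_,
                      label = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  d <- dim(pixels)
  if (d[1] < 8L || d[2] < 8L)
    stop(sprintf("image '%s' is %dx%d; at least 8x8 is required", sample_id, d[1], d[2]),
         call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop(sprintf("image '%s' has channel values outside [0, 255]", sample_id),
         call. = FALSE)
  if (!is.na(label) && !label %in% c("malting", "naked"))
    stop("label must be 'malting', 'naked' or NA", call. = FALSE)
  structure(
    list(pixels = pixels, sample_id = as.character(sample_id),
         cultivar_id = as.character(cultivar_id), label = label),
    class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %s  %d x %d  cultivar=%s label=%s\n",
              x$sample_id, d[1], d[2], x$cultivar_id, x$label))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Read an image file into an `rgb_image`
#'
#' PNG and JPEG rasters are supported. Greyscale and alpha-carrying files are
#' promoted/truncated to plain 3-channel RGB.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @param sample_id,cultivar_id,label provenance; `sample_id` defaults to the
#'   file name without extension.
#' @return an `rgb_image`.
#' @export
read_image <- function(path, sample_id = NULL, cultivar_id = NA_character_,
                       label = NA_character_) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' (png/jpeg only): ", path, call. = FALSE))
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 3L))  # greyscale
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]         # drop alpha
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  rgb_image(round(raw * 255), sample_id = sample_id,
            cultivar_id = cultivar_id, label = label)
}

#' Write an `rgb_image` (or ROI) to a PNG file
#'
#' @param img an `rgb_image` or `flour_roi`.
#' @param path output path (`.png`).
#' @return `path`, invisibly. For a ROI a JSON sidecar
#'   `{sample_id, origin, side}` is written next to the PNG.
#' @export
write_image <- function(img, path) {
  px <- img$pixels
  png::writePNG(pmin(pmax(px / 255, 0), 1), target = path)
  if (inherits(img, "flour_roi")) {
    side_car <- paste0(tools::file_path_sans_ext(path), ".json")
    jsonlite::write_json(
      list(sample_id = img$sample_id, origin = img$origin, side = img$side),
      side_car, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a sample manifest
#'
#' The manifest is a CSV with header `sample_id,cultivar_id,label,path`
#' binding each image file to its provenance.
#'
#' @param path CSV path.
#' @return a data.frame with the four manifest columns.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cultivar_id", "label", "path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ","), call. = FALSE)
  m[need]
}

#' @rdname read_manifest
#' @param manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load all images listed in a manifest
#'
#' @param manifest data.frame as returned by [read_manifest()].
#' @param dir optional directory that relative `path` entries are resolved
#'   against.
#' @return list of `rgb_image` objects.
#' @export
load_manifest_images <- function(manifest, dir = NULL) {
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!is.null(dir) && !file.exists(p)) p <- file.path(dir, p)
    read_image(p, sample_id = manifest$sample_id[i],
               cultivar_id = manifest$cultivar_id[i], label = manifest$label[i])
  })
}
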