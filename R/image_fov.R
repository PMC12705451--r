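#' Single field-of-view image with a domain tag
#'
#' The package's canonical image container: a numeric pixel grid in `[0, 1]`,
#' stored row-major with origin at the top-left, together with a tag saying
#' which imaging domain the image belongs to. `"AF"` marks label-free
#' autofluorescence-like images (1 channel); `"STAIN"` marks brightfield
#' stain-like images (3 RGB channels). Pixels are kept as floating point
#' throughout and only quantised to 8/16 bits at I/O boundaries.
#'
#' @param pixels numeric matrix (`H x W`) or array (`H x W x C`) with values
#'   in `[0, 1]`. A matrix is promoted to a single-channel array.
#' @param domain `"AF"` or `"STAIN"`.
#' @return an object of class `image_fov` with elements `pixels` and `domain`.
#' @examples
#' fov <- image_fov(matrix(runif(64), 8, 8), "AF")
#' dim(fov$pixels)
#' @export
image_fov <- function(pixels, domain = c("AF", "STAIN")) {
  domain <- match.arg(domain)
  pixels <- as_pixels(pixels)
  if (anyNA(pixels) || min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("image_fov pixels must be finite and lie in [0, 1]", call. = FALSE)
  structure(list(pixels = clamp01(pixels), domain = domain),
            class = "image_fov")
}

#' @export
print.image_fov <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_fov %s %dx%dx%d, range [%.3f, %.3f]>\n",
              x$domain, d[1], d[2], d[3], min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_image_fov <- function(x) inherits(x, "image_fov")

n_channels <- function(fov) dim(as_pixels(fov))[3]

#' Read an image file into an `image_fov`
#'
#' Supports 8-bit PNG and 8/16-bit TIFF. Pixel values are normalised to
#' `[0, 1]` from the file's bit depth (255 maps to 1.0 for 8-bit files,
#' 65535 to 1.0 for 16-bit files).
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param domain domain tag; if `NULL`, guessed from a `_af` / `_stain`
#'   filename suffix, defaulting to `"STAIN"` for 3-channel files and `"AF"`
#'   otherwise.
#' @return an [image_fov].
#' @export
read_image <- function(path, domain = NULL) {
  if (!file.exists(path)) stop("unreadable-file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported file type: .", ext, call. = FALSE))
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  if (is.null(domain)) {
    stem <- tolower(tools::file_path_sans_ext(basename(path)))
    domain <- if (grepl("_af$", stem)) "AF"
      else if (grepl("_stain$", stem)) "STAIN"
      else if (length(dim(px)) == 3L && dim(px)[3] == 3L) "STAIN" else "AF"
  }
  image_fov(px, domain)
}

#' Write an `image_fov` to disk
#'
#' Pixels are quantised to the requested bit depth. PNG output is 8-bit;
#' TIFF output may be 8- or 16-bit. Writing then re-reading at the same depth
#' reproduces the quantised pixels bit-identically.
#'
#' @param fov an [image_fov].
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @param bits 8 or 16 (16 only for TIFF).
#' @return `path`, invisibly.
#' @export
write_image <- function(fov, path, bits = 8) {
  stopifnot(is_image_fov(fov), bits %in% c(8, 16))
  px <- fov$pixels
  if (dim(px)[3] == 1L) px <- px[, , 1]
  scale <- 2^bits - 1
  px <- round(px * scale) / scale
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits != 8) stop("unsupported-depth: PNG output is 8-bit", call. = FALSE)
    png::writePNG(px, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = bits)
  } else {
    stop("unsupported file type: .", ext, call. = FALSE)
  }
  invisible(path)
}
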