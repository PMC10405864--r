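#' Grayscale angiogram raster
#'
#' A thin container for a 2-D 8-bit intensity raster together with its
#' physical pixel pitch and the foveal-center coordinate. Coordinates follow
#' the `(x, y)` = (column, row) convention, 1-based.
#'
#' @param pixels Numeric or integer matrix with values in \[0, 255\]
#'   (rows = y, columns = x).
#' @param pitch_um Physical size of one pixel (um).
#' @param fovea_xy Length-2 numeric `(x, y)` of the foveal center, or `NULL`
#'   for the image center.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, pitch_um, fovea_xy = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must be finite and in [0, 255]")
  stopifnot(pitch_um > 0)
  if (is.null(fovea_xy)) fovea_xy <- c(ncol(pixels) / 2, nrow(pixels) / 2)
  fovea_xy <- as.numeric(fovea_xy)
  if (length(fovea_xy) != 2 ||
      fovea_xy[1] < 1 || fovea_xy[1] > ncol(pixels) ||
      fovea_xy[2] < 1 || fovea_xy[2] > nrow(pixels))
    stop("fovea_xy must lie within the image bounds")
  structure(list(pixels = pixels, pitch_um = pitch_um, fovea_xy = fovea_xy),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.3f um/px, fovea (%.1f, %.1f)\n",
              nrow(x$pixels), ncol(x$pixels), x$pitch_um,
              x$fovea_xy[1], x$fovea_xy[2]))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Read a grayscale image with its JSON sidecar
#'
#' Reads an 8-bit grayscale TIFF or PNG. A sidecar JSON file (same path with
#' extension `.json`) may carry `pitch_um`, `fovea_xy` and `axial_length_mm`;
#' explicit arguments override it.
#'
#' @param path Image file (`.tif`, `.tiff` or `.png`).
#' @param pitch_um,fovea_xy Optional overrides of the sidecar values.
#' @return A `gray_image`; any `axial_length_mm` found in the sidecar is
#'   attached as an attribute.
#' @export
read_gray_image <- function(path, pitch_um = NULL, fovea_xy = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  side <- sub("\\.[^.]+$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  if (is.null(pitch_um)) pitch_um <- meta$pitch_um
  if (is.null(fovea_xy)) fovea_xy <- meta$fovea_xy
  if (is.null(pitch_um)) stop("pitch_um not given and no sidecar value found")
  img <- gray_image(round(raw * 255), pitch_um, fovea_xy)
  if (!is.null(meta$axial_length_mm))
    attr(img, "axial_length_mm") <- meta$axial_length_mm
  img
}

#' Write a grayscale image and its JSON sidecar
#'
#' @param img A `gray_image`.
#' @param path Output file (`.tif`/`.tiff`/`.png` decide the format).
#' @param axial_length_mm Optional axial length recorded in the sidecar.
#' @param sidecar Write the JSON sidecar next to the image.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, axial_length_mm = NULL, sidecar = TRUE) {
  stopifnot(inherits(img, "gray_image"))
  m <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    png = png::writePNG(m, path),
    stop("unsupported image format: ", ext))
  if (sidecar) {
    meta <- list(pitch_um = img$pitch_um, fovea_xy = img$fovea_xy)
    if (!is.null(axial_length_mm)) meta$axial_length_mm <- axial_length_mm
    jsonlite::write_json(meta, sub("\\.[^.]+$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a binary raster as a black-and-white PNG
#' @param bw Logical matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_binary_image <- function(bw, path) {
  png::writePNG(matrix(as.numeric(bw), nrow(bw), ncol(bw)), path)
  invisible(path)
}

# clamp to 8-bit range
clip255 <- function(x) pmin(pmax(x, 0), 255)

# percentile contrast stretch to the full 8-bit range; degenerate images are
# returned unchanged with a warning
contrast_stretch <- function(mat, pct = 1) {
  q <- stats::quantile(mat, c(pct / 100, 1 - pct / 100), names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant-intensity image: contrast stretch skipped")
    return(mat)
  }
  clip255((mat - q[1]) / (q[2] - q[1]) * 255)
}

# Otsu threshold on an 8-bit histogram
otsu_threshold <- function(mat) {
  h <- as.double(tabulate(as.integer(round(mat)) + 1L, nbins = 256L))
  n <- sum(h)
  lev <- 0:255
  w <- cumsum(h)
  mu <- cumsum(h * lev)
  mu_t <- mu[256]
  between <- (mu_t * w - mu * n)^2 / (w * (n - w) * 1.0)
  between[!is.finite(between)] <- -Inf
  lev[which.max(between)]
}
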