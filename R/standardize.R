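#' Rescale an image by the axial-length ratio
#'
#' Resamples the image by `r = axial_length_mm / min_axial_length_mm` (bicubic)
#' so that all specimens of a cohort share the physical scale of the
#' shortest eye. Output dimensions are rounded up so no field is lost at the
#' margins; the foveal coordinate is multiplied by the same ratio and the
#' pixel pitch updated to conserve the physical field.
#'
#' @param img A `gray_image`.
#' @param axial_length_mm Axial length of the specimen (mm); must be at least
#'   the cohort minimum.
#' @param cfg A [scale_config()] object.
#' @return The rescaled `gray_image`.
#' @export
rescale_by_axial_length <- function(img, axial_length_mm, cfg = scale_config()) {
  stopifnot(inherits(img, "gray_image"), inherits(cfg, "scale_config"))
  if (axial_length_mm < cfg$min_axial_length_mm)
    stop("axial length below the cohort minimum (scaling anchor)")
  r <- axial_length_mm / cfg$min_axial_length_mm
  if (r == 1) return(img)
  d <- dim(img$pixels)
  out_d <- as.integer(ceiling(d * r))
  px <- clip255(cpp_resize_bicubic(img$pixels, out_d[1], out_d[2]))
  gray_image(px, img$pitch_um * d[2] / out_d[2], img$fovea_xy * r)
}

#' Crop the common field around the fovea and resample to the output grid
#'
#' Extracts a `common_crop_um` square window centered on the foveal
#' coordinate and resamples it to `output_size_px` pixels, giving the final
#' common resolution (2380/304 = 7.83 um/px at defaults).
#'
#' @param img A `gray_image`.
#' @param cfg A [scale_config()] object.
#' @return A standardized `gray_image` with the fovea at the image center.
#' @export
crop_common_field <- function(img, cfg = scale_config()) {
  stopifnot(inherits(img, "gray_image"), inherits(cfg, "scale_config"))
  w_px <- cfg$common_crop_um / img$pitch_um
  half <- w_px / 2
  x0 <- round(img$fovea_xy[1] - half) + 1L; x1 <- x0 + round(w_px) - 1
  y0 <- round(img$fovea_xy[2] - half) + 1L; y1 <- y0 + round(w_px) - 1
  d <- dim(img$pixels)
  if (x0 < 1 || y0 < 1 || x1 > d[2] || y1 > d[1])
    stop("field too small after rescale")
  crop <- img$pixels[y0:y1, x0:x1, drop = FALSE]
  n <- cfg$output_size_px
  px <- if (all(dim(crop) == c(n, n))) crop else
    clip255(cpp_resize_bicubic(crop, n, n))
  gray_image(px, cfg$common_crop_um / n, c(n / 2, n / 2))
}

#' Standardize an image to the common scale and field
#'
#' Convenience composition of [rescale_by_axial_length()] and
#' [crop_common_field()].
#'
#' @inheritParams rescale_by_axial_length
#' @return A standardized `gray_image`.
#' @export
standardize_image <- function(img, axial_length_mm, cfg = scale_config()) {
  crop_common_field(rescale_by_axial_length(img, axial_length_mm, cfg), cfg)
}
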