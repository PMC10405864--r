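new_vessel_segmentation <- function(binary, large_mask, full_skeleton,
                                    capillary_skeleton, center_xy,
                                    px_area_mm2, dilate_radius) {
  structure(list(binary = binary, large_mask = large_mask,
                 full_skeleton = full_skeleton,
                 capillary_skeleton = capillary_skeleton,
                 center_xy = center_xy, px_area_mm2 = px_area_mm2,
                 dilate_radius = as.integer(dilate_radius)),
            class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf(
    "<vessel_segmentation> %d x %d px, vessel density %.1f%%, %d capillary skeleton px\n",
    nrow(x$binary), ncol(x$binary), 100 * mean(x$binary),
    sum(x$capillary_skeleton)))
  invisible(x)
}

#' Intensity preprocessing to the analysis scale
#'
#' Applies, in order: percentile contrast stretch; background estimation by
#' grayscale morphological opening with a disk and subtraction; a second
#' contrast stretch; bicubic upsampling to the analysis scale; a dual
#' intensity threshold that crushes values below `dual_lo` to 0 and saturates
#' values above `dual_hi` to 255 while intermediate values pass through; and
#' an optional small averaging filter. The result is the smoothed thresholded
#' image consumed by the capillary segmentation; the upsampled stretched
#' image from before the dual threshold is attached as attribute
#' `"stretched"` because the large-vessel stages operate on it.
#'
#' @param img A standardized `gray_image`.
#' @param cfg A [segmentation_config()] object.
#' @return A `gray_image` at the analysis scale (attribute `"stretched"`:
#'   the pre-dual-threshold intensity matrix).
#' @export
preprocess_intensity <- function(img, cfg = segmentation_config()) {
  stopifnot(inherits(img, "gray_image"), inherits(cfg, "segmentation_config"))
  px <- img$pixels
  if (max(px) == min(px)) {
    warning("constant-intensity input: preprocessing degenerates to upsampling")
    f <- cfg$upsample_factor
    d <- dim(px) * f
    return(gray_image(matrix(px[1], d[1], d[2]), img$pitch_um / f,
                      img$fovea_xy * f))
  }
  px <- contrast_stretch(px, cfg$stretch_pct)
  bg <- cpp_gray_open(px, cfg$background_open_radius_px)
  px <- pmax(px - bg, 0)
  px <- contrast_stretch(px, cfg$stretch_pct)
  f <- cfg$upsample_factor
  if (f > 1) {
    d <- dim(px)
    px <- clip255(cpp_resize_bicubic(px, d[1] * f, d[2] * f))
  }
  stretched <- px
  px[px < cfg$dual_lo] <- 0
  px[px > cfg$dual_hi] <- 255
  if (cfg$smooth_filter_px > 1) px <- cpp_local_mean(px, cfg$smooth_filter_px)
  out <- gray_image(px, img$pitch_um / f, img$fovea_xy * f)
  attr(out, "stretched") <- stretched
  out
}

#' Segment the small capillaries
#'
#' Local-mean adaptive thresholding at a small window, perimeter subtraction,
#' inversion-median-inversion denoising, skeletonization with cleanup
#' (small-object removal, spur pruning, isolated-pixel deletion, intensity
#' floor), and dilation back to capillary caliber.
#'
#' @param pre Analysis-scale preprocessed `gray_image` (from
#'   [preprocess_intensity()]).
#' @param cfg A [segmentation_config()] object.
#' @return Logical matrix of the segmented small vasculature.
#' @export
segment_small_vessels <- function(pre, cfg = segmentation_config()) {
  px <- pre$pixels
  fg <- px > cpp_local_mean(px, cfg$adapt_window_small) + cfg$adapt_offset
  fg <- fg & !cpp_perimeter_image(fg)
  inv <- cpp_median3(matrix(as.double(!fg), nrow(fg), ncol(fg)))
  fg <- inv < 0.5
  skel <- cpp_thin(fg)
  skel <- cpp_remove_small(skel, cfg$skel_min_object_px + 1, 8L)
  if (cfg$spur_iterations > 0) skel <- cpp_prune_spurs(skel, cfg$spur_iterations)
  skel <- cpp_remove_isolated(skel)
  skel <- skel & (px >= cfg$skel_intensity_floor)
  if (!any(skel)) {
    warning("small-vessel segmentation is empty")
    return(skel)
  }
  cpp_dilate_disk(skel, cfg$dilate_radius_small)
}

#' Segment the larger blood vessels
#'
#' Local-mean adaptive thresholding at a large window on the stretched
#' (pre-dual-threshold) image, removal of components below the large-vessel
#' size floor, and masking by an intensity floor.
#'
#' @inheritParams segment_small_vessels
#' @return Logical matrix of the segmented large vessels.
#' @export
segment_large_vessels <- function(pre, cfg = segmentation_config()) {
  px <- attr(pre, "stretched") %||% pre$pixels
  fg <- px > cpp_local_mean(px, cfg$adapt_window_large) + cfg$adapt_offset
  fg <- cpp_remove_small(fg, cfg$large_min_object_px, 8L)
  fg & (px > cfg$large_intensity_floor)
}

#' Combine segmentations and clean the avascular zone
#'
#' Takes the union of the small- and large-vessel segmentations, then deletes
#' isolated foreground blobs lying wholly inside the background component
#' containing the image center (the FAZ): a blob is removed when it is
#' smaller than `faz_clean_max_blob_px` and every background pixel it touches
#' belongs to the FAZ component. Blobs connected to the surrounding
#' vasculature are retained. This is the deterministic, operator-free
#' replacement for interactive noise removal.
#'
#' @param small,large Logical matrices of equal dimensions.
#' @param center_xy `(x, y)` image-center coordinate (1-based).
#' @param cfg A [segmentation_config()] object.
#' @return Logical matrix of the cleaned combined vasculature.
#' @export
combine_and_clean_faz <- function(small, large, center_xy,
                                  cfg = segmentation_config()) {
  stopifnot(all(dim(small) == dim(large)))
  u <- small | large
  bg <- cpp_label(!u, 4L)
  cl <- bg[round(center_xy[2]), round(center_xy[1])]
  if (cl == 0L) {
    # center on a vessel: clean around the nearest background component
    idx <- which(bg > 0)
    if (length(idx) == 0L) return(u)
    nr <- nrow(u)
    ii <- (idx - 1L) %% nr + 1L; jj <- (idx - 1L) %/% nr + 1L
    d2 <- (jj - center_xy[1])^2 + (ii - center_xy[2])^2
    cl <- bg[idx[which.min(d2)]]
  }
  fgl <- cpp_label(u, 8L)
  areas <- attr(fgl, "areas")
  nr <- nrow(u); nc <- ncol(u)
  cand <- which(areas < cfg$faz_clean_max_blob_px)
  if (length(cand) == 0L) return(u)
  for (comp in cand) {
    idx <- which(fgl == comp)
    ii <- (idx - 1L) %% nr + 1L; jj <- (idx - 1L) %/% nr + 1L
    # 4-neighbor background labels around the blob
    nb <- integer(0)
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      i2 <- ii + d[1]; j2 <- jj + d[2]
      ok <- i2 >= 1L & i2 <= nr & j2 >= 1L & j2 <= nc
      nb <- c(nb, bg[cbind(i2[ok], j2[ok])])
    }
    nb <- unique(nb[nb > 0L])
    if (length(nb) > 0L && all(nb == cl)) u[idx] <- FALSE
  }
  if (u[round(center_xy[2]), round(center_xy[1])])
    warning("center pixel lies on foreground after FAZ cleaning")
  u
}

#' Build the arteriole/venule mask
#'
#' Global (Otsu) binarization of the stretched (pre-dual-threshold) image,
#' removal of components at or below the mask size floor, and dilation so
#' the mask covers the full caliber of the large vessels.
#'
#' @inheritParams segment_small_vessels
#' @return Logical matrix of the large-vessel mask.
#' @export
make_large_vessel_mask <- function(pre, cfg = segmentation_config()) {
  px <- attr(pre, "stretched") %||% pre$pixels
  bw <- px > otsu_threshold(px)
  bw <- cpp_remove_small(bw, cfg$mask_min_object_px + 1, 8L)
  cpp_dilate_disk(bw, cfg$mask_dilate_radius)
}

#' Skeletonize the vasculature
#'
#' The full skeleton is the 1-px medial line of the binary vasculature; the
#' capillary skeleton removes every skeleton pixel covered by the
#' arteriole/venule mask, guaranteeing that simulated segment removals are
#' always a subset of the full skeleton.
#'
#' @param binary Logical matrix of the cleaned vasculature.
#' @param mask Logical matrix of the large-vessel mask.
#' @return List with `full_skeleton` and `capillary_skeleton`.
#' @export
make_skeletons <- function(binary, mask) {
  stopifnot(all(dim(binary) == dim(mask)))
  full <- cpp_thin(binary)
  list(full_skeleton = full, capillary_skeleton = full & !mask)
}

#' Segment a standardized angiogram
#'
#' Runs the full segmentation pipeline: intensity preprocessing, small- and
#' large-vessel segmentation, combination with automated FAZ cleanup,
#' arteriole/venule mask construction, and skeletonization.
#'
#' @param img A standardized `gray_image`.
#' @param cfg A [segmentation_config()] object.
#' @return An object of class `vessel_segmentation` holding the cleaned
#'   binary image, large-vessel mask, both skeletons, the analysis-scale
#'   center coordinate and pixel area.
#' @export
segment_vessels <- function(img, cfg = segmentation_config()) {
  pre <- preprocess_intensity(img, cfg)
  small <- segment_small_vessels(pre, cfg)
  large <- segment_large_vessels(pre, cfg)
  center <- round(img$fovea_xy * cfg$upsample_factor)
  combined <- combine_and_clean_faz(small, large, center, cfg)
  mask <- make_large_vessel_mask(pre, cfg)
  sk <- make_skeletons(combined, mask)
  new_vessel_segmentation(
    binary = combined, large_mask = mask,
    full_skeleton = sk$full_skeleton,
    capillary_skeleton = sk$capillary_skeleton,
    center_xy = center,
    px_area_mm2 = (pre$pitch_um * 1e-3)^2,
    dilate_radius = cfg$dilate_radius_small)
}
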