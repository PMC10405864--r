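#' Parameters of the synthetic capillary network generator
#'
#' Defines the geometry and photometry of one synthetic en-face angiogram.
#' Defaults emulate a healthy parafoveal full-slab OCT-A acquisition at the
#' common analysis scale: a 1824 x 1824 px raster covering a 2380 um square
#' field, a foveal avascular zone (FAZ) of about 0.272 mm^2, a capillary mesh
#' dense enough to yield a vessel density near 49%, and a few thick
#' arterioles/venules.
#'
#' @param image_size_px Side of the square analysis-scale raster (px).
#' @param pixel_pitch_um Physical size of one analysis-scale pixel (um).
#' @param faz_area_mm2 Target area of the central avascular zone (mm^2);
#'   0 suppresses the imposed FAZ so the central mesh cell plays its role.
#' @param capillary_point_density Mesh seed density (points per mm^2); higher
#'   values give a finer capillary mesh and a higher vessel density.
#' @param n_large_vessels Number of thick arteriole/venule curves.
#' @param large_vessel_width_px Width of the large vessels (px, analysis scale).
#' @param capillary_width_px Width of rendered capillaries (px); must be odd
#'   (a 1-px skeleton dilated by a disk of radius (width-1)/2).
#' @param noise_level Relative standard deviation of multiplicative speckle.
#' @param vessel_intensity,background_intensity,large_vessel_intensity 8-bit
#'   mean intensities of capillaries, background and arterioles/venules.
#'   Arterioles/venules carry a stronger decorrelation signal than
#'   capillaries, which is what lets the mask stage isolate them.
#' @return An object of class `network_params`.
#' @export
network_params <- function(image_size_px = 1824L,
                           pixel_pitch_um = 2380 / 1824,
                           faz_area_mm2 = 0.272,
                           capillary_point_density = 410,
                           n_large_vessels = 4L,
                           large_vessel_width_px = 25L,
                           capillary_width_px = 11L,
                           noise_level = 0.15,
                           vessel_intensity = 80,
                           background_intensity = 30,
                           large_vessel_intensity = 240) {
  p <- list(image_size_px = as.integer(image_size_px),
            pixel_pitch_um = pixel_pitch_um,
            faz_area_mm2 = faz_area_mm2,
            capillary_point_density = capillary_point_density,
            n_large_vessels = as.integer(n_large_vessels),
            large_vessel_width_px = as.integer(large_vessel_width_px),
            capillary_width_px = as.integer(capillary_width_px),
            noise_level = noise_level,
            vessel_intensity = vessel_intensity,
            background_intensity = background_intensity,
            large_vessel_intensity = large_vessel_intensity)
  stopifnot(p$image_size_px > 0, p$faz_area_mm2 >= 0, p$pixel_pitch_um > 0,
            p$capillary_point_density > 0, p$n_large_vessels >= 0,
            p$noise_level >= 0)
  if (p$capillary_width_px %% 2L != 1L)
    stop("capillary_width_px must be odd (skeleton dilated by an integer-radius disk)")
  for (f in c("vessel_intensity", "background_intensity", "large_vessel_intensity"))
    if (p[[f]] < 0 || p[[f]] > 255) stop(f, " must lie in [0, 255]")
  structure(p, class = "network_params")
}

#' Cohort-level parameters for synthetic specimen generation
#'
#' Distributional specifications for per-specimen draws. FAZ area and mesh
#' density are drawn from normal distributions (redrawn while out of physical
#' range); axial length follows a truncated normal bounded below so that the
#' cohort minimum coincides with the scaling anchor of the standardization
#' step.
#'
#' @param n_specimens Number of specimens (>= 2).
#' @param faz_area_mean,faz_area_sd FAZ area distribution (mm^2).
#' @param density_mean,density_sd Mesh seed density distribution (points/mm^2).
#'   Defaults give a baseline vessel density spread of roughly 2 percentage
#'   points across the cohort.
#' @param axial_length_mean,axial_length_sd,axial_length_min Axial length
#'   distribution (mm), truncated at `axial_length_min`.
#' @param master_seed Integer master seed; per-specimen substreams are derived
#'   from it.
#' @param base A [network_params()] object providing all non-drawn fields.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_specimens = 20L,
                          faz_area_mean = 0.272, faz_area_sd = 0.102,
                          density_mean = 410, density_sd = 0.08 * density_mean,
                          axial_length_mean = 23.8, axial_length_sd = 1.2,
                          axial_length_min = 21.39,
                          master_seed = 1L,
                          base = network_params()) {
  stopifnot(n_specimens >= 2, faz_area_sd >= 0, density_sd >= 0,
            axial_length_sd >= 0, axial_length_min > 0,
            inherits(base, "network_params"))
  structure(list(n_specimens = as.integer(n_specimens),
                 faz_area_mean = faz_area_mean, faz_area_sd = faz_area_sd,
                 density_mean = density_mean, density_sd = density_sd,
                 axial_length_mean = axial_length_mean,
                 axial_length_sd = axial_length_sd,
                 axial_length_min = axial_length_min,
                 master_seed = as.integer(master_seed),
                 base = base),
            class = "cohort_params")
}

#' Standardization geometry
#'
#' Common physical scale used before segmentation: images are rescaled by the
#' ratio of the specimen's axial length to the smallest axial length of the
#' cohort, then cropped to a common square field centered on the fovea and
#' resampled to a fixed pixel grid. The defaults give the canonical
#' 2380 um / 304 px = 7.83 um/px resolution.
#'
#' @param min_axial_length_mm Smallest axial length (scaling anchor, mm).
#' @param common_crop_um Side of the common cropped field (um).
#' @param output_size_px Side of the standardized raster (px).
#' @return An object of class `scale_config`.
#' @export
scale_config <- function(min_axial_length_mm = 21.39,
                         common_crop_um = 2380,
                         output_size_px = 304L) {
  stopifnot(min_axial_length_mm > 0, common_crop_um > 0, output_size_px > 0)
  structure(list(min_axial_length_mm = min_axial_length_mm,
                 common_crop_um = common_crop_um,
                 output_size_px = as.integer(output_size_px)),
            class = "scale_config")
}

#' Vessel segmentation configuration
#'
#' Houses every constant of the segmentation pipeline. Defaults are the
#' canonical values at the 304-px input / 1824-px analysis geometry. The
#' `scale` argument rescales the geometry-dependent constants for runs at a
#' reduced raster size: linear quantities (windows, radii) are multiplied by
#' `scale`, area thresholds by `scale^2` (each kept at least 1; windows kept
#' odd). Intensity constants are scale-free and unchanged.
#'
#' @param scale Linear scale factor relative to the default geometry.
#' @param stretch_pct Percentile (in percent) for contrast stretching tails.
#' @param background_open_radius_px Disk radius of the morphological opening
#'   used to estimate the background (input scale).
#' @param upsample_factor Bicubic upsampling factor to the analysis scale.
#' @param dual_lo,dual_hi Dual intensity threshold: values below `dual_lo` are
#'   set to 0, above `dual_hi` to 255, the rest pass through unchanged.
#' @param smooth_filter_px Side of the averaging filter applied after the dual
#'   threshold (1 = identity).
#' @param adapt_window_small,adapt_window_large Local-mean windows (analysis
#'   scale) of the capillary and large-vessel adaptive thresholds.
#' @param adapt_offset Constant offset added to the local mean before
#'   comparison (0-255 scale).
#' @param skel_min_object_px Skeleton components at or below this size are
#'   removed.
#' @param spur_iterations Endpoint-pruning passes applied to the skeleton.
#' @param skel_intensity_floor Skeleton pixels where the preprocessed image is
#'   below this intensity are removed.
#' @param dilate_radius_small Disk radius used to dilate the capillary
#'   skeleton back to vessel caliber.
#' @param large_min_object_px Components below this size are removed from the
#'   large-vessel segmentation.
#' @param large_intensity_floor Intensity mask floor of the large-vessel
#'   segmentation.
#' @param mask_min_object_px Components at or below this size are removed when
#'   building the arteriole/venule mask.
#' @param mask_dilate_radius Disk radius of the mask dilation.
#' @param faz_clean_max_blob_px Isolated foreground blobs up to this size
#'   found inside the FAZ are deleted (automated stand-in for interactive
#'   cleanup).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(scale = 1,
                                stretch_pct = 1,
                                background_open_radius_px = 15L,
                                upsample_factor = 6L,
                                dual_lo = 20, dual_hi = 35,
                                smooth_filter_px = 1L,
                                adapt_window_small = 15L,
                                adapt_window_large = 30L,
                                adapt_offset = 0,
                                skel_min_object_px = 10L,
                                spur_iterations = 1L,
                                skel_intensity_floor = 30,
                                dilate_radius_small = 5L,
                                large_min_object_px = 3000L,
                                large_intensity_floor = 30,
                                mask_min_object_px = 400L,
                                mask_dilate_radius = 6L,
                                faz_clean_max_blob_px = 200L) {
  lin <- function(x) max(1L, as.integer(round(x * scale)))
  odd <- function(x) { v <- lin(x); if (v %% 2L == 0L) v + 1L else v }
  are <- function(x) max(1L, as.integer(round(x * scale^2)))
  cfg <- list(stretch_pct = stretch_pct,
              background_open_radius_px = lin(background_open_radius_px),
              upsample_factor = as.integer(upsample_factor),
              dual_lo = dual_lo, dual_hi = dual_hi,
              smooth_filter_px = as.integer(smooth_filter_px),
              adapt_window_small = odd(adapt_window_small),
              adapt_window_large = lin(adapt_window_large),
              adapt_offset = adapt_offset,
              skel_min_object_px = are(skel_min_object_px),
              spur_iterations = as.integer(spur_iterations),
              skel_intensity_floor = skel_intensity_floor,
              dilate_radius_small = lin(dilate_radius_small),
              large_min_object_px = are(large_min_object_px),
              large_intensity_floor = large_intensity_floor,
              mask_min_object_px = are(mask_min_object_px),
              mask_dilate_radius = lin(mask_dilate_radius),
              faz_clean_max_blob_px = are(faz_clean_max_blob_px),
              scale = scale)
  if (!(cfg$dual_lo >= 0 && cfg$dual_lo < cfg$dual_hi && cfg$dual_hi <= 255))
    stop("dual thresholds must satisfy 0 <= lo < hi <= 255")
  stopifnot(cfg$upsample_factor >= 1, cfg$stretch_pct >= 0,
            cfg$smooth_filter_px >= 1, cfg$spur_iterations >= 0)
  structure(cfg, class = "segmentation_config")
}

#' Capillary-loss sweep configuration
#'
#' The default design matches the full study protocol: intended loss from 1%
#' to 50% in 1% steps with 1000 randomized iterations per level.
#'
#' @param pct_min,pct_max,pct_step Intended-loss grid (percent).
#' @param n_iter Randomized iterations per loss level.
#' @param master_seed Integer master seed; each trial uses an independent
#'   substream derived from (seed, specimen, level, iteration).
#' @param retain_images Keep rebuilt binary rasters in memory (heavy).
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(pct_min = 1, pct_max = 50, pct_step = 1,
                         n_iter = 1000L, master_seed = 1L,
                         retain_images = FALSE) {
  stopifnot(pct_min > 0, pct_min <= pct_max, pct_max <= 100, pct_step > 0,
            n_iter >= 1)
  structure(list(pct_min = pct_min, pct_max = pct_max, pct_step = pct_step,
                 n_iter = as.integer(n_iter),
                 master_seed = as.integer(master_seed),
                 retain_images = isTRUE(retain_images)),
            class = "sweep_config")
}

#' Levels of a sweep configuration
#' @param cfg A [sweep_config()] object.
#' @return Numeric vector of intended loss levels (percent).
#' @export
sweep_levels <- function(cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  seq(cfg$pct_min, cfg$pct_max, by = cfg$pct_step)
}

#' Number of simulated images a sweep design enumerates
#'
#' The full study design (94 specimens, levels 1-50 by 1, 1000 iterations)
#' enumerates 4,700,000 simulated images.
#'
#' @param n_specimens Number of specimens.
#' @param cfg A [sweep_config()] object.
#' @return Number of simulated trials (baselines not included).
#' @export
sweep_plan <- function(n_specimens, cfg = sweep_config()) {
  stopifnot(n_specimens >= 1)
  n_specimens * length(sweep_levels(cfg)) * cfg$n_iter
}

#' Intercapillary-area (PICA) configuration
#'
#' @param min_area_px2 Background regions smaller than this (in analysis-scale
#'   squared pixels) are excluded from the PICA statistics; the canonical
#'   value of 51 discards resampling imperfections.
#' @param include_border_regions Count background regions touching the image
#'   border.
#' @param connectivity Background connectivity (4 or 8). The default pairs
#'   4-connected background with 8-connected vessels so intercapillary areas
#'   cannot leak diagonally through vessel walls.
#' @param sd_denominator `"n-1"` (sample) or `"n"` (population) convention for
#'   the PICA standard deviation.
#' @return An object of class `pica_config`.
#' @export
pica_config <- function(min_area_px2 = 51, include_border_regions = TRUE,
                        connectivity = 4L, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  stopifnot(min_area_px2 >= 0, connectivity %in% c(4L, 8L))
  structure(list(min_area_px2 = min_area_px2,
                 include_border_regions = isTRUE(include_border_regions),
                 connectivity = as.integer(connectivity),
                 sd_denominator = sd_denominator),
            class = "pica_config")
}
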