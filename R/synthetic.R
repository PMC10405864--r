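# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic substream seed from a master seed and integer/character keys;
# stays below 2^31 - 1
substream_seed <- function(master, ...) {
  keys <- list(...)
  h <- as.double(master) %% 2147483647
  for (k in keys) {
    v <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.double(k)
    h <- (h * 48271 + v * 16807 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

#' Generate one synthetic angiogram specimen
#'
#' Builds a seeded synthetic en-face angiogram with known ground truth. The
#' capillary mesh is the cell-boundary network of a relaxed (jittered-grid)
#' point process, which yields simply connected intercapillary polygons like
#' the parafoveal intercapillary areas of real angiograms. The foveal
#' avascular zone is imposed as an additively weighted central cell whose
#' boundary capillaries form a closed ring; its radius is calibrated in a
#' second rasterization pass so the enclosed background area matches
#' `faz_area_mm2`. A few thick arteriole/venule curves arc through the
#' periphery. The grayscale rendering is the blurred truth raster with
#' intensity offsets and multiplicative speckle, downsampled to the
#' acquisition scale.
#'
#' @param params A [network_params()] object.
#' @param seed Integer seed; output is a pure function of (params, seed).
#' @param axial_length_mm Axial length recorded for the specimen (mm).
#' @param specimen_id Identifier string; derived from the seed when `NULL`.
#' @param downsample_factor Factor between the analysis-scale truth raster and
#'   the rendered grayscale image (6 mirrors the acquisition geometry;
#'   1 renders at analysis scale).
#' @return An object of class `synthetic_specimen`: grayscale image (`gray`),
#'   ground-truth binary vasculature (`truth_binary`), large-vessel mask
#'   (`truth_large_vessel_mask`), FAZ pixel set (`truth_faz_idx`) and area,
#'   plus geometry metadata.
#' @export
generate_network <- function(params = network_params(), seed = 1L,
                             axial_length_mm = 21.39, specimen_id = NULL,
                             downsample_factor = 6L) {
  stopifnot(inherits(params, "network_params"))
  S <- params$image_size_px
  pitch <- params$pixel_pitch_um
  px_area_mm2 <- (pitch * 1e-3)^2
  cx <- cy <- S / 2
  r_cap <- (params$capillary_width_px - 1L) %/% 2L
  A_px <- params$faz_area_mm2 / px_area_mm2
  R0 <- sqrt(A_px / pi)
  if (2 * R0 >= S) stop("faz exceeds field")
  if (is.null(specimen_id)) specimen_id <- sprintf("synth_%06d", seed %% 1e6)

  with_seed(seed, {
    # relaxed point process: jittered grid at the target density
    lambda_px <- params$capillary_point_density * px_area_mm2
    g <- 1 / sqrt(lambda_px)
    centers <- seq(g / 2 - g, S + g, by = g)
    n_pts <- length(centers)^2
    sx <- rep(centers, times = length(centers)) + stats::runif(n_pts, -0.35 * g, 0.35 * g)
    sy <- rep(centers, each = length(centers)) + stats::runif(n_pts, -0.35 * g, 0.35 * g)

    build_skel <- function(Rw) {
      keep <- (sx - cx)^2 + (sy - cy)^2 > Rw^2
      if (sum(keep) < 4) stop("faz exceeds field")
      lab <- cpp_voronoi_labels(sx[keep], sy[keep], S, S, cx, cy, Rw)
      cpp_label_boundaries(lab)
    }
    central_bg_px <- function(bin) {
      lab <- cpp_label(!bin, 4L)
      l <- lab[round(cy), round(cx)]
      if (l == 0L) return(NA_real_)
      attr(lab, "areas")[l]
    }

    cap_skel <- build_skel(R0)
    if (A_px > 0) {
      # one calibration pass: adjust the imposed radius so the measured
      # central background area hits the target
      A0 <- central_bg_px(cpp_dilate_disk(cap_skel, r_cap))
      if (is.finite(A0) && A0 > 0) {
        R1 <- R0 * sqrt(A_px / A0)
        cap_skel <- build_skel(R1)
      }
    }

    # large vessels: quadratic Bezier arcs between two border points, pushed
    # away from the center so they never cross the FAZ
    lv <- matrix(FALSE, S, S)
    min_center_dist <- max(1.6 * R0, 0.12 * S)
    for (v in seq_len(params$n_large_vessels)) {
      for (attempt in 1:50) {
        th1 <- stats::runif(1, 0, 2 * pi)
        th2 <- th1 + sample(c(-1, 1), 1) * stats::runif(1, 0.4 * pi, 0.9 * pi)
        border_pt <- function(th) {
          d <- c(cos(th), sin(th))
          t <- (S / 2 - 1) / max(abs(d))
          c(cx, cy) + t * d
        }
        p1 <- border_pt(th1); p2 <- border_pt(th2)
        m <- (p1 + p2) / 2
        dvec <- m - c(cx, cy)
        nd <- sqrt(sum(dvec^2))
        if (nd < 1e-6) next
        ctrl <- c(cx, cy) + dvec / nd * max(nd * 1.5, 0.45 * S)
        tt <- seq(0, 1, length.out = 4L * S)
        bx <- (1 - tt)^2 * p1[1] + 2 * (1 - tt) * tt * ctrl[1] + tt^2 * p2[1]
        by <- (1 - tt)^2 * p1[2] + 2 * (1 - tt) * tt * ctrl[2] + tt^2 * p2[2]
        if (min(sqrt((bx - cx)^2 + (by - cy)^2)) <= min_center_dist) next
        ix <- round(bx); iy <- round(by)
        ok <- ix >= 1 & ix <= S & iy >= 1 & iy <= S
        lv[cbind(iy[ok], ix[ok])] <- TRUE
        break
      }
    }
    mask <- cpp_dilate_disk(lv, params$large_vessel_width_px %/% 2L)

    truth <- cpp_dilate_disk(cap_skel, r_cap) | mask

    lab_bg <- cpp_label(!truth, 4L)
    lfaz <- lab_bg[round(cy), round(cx)]
    if (lfaz == 0L) {
      # center landed on a vessel (possible only without an imposed FAZ):
      # take the nearest background cell so the region is always defined
      idx <- which(lab_bg > 0)
      ii <- (idx - 1L) %% S + 1L; jj <- (idx - 1L) %/% S + 1L
      lfaz <- lab_bg[idx[which.min((jj - cx)^2 + (ii - cy)^2)]]
    }
    faz_idx <- which(lab_bg == lfaz)

    # grayscale rendering: blurred truth + offsets + multiplicative speckle;
    # arterioles/venules carry a stronger signal than capillaries
    base <- cpp_local_mean(matrix(as.double(truth), S, S), 3L)
    lvw <- cpp_local_mean(matrix(as.double(mask), S, S), 3L)
    gray_a <- params$background_intensity +
      (params$vessel_intensity - params$background_intensity) * base +
      (params$large_vessel_intensity - params$vessel_intensity) * lvw
    if (params$noise_level > 0)
      gray_a <- gray_a * (1 + params$noise_level * stats::rnorm(length(gray_a)))
    gray_a <- matrix(clip255(gray_a), S, S)

    f <- as.integer(downsample_factor)
    if (f > 1) {
      n_in <- as.integer(round(S / f))
      gpix <- clip255(round(cpp_resize_bicubic(gray_a, n_in, n_in)))
      gray <- gray_image(gpix, pitch * S / n_in, c(cx, cy) * n_in / S)
    } else {
      gray <- gray_image(round(gray_a), pitch, c(cx, cy))
    }

    structure(list(specimen_id = specimen_id,
                   gray = gray,
                   truth_binary = truth,
                   truth_large_vessel_mask = mask,
                   truth_faz_idx = faz_idx,
                   truth_faz_px = length(faz_idx),
                   truth_faz_area_mm2 = length(faz_idx) * px_area_mm2,
                   axial_length_mm = axial_length_mm,
                   center_xy = c(cx, cy),
                   pitch_um = pitch,
                   px_area_mm2 = px_area_mm2,
                   capillary_width_px = params$capillary_width_px,
                   seed = as.integer(seed),
                   params = params),
              class = "synthetic_specimen")
  })
}

#' @export
print.synthetic_specimen <- function(x, ...) {
  cat(sprintf(
    "<synthetic_specimen> %s: %d px field, FAZ %.3f mm^2, vessel density %.1f%%, seed %d\n",
    x$specimen_id, x$params$image_size_px, x$truth_faz_area_mm2,
    100 * mean(x$truth_binary), x$seed))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws per-specimen parameters (FAZ area, mesh density, axial length) from
#' the cohort distributions using independent substreams of the master seed,
#' and generates one specimen per draw. Out-of-range draws are redrawn (at
#' most 100 attempts).
#'
#' @param cohort A [cohort_params()] object.
#' @param downsample_factor Passed to [generate_network()].
#' @return List of `synthetic_specimen`, with the drawn parameters attached as
#'   attribute `"draws"` (a data frame).
#' @export
generate_cohort <- function(cohort = cohort_params(), downsample_factor = 6L) {
  stopifnot(inherits(cohort, "cohort_params"))
  draw_trunc <- function(n_attempts, mean, sd, lower, upper = Inf) {
    for (a in seq_len(n_attempts)) {
      v <- stats::rnorm(1, mean, sd)
      if (v > lower && v < upper) return(v)
    }
    stop("failed to draw an in-range parameter after ", n_attempts, " attempts")
  }
  out <- vector("list", cohort$n_specimens)
  draws <- data.frame(specimen_id = character(cohort$n_specimens),
                      faz_area_mm2 = NA_real_, density = NA_real_,
                      axial_length_mm = NA_real_, seed = NA_integer_)
  for (i in seq_len(cohort$n_specimens)) {
    s_draw <- substream_seed(cohort$master_seed, "draw", i)
    s_gen <- substream_seed(cohort$master_seed, "gen", i)
    par_i <- with_seed(s_draw, {
      faz <- if (cohort$faz_area_sd == 0) cohort$faz_area_mean else
        draw_trunc(100, cohort$faz_area_mean, cohort$faz_area_sd, lower = 0.01)
      den <- if (cohort$density_sd == 0) cohort$density_mean else
        draw_trunc(100, cohort$density_mean, cohort$density_sd,
                   lower = 0.2 * cohort$density_mean)
      al <- if (cohort$axial_length_sd == 0) max(cohort$axial_length_mean, cohort$axial_length_min) else
        draw_trunc(100, cohort$axial_length_mean, cohort$axial_length_sd,
                   lower = cohort$axial_length_min)
      list(faz = faz, den = den, al = al)
    })
    p <- cohort$base
    p$faz_area_mm2 <- par_i$faz
    p$capillary_point_density <- par_i$den
    id <- sprintf("synth_%03d", i)
    out[[i]] <- generate_network(p, seed = s_gen, axial_length_mm = par_i$al,
                                 specimen_id = id,
                                 downsample_factor = downsample_factor)
    draws[i, ] <- list(id, par_i$faz, par_i$den, par_i$al, s_gen)
  }
  attr(out, "draws") <- draws
  out
}

#' Add multiplicative speckle to a grayscale image
#'
#' @param gray A `gray_image`.
#' @param noise_level Relative intensity SD of the speckle; 0 returns the
#'   input unchanged.
#' @param seed Integer seed.
#' @return A degraded `gray_image`.
#' @export
degrade_image <- function(gray, noise_level, seed = 1L) {
  stopifnot(inherits(gray, "gray_image"), noise_level >= 0)
  if (noise_level == 0) return(gray)
  with_seed(seed, {
    px <- gray$pixels * (1 + noise_level * stats::rnorm(length(gray$pixels)))
    gray_image(matrix(clip255(round(px)), nrow(gray$pixels)),
               gray$pitch_um, gray$fovea_xy)
  })
}

#' Derive a ground-truth vessel segmentation from a synthetic specimen
#'
#' Skeletonizes the ground-truth binary vasculature so that the capillary-loss
#' simulator can operate on a specimen without running image segmentation
#' (useful for testing the simulator and sensitivity stages in isolation).
#'
#' @param specimen A `synthetic_specimen`.
#' @return A `vessel_segmentation` object (see [segment_vessels()]).
#' @export
as_vessel_segmentation <- function(specimen) {
  stopifnot(inherits(specimen, "synthetic_specimen"))
  full <- cpp_thin(specimen$truth_binary)
  mask <- specimen$truth_large_vessel_mask
  new_vessel_segmentation(
    binary = specimen$truth_binary,
    large_mask = mask,
    full_skeleton = full,
    capillary_skeleton = full & !mask,
    center_xy = specimen$center_xy,
    px_area_mm2 = specimen$px_area_mm2,
    dilate_radius = (specimen$capillary_width_px - 1L) %/% 2L)
}
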