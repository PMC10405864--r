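#' Names of the thirteen vasculature metrics
#'
#' Order: FAZ area, vessel density, VCI, VPI, FD, then the four PICA
#' statistics including the FAZ and the four excluding it (`nf_` prefix).
#'
#' @return Character vector of length 13.
#' @export
octa_metric_names <- function() {
  c("faz_area_mm2", "vessel_density", "vci", "vpi", "fd",
    "pica_mean_mm2", "pica_sum_mm2", "pica_regularity", "pica_sd_mm2",
    "nf_pica_mean_mm2", "nf_pica_sum_mm2", "nf_pica_regularity",
    "nf_pica_sd_mm2")
}

#' Vessel density of a binary image
#'
#' Foreground (vessel) pixel count divided by the total pixel count.
#'
#' @param binary Logical matrix.
#' @return Fraction in \[0, 1\].
#' @export
vessel_density <- function(binary) {
  stopifnot(length(binary) > 0)
  sum(binary) / length(binary)
}

#' Vessel perimeter pixel count
#'
#' Number of foreground pixels with at least one background pixel among their
#' eight neighbors; the image border counts as background.
#'
#' @param binary Logical matrix.
#' @return Perimeter pixel count.
#' @export
vessel_perimeter <- function(binary) cpp_perimeter_count(binary)

#' Vessel perimeter index
#'
#' Vessel perimeter pixel count divided by the total image pixel count.
#'
#' @param binary Logical matrix.
#' @return VPI value.
#' @export
vpi <- function(binary) cpp_perimeter_count(binary) / length(binary)

#' Vessel complexity index
#'
#' `perimeter^2 / (4 pi area)` of the vessels, normalized so that a filled
#' circle inscribed in the analysis frame scores 1 (see
#' [vci_norm_constant()]).
#'
#' @param binary Logical matrix.
#' @param norm_const Normalization constant (canonically 1.6169).
#' @return VCI value, or `NA` for an empty foreground.
#' @export
vci <- function(binary, norm_const = 1.6169) {
  a <- sum(binary)
  if (a == 0) return(NA_real_)
  p <- cpp_perimeter_count(binary)
  p^2 / (4 * pi * a) / norm_const
}

#' Recompute the VCI normalization constant from a rasterized circle
#'
#' Rasterizes a filled circle with membership rule
#' `(x - cx)^2 + (y - cy)^2 <= r^2`, centered on the frame's center pixel,
#' and returns its raw complexity `perimeter^2 / (4 pi area)` under the
#' 8-connectivity boundary-pixel perimeter. At the canonical 1824-px frame
#' this reproduces the constant used to normalize the VCI.
#'
#' @param size Frame side (px).
#' @param center `(x, y)` circle center (defaults to the center pixel
#'   `size/2`).
#' @param radius Circle radius in px (defaults to `size/2`).
#' @return The raw complexity of the inscribed circle.
#' @export
vci_norm_constant <- function(size = 1824L, center = NULL, radius = NULL) {
  if (is.null(center)) center <- c(size / 2, size / 2)
  if (is.null(radius)) radius <- size / 2
  x <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  y <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  disk <- (x - center[1])^2 + (y - center[2])^2 <= radius^2
  p <- cpp_perimeter_count(disk)
  p^2 / (4 * pi * sum(disk))
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes at dyadic box sizes (1, 2, 4, ... up to the smaller
#' image side) and returns minus the slope of the least-squares fit of
#' `log N(s)` against `log s`.
#'
#' @param binary Logical matrix.
#' @return FD value, or `NA` when fewer than two foreground pixels exist.
#' @export
fractal_dimension <- function(binary) {
  if (sum(binary) < 2) return(NA_real_)
  bc <- cpp_boxcount(binary)
  fit <- stats::lm.fit(cbind(1, log(bc$size)), log(bc$count))
  -unname(fit$coefficients[2])
}

#' Locate the foveal avascular zone
#'
#' Background connected components are ordered by area (descending) and the
#' ten largest are scanned for the image-center pixel; the component
#' containing it is the FAZ. When the center lies on a vessel or its
#' component is not among the ten largest, the background component nearest
#' to the center is returned with a warning.
#'
#' @param binary Logical matrix.
#' @param center_xy `(x, y)` center coordinate (1-based).
#' @param connectivity Background connectivity (4 or 8).
#' @param px_area_mm2 Area of one pixel (mm^2), used for `area_mm2`.
#' @return List with `idx` (pixel indices of the FAZ component), `area_px`,
#'   `area_mm2` and `fallback` (logical).
#' @export
find_faz <- function(binary, center_xy, connectivity = 4L, px_area_mm2 = 1) {
  lab <- cpp_label(!binary, as.integer(connectivity))
  areas <- attr(lab, "areas")
  if (length(areas) == 0L) stop("fully perfused image: no background pixels")
  cl <- lab[round(center_xy[2]), round(center_xy[1])]
  fallback <- FALSE
  if (cl > 0L) {
    rank <- sum(areas > areas[cl]) + 1L
    if (rank > 10L) {
      fallback <- TRUE
      warning("center component not among the 10 largest nonperfused areas; ",
              "using it as fallback")
    }
  } else {
    fallback <- TRUE
    warning("center pixel lies on a vessel; using nearest background component")
    nr <- nrow(binary)
    idx <- which(lab > 0L)
    ii <- (idx - 1L) %% nr + 1L; jj <- (idx - 1L) %/% nr + 1L
    d2 <- (jj - center_xy[1])^2 + (ii - center_xy[2])^2
    cl <- lab[idx[which.min(d2)]]
  }
  list(idx = which(lab == cl), area_px = areas[cl],
       area_mm2 = areas[cl] * px_area_mm2, fallback = fallback)
}

#' Intercapillary area statistics
#'
#' Statistics of the background (nonperfused) connected-component areas:
#' mean, sum, standard deviation and regularity (mean/SD), over regions at
#' least `cfg$min_area_px2` pixels large, optionally excluding the FAZ
#' component.
#'
#' @param binary Logical matrix.
#' @param faz_region Result of [find_faz()] on the same image (or `NULL`).
#' @param cfg A [pica_config()] object.
#' @param include_faz Include the FAZ component in the statistics.
#' @param px_area_mm2 Area of one pixel (mm^2).
#' @return Named list `mean_mm2`, `sum_mm2`, `sd_mm2`, `regularity` (each
#'   `NA` when undefined).
#' @export
pica_stats <- function(binary, faz_region = NULL, cfg = pica_config(),
                       include_faz = TRUE, px_area_mm2 = 1) {
  lab <- cpp_label(!binary, cfg$connectivity)
  areas <- attr(lab, "areas")
  if (length(areas) == 0L)
    return(list(mean_mm2 = NA_real_, sum_mm2 = NA_real_, sd_mm2 = NA_real_,
                regularity = NA_real_))
  faz_lab <- if (!is.null(faz_region) && length(faz_region$idx) > 0)
    lab[faz_region$idx[1]] else 0L
  keep <- areas >= cfg$min_area_px2
  if (!cfg$include_border_regions) {
    border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border_labs <- setdiff(border_labs[border_labs > 0L], faz_lab)
    keep[border_labs] <- FALSE
  }
  if (!include_faz && faz_lab > 0L) keep[faz_lab] <- FALSE
  a <- areas[keep] * px_area_mm2
  n <- length(a)
  if (n == 0L)
    return(list(mean_mm2 = NA_real_, sum_mm2 = NA_real_, sd_mm2 = NA_real_,
                regularity = NA_real_))
  m <- mean(a)
  s <- if (cfg$sd_denominator == "n") sqrt(mean((a - m)^2)) else
    if (n > 1) stats::sd(a) else NA_real_
  reg <- if (!is.na(s) && s > 0) m / s else NA_real_
  if (!is.na(s) && s == 0) warning("identical region areas: regularity undefined")
  list(mean_mm2 = m, sum_mm2 = sum(a), sd_mm2 = s, regularity = reg)
}

#' Compute the full thirteen-metric battery
#'
#' Computes all metrics on a binary vessel image in one pass: FAZ area,
#' vessel density, VCI, VPI, box-counting FD, and the four PICA statistics
#' with and without the FAZ component. The FAZ is located once and shared by
#' both PICA variants; undefined values propagate as `NA` without aborting.
#'
#' @param binary Logical matrix (analysis scale).
#' @param center_xy `(x, y)` center coordinate (1-based).
#' @param px_area_mm2 Area of one pixel (mm^2).
#' @param cfg A [pica_config()] object.
#' @param vci_norm VCI normalization constant.
#' @return Named numeric vector of class `octa_metrics` with the 13 metrics;
#'   attributes carry `px_area_mm2`, the FAZ pixel count and the fallback
#'   flag.
#' @export
compute_all <- function(binary, center_xy, px_area_mm2,
                        cfg = pica_config(), vci_norm = 1.6169) {
  m <- cpp_binary_metrics(binary,
                          as.integer(round(center_xy[2])),
                          as.integer(round(center_xy[1])),
                          cfg$min_area_px2, px_area_mm2, vci_norm,
                          cfg$connectivity,
                          as.integer(cfg$include_border_regions),
                          as.integer(cfg$sd_denominator == "n"))
  out <- m[octa_metric_names()]
  attr(out, "px_area_mm2") <- px_area_mm2
  attr(out, "faz_px") <- unname(m["faz_px"])
  attr(out, "faz_fallback") <- unname(m["faz_fallback"]) > 0
  class(out) <- "octa_metrics"
  out
}

#' @export
print.octa_metrics <- function(x, ...) {
  cat("<octa_metrics>\n")
  v <- unclass(x)
  attributes(v) <- list(names = names(x))
  print(signif(v, 4))
  invisible(x)
}
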