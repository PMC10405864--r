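# Reduced test geometry: the same physical 2380 um field rasterized at
# 456 px (1/4 of the canonical analysis scale), with capillary caliber and
# area thresholds scaled accordingly. Keeps the sweep-heavy tests fast while
# preserving the field's physical statistics (FAZ area, vessel density,
# intercapillary areas in mm^2).
SMALL_SIZE <- 456L
SMALL_SCALE <- SMALL_SIZE / 1824

small_params <- function(capillary_point_density = 350, ...) {
  network_params(image_size_px = SMALL_SIZE,
                 pixel_pitch_um = 2380 / SMALL_SIZE,
                 capillary_width_px = 3L,
                 large_vessel_width_px = 7L,
                 capillary_point_density = capillary_point_density,
                 ...)
}

small_pica <- function(...) {
  pica_config(min_area_px2 = 51 * SMALL_SCALE^2, ...)
}

small_cohort <- function(n = 10L, seed = 1L, ...) {
  cohort_params(n_specimens = n, density_mean = 350, master_seed = seed,
                base = small_params(), ...)
}

small_specimen <- function(seed = 42L, ...) {
  generate_network(small_params(...), seed = seed, downsample_factor = 1L)
}

# internal raster primitives exercised directly in tests
cpp_label <- octasens:::cpp_label
cpp_dilate_disk <- octasens:::cpp_dilate_disk
cpp_remove_small <- octasens:::cpp_remove_small
cpp_thin <- octasens:::cpp_thin
cpp_resize_bicubic <- octasens:::cpp_resize_bicubic
cpp_local_mean <- octasens:::cpp_local_mean

# random blob raster: thresholded smoothed noise, reproducible
random_blobs <- function(nr = 80, nc = 80, p = 0.45, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(nr * nc), nr, nc)
  sm <- octasens:::cpp_local_mean(m, 5L)
  sm > stats::quantile(sm, 1 - p)
}

# independent connected-component labeling oracle (plain BFS in R)
label_bfs <- function(bw, conn = 4L) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  nbr <- if (conn == 8L)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1)) else
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (k in which(bw)) {
    if (lab[k] > 0L) next
    nxt <- nxt + 1L
    queue <- k
    lab[k] <- nxt
    while (length(queue) > 0) {
      q <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- (q - 1L) %% nr + 1L; j <- (q - 1L) %/% nr + 1L
      for (t in seq_len(nrow(nbr))) {
        ii <- i + nbr[t, 1]; jj <- j + nbr[t, 2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        q2 <- ii + (jj - 1L) * nr
        if (bw[q2] && lab[q2] == 0L) { lab[q2] <- nxt; queue <- c(queue, q2) }
      }
    }
  }
  lab
}
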