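#' Decompose a capillary skeleton into a segment graph
#'
#' Nodes are skeleton pixels with a number of foreground 8-neighbors other
#' than two (branch points and end points); segments are the maximal
#' degree-two pixel chains between nodes. Pure cycles are assigned a
#' designated break node and become a single segment. Node pixels belong to
#' no segment, so segments are pixel-disjoint and junction geometry survives
#' any removal.
#'
#' @param capillary_skeleton Logical matrix, a 1-px-wide skeleton.
#' @return An object of class `skeleton_graph`: `nodes` (pixel indices),
#'   `n_branch_clusters` (8-connected clusters of branch pixels), `segments`
#'   (list of pixel-index chains), `lengths`, `total_capillary_px`, `dim`.
#' @export
skeleton_to_graph <- function(capillary_skeleton) {
  g <- cpp_skeleton_graph(capillary_skeleton)
  d <- dim(capillary_skeleton)
  nodemat <- matrix(FALSE, d[1], d[2])
  nodemat[g$nodes] <- TRUE
  # branch points have >= 3 neighbors; adjacent branch pixels form one junction
  skn <- matrix(as.double(capillary_skeleton), d[1], d[2])
  nbcount <- round(cpp_local_mean(skn, 3L) * 9) - skn
  branch <- nodemat & capillary_skeleton & nbcount >= 3
  structure(list(nodes = as.integer(g$nodes),
                 n_branch_clusters = max(cpp_label(branch, 8L), 0L),
                 segments = g$segments,
                 lengths = as.numeric(g$lengths),
                 total_capillary_px = g$total_px,
                 dim = dim(capillary_skeleton)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d segments, %d node pixels, %d skeleton px\n",
              length(x$segments), length(x$nodes),
              as.integer(x$total_capillary_px)))
  invisible(x)
}

#' Randomized segment removal until an intended loss is just exceeded
#'
#' Draws a seeded uniform random permutation of the segment indices and
#' removes segments in permutation order, accumulating removed pixels, until
#' the removed fraction of capillary skeleton pixels strictly exceeds the
#' intended percentage. Ties (cumulative loss exactly equal to the intended
#' level) continue to the next segment.
#'
#' @param graph A `skeleton_graph`.
#' @param intended_pct Intended capillary loss (percent, 0-100).
#' @param seed Integer seed for the permutation.
#' @param exceed `"strict"` removes until the intended level is strictly
#'   exceeded (canonical); `"gte"` stops at the first level reaching it.
#' @return List with `removed_segment_ids`, `removed_px` (pixel indices) and
#'   `actual_pct`.
#' @export
remove_segments_until <- function(graph, intended_pct, seed = 1L,
                                  exceed = c("strict", "gte")) {
  stopifnot(inherits(graph, "skeleton_graph"),
            intended_pct >= 0, intended_pct <= 100)
  exceed <- match.arg(exceed)
  n <- length(graph$segments)
  if (intended_pct == 0)
    return(list(removed_segment_ids = integer(0), removed_px = integer(0),
                actual_pct = 0))
  if (n == 0L) stop("nothing to remove: skeleton graph has no segments")
  with_seed(seed, {
    perm <- sample.int(n)
    cum <- cumsum(graph$lengths[perm])
    pct <- 100 * cum / graph$total_capillary_px
    k <- if (exceed == "strict") which(pct > intended_pct)[1] else
      which(pct >= intended_pct)[1]
    if (is.na(k)) k <- n  # intended level unreachable: remove everything
    ids <- perm[seq_len(k)]
    list(removed_segment_ids = ids,
         removed_px = unlist(graph$segments[ids], use.names = FALSE),
         actual_pct = pct[k])
  })
}

#' Rebuild a binary vessel image after segment removal
#'
#' Subtracts the removed segment pixels from the full (unmasked) skeleton,
#' dilates the remainder by a disk to restore capillary caliber, and adds the
#' large-vessel mask back so arterioles/venules keep their full size.
#'
#' @param full_skeleton Logical matrix.
#' @param removed Either the list returned by [remove_segments_until()] or an
#'   integer vector of removed pixel indices.
#' @param large_mask Logical matrix.
#' @param dilate_radius Disk radius of the re-dilation.
#' @return Logical matrix, the rebuilt binary vessel image.
#' @export
rebuild_binary <- function(full_skeleton, removed, large_mask,
                           dilate_radius = 5L) {
  idx <- if (is.list(removed)) removed$removed_px else as.integer(removed)
  if (length(idx) > 0 && !all(full_skeleton[idx]))
    stop("removed pixels must be a subset of the full skeleton")
  cpp_rebuild(full_skeleton, as.integer(idx), large_mask,
              as.integer(dilate_radius))
}

#' Run a capillary-loss sweep on one segmented specimen
#'
#' For every intended loss level and iteration, removes a random set of
#' capillary segments ([remove_segments_until()]), rebuilds the binary image
#' and computes the full metric battery. Each trial uses an independent
#' substream seed derived from (master seed, specimen, level, iteration), so
#' any single trial is reproducible in isolation.
#'
#' @param seg A `vessel_segmentation`.
#' @param cfg A [sweep_config()] object.
#' @param pica A [pica_config()] object.
#' @param specimen_id Identifier used in the output and the trial seeds.
#' @param vci_norm Normalization constant of the vessel complexity index.
#' @return An object of class `loss_sweep`: `trials` (data frame with one row
#'   per trial: intended/actual loss, iteration, seed and the 13 metrics),
#'   `baseline` (metric vector at 0% loss), `graph`, and the sweep design.
#' @export
run_sweep <- function(seg, cfg = sweep_config(), pica = pica_config(),
                      specimen_id = "specimen", vci_norm = 1.6169) {
  stopifnot(inherits(seg, "vessel_segmentation"), inherits(cfg, "sweep_config"))
  graph <- skeleton_to_graph(seg$capillary_skeleton)
  if (length(graph$segments) == 0L)
    stop("capillary skeleton has no segments to remove")
  levels <- sweep_levels(cfg)
  n_lev <- length(levels); n_it <- cfg$n_iter
  inc_border <- as.integer(pica$include_border_regions)
  sd_pop <- as.integer(pica$sd_denominator == "n")
  met <- function(removed_px) {
    cpp_rebuild_metrics(seg$full_skeleton, as.integer(removed_px),
                        seg$large_mask, seg$dilate_radius,
                        as.integer(round(seg$center_xy[2])),
                        as.integer(round(seg$center_xy[1])),
                        pica$min_area_px2, seg$px_area_mm2, vci_norm,
                        pica$connectivity, inc_border, sd_pop)
  }
  baseline <- met(integer(0))
  n_tr <- n_lev * n_it
  nm <- octa_metric_names()
  res <- matrix(NA_real_, n_tr, length(nm) + 4,
                dimnames = list(NULL, c("intended_pct", "iteration", "seed",
                                        "actual_pct", nm)))
  images <- if (cfg$retain_images) vector("list", n_tr) else NULL
  row <- 0L
  n_failed <- 0L
  for (li in seq_len(n_lev)) {
    lev <- levels[li]
    for (it in seq_len(n_it)) {
      row <- row + 1L
      s <- substream_seed(cfg$master_seed, specimen_id, lev * 100, it)
      ok <- tryCatch({
        rem <- remove_segments_until(graph, lev, seed = s)
        m <- met(rem$removed_px)
        res[row, ] <- c(lev, it, s, rem$actual_pct, m[nm])
        if (cfg$retain_images)
          images[[row]] <- rebuild_binary(seg$full_skeleton, rem,
                                          seg$large_mask, seg$dilate_radius)
        TRUE
      }, error = function(e) {
        warning(sprintf("trial (level %g, iteration %d) failed: %s",
                        lev, it, conditionMessage(e)))
        FALSE
      })
      if (!ok) n_failed <- n_failed + 1L
    }
  }
  trials <- as.data.frame(res)
  if (n_failed > 0) {
    trials <- trials[stats::complete.cases(trials[, 1:4]), , drop = FALSE]
    message(n_failed, " failed trial(s) skipped")
  }
  structure(list(trials = trials,
                 baseline = baseline,
                 n_failed = n_failed,
                 graph = graph,
                 levels = levels,
                 specimen_id = specimen_id,
                 images = images,
                 cfg = cfg),
            class = "loss_sweep")
}

#' @export
print.loss_sweep <- function(x, ...) {
  cat(sprintf("<loss_sweep> %s: %d trials (%d levels x %d iterations)\n",
              x$specimen_id, nrow(x$trials), length(x$levels), x$cfg$n_iter))
  cat(sprintf("  mean overshoot (actual - intended): %.3f%%\n",
              mean(x$trials$actual_pct - x$trials$intended_pct)))
  invisible(x)
}
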