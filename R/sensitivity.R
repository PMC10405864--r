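#' Build the cohort normative reference
#'
#' Mean, standard deviation (sample, n-1) and the mean +/- 2 SD band per
#' metric, computed from the baseline (0%-loss) metric sets of all
#' specimens. Metrics with fewer than two finite values are marked unusable.
#'
#' @param baselines Numeric matrix (specimens x metrics) or list of baseline
#'   metric vectors.
#' @return An object of class `normative_reference`.
#' @export
build_reference <- function(baselines) {
  if (is.list(baselines) && !is.data.frame(baselines))
    baselines <- do.call(rbind, lapply(baselines, function(b) b[octa_metric_names()]))
  baselines <- as.matrix(baselines)
  if (nrow(baselines) < 2) stop("need at least two baseline metric sets")
  mu <- apply(baselines, 2, function(v) mean(v[is.finite(v)]))
  sdv <- apply(baselines, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  })
  nval <- apply(baselines, 2, function(v) sum(is.finite(v)))
  usable <- nval >= 2 & is.finite(sdv)
  degenerate <- usable & sdv == 0
  if (any(degenerate))
    warning("degenerate normative band (zero SD) for: ",
            paste(names(sdv)[degenerate], collapse = ", "))
  structure(list(mean = mu, sd = sdv, lo = mu - 2 * sdv, hi = mu + 2 * sdv,
                 n_values = nval, usable = usable,
                 n_specimens = nrow(baselines)),
            class = "normative_reference")
}

#' @export
print.normative_reference <- function(x, ...) {
  cat(sprintf("<normative_reference> n = %d specimens\n", x$n_specimens))
  print(signif(data.frame(mean = x$mean, sd = x$sd, lo = x$lo, hi = x$hi), 4))
  invisible(x)
}

#' Normalize a specimen's metric trajectory to the cohort mean
#'
#' Rescales every trial value by `population mean / specimen baseline` per
#' metric, so each specimen starts exactly at the population mean at 0%
#' loss. Metrics with a zero or non-finite baseline are skipped (set `NA`)
#' with a warning.
#'
#' @param specimen_baseline Named numeric vector of baseline metric values.
#' @param trials Numeric matrix (trials x metrics) of raw metric values.
#' @param ref A `normative_reference`.
#' @param method `"ratio"` (multiplicative, canonical) or `"shift"`
#'   (additive offset to the population mean).
#' @return Matrix of normalized trial values.
#' @export
normalize_trajectory <- function(specimen_baseline, trials, ref,
                                 method = c("ratio", "shift")) {
  method <- match.arg(method)
  nm <- colnames(trials)
  b <- specimen_baseline[nm]
  mu <- ref$mean[nm]
  out <- trials
  for (j in seq_along(nm)) {
    if (method == "ratio") {
      if (!is.finite(b[j]) || b[j] == 0) {
        if (!is.finite(b[j]) || b[j] == 0) out[, j] <- NA_real_
        next
      }
      out[, j] <- (trials[, j] / b[j]) * mu[j]
    } else {
      if (!is.finite(b[j])) { out[, j] <- NA_real_; next }
      out[, j] <- trials[, j] + (mu[j] - b[j])
    }
  }
  bad <- if (method == "ratio") !is.finite(b) | b == 0 else !is.finite(b)
  if (any(bad))
    warning("baseline unusable for: ", paste(nm[bad], collapse = ", "))
  out
}

#' Z-scores of normalized trials against the normative reference
#'
#' `z = (value - population mean) / population SD`; a trial is outside the
#' normative band when `|z| > 2` (strict inequality: a value exactly on the
#' band boundary counts as inside).
#'
#' @param normalized Numeric matrix (trials x metrics) of normalized values.
#' @param ref A `normative_reference`.
#' @return List with matrices `z` and `outside` (logical).
#' @export
score_trials <- function(normalized, ref) {
  nm <- colnames(normalized)
  z <- sweep(sweep(normalized, 2, ref$mean[nm]), 2, ref$sd[nm], "/")
  z[, !ref$usable[nm] | ref$sd[nm] == 0] <- NA_real_
  list(z = z, outside = abs(z) > 2)
}

#' Per-specimen sensitivity from the outside-band fraction profile
#'
#' The sensitivity is the loss level at which the fraction of iterations
#' outside the normative band reaches the criterion (default 80% of trials).
#' The crossing is linearly interpolated between the first qualifying level
#' and its predecessor; when the first grid level already qualifies the
#' sensitivity is that level; when no level qualifies the specimen is
#' censored.
#'
#' @param frac_outside Numeric vector of outside-band fractions, named or
#'   accompanied by `levels`.
#' @param levels Increasing numeric grid of intended loss levels (percent).
#' @param criterion Required fraction of trials outside the band.
#' @param interpolate Linearly interpolate the crossing (canonical); `FALSE`
#'   reports the first qualifying grid level.
#' @return List with `sensitivity_pct` (`NA` when censored) and `censored`.
#' @export
specimen_sensitivity <- function(frac_outside, levels = NULL, criterion = 0.8,
                                 interpolate = TRUE) {
  if (is.null(levels)) levels <- as.numeric(names(frac_outside))
  if (length(levels) == 0L || anyNA(levels)) stop("levels must be provided")
  ok <- which(is.finite(frac_outside) & frac_outside >= criterion)
  if (length(ok) == 0L)
    return(list(sensitivity_pct = NA_real_, censored = TRUE))
  k <- ok[1]
  if (k == 1L || !interpolate)
    return(list(sensitivity_pct = levels[k], censored = FALSE))
  f0 <- frac_outside[k - 1]; f1 <- frac_outside[k]
  s <- levels[k - 1] + (levels[k] - levels[k - 1]) * (criterion - f0) / (f1 - f0)
  list(sensitivity_pct = unname(s), censored = FALSE)
}

#' Cohort summary of per-metric sensitivities
#'
#' Averages sensitivities over non-censored specimens, counts achieving
#' specimens, ranks metrics within each specimen (rank 1 = most sensitive;
#' censored metrics rank after all non-censored ones, ties resolved by
#' metric order) and assigns tier labels by thresholds on the mean
#' sensitivity.
#'
#' @param sens Numeric matrix (specimens x metrics) of sensitivities with
#'   `NA` for censored specimen-metric pairs.
#' @param tier_thresholds Upper bounds of tiers 1 and 2 (percent loss).
#' @return Data frame with one row per metric: mean sensitivity, achieving
#'   counts, rank statistics and tier.
#' @export
cohort_summary <- function(sens, tier_thresholds = c(12, 20)) {
  sens <- as.matrix(sens)
  nm <- colnames(sens)
  n_spec <- nrow(sens)
  ranks <- t(apply(sens, 1, function(v) {
    key <- ifelse(is.na(v), Inf, v)
    rank(key, ties.method = "first")
  }))
  if (n_spec == 1L) ranks <- matrix(ranks, nrow = 1, dimnames = list(NULL, nm))
  mean_sens <- apply(sens, 2, function(v) if (all(is.na(v))) NA_real_ else
    mean(v, na.rm = TRUE))
  tier <- ifelse(is.na(mean_sens), NA_integer_,
                 ifelse(mean_sens < tier_thresholds[1], 1L,
                        ifelse(mean_sens < tier_thresholds[2], 2L, 3L)))
  data.frame(metric = nm,
             mean_sensitivity_pct = mean_sens,
             n_achieving = colSums(!is.na(sens)),
             n_total = n_spec,
             mean_rank = colMeans(ranks),
             sd_rank = apply(ranks, 2, stats::sd),
             rank_min = apply(ranks, 2, min),
             rank_max = apply(ranks, 2, max),
             tier = tier,
             row.names = NULL)
}

#' Metric sensitivity analysis under simulated capillary loss
#'
#' The top-level analysis. For every specimen the capillary skeleton graph is
#' extracted and randomized segment-dropout trials are run over the intended
#' loss grid; the thirteen metrics are computed on every rebuilt image. The
#' cohort's baseline metric sets define a normative mean +/- 2 SD band; each
#' specimen's trajectory is ratio-normalized to the cohort mean, z-scored,
#' and the per-metric sensitivity is the loss level at which the criterion
#' fraction of iterations (default 80%) falls outside the band.
#'
#' @param specimens A list of `synthetic_specimen` or `vessel_segmentation`
#'   objects (possibly mixed). Synthetic specimens are converted with
#'   [as_vessel_segmentation()] when `use = "truth"` or segmented from their
#'   grayscale image when `use = "segmentation"`.
#' @param sweep A [sweep_config()] object.
#' @param pica A [pica_config()] object.
#' @param seg_cfg A [segmentation_config()] used when `use = "segmentation"`.
#' @param use How to obtain the vessel segmentation of synthetic specimens.
#' @param criterion Required fraction of trials outside the band.
#' @param vci_norm VCI normalization constant.
#' @param progress Print one line per specimen.
#' @return An object of class `octa_sensitivity` with the baselines, the
#'   normative reference, per-specimen outside-band profiles and
#'   sensitivities, ranks, and the cohort summary. Methods: `print`,
#'   `summary`, `plot`.
#' @export
octa_sensitivity <- function(specimens, sweep = sweep_config(),
                             pica = pica_config(),
                             seg_cfg = segmentation_config(),
                             use = c("truth", "segmentation"),
                             criterion = 0.8, vci_norm = 1.6169,
                             progress = FALSE) {
  use <- match.arg(use)
  stopifnot(is.list(specimens), length(specimens) >= 2)
  nm <- octa_metric_names()
  n_spec <- length(specimens)
  levels <- sweep_levels(sweep)

  sweeps <- vector("list", n_spec)
  ids <- character(n_spec)
  baselines <- matrix(NA_real_, n_spec, length(nm), dimnames = list(NULL, nm))
  for (i in seq_len(n_spec)) {
    sp <- specimens[[i]]
    if (inherits(sp, "synthetic_specimen")) {
      ids[i] <- sp$specimen_id
      seg <- if (use == "truth") as_vessel_segmentation(sp) else
        segment_vessels(sp$gray, seg_cfg)
    } else if (inherits(sp, "vessel_segmentation")) {
      ids[i] <- sprintf("specimen_%03d", i)
      seg <- sp
    } else stop("unsupported specimen type")
    if (progress)
      message(sprintf("sweep %d/%d (%s)", i, n_spec, ids[i]))
    sw <- run_sweep(seg, sweep, pica, specimen_id = ids[i], vci_norm = vci_norm)
    baselines[i, ] <- sw$baseline[nm]
    sweeps[[i]] <- sw
  }
  rownames(baselines) <- ids

  ref <- build_reference(baselines)

  frac_outside <- vector("list", n_spec)
  sens <- matrix(NA_real_, n_spec, length(nm), dimnames = list(ids, nm))
  censored <- matrix(FALSE, n_spec, length(nm), dimnames = list(ids, nm))
  for (i in seq_len(n_spec)) {
    tr <- sweeps[[i]]$trials
    vals <- as.matrix(tr[nm])
    norm <- suppressWarnings(normalize_trajectory(baselines[i, ], vals, ref))
    out <- score_trials(norm, ref)$outside
    fo <- matrix(NA_real_, length(levels), length(nm),
                 dimnames = list(levels, nm))
    for (li in seq_along(levels)) {
      sel <- tr$intended_pct == levels[li]
      fo[li, ] <- colMeans(out[sel, , drop = FALSE], na.rm = FALSE)
    }
    frac_outside[[i]] <- fo
    for (j in seq_along(nm)) {
      if (!ref$usable[j] || ref$sd[j] == 0 || anyNA(fo[, j])) {
        censored[i, j] <- TRUE
        next
      }
      r <- specimen_sensitivity(fo[, j], levels, criterion)
      sens[i, j] <- r$sensitivity_pct
      censored[i, j] <- r$censored
    }
  }

  ranks <- t(apply(sens, 1, function(v)
    rank(ifelse(is.na(v), Inf, v), ties.method = "first")))

  structure(list(baselines = baselines,
                 reference = ref,
                 frac_outside = frac_outside,
                 sensitivity = sens,
                 censored = censored,
                 ranks = ranks,
                 cohort = cohort_summary(sens),
                 levels = levels,
                 criterion = criterion,
                 n_iter = sweep$n_iter,
                 trials = lapply(sweeps, function(s) s$trials),
                 specimen_ids = ids,
                 call = match.call()),
            class = "octa_sensitivity")
}

#' @export
print.octa_sensitivity <- function(x, ...) {
  cat(sprintf(
    "<octa_sensitivity> %d specimens, %d loss levels (%g-%g%%), %d iterations\n",
    nrow(x$sensitivity), length(x$levels), min(x$levels), max(x$levels),
    x$n_iter))
  co <- x$cohort[order(co_key <- ifelse(is.na(x$cohort$mean_sensitivity_pct),
                                        Inf, x$cohort$mean_sensitivity_pct)), ]
  cat("most sensitive metrics (cohort mean sensitivity, % loss):\n")
  for (i in seq_len(min(5, nrow(co))))
    cat(sprintf("  %-20s %6.2f%%  (tier %s, %d/%d achieving)\n",
                co$metric[i], co$mean_sensitivity_pct[i],
                ifelse(is.na(co$tier[i]), "-", co$tier[i]),
                co$n_achieving[i], co$n_total[i]))
  invisible(x)
}

#' @export
summary.octa_sensitivity <- function(object, ...) {
  co <- object$cohort
  co[order(ifelse(is.na(co$mean_sensitivity_pct), Inf,
                  co$mean_sensitivity_pct)), ]
}

#' Plot sensitivity profiles
#'
#' `type = "profile"` draws, per metric, the fraction of iterations outside
#' the normative band against intended loss (cohort mean across specimens)
#' with the criterion line; `type = "rank"` draws the cohort mean
#' sensitivity per metric.
#'
#' @param x An `octa_sensitivity` object.
#' @param type Plot type.
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.octa_sensitivity <- function(x, type = c("profile", "rank"), ...) {
  type <- match.arg(type)
  nm <- octa_metric_names()
  if (type == "profile") {
    fo <- Reduce(`+`, x$frac_outside) / length(x$frac_outside)
    graphics::matplot(x$levels, fo, type = "l", lty = 1,
                      col = grDevices::hcl.colors(length(nm), "Dark 3"),
                      xlab = "intended capillary loss (%)",
                      ylab = "fraction of trials outside +/- 2 SD", ...)
    graphics::abline(h = x$criterion, lty = 2)
    graphics::legend("bottomright", legend = nm, lty = 1, cex = 0.6,
                     col = grDevices::hcl.colors(length(nm), "Dark 3"))
  } else {
    co <- x$cohort
    o <- order(ifelse(is.na(co$mean_sensitivity_pct), Inf,
                      co$mean_sensitivity_pct))
    graphics::barplot(co$mean_sensitivity_pct[o], names.arg = co$metric[o],
                      las = 2, cex.names = 0.6,
                      ylab = "mean sensitivity (% capillary loss)", ...)
  }
  invisible(x)
}
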