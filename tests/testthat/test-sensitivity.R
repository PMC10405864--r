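mk_baselines <- function(...) {
  rows <- list(...)
  nm <- octa_metric_names()
  out <- matrix(NA_real_, length(rows), 13, dimnames = list(NULL, nm))
  for (i in seq_along(rows)) out[i, ] <- rows[[i]]
  out
}

test_that("the normative band matches hand-computed two-point statistics", {
  b <- mk_baselines(rep(0.48, 13), rep(0.50, 13))
  ref <- build_reference(b)
  expect_equal(unname(ref$mean["vessel_density"]), 0.49)
  expect_equal(unname(ref$sd["vessel_density"]), sqrt(2) * 0.01)
  expect_equal(unname(ref$lo["vessel_density"]), 0.49 - 2 * sqrt(2) * 0.01)
  expect_equal(unname(ref$hi["vessel_density"]), 0.49 + 2 * sqrt(2) * 0.01)
  expect_true(all(ref$usable))
})

test_that("identical baselines give a degenerate band with a warning", {
  b <- mk_baselines(rep(1, 13), rep(1, 13), rep(1, 13))
  expect_warning(ref <- build_reference(b), "degenerate")
  expect_true(all(ref$sd == 0))
  expect_error(build_reference(b[1, , drop = FALSE]), "at least two")
})

test_that("ratio normalization anchors every specimen at the cohort mean", {
  b <- mk_baselines(seq(1, 13), seq(2, 26, by = 2))
  ref <- build_reference(b)
  trials <- matrix(rep(b[2, ], each = 4), 4, 13,
                   dimnames = list(NULL, octa_metric_names()))
  norm <- normalize_trajectory(b[2, ], trials, ref)
  expect_equal(unname(norm[1, ]), unname(ref$mean))   # baseline -> mean exactly
  z <- score_trials(norm, ref)$z
  expect_true(all(z == 0))
  # baseline at twice the mean halves every trial value
  half <- normalize_trajectory(2 * ref$mean, trials, ref)
  expect_equal(half, trials / 2)
})

test_that("a zero baseline skips the metric with a warning", {
  b <- mk_baselines(rep(2, 13), rep(4, 13))
  ref <- build_reference(b)
  bad <- b[1, ]; bad["vci"] <- 0
  trials <- matrix(1, 2, 13, dimnames = list(NULL, octa_metric_names()))
  expect_warning(norm <- normalize_trajectory(bad, trials, ref), "vci")
  expect_true(all(is.na(norm[, "vci"])))
  expect_false(anyNA(norm[, "vpi"]))
})

test_that("the outside-band rule is strict at the boundary", {
  b <- mk_baselines(rep(1, 13), rep(3, 13))
  ref <- build_reference(b)     # mean 2, sd sqrt(2)
  nm <- octa_metric_names()
  vals <- matrix(rep(c(2, 2 + 2 * sqrt(2), 2 + 2.0001 * sqrt(2),
                       2 - 2 * sqrt(2), 2 - 2.1 * sqrt(2)), 13), 5, 13,
                 dimnames = list(NULL, nm))
  sc <- score_trials(vals, ref)
  expect_equal(unname(sc$outside[, 1]), c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(unname(sc$z[2, 1]), 2)
})

test_that("sensitivity interpolates the criterion crossing", {
  lv <- 1:20
  fo <- rep(0, 20); fo[13] <- 0.74; fo[14:20] <- 0.95
  r <- specimen_sensitivity(fo, lv)
  expect_false(r$censored)
  expect_equal(r$sensitivity_pct, 13 + (0.8 - 0.74) / (0.95 - 0.74))
  # first grid level already qualifying: sensitivity is the grid minimum
  r1 <- specimen_sensitivity(rep(1, 20), lv)
  expect_equal(r1$sensitivity_pct, 1)
  # never qualifying: censored
  rc <- specimen_sensitivity(rep(0.5, 20), lv)
  expect_true(rc$censored)
  expect_true(is.na(rc$sensitivity_pct))
  # non-interpolated variant reports the grid level
  rg <- specimen_sensitivity(fo, lv, interpolate = FALSE)
  expect_equal(rg$sensitivity_pct, 14)
})

test_that("cohort summary ranks metrics and handles censoring", {
  nm <- octa_metric_names()
  sens <- matrix(NA_real_, 2, 13, dimnames = list(NULL, nm))
  sens[1, ] <- c(5, 15, 21, rep(25, 10))
  sens[2, ] <- c(6, 13, 20, rep(25, 9), NA)
  co <- cohort_summary(sens)
  expect_equal(co$mean_rank[1:3], c(1, 2, 3))
  expect_equal(co$n_achieving[13], 1L)
  expect_equal(co$rank_max[13], 13L)      # censored ranks after all others
  expect_equal(co$tier[1:3], c(1L, 2L, 3L))
  all_cens <- matrix(NA_real_, 2, 13, dimnames = list(NULL, nm))
  co2 <- cohort_summary(all_cens)
  expect_true(all(is.na(co2$mean_sensitivity_pct)))
  expect_true(all(co2$n_achieving == 0))
})

test_that("planted band crossings are recovered within one grid step", {
  set.seed(42)
  nm <- octa_metric_names()
  levels <- 1:30
  n_spec <- 6; n_iter <- 40
  k_true <- c(5, 9, 14, 18, 22, 26, 7, 11, 15, 19, 23, 27, 12)
  baselines <- matrix(rep(10, n_spec * 13), n_spec, 13,
                      dimnames = list(NULL, nm))
  baselines <- baselines * matrix(runif(n_spec * 13, 0.9, 1.1), n_spec, 13)
  ref <- build_reference(baselines)
  sigma <- ref$sd * 0.05
  for (i in seq_len(n_spec)) {
    sens_i <- rep(NA_real_, 13)
    for (j in seq_len(13)) {
      fo <- vapply(levels, function(lv) {
        vals <- baselines[i, j] +
          ifelse(lv >= k_true[j], 3 * ref$sd[j] * baselines[i, j] / ref$mean[j], 0) +
          rnorm(n_iter, 0, sigma[j])
        m <- matrix(vals, n_iter, 1, dimnames = list(NULL, nm[j]))
        norm <- normalize_trajectory(stats::setNames(baselines[i, j], nm[j]),
                                     m, ref)
        mean(abs((norm - ref$mean[j]) / ref$sd[j]) > 2)
      }, 0)
      r <- specimen_sensitivity(fo, levels)
      sens_i[j] <- r$sensitivity_pct
    }
    expect_true(all(sens_i >= k_true - 1 & sens_i <= k_true))
  }
})

test_that("sensitivities are invariant to a cohort-wide metric rescaling", {
  set.seed(7)
  nm <- octa_metric_names()
  levels <- seq(2, 20, by = 2)
  base <- matrix(runif(4 * 13, 5, 15), 4, 13, dimnames = list(NULL, nm))
  sens_for <- function(scale) {
    b <- base; b[, "fd"] <- b[, "fd"] * scale
    ref <- build_reference(b)
    fo <- vapply(levels, function(lv) {
      vals <- matrix(b[1, "fd"] * (1 + 0.03 * lv), 30, 1,
                     dimnames = list(NULL, "fd"))
      norm <- normalize_trajectory(b[1, ], vals, ref)
      mean(abs((norm - ref$mean["fd"]) / ref$sd["fd"]) > 2)
    }, 0)
    specimen_sensitivity(fo, levels)$sensitivity_pct
  }
  expect_equal(sens_for(1), sens_for(37.5))
})

test_that("the assembled analysis is reproducible and self-consistent", {
  cohort <- generate_cohort(small_cohort(n = 3L, seed = 41L),
                            downsample_factor = 1L)
  sw <- sweep_config(pct_min = 10, pct_max = 30, pct_step = 10, n_iter = 8,
                     master_seed = 5)
  fit1 <- octa_sensitivity(cohort, sweep = sw, pica = small_pica(),
                           use = "truth")
  fit2 <- octa_sensitivity(cohort, sweep = sw, pica = small_pica(),
                           use = "truth")
  expect_identical(fit1$sensitivity, fit2$sensitivity)
  expect_identical(fit1$trials, fit2$trials)
  # baselines score exactly zero against the normalized reference
  for (i in 1:3) {
    norm <- normalize_trajectory(fit1$baselines[i, ],
                                 fit1$baselines[i, , drop = FALSE],
                                 fit1$reference)
    z <- score_trials(norm, fit1$reference)$z
    expect_true(all(z[is.finite(z)] == 0))
  }
  expect_s3_class(summary(fit1), "data.frame")
  expect_output(print(fit1), "octa_sensitivity")
})
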