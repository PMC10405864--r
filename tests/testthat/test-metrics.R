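test_that("vessel density and perimeter behave on canonical rasters", {
  expect_equal(vessel_density(matrix(TRUE, 8, 8)), 1)
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  expect_equal(vessel_density(half), 0.5)
  expect_equal(vessel_perimeter(matrix(TRUE, 3, 3)), 8)   # center excluded
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_equal(vessel_perimeter(one), 1)
  expect_equal(vessel_perimeter(matrix(FALSE, 5, 5)), 0)
  expect_equal(vpi(matrix(FALSE, 5, 5)), 0)
  expect_equal(vpi(one), 1 / 81)
})

test_that("a frame-filling circle scores a VCI of one", {
  v <- vci_norm_constant(304)
  d <- sqrt(outer((1:304 - 152)^2, (1:304 - 152)^2, "+")) <= 152
  expect_lt(abs(vci(d, norm_const = v) - 1), 1e-12)
  # and the canonical constant normalizes it to ~1 as well
  expect_lt(abs(vci(d) - 1), 0.02)
})

test_that("the VCI-VPI-density identity holds to machine precision", {
  for (seed in 1:5) {
    bw <- random_blobs(90, 110, p = 0.4, seed = seed)
    n <- length(bw)
    lhs <- vci(bw)
    rhs <- vpi(bw)^2 * n / (4 * pi * vessel_density(bw) * 1.6169)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("fractal dimension recovers canonical dimensions", {
  line <- matrix(FALSE, 512, 512); line[256, ] <- TRUE
  expect_lt(abs(fractal_dimension(line) - 1), 0.05)
  expect_equal(fractal_dimension(matrix(TRUE, 512, 512)), 2, tolerance = 1e-12)
  expect_true(is.na(fractal_dimension(matrix(FALSE, 16, 16))))
  for (seed in 1:3) {
    fd <- fractal_dimension(random_blobs(128, 128, p = 0.4, seed = seed))
    expect_gte(fd, 1); expect_lte(fd, 2)
  }
})

test_that("the FAZ is the center-containing nonperfused area", {
  bw <- matrix(TRUE, 100, 100)
  d <- sqrt(outer((1:100 - 50)^2, (1:100 - 50)^2, "+"))
  bw[d <= 17.8] <- FALSE    # central hole of ~1000 px
  faz <- find_faz(bw, c(50, 50))
  expect_false(faz$fallback)
  expect_equal(faz$area_px, sum(d <= 17.8))
  expect_setequal(faz$idx, which(d <= 17.8))
})

test_that("a center pixel on a vessel triggers the nearest-component fallback", {
  bw <- matrix(TRUE, 60, 60)
  bw[10:20, 10:20] <- FALSE
  expect_warning(faz <- find_faz(bw, c(30, 30)), "vessel")
  expect_true(faz$fallback)
  expect_equal(faz$area_px, 121)
  expect_error(find_faz(matrix(TRUE, 10, 10), c(5, 5)), "fully perfused")
})

test_that("PICA statistics follow the area threshold and SD conventions", {
  # two holes of exactly 100 and 300 px in a vessel field
  bw <- matrix(TRUE, 80, 80)
  bw[11:20, 11:20] <- FALSE                     # 100 px
  bw[41:60, 41:55] <- FALSE                     # 300 px
  pxa <- 2.5e-6
  st <- pica_stats(bw, NULL, pica_config(min_area_px2 = 51), TRUE, pxa)
  expect_equal(st$mean_mm2, 200 * pxa)
  expect_equal(st$sum_mm2, 400 * pxa)
  expect_equal(st$sd_mm2, sqrt(2) * 100 * pxa)  # 141.42 x pixel area, n-1
  expect_equal(st$regularity, st$mean_mm2 / st$sd_mm2)
  # population-SD convention
  stp <- pica_stats(bw, NULL, pica_config(min_area_px2 = 51,
                                          sd_denominator = "n"), TRUE, pxa)
  expect_equal(stp$sd_mm2, 100 * pxa)

  # threshold boundary: a 50-px region is excluded, a 51-px region included
  bw2 <- matrix(TRUE, 60, 120)
  bw2[11:15, 11:20] <- FALSE                    # 50 px
  bw2[31:33, 61:77] <- FALSE                    # 51 px
  st2 <- pica_stats(bw2, NULL, pica_config(min_area_px2 = 51), TRUE, 1)
  expect_equal(st2$sum_mm2, 51)
})

test_that("identical lattice holes give zero SD and undefined regularity", {
  bw <- matrix(TRUE, 90, 90)
  for (i in 0:2) for (j in 0:2)
    bw[(10 + 25 * i):(17 + 25 * i), (10 + 25 * j):(17 + 25 * j)] <- FALSE
  expect_warning(st <- pica_stats(bw, NULL, pica_config(min_area_px2 = 51),
                                  TRUE, 1), "regularity")
  expect_equal(st$mean_mm2, 64)
  expect_equal(st$sum_mm2, 9 * 64)
  expect_equal(st$sd_mm2, 0)
  expect_true(is.na(st$regularity))
})

test_that("the full battery returns thirteen coherent metrics", {
  sp <- small_specimen(seed = 3)
  m <- compute_all(sp$truth_binary, sp$center_xy, sp$px_area_mm2, small_pica())
  expect_named(m, octa_metric_names())
  expect_false(anyNA(m))
  expect_equal(unname(m["faz_area_mm2"]), sp$truth_faz_area_mm2)
  expect_gte(m[["pica_sum_mm2"]], m[["nf_pica_sum_mm2"]])
  # all-foreground image: density 1, everything FAZ/PICA undefined
  mf <- compute_all(matrix(TRUE, 40, 40), c(20, 20), 1)
  expect_equal(unname(mf["vessel_density"]), 1)
  expect_true(all(is.na(mf[c("faz_area_mm2", "pica_mean_mm2", "pica_sum_mm2")])))
})

test_that("fast-path metrics agree with the standalone R implementations", {
  for (seed in 1:4) {
    bw <- random_blobs(120, 130, p = 0.55, seed = seed)
    center <- c(65, 60)
    pxa <- 3e-6
    cfg <- pica_config(min_area_px2 = 20)
    m <- compute_all(bw, center, pxa, cfg)
    expect_equal(unname(m["vessel_density"]), vessel_density(bw))
    expect_equal(unname(m["vpi"]), vpi(bw))
    expect_equal(unname(m["vci"]), vci(bw))
    expect_equal(unname(m["fd"]), fractal_dimension(bw), tolerance = 1e-10)
    faz <- suppressWarnings(find_faz(bw, center, cfg$connectivity))
    expect_equal(unname(m["faz_area_mm2"]), faz$area_px * pxa)
    st <- suppressWarnings(pica_stats(bw, faz, cfg, TRUE, pxa))
    expect_equal(unname(m["pica_mean_mm2"]), st$mean_mm2)
    expect_equal(unname(m["pica_sd_mm2"]), st$sd_mm2)
    stx <- suppressWarnings(pica_stats(bw, faz, cfg, FALSE, pxa))
    expect_equal(unname(m["nf_pica_sum_mm2"]), stx$sum_mm2)
    expect_equal(unname(m["nf_pica_regularity"]), stx$regularity)
  }
})

test_that("background areas and vessel pixels conserve the image area", {
  for (seed in 1:6) {
    bw <- random_blobs(100, 100, p = 0.5, seed = seed)
    all_bg <- pica_stats(bw, NULL, pica_config(min_area_px2 = 0), TRUE, 1)
    expect_equal(all_bg$sum_mm2 + sum(bw), length(bw))
    # with exclusions the summed area can only shrink
    some <- pica_stats(bw, NULL, pica_config(min_area_px2 = 30), TRUE, 1)
    expect_lte(some$sum_mm2, all_bg$sum_mm2)
  }
})

test_that("summed intercapillary area and vessel density are exact inverses", {
  bw <- random_blobs(80, 80, p = 0.5, seed = 9)
  s0 <- pica_stats(bw, NULL, pica_config(min_area_px2 = 0), TRUE, 1)$sum_mm2
  flip <- bw; flip[40, 40] <- !flip[40, 40]
  s1 <- pica_stats(flip, NULL, pica_config(min_area_px2 = 0), TRUE, 1)$sum_mm2
  dv <- (vessel_density(flip) - vessel_density(bw)) * length(bw)
  expect_equal(s1 - s0, -dv)
})

test_that("loss simulation moves density down and the FAZ up", {
  sp <- small_specimen(seed = 16)
  seg <- as_vessel_segmentation(sp)
  g <- skeleton_to_graph(seg$capillary_skeleton)
  met <- function(pct, s) {
    r <- remove_segments_until(g, pct, seed = s)
    bw <- rebuild_binary(seg$full_skeleton, r, seg$large_mask, seg$dilate_radius)
    compute_all(bw, seg$center_xy, seg$px_area_mm2, small_pica())
  }
  base <- compute_all(rebuild_binary(seg$full_skeleton, integer(0),
                                     seg$large_mask, seg$dilate_radius),
                      seg$center_xy, seg$px_area_mm2, small_pica())
  for (s in 1:3) {
    m25 <- met(25, s)
    expect_lt(m25[["vessel_density"]], base[["vessel_density"]])
    expect_gte(m25[["faz_area_mm2"]], base[["faz_area_mm2"]])
  }
})
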