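# a standardized-scale gray image from a flat background with bright shapes
flat_img <- function(n = 64, bg = 0, pitch = 2380 / 304) {
  gray_image(matrix(bg, n, n), pitch)
}

# config for tests that feed analysis-scale images directly
noup <- function(...) segmentation_config(upsample_factor = 1L, ...)

test_that("preprocessing honors the dual threshold and the analysis scale", {
  sp <- generate_network(network_params(noise_level = 0.05), seed = 3)
  pre <- preprocess_intensity(sp$gray)
  expect_equal(dim(pre$pixels), c(1824L, 1824L))   # 6 x 304
  px <- pre$pixels
  expect_false(any(px > 0 & px < 20))       # below dual_lo crushed to 0
  expect_false(any(px > 35 & px < 255))     # above dual_hi saturated to 255
  expect_equal(pre$fovea_xy, sp$gray$fovea_xy * 6)
})

test_that("constant input degenerates with a warning", {
  img <- flat_img(32, bg = 77)
  expect_warning(pre <- preprocess_intensity(img), "constant")
  expect_true(all(pre$pixels == 77))
  expect_equal(dim(pre$pixels), c(192L, 192L))
})

test_that("a bright ridge is segmented at the canonical capillary caliber", {
  n <- 101
  m <- matrix(0, n, n)
  m[, 46:54] <- 255                   # 9-px-wide vertical ridge
  pre <- gray_image(m, 1)
  out <- segment_small_vessels(pre, noup())
  lab <- cpp_label(out, 8L)
  expect_equal(max(lab), 1L)
  # medial skeleton dilated by disk r=5: width 11 away from the ends
  widths <- rowSums(out)
  expect_equal(stats::median(widths[20:80]), 11)
})

test_that("small skeleton debris is removed, large ridges survive", {
  n <- 120
  m <- matrix(0, n, n)
  m[, 20:28] <- 255
  m[60:62, 80:84] <- 255             # thins to <= 10 px -> removed
  out <- segment_small_vessels(gray_image(m, 1), noup())
  expect_false(any(out[, 70:120]))
  expect_true(any(out[, 15:35]))
})

test_that("uniform input yields an empty small-vessel segmentation", {
  expect_warning(out <- segment_small_vessels(flat_img(64, bg = 128), noup()),
                 "empty")
  expect_false(any(out))
})

test_that("large-vessel segmentation applies the component-size floor exactly", {
  n <- 200
  m <- matrix(0, n, n)
  m[11:30, 11:160] <- 255            # 20 x 150 = 3000 px -> retained
  m[101:120, 11:160] <- 255
  m[120, 160] <- 0                   # 2999 px -> removed
  out <- segment_large_vessels(gray_image(m, 1), noup())
  expect_true(all(out[11:30, 11:160]))
  expect_false(any(out[101:120, 11:160]))
})

test_that("an image at or below the intensity floor segments to nothing", {
  m <- matrix(0, 80, 80)
  m[10:70, 30:50] <- 30              # never exceeds the floor (> 30 required)
  out <- segment_large_vessels(gray_image(m, 1), noup())
  expect_false(any(out))
})

test_that("FAZ cleanup deletes isolated blobs but keeps attached ones", {
  n <- 120
  small <- matrix(FALSE, n, n)
  # a ring of vessels enclosing the center
  d <- sqrt(outer((1:n - 60)^2, (1:n - 60)^2, "+"))
  small[d >= 40 & d <= 46] <- TRUE
  large <- matrix(FALSE, n, n)
  clean0 <- combine_and_clean_faz(small, large, c(60, 60), noup())
  expect_identical(clean0, small | large)   # nothing to clean

  blob <- small
  blob[80:83, 55:59] <- TRUE                # isolated 20-px blob inside FAZ
  cleaned <- combine_and_clean_faz(blob, large, c(60, 60),
                                   noup(faz_clean_max_blob_px = 100))
  expect_false(any(cleaned[80:83, 55:59]))
  expect_identical(cleaned, small)

  attached <- small
  attached[16:83, 58] <- TRUE               # bridge touching the rim
  kept <- combine_and_clean_faz(attached, large, c(60, 60),
                                noup(faz_clean_max_blob_px = 1e5))
  expect_identical(kept, attached)
})

test_that("the arteriole/venule mask filters by size then dilates", {
  n <- 300
  m <- matrix(0, n, n)
  m[3, 1:300] <- 255                 # 300 px
  m[4, 1:100] <- 255                 # 400 px component -> removed
  m2 <- matrix(0, n, n)
  m2[150, 1:300] <- 255
  m2[151, 1:101] <- 255              # 401 px component -> retained
  expect_false(any(make_large_vessel_mask(gray_image(m, 1), noup())))
  mask <- make_large_vessel_mask(gray_image(m2, 1), noup())
  expect_true(any(mask))
  # 1-px-wide retained line dilates to 13 px (r = 6)
  expect_equal(max(colSums(mask[, 150:250])), 13)
})

test_that("skeletons are one pixel wide and respect the mask", {
  bar <- matrix(FALSE, 60, 120)
  bar[25:35, 10:110] <- TRUE
  sk <- make_skeletons(bar, matrix(FALSE, 60, 120))
  expect_true(all(bar[sk$full_skeleton]))
  expect_lte(max(colSums(sk$full_skeleton)[20:100]), 1)
  all_mask <- make_skeletons(bar, matrix(TRUE, 60, 120))
  expect_false(any(all_mask$capillary_skeleton))
})

test_that("segmentation is deterministic and reconstruction stays in bounds", {
  sp <- small_specimen(seed = 12)
  seg1 <- as_vessel_segmentation(sp)
  seg2 <- as_vessel_segmentation(sp)
  expect_identical(seg1$full_skeleton, seg2$full_skeleton)
  # reconstruction closure: rebuilt capillaries + mask within dilated binary
  recon <- cpp_dilate_disk(seg1$capillary_skeleton, seg1$dilate_radius) |
    seg1$large_mask
  bound <- cpp_dilate_disk(seg1$binary, seg1$dilate_radius)
  expect_true(all(bound[recon]))
})

test_that("full-scale segmentation recovers the truth vasculature", {
  sp <- generate_network(network_params(noise_level = 0), seed = 21)
  seg <- segment_vessels(sp$gray)
  rec <- rebuild_binary(seg$full_skeleton, integer(0), seg$large_mask,
                        seg$dilate_radius)
  recall <- sum(rec & sp$truth_binary) / sum(sp$truth_binary)
  expect_gt(recall, 0.95)
  # recovered vessel density within 2 percentage points of ground truth
  expect_lt(abs(mean(rec) - mean(sp$truth_binary)), 0.02)
})
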