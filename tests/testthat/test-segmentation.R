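test_that("k-means body mask recovers the body to within 1 %", {
  fx <- seg_fixture(seed = 5)
  bm <- body_mask(fx$in_phase, seed = 1)
  truth <- fx$labels > 0
  expect_gt(mean(bm$mask[truth]), 0.99)    # sensitivity
  expect_lt(mean(bm$mask[!truth]), 0.01)   # background leak
  expect_error(body_mask(matrix(0, 64, 64)), "foreground")
  bm2 <- body_mask(fx$in_phase, seed = 1)
  expect_identical(bm$mask, bm2$mask)
})

test_that("active contour locks onto the inner SAT edge", {
  fx <- seg_fixture(seed = 5)
  bm <- body_mask(fx$in_phase, seed = 1)
  inner <- inner_sat_boundary(fx$in_phase, bm$outer_contour)
  expect_true(inner$converged)
  # true inner edge: interior pixels with a SAT 4-neighbour
  lab <- fx$labels
  interior <- matrix(lab %in% c(2L, 3L, 4L), nrow(lab), ncol(lab))
  sat <- lab == 1L
  sat_nb <- rbind(sat[-1, ], FALSE) | rbind(FALSE, sat[-nrow(sat), ]) |
    cbind(sat[, -1], FALSE) | cbind(FALSE, sat[, -ncol(sat)])
  edge <- which(interior & sat_nb, arr.ind = TRUE) - 1  # 0-based
  dmin <- vapply(seq_len(nrow(inner$contour)), function(i)
    sqrt(min((edge[, 1] - inner$contour[i, 1])^2 +
             (edge[, 2] - inner$contour[i, 2])^2)), numeric(1))
  expect_gte(mean(dmin <= 2), 0.95)
})

test_that("higher snake smoothness gives non-increasing contour length", {
  fx <- seg_fixture(seed = 5)
  bm <- body_mask(fx$in_phase, seed = 1)
  lens <- vapply(c(0.1, 0.25, 0.4, 0.6), function(w)
    adipoquant:::poly_length(
      inner_sat_boundary(fx$in_phase, bm$outer_contour, smoothness = w)$contour),
    numeric(1))
  expect_true(all(diff(lens) <= 1e-9))
})

test_that("region growing covers VAT from blob seeds and rejects lean seeds", {
  fx <- seg_fixture(seed = 4)
  bm <- body_mask(fx$in_phase, seed = 1)
  inner <- inner_sat_boundary(fx$in_phase, bm$outer_contour)
  lab <- fx$labels
  vat <- which(lab == 2L, arr.ind = TRUE)
  set.seed(1)
  km <- stats::kmeans(vat, centers = 4, nstart = 5)
  seeds <- round(km$centers) - 1
  vr <- vat_region(fx$in_phase, inner$contour, seeds = seeds)
  expect_gt(mean(vr$mask[lab == 2L]), 0.99)
  # a seed in lean tissue grows a sub-threshold region and is excluded
  lean <- which(lab == 3L & fx$in_phase < 60, arr.ind = TRUE)
  mid <- lean[which.min(rowSums((lean - 48)^2)), ]
  vr2 <- vat_region(fx$in_phase, inner$contour, seeds = matrix(mid - 1, 1))
  expect_equal(vr2$excluded_seeds, 1L)
  expect_false(any(vr2$mask))
  # degenerate interior: a tiny polygon holds no pixels
  tiny <- cbind(c(0.1, 0.4, 0.4, 0.1), c(0.1, 0.1, 0.4, 0.4))
  vr3 <- vat_region(fx$in_phase, tiny, seeds = NULL)
  expect_false(any(vr3$mask))
  # no seeds: the whole interior is the candidate region
  vr4 <- vat_region(fx$in_phase, inner$contour, seeds = NULL)
  expect_true(all(vr4$mask == vr4$interior))
})

test_that("contour correction repairs defects, is idempotent and validates input", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- cbind(40 + 20 * cos(th), 40 + 20 * sin(th))
  defect <- circ
  defect[10:19, ] <- cbind(40 + 26 * cos(th[10:19]), 40 + 26 * sin(th[10:19]))
  repl <- circ[9:20, ]
  fixed <- apply_correction(defect, repl)
  expect_identical(attr(fixed, "provenance"), "corrected")
  radial <- abs(sqrt((fixed[, 1] - 40)^2 + (fixed[, 2] - 40)^2) - 20)
  expect_lt(max(radial), 1)
  # idempotence: same point set after a second application
  again <- apply_correction(fixed, repl)
  ord <- function(m) m[order(m[, 1], m[, 2]), ]
  expect_equal(ord(unclass(fixed)), ord(unclass(again)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # identity replacement leaves the contour unchanged
  same <- apply_correction(circ, circ[9:20, ])
  expect_equal(ord(unclass(same)), ord(circ), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(apply_correction(circ, rbind(c(80, 80), c(85, 85))),
               "not on the contour")
})

test_that("histogram fat area is exact for separable classes and conserves area", {
  img <- matrix(10, 40, 40)
  img[1:40, 1:15] <- 100                 # 600 fat pixels
  mask <- matrix(TRUE, 40, 40)
  res <- histogram_fat_area(img, mask, pixel_area_cm2 = 0.16)
  expect_equal(res$fat_pixels, 600)
  expect_equal(res$fat_area_cm2, 600 * 0.16)
  # all-lean region: fat area below 1 % of the region
  fx <- seg_fixture(seed = 6)
  lean_mask <- fx$labels == 3L
  dim(lean_mask) <- dim(fx$labels)
  res2 <- histogram_fat_area(fx$in_phase, lean_mask, 0.16)
  expect_lt(res2$fat_pixels, 0.01 * sum(lean_mask))
  # conservation on mixed regions
  body <- fx$labels > 0; dim(body) <- dim(fx$labels)
  res3 <- histogram_fat_area(fx$in_phase, body, 0.16)
  expect_lte(res3$fat_pixels, sum(body))
  expect_gte(res3$fat_pixels, 0)
  expect_error(histogram_fat_area(fx$in_phase, matrix(FALSE, 96, 96), 0.16),
               "empty")
})

test_that("histogram fat area tracks the true fat count under noise", {
  fx <- seg_fixture(seed = 9)
  bm <- body_mask(fx$in_phase, seed = 1)
  inner <- inner_sat_boundary(fx$in_phase, bm$outer_contour)
  vr <- vat_region(fx$in_phase, inner$contour)
  res <- histogram_fat_area(fx$in_phase, vr$mask, 0.16)
  true_fat <- sum(fx$labels == 2L & vr$mask)
  expect_lt(abs(res$fat_pixels - true_fat) / true_fat, 0.02)
})

test_that("slice-stack volumetry arithmetic is exact", {
  v <- fat_volume_from_areas(rep(100, 5), 10, 0.5)
  expect_identical(v$total_volume_l, 0.525)
  expect_error(fat_volume_from_areas(c(100, -1)), "non-negative")
})

test_that("end-to-end volume recovery stays within a few percent", {
  errs <- vapply(1:6, function(s) {
    ph <- make_phantom(96, 96, 2, seed = s)
    io <- simulate_in_opposed(ph, acquisition_spec("in_opposed",
                                                   noise_sigma = 1.6,
                                                   seed = s))
    vol <- total_vat_volume(io, segment_slices(io, seed = 1))
    100 * (vol$total_volume_l - ph$true_vat_volume_l) / ph$true_vat_volume_l
  }, numeric(1))
  expect_lt(stats::median(abs(errs)), 3)
  expect_lt(max(abs(errs)), 8)
})

test_that("volumetry validates its slice range", {
  fx <- seg_fixture(seed = 3, nslices = 2)
  cs <- segment_slices(fx$series, seed = 1)
  expect_error(total_vat_volume(fx$series, cs[1], slice_range = 0:1),
               "slice")
  expect_error(total_vat_volume(fx$series, cs, slice_range = integer(0)),
               "empty")
  v <- total_vat_volume(fx$series, cs)
  expect_length(v$per_slice_fat_area_cm2, 2)
})
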