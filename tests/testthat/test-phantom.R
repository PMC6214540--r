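test_that("phantom VAT volume matches the voxel-count identity", {
  ph <- make_phantom(64, 64, 5, n_vat_blobs = 1, vat_blob_radius_px = 10,
                     spacing_mm = 4, seed = 2)
  n_vat <- sum(ph$labels == 2L)
  expect_equal(ph$true_vat_volume_l, n_vat * 16 * 10.5 / 1e6)
  # rasterised circle of radius 10 per slice, 5 slices
  expect_gt(n_vat, 0.9 * 5 * pi * 100)
  expect_lt(n_vat, 1.1 * 5 * pi * 100)
})

test_that("phantom generation is deterministic per seed and validates geometry", {
  a <- make_phantom(64, 64, 2, seed = 11)
  b <- make_phantom(64, 64, 2, seed = 11)
  expect_identical(a$labels, b$labels)
  expect_error(make_phantom(16, 16, 1), "32 x 32")
  expect_error(make_phantom(64, 64, 1, sat_ring_frac = 0), "SAT ring")
  expect_error(make_phantom(64, 64, 1, vat_blob_radius_px = 30),
               "cannot fit")
})

test_that("SAT ring is closed and encloses the VAT blobs", {
  ph <- make_phantom(96, 96, 1, seed = 3)
  lab <- ph$labels[, , 1]
  # walking out from any VAT pixel along +x must cross SAT before background
  vat <- which(lab == 2L, arr.ind = TRUE)
  for (i in seq_len(min(25, nrow(vat)))) {
    row <- lab[vat[i, 1]:96, vat[i, 2]]
    first_bg <- which(row == 0L)[1]
    expect_true(any(row[seq_len(first_bg)] == 1L))
  }
  expect_true(all(unique(as.vector(lab)) %in% ph$tissue_table$label))
})

test_that("randomised blob placement keeps VAT volume near nominal", {
  vols <- vapply(1:100, function(s) {
    ph <- make_phantom(64, 64, 1, n_vat_blobs = 3, vat_blob_radius_px = 6,
                       seed = s)
    ph$true_vat_volume_l / ph$nominal_vat_volume_l
  }, numeric(1))
  expect_true(all(vols >= 0.8 & vols <= 1.2))
})

test_that("IR simulation follows the saturation-corrected forward model", {
  tt <- default_tissue_table()
  tt$t1_ms[tt$name == "VAT"] <- 300
  ph <- make_phantom(64, 64, 1, tissue_table = tt, seed = 1)
  vat1 <- which(ph$labels[, , 1] == 2L, arr.ind = TRUE)[1, ]
  # null point of the ideal IR curve, up to the saturation term
  ti_null <- 300 * log(2)
  acq <- acquisition_spec("inversion_recovery",
                          ti_list_ms = c(ti_null, 500, 750, 1000),
                          noise_sigma = 0)
  ir <- simulate_ir_series(ph, acq)
  s0 <- tt$proton_density[tt$name == "VAT"]
  expect_lt(ir$images[vat1[1], vat1[2], 1, 1], 1e-3 * s0)
  # long-TI asymptote: signal -> S0 (1 + e^(-TSAT/T1))
  acq2 <- acquisition_spec("inversion_recovery",
                           ti_list_ms = c(100, 500, 1000, 4499.9),
                           noise_sigma = 0)
  ir2 <- simulate_ir_series(ph, acq2)
  expect_equal(ir2$images[vat1[1], vat1[2], 1, 4],
               s0 * abs(1 - 2 * exp(-4499.9 / 300) + exp(-4500 / 300)),
               tolerance = 1e-10)
})

test_that("Dixon simulation degenerates correctly at FF = 0 and FF = 100", {
  tt <- default_tissue_table()
  tt$fat_fraction_pct[tt$name == "VAT"] <- 0
  tt$fat_fraction_pct[tt$name == "SAT"] <- 100
  ph <- make_phantom(64, 64, 1, tissue_table = tt, seed = 1)
  dx <- simulate_dixon_series(ph, acquisition_spec("multiecho_dixon",
                                                   noise_sigma = 0))
  lab <- ph$labels[, , 1]
  v <- which(lab == 2L, arr.ind = TRUE)[1, ]
  s <- which(lab == 1L, arr.ind = TRUE)[1, ]
  te <- dx$index_ms
  t2 <- tt$t2star_ms[tt$name == "VAT"]
  pd <- tt$proton_density[tt$name == "VAT"]
  expect_equal(dx$images[v[1], v[2], 1, ], pd * exp(-te / t2),
               tolerance = 1e-12)
  expect_equal(dx$images[s[1], s[2], 1, ],
               tt$proton_density[tt$name == "SAT"] *
                 exp(-te / tt$t2star_ms[tt$name == "SAT"]),
               tolerance = 1e-12)
})

test_that("in-phase echo adds water and fat amplitudes", {
  # FF = 85 voxel at the exactly-in-phase echo TE = 1/delta_f
  df <- 220
  te_ip <- 1000 / df
  tt <- default_tissue_table()
  ph <- make_phantom(64, 64, 1, tissue_table = tt, seed = 1)
  acq <- acquisition_spec("multiecho_dixon",
                          te_list_ms = te_ip * (1:4) / 2,  # uniform spacing
                          delta_f_hz = df, noise_sigma = 0)
  dx <- simulate_dixon_series(ph, acq)
  v <- which(ph$labels[, , 1] == 2L, arr.ind = TRUE)[1, ]
  pd <- tt$proton_density[tt$name == "VAT"]
  t2 <- tt$t2star_ms[tt$name == "VAT"]
  # echoes 2 and 4 are in-phase (cos = 1): signal = (W + F) e^(-TE/T2*)
  expect_equal(dx$images[v[1], v[2], 1, 2], pd * exp(-te_ip / t2),
               tolerance = 1e-12)
  expect_equal(dx$images[v[1], v[2], 1, 4], pd * exp(-2 * te_ip / t2),
               tolerance = 1e-12)
})

test_that("in/opposed series gives segmentable fat-lean contrast", {
  fx <- seg_fixture(seed = 7)
  fat <- fx$in_phase[fx$labels %in% c(1L, 2L)]
  lean <- fx$in_phase[fx$labels == 3L]
  sigma <- 1.6
  gap <- stats::quantile(fat, 0.05) - stats::quantile(lean, 0.95)
  expect_gt(gap, 3 * sigma)
  # FF = 50 tissue cancels on the opposed-phase echo
  tt <- default_tissue_table()
  tt$fat_fraction_pct[tt$name == "VAT"] <- 50
  ph <- make_phantom(64, 64, 1, tissue_table = tt, seed = 1)
  # TE1 chosen exactly at the opposed-phase condition for the series' df
  df <- 220
  acq <- acquisition_spec("in_opposed", te_list_ms = c(500 / df, 1000 / df),
                          delta_f_hz = df, noise_sigma = 0)
  io <- simulate_in_opposed(ph, acq)
  v <- which(ph$labels[, , 1] == 2L, arr.ind = TRUE)[1, ]
  expect_lt(io$images[v[1], v[2], 1, 1], 1e-10)
  # pure-water tissue: in/opposed ratio is just the T2* decay factor
  tt$fat_fraction_pct[tt$name == "lean"] <- 0
  ph2 <- make_phantom(64, 64, 1, tissue_table = tt, seed = 1)
  io2 <- simulate_in_opposed(ph2, acq)
  l <- which(ph2$labels[, , 1] == 3L, arr.ind = TRUE)[1, ]
  t2l <- tt$t2star_ms[tt$name == "lean"]
  expect_equal(io2$images[l[1], l[2], 1, 2] / io2$images[l[1], l[2], 1, 1],
               exp(-(acq$te_list_ms[2] - acq$te_list_ms[1]) / t2l),
               tolerance = 1e-10)
})

test_that("Rician noise has the right background mean and high-SNR limit", {
  img <- array(0, dim = c(100, 100, 100))  # 1e6 samples
  noisy <- add_rician_noise(img, sigma = 1, seed = 42)
  expect_equal(mean(noisy), sqrt(pi / 2), tolerance = 0.01)
  hi <- add_rician_noise(array(50, dim = c(100, 100, 10)), sigma = 1,
                         seed = 42)
  expect_equal(mean(hi), 50, tolerance = 0.002 * 50)
  expect_identical(add_rician_noise(img, 0), img)
  expect_error(add_rician_noise(img, -1), "non-negative")
  expect_identical(add_rician_noise(img[1:5, 1:5, 1], 2, seed = 9),
                   add_rician_noise(img[1:5, 1:5, 1], 2, seed = 9))
})

test_that("cohort generator honours means, shifts and determinism", {
  null_spec <- data.frame(parameter = "bmi_kg_m2", m0_mean = 45, m0_sd = 5,
                          shift_mean_pct = 0, shift_sd_pct = 2)
  co <- make_cohort(10000, null_spec, seed = 1)
  m0 <- co$bmi_kg_m2[co$timepoint == "M0"]
  m1 <- co$bmi_kg_m2[co$timepoint == "M1"]
  expect_lt(abs(mean(percent_change(m0, m1))), 0.5)
  expect_identical(make_cohort(23, seed = 4), make_cohort(23, seed = 4))
  tiny <- make_cohort(3, seed = 1)
  expect_equal(nrow(tiny), 6)
  expect_true(all(tiny$bmi_kg_m2 > 0))
  bad <- default_effect_spec(); bad$m0_sd[1] <- 0
  expect_error(make_cohort(23, bad), "positive")
  expect_error(make_cohort(2), "at least 3")
})

test_that("cohort generator recovers the dominant effect directions at n = 23", {
  spec <- default_effect_spec()
  big <- c("bmi_kg_m2", "v_vat_l")
  hits <- sapply(1:200, function(s) {
    co <- make_cohort(23, spec, seed = s)
    sapply(big, function(p) {
      pc <- percent_change(co[[p]][co$timepoint == "M0"],
                           co[[p]][co$timepoint == "M1"])
      sign(mean(pc)) == sign(spec$shift_mean_pct[spec$parameter == p])
    })
  })
  expect_true(all(rowMeans(hits) >= 0.8))
})
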