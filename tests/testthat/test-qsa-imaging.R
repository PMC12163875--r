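test_that("block averages follow the min-valid rule", {
  v <- c(rep(0.5, 8), NaN, NaN, NaN, NaN, NaN, 0.2, 0.3, 0.1)
  b <- block_average(v, 1, 8)
  expect_equal(b$mean, 0.5)
  expect_false(b$empty)
  # 3 valid of 8 -> empty under the default min_valid = 4
  b2 <- block_average(v, 9, 8)
  expect_true(b2$empty)
  expect_true(is.nan(b2$mean))
  b3 <- block_average(v, 9, 8, min_valid = 3)
  expect_equal(b3$mean, 0.2)
  expect_error(block_average(v, 1, 0), "width")
})

test_that("sliding windows enumerate complete solvent triplets", {
  sch <- test_scheme()
  lm6 <- data.frame(solvent_id = rep(c("s1", "s2", "s3"), 2),
                    y_position = (0:5) * 150)
  wins <- window_triplets(lm6, sch)
  expect_length(wins, 4)   # starts 1..4, each a permutation of s1/s2/s3
  expect_equal(wins[[1]], 1:3)
  expect_equal(wins[[2]], c(4, 2, 3))  # reordered to ascending addition
  # degenerate pattern: no complete window
  lm_bad <- data.frame(solvent_id = rep("s1", 3), y_position = (0:2) * 150)
  expect_warning(w0 <- window_triplets(lm_bad, sch), "skipped")
  expect_length(w0, 0)
  # non-overlap mode steps by the window height
  wins_no <- window_triplets(lm6, sch, overlap = FALSE)
  expect_length(wins_no, 2)
})

test_that("noiseless piecewise-constant phantom is recovered exactly", {
  # truth and suppression constant within each window column so the
  # window-averaged truth is the exact regression answer
  n_l <- 6; n_px <- 16
  conc <- matrix(rep(c(4, 12), each = 8), n_l, n_px, byrow = TRUE)
  supp <- matrix(rep(c(0.4, 0.9), each = 8), n_l, n_px, byrow = TRUE)
  # tiny gain: analyte is a vanishing TIC fraction, so TIC normalization
  # cannot distort the affine response
  ph <- manual_phantom(conc, supp, gain = 1e-6, bg_intensity = 1e6)
  sch <- test_scheme(lo = 10, hi = 20)
  lss <- simulate_linescans(ph, sch, rep(c("s1", "s2", "s3"), 2),
                            noise_model(0, 0, seed = 1), mz_jitter_ppm = 0)
  cube <- build_cube(lss, align_features(lss), sch,
                     compute_geometry(0.04, 1.96, 150))
  qi <- sliding_qsa(cube, 148.0604, sch)
  wins <- window_triplets(cube$line_meta, sch)
  bt <- window_truth(conc, wins, ncol(qi$conc))
  quant <- qi$flags %in% c(FLAG_OK, FLAG_LOF_FAIL)
  expect_true(all(quant))
  expect_lt(max(abs(qi$conc - bt) / bt), 1e-9)
  # noiseless extrapolation uncertainty vanishes
  expect_lt(max(qi$sd), 1e-9)
})

test_that("output raster geometry matches the reading-frame contract", {
  sim <- test_simulation(n_lines = 9, width_px = 40, cv = 0.05, seed = 2,
                         n_background = 10)
  cube <- build_cube(sim$linescans, align_features(sim$linescans),
                     sim$scheme, compute_geometry(0.04, 1.96, 150))
  qi <- suppressWarnings(sliding_qsa(cube, 148.0604, sim$scheme))
  expect_equal(nrow(qi$conc), 7)            # 9 lines, overlapping triplets
  expect_equal(ncol(qi$conc), 40 %/% 8)     # non-overlapping 8-px blocks
  expect_equal(qi$geometry$out_dx, 8 * 1000 * 0.04 / 1.96)
  expect_equal(qi$geometry$out_dy, 150)
  expect_equal(diff(qi$y_positions), rep(150, 6))
})

test_that("window responses rescaled by a common factor leave qSA unchanged", {
  sim <- test_simulation(n_lines = 3, width_px = 24, cv = 0.1, seed = 9,
                         n_background = 10)
  cube <- build_cube(sim$linescans, align_features(sim$linescans),
                     sim$scheme)
  qi1 <- sliding_qsa(cube, 148.0604, sim$scheme)
  for (c_scale in c(1e-3, 0.5, 7, 1e4)) {
    cube2 <- cube
    cube2$values <- cube$values * c_scale
    qi2 <- sliding_qsa(cube2, 148.0604, sim$scheme)
    sel <- qi1$flags %in% c(FLAG_OK, FLAG_LOF_FAIL)
    expect_lt(max(abs(qi2$conc[sel] - qi1$conc[sel]) / qi1$conc[sel]),
              1e-9)
    expect_identical(qi1$flags, qi2$flags)
  }
})

test_that("a feature with no signal anywhere is flagged, never quantified", {
  sim <- test_simulation(n_lines = 3, width_px = 16, cv = 0, seed = 2,
                         n_background = 5)
  cube <- build_cube(sim$linescans, align_features(sim$linescans),
                     sim$scheme)
  fidx <- qsaMSI:::match_feature(cube$feature_axis, 148.0604)
  cube$values[, , fidx] <- 0
  qi <- sliding_qsa(cube, 148.0604, sim$scheme)
  expect_true(all(qi$flags %in% c(FLAG_NEG_SLOPE, FLAG_EMPTY)))
  expect_true(all(is.nan(qi$conc)))
})

test_that("percentile clipping caps only the display tail", {
  conc <- matrix(1:100, 10, 10)
  img <- qsaMSI:::new_quant_image(conc, conc * 0, matrix(0L, 10, 10),
                                  list(out_dx = 160, out_dy = 150), "uM")
  disp <- percentile_clip(img, 99)
  cap <- as.numeric(quantile(1:100, 0.99))   # linear-interpolation percentile
  expect_equal(max(disp), cap)
  expect_equal(disp[conc <= cap], conc[conc <= cap])
  # identity cases: pct = 100 and a constant image
  expect_equal(percentile_clip(img, 100), conc)
  img2 <- qsaMSI:::new_quant_image(matrix(5, 3, 3), matrix(0, 3, 3),
                                   matrix(0L, 3, 3),
                                   list(out_dx = 160, out_dy = 150), "uM")
  expect_equal(percentile_clip(img2, 99), matrix(5, 3, 3))
  expect_error(percentile_clip(img, 0), "pct")
  # no quantifiable pixels -> empty display raster
  img3 <- qsaMSI:::new_quant_image(matrix(NaN, 2, 2), matrix(NaN, 2, 2),
                                   matrix(FLAG_EMPTY, 2, 2),
                                   list(out_dx = 160, out_dy = 150), "uM")
  expect_equal(length(percentile_clip(img3, 99)), 0)
})

test_that("median extrapolation sd does not decrease with noise", {
  # mild suppression contrast so s_yx reflects measurement noise rather
  # than within-window tissue heterogeneity; averaged over seeds
  med_sd <- function(cv, seed) {
    sim <- test_simulation(n_lines = 9, width_px = 48, cv = cv, seed = seed,
                           suppression = c(0.85, 1), n_background = 10)
    cube <- build_cube(sim$linescans, align_features(sim$linescans),
                       sim$scheme)
    qi <- suppressWarnings(sliding_qsa(cube, 148.0604, sim$scheme))
    median(qi$sd[is.finite(qi$sd)])
  }
  lo <- vapply(1:5, function(s) med_sd(0.03, s), 0)
  hi <- vapply(1:5, function(s) med_sd(0.20, s), 0)
  expect_gt(mean(hi), mean(lo))
})

test_that("qIS images cancel suppression exactly on noiseless data", {
  n_l <- 6; n_px <- 16
  conc <- matrix(8, n_l, n_px)
  supp <- matrix(runif(n_l * n_px, 0.3, 1), n_l, n_px)
  ph <- manual_phantom(conc, supp, gain = 1, bg_intensity = 1e5)
  sch <- test_scheme()
  lss <- simulate_linescans(ph, sch, rep(c("s1", "s2", "s3"), 2),
                            noise_model(0, 0, seed = 1), mz_jitter_ppm = 0)
  cube <- build_cube(lss, align_features(lss), sch,
                     compute_geometry(0.04, 1.96, 150))
  qi <- qis_image(cube, 148.0604, 149.0574, sch)
  expect_equal(dim(qi$conc), c(2, n_px))   # two baseline lines
  # suppression varies 0.3-1 but truth is flat: the image is flat at 8
  expect_lt(max(abs(qi$conc - 8)), 1e-9)

  # dead IS channel -> all pixels empty
  cube2 <- cube
  cube2$values[, , qsaMSI:::match_feature(cube$feature_axis, 149.0574)] <- 0
  qi2 <- qis_image(cube2, 148.0604, 149.0574, sch)
  expect_true(all(qi2$flags == FLAG_EMPTY))
  expect_true(all(is.nan(qi2$conc)))
})
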