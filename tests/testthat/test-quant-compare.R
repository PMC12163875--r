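test_that("median fold change is exact for scaled inputs and
           scale-equivariant", {
  ref <- c(2, 4, 8, 16)
  expect_equal(median_fold_change(ref, ref), 1)
  expect_equal(median_fold_change(0.5 * ref, ref), 0.5)
  set.seed(2)
  est <- ref * runif(4, 0.5, 2)
  for (c_scale in c(0.1, 3)) {
    expect_equal(median_fold_change(c_scale * est, ref),
                 c_scale * median_fold_change(est, ref))
  }
  # flagged / invalid analytes are excluded; all-invalid warns and is NaN
  expect_equal(median_fold_change(c(1, NA, 3), c(2, 2, 0)), 0.5)
  expect_warning(out <- median_fold_change(c(NA, NA), c(1, 1)), "no valid")
  expect_true(is.nan(out))
  expect_error(median_fold_change(1:3, 1:2), "paired")
})

test_that("ROI extraction follows floor arithmetic on the pixel grid", {
  conc <- matrix(seq_len(80) / 10, 8, 10)
  img <- qsaMSI:::new_quant_image(conc, conc * 0, matrix(0L, 8, 10),
                                  list(out_dx = 160, out_dy = 150), "uM",
                                  y_positions = (0:7) * 150)
  # 640 x 600 um ROI at 160 x 150 um resolution -> 4 x 4 pixels
  px <- roi_extract(img, roi_rect("r", 0, 0, 640, 600))
  expect_equal(nrow(px), 16)
  # full-cover ROI returns every OK pixel
  all_px <- roi_extract(img, roi_rect("all", 0, 0, 1600, 1200))
  expect_equal(nrow(all_px), 80)
  # flags gate the extraction
  img$flags[1, ] <- qsaMSI::FLAG_EMPTY
  expect_equal(nrow(roi_extract(img, roi_rect("all", 0, 0, 1600, 1200))),
               70)
  # out-of-bounds ROI warns and returns an empty frame
  expect_warning(none <- roi_extract(img, roi_rect("out", 5000, 5000,
                                                   6000, 6000)),
                 "no quantified")
  expect_equal(nrow(none), 0)
  expect_error(roi_rect("bad", 10, 0, 5, 100), "x0 < x1")
})

test_that("rank-sum comparison summarizes groups and detects separation", {
  set.seed(31)
  a <- rnorm(30, 10, 1)
  cm_same <- compare_methods(a, a)
  expect_equal(cm_same$p_value, 1, tolerance = 1e-9)
  expect_equal(cm_same$summary$median, rep(median(a), 2))
  # groups 5 sd apart are detected decisively
  cm_far <- compare_methods(a, a + 5)
  expect_lt(cm_far$p_value, 1e-3)
  # too few pixels: summary only
  cm_small <- compare_methods(a[1:2], a[1:5])
  expect_true(is.na(cm_small$p_value))
})

test_that("rank-sum type-I error stays near alpha under the null", {
  set.seed(17)
  nrep <- 2000
  rej <- 0
  for (i in seq_len(nrep)) {
    a <- rnorm(12); b <- rnorm(12)
    if (compare_methods(a, b)$p_value < 0.05) rej <- rej + 1
  }
  half <- 2.576 * sqrt(0.05 * 0.95 / nrep)
  expect_gt(rej / nrep, 0.035 - half)
  expect_lt(rej / nrep, 0.05 + half)
})

test_that("paired method comparison picks its test by normality screening", {
  set.seed(41)
  a <- rnorm(12, 10, 1)
  t_out <- paired_method_test(a, a + rnorm(12, 0, 0.5))
  expect_equal(t_out$test, "t")
  # a gross outlier in the differences pushes the fallback to the
  # signed-rank test
  b <- a + c(rnorm(11, 0, 0.2), 30)
  w_out <- paired_method_test(a, b)
  expect_equal(w_out$test, "wilcoxon")
  # identical vectors: no difference, reported without a crash
  id <- paired_method_test(a, a)
  expect_equal(id$p_value, 1)
  expect_equal(id$test, "none")
  expect_error(paired_method_test(1:2, 2:3), ">= 3")
})

test_that("qSA and qIS rarely differ significantly across analytes,
           while the qEC bias is detected", {
  # spot-mode study over many analytes, built directly from the response
  # model: each touchdown samples a spot with its own suppression factor;
  # both qSA and qIS are unbiased, so the paired test across analytes
  # should reject near its nominal rate only
  n_analytes <- 10
  sim_study <- function(seed, cv = 0.1) {
    set.seed(seed)
    analytes <- paste0("A", seq_len(n_analytes))
    C <- exp(rnorm(n_analytes, log(8), 0.5))
    is_names <- paste0(analytes, "_IS")   # one labeled IS per analyte
    adds <- c(0, 4, 8, 12, 16, 20)
    sol <- lapply(adds, function(a) {
      list(added = stats::setNames(rep(a, n_analytes), analytes),
           is = stats::setNames(rep(10, n_analytes), is_names))
    })
    names(sol) <- paste0("s", seq_along(adds))
    sch <- solvent_scheme(sol)
    records <- list()
    # touchdowns are closely spaced within one region precisely so that the
    # suppression is shared by the whole series; per-channel noise is then
    # the dominant error and is independent across analytes
    s_spot <- runif(1, 0.3, 1)
    for (sid in names(sol)) for (rep in 1:3) {
      x <- sol[[sid]]$added
      noisy <- function(v) v * exp(rnorm(length(v), 0, sqrt(log(1 + cv^2))))
      integ <- noisy(20 * s_spot * (C + x)) * 1e-3
      is_int <- noisy(20 * s_spot * rep(10, n_analytes)) * 1e-3
      records[[length(records) + 1]] <- structure(
        list(spot_id = paste0(sid, "_", rep), solvent_id = sid,
             window = c(t_start = 0, t_end = 12), n_scans = 20L,
             integrated = c(stats::setNames(integ, analytes),
                            stats::setNames(is_int, is_names)),
             baseline = c(stats::setNames(noisy(x) * 1e-3 / 20, analytes),
                          stats::setNames(noisy(rep(10, n_analytes)) *
                                            1e-3 / 20, is_names))),
        class = "touchdown_record")
    }
    run_touchdown_study(records, sch,
                        is_map = stats::setNames(is_names, analytes))
  }
  sig_sa <- 0
  n_seeds <- 60
  for (seed in seq_len(n_seeds)) {
    tab <- sim_study(seed)
    p <- paired_method_test(tab$qSA, tab$qIS)$p_value
    if (is.finite(p) && p < 0.05) sig_sa <- sig_sa + 1
  }
  expect_gte(1 - sig_sa / n_seeds, 0.9)

  # mirror of the underestimation finding: qEC vs truth under suppression
  sim <- test_simulation(n_lines = 9, width_px = 48, cv = 0.1, seed = 1,
                         n_background = 15)
  truth <- sim$phantom$analytes$Glu$true_conc_map
  supp <- sim$phantom$suppression_map
  ec <- fit_line(c(0, 10, 20), c(0, 10, 20) * 0.001)  # unsuppressed curve
  resp <- 0.001 * supp * truth                        # suppressed pixels
  qec <- qec_concentration(as.vector(resp), ec)
  p <- paired_method_test(qec$conc, as.vector(truth))
  expect_lt(p$p_value, 1e-6)
  expect_lt(median_fold_change(qec$conc, as.vector(truth)), 1)
})
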