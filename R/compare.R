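#' Median fold change between two sets of concentrations
#'
#' Median over analytes (or pixels) of `est / ref`, the summary the method
#' comparison is judged by: an unbiased method has a median fold change near
#' 1 against the reference, while external calibration under suppression
#' falls below it. Non-finite pairs and nonpositive references are excluded.
#'
#' @param est estimated concentrations.
#' @param ref reference concentrations (paired with `est`).
#' @return scalar median fold change (`NaN` with a warning when no valid
#'   pair remains).
#' @export
median_fold_change <- function(est, ref) {
  if (length(est) != length(ref)) stop("est and ref must be paired",
                                       call. = FALSE)
  ok <- is.finite(est) & is.finite(ref) & ref > 0
  if (!any(ok)) {
    warning("no valid analyte pairs; fold change undefined", call. = FALSE)
    return(NaN)
  }
  stats::median(est[ok] / ref[ok])
}

#' Rectangular region of interest
#'
#' @param name ROI label.
#' @param x0,y0,x1,y1 rectangle bounds in µm, half-open (`x0 <= x < x1`).
#' @return an object of class `msi_roi`.
#' @export
roi_rect <- function(name, x0, y0, x1, y1) {
  if (!(x0 < x1 && y0 < y1)) stop("ROI must satisfy x0 < x1 and y0 < y1",
                                  call. = FALSE)
  structure(list(name = name, x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            class = "msi_roi")
}

#' Extract quantified pixels inside an ROI
#'
#' Returns the OK-flagged pixels whose area falls inside a rectangular ROI.
#' Columns are addressed by their pixel origin (`(j-1) * out_dx`), rows by
#' their stored y positions, both half-open, so a 640 x 600 µm ROI on a
#' 160 x 150 µm raster selects exactly 4 x 4 pixels.
#'
#' @param image a `quant_image`.
#' @param roi an [roi_rect()] (or list with `x0`, `y0`, `x1`, `y1`).
#' @param include_lof include pixels flagged only for lack of fit
#'   (default FALSE).
#' @return data frame with `x_um`, `y_um`, `conc`; empty (with a warning)
#'   when the ROI misses the image.
#' @export
roi_extract <- function(image, roi, include_lof = FALSE) {
  stopifnot(inherits(image, "quant_image"))
  d <- dim(image$conc)
  x_origin <- (seq_len(d[2]) - 1) * image$geometry$out_dx
  yy <- if (!is.null(image$y_positions)) image$y_positions
        else (seq_len(d[1]) - 1) * image$geometry$out_dy
  cols <- which(x_origin >= roi$x0 & x_origin + image$geometry$out_dx <= roi$x1)
  rows <- which(yy >= roi$y0 & yy < roi$y1)
  keep_flags <- if (include_lof) c(FLAG_OK, FLAG_LOF_FAIL) else FLAG_OK
  out <- do.call(rbind, lapply(rows, function(r) {
    sel <- cols[image$flags[r, cols] %in% keep_flags &
                  is.finite(image$conc[r, cols])]
    if (!length(sel)) return(NULL)
    data.frame(x_um = x_origin[sel] + image$geometry$out_dx / 2,
               y_um = yy[r], conc = image$conc[r, sel])
  }))
  if (is.null(out) || nrow(out) == 0) {
    warning("ROI '", roi$name, "' contains no quantified pixels",
            call. = FALSE)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      conc = numeric(0)))
  }
  out
}

#' Compare two sets of pixel concentrations in a region
#'
#' Summarizes the two groups (median, IQR) and tests for a location
#' difference with a two-sided Mann-Whitney rank-sum test; the test is
#' skipped (p = NA) when either group has fewer than 3 values.
#'
#' @param roi_concs_a,roi_concs_b numeric concentration vectors.
#' @param alpha significance level reported alongside the p-value.
#' @return list with `summary` (data frame of n/median/IQR per group),
#'   `p_value`, `significant`.
#' @export
compare_methods <- function(roi_concs_a, roi_concs_b, alpha = 0.05) {
  a <- roi_concs_a[is.finite(roi_concs_a)]
  b <- roi_concs_b[is.finite(roi_concs_b)]
  smry <- data.frame(
    group = c("a", "b"), n = c(length(a), length(b)),
    median = c(stats::median(a), stats::median(b)),
    iqr = c(stats::IQR(a), stats::IQR(b))
  )
  if (length(a) < 3 || length(b) < 3) {
    return(list(summary = smry, p_value = NA_real_, significant = NA))
  }
  p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  list(summary = smry, p_value = p, significant = p < alpha)
}

#' Compare ROI concentrations across several regions
#'
#' Runs [compare_methods()] per ROI and applies a Holm step-down correction
#' across regions.
#'
#' @param image_a,image_b two `quant_image`s (e.g. qSA and qIS).
#' @param rois list of [roi_rect()]s.
#' @param alpha family significance level.
#' @return data frame with one row per ROI: pixel counts, medians, raw and
#'   Holm-adjusted p-values.
#' @export
compare_roi_table <- function(image_a, image_b, rois, alpha = 0.05) {
  rows <- lapply(rois, function(r) {
    ca <- roi_extract(image_a, r)$conc
    cb <- roi_extract(image_b, r)$conc
    cm <- compare_methods(ca, cb, alpha)
    data.frame(roi = r$name, n_a = length(ca), n_b = length(cb),
               median_a = stats::median(ca), median_b = stats::median(cb),
               p_value = cm$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, "holm")
  out$significant <- out$p_holm < alpha
  out
}

#' Paired test between quantification methods across analytes
#'
#' Tests whether two methods differ systematically over the same analytes.
#' Normality of the paired differences is screened with Shapiro-Wilk at
#' alpha = 0.05: a paired two-tailed t test when tenable, otherwise a
#' Wilcoxon signed-rank test (labeled). Identical vectors (zero-variance
#' differences) are reported as no difference with p = 1.
#'
#' @param per_analyte_a,per_analyte_b paired concentration vectors.
#' @return list with `p_value`, `test` (`"t"`, `"wilcoxon"`, or `"none"`),
#'   `normal` (Shapiro p-value).
#' @export
paired_method_test <- function(per_analyte_a, per_analyte_b) {
  ok <- is.finite(per_analyte_a) & is.finite(per_analyte_b)
  a <- per_analyte_a[ok]; b <- per_analyte_b[ok]
  if (length(a) < 3) stop("need >= 3 paired analytes", call. = FALSE)
  d <- a - b
  if (all(d == 0)) {
    return(list(p_value = 1, test = "none", normal = NA_real_))
  }
  sw <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) 0)
  if (sw >= 0.05) {
    list(p_value = stats::t.test(a, b, paired = TRUE)$p.value,
         test = "t", normal = sw)
  } else {
    list(p_value = suppressWarnings(
           stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value),
         test = "wilcoxon", normal = sw)
  }
}
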