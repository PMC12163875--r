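#' Detect a touchdown extraction window in a chronogram
#'
#' The extraction window of a touchdown (the probe parked on one spot until
#' the extractable signal is exhausted) is the contiguous run of scans
#' around the chronogram maximum whose intensity exceeds
#' `threshold_frac * max`; with the default 1% threshold the window ends
#' when the monitor ion has decayed to 1% relative abundance, the
#' exhaustive-extraction convention.
#'
#' @param chronogram data frame with `rt` and `intensity`
#'   (see [extract_chronogram()]).
#' @param threshold_frac onset/offset threshold as a fraction of the
#'   chronogram maximum (default 0.01).
#' @return numeric `c(t_start, t_end)` in seconds.
#' @export
detect_touchdown <- function(chronogram, threshold_frac = 0.01) {
  i <- chronogram$intensity
  if (length(i) == 0 || max(i) <= 0) {
    stop("no touchdown: chronogram is flat", call. = FALSE)
  }
  thr <- threshold_frac * max(i)
  above <- i > thr
  if (!any(above)) {
    stop("no touchdown: threshold leaves a zero-length window", call. = FALSE)
  }
  peak <- which.max(i)
  start <- peak
  while (start > 1 && above[start - 1]) start <- start - 1
  end <- peak
  while (end < length(i) && above[end + 1]) end <- end + 1
  c(t_start = chronogram$rt[start], t_end = chronogram$rt[end])
}

#' Slice spectra to an extraction window
#'
#' Keeps the spectra whose retention times fall inside the touchdown window,
#' truncated to `max_duration` seconds from the window start (12 s by
#' default, the time within which exhaustive extraction of the target
#' analytes is reached).
#'
#' @param spectra list of centroid spectra.
#' @param window numeric `c(t_start, t_end)`.
#' @param max_duration maximal slice duration in seconds.
#' @return list of spectra inside the (possibly truncated) window.
#' @export
slice_window <- function(spectra, window, max_duration = 12) {
  t0 <- window[1]
  t1 <- min(window[2], window[1] + max_duration)
  rt <- vapply(spectra, `[[`, 0, "rt")
  keep <- rt >= t0 & rt <= t1
  if (!any(keep)) {
    stop("window does not overlap the acquisition", call. = FALSE)
  }
  spectra[keep]
}

#' Build a touchdown record from one acquisition
#'
#' Integrates the TIC-normalized responses of the target ions over the
#' extraction window (discrete sum at scan granularity) and measures the
#' solvent-only baseline as the mean TIC-normalized response over a
#' pre-touchdown segment — by default the 10 s ending 2 s before window
#' onset, the portion of the acquisition recorded before the probe touches
#' the tissue, from which external calibration draws its points.
#'
#' @param spot_id identifier of the sampled spot.
#' @param solvent_id solvent used for this acquisition.
#' @param spectra list of centroid spectra for the whole acquisition.
#' @param window touchdown window `c(t_start, t_end)` (seconds).
#' @param targets named numeric vector of target m/z values
#'   (analytes and internal standards).
#' @param tolerance_ppm m/z matching tolerance.
#' @param max_duration window truncation, seconds (default 12).
#' @param baseline_len,baseline_gap pre-touchdown segment length and gap
#'   before onset, seconds (defaults 10 and 2).
#' @return object of class `touchdown_record`: `integrated` (sum of
#'   TIC-normalized responses over the window), `baseline` (mean per scan in
#'   the pre-touchdown segment), `n_scans` in the window, `window`.
#' @export
touchdown_record <- function(spot_id, solvent_id, spectra, window, targets,
                             tolerance_ppm = 5, max_duration = 12,
                             baseline_len = 10, baseline_gap = 2) {
  stopifnot(window[1] < window[2], length(targets) > 0,
            !is.null(names(targets)))
  sl <- slice_window(spectra, window, max_duration)
  rt <- vapply(spectra, `[[`, 0, "rt")
  b0 <- window[1] - baseline_gap - baseline_len
  b1 <- window[1] - baseline_gap
  base_idx <- which(rt >= b0 & rt < b1)

  norm_response <- function(sp) {
    tic <- sum(sp$intensity)
    if (tic <= 0) return(rep(NA_real_, length(targets)))
    vapply(targets, function(m) {
      hit <- abs(ppm_diff(sp$mz, m)) <= tolerance_ppm
      sum(sp$intensity[hit]) / tic
    }, 0)
  }
  win_resp <- vapply(sl, norm_response, numeric(length(targets)))
  win_resp <- matrix(win_resp, nrow = length(targets))
  base_resp <- if (length(base_idx)) {
    m <- vapply(spectra[base_idx], norm_response, numeric(length(targets)))
    rowMeans(matrix(m, nrow = length(targets)), na.rm = TRUE)
  } else {
    rep(NA_real_, length(targets))
  }
  structure(
    list(spot_id = spot_id, solvent_id = as.character(solvent_id),
         window = c(t_start = unname(window[1]), t_end = unname(window[2])),
         n_scans = length(sl),
         integrated = stats::setNames(rowSums(win_resp, na.rm = TRUE),
                                      names(targets)),
         baseline = stats::setNames(unname(base_resp), names(targets))),
    class = "touchdown_record"
  )
}

#' Spot-mode quantification with qIS, qSA and qEC
#'
#' Runs the three quantification approaches on a set of touchdown records:
#'
#' * **qSA** regresses the integrated on-tissue response against the added
#'   standard concentration across all solvents and extrapolates to zero
#'   response; the added standards flow in the extraction solvent during the
#'   touchdown and therefore share the pixel's suppression, which is what
#'   makes the slope match the endogenous response. The uncertainty is the
#'   x-extrapolation standard deviation from [qsa_concentration()].
#' * **qEC** builds its calibration from the pre-touchdown (solvent-only)
#'   baseline responses against added concentration, and inverts it at the
#'   on-tissue per-scan response of the baseline-solvent records; the sd is
#'   the spread over replicates.
#' * **qIS** uses the analyte / internal-standard ratio of the
#'   baseline-solvent (zero-addition) records at the known IS
#'   concentration; sd over replicates.
#'
#' @param records list of [touchdown_record()] objects.
#' @param scheme a [solvent_scheme()].
#' @param is_map named character vector mapping each analyte to the name of
#'   its internal standard among the record targets; analytes missing an IS
#'   are skipped for qIS with a warning.
#' @param alpha significance level reported with the lack-of-fit p-value.
#' @return data frame with one row per analyte: `qIS`, `qIS_sd`, `qSA`,
#'   `qSA_sd`, `qEC`, `qEC_sd`, `r2`, `lof_p`, `flags`.
#' @export
run_touchdown_study <- function(records, scheme, is_map = NULL,
                                alpha = 0.05) {
  stopifnot(length(records) > 0, inherits(scheme, "solvent_scheme"))
  base_ids <- baseline_solvents(scheme)
  rec_solv <- vapply(records, `[[`, "", "solvent_id")
  if (!any(rec_solv %in% base_ids)) {
    stop("no record with the baseline (zero-addition) solvent", call. = FALSE)
  }
  analytes <- unique(unlist(lapply(scheme$solvents,
                                   function(s) names(s$added))))
  n_levels <- length(unique(vapply(records, `[[`, "", "solvent_id")))
  if (n_levels < 3) {
    stop("qSA needs records from >= 3 addition levels", call. = FALSE)
  }

  out <- lapply(analytes, function(an) {
    x_all <- vapply(records, function(r) added_conc(scheme, r$solvent_id, an),
                    0)
    y_int <- vapply(records, function(r) {
      if (an %in% names(r$integrated)) r$integrated[[an]] else NA_real_
    }, 0)
    y_base <- vapply(records, function(r) {
      if (an %in% names(r$baseline)) r$baseline[[an]] else NA_real_
    }, 0)
    nsc <- vapply(records, `[[`, 0L, "n_scans")
    is_base <- rec_solv %in% base_ids
    flags <- character(0)

    # qSA: integrated on-tissue response vs added concentration
    sa_fit <- tryCatch(fit_line(x_all, y_int), error = function(e) NULL)
    if (is.null(sa_fit)) {
      qsa <- list(conc = NA_real_, sd = NA_real_, flag = "no_fit")
      r2 <- NA_real_; lof <- NA_real_
    } else {
      qsa <- qsa_concentration(sa_fit)
      r2 <- sa_fit$r2; lof <- sa_fit$lof_pvalue
    }
    if (qsa$flag != "ok") flags <- c(flags, paste0("qSA:", qsa$flag))
    if (is.finite(lof) && lof < alpha) flags <- c(flags, "qSA:lof_fail")

    # qEC: solvent-only calibration, inverted at baseline-solvent
    # on-tissue per-scan responses
    ec_fit <- tryCatch(fit_line(x_all, y_base), error = function(e) NULL)
    if (is.null(ec_fit)) {
      qec_m <- NA_real_; qec_sd <- NA_real_
      flags <- c(flags, "qEC:no_fit")
    } else {
      resp <- y_int[is_base] / nsc[is_base]
      qec <- qec_concentration(resp, ec_fit)
      qec_m <- mean(qec$conc, na.rm = TRUE)
      qec_sd <- stats::sd(qec$conc, na.rm = TRUE)
      if (any(qec$flag == "neg_conc")) flags <- c(flags, "qEC:neg_conc")
      if (any(qec$flag == "non_quantifiable")) {
        flags <- c(flags, "qEC:non_quantifiable")
      }
    }

    # qIS: one-point ratio calibration on baseline-solvent records
    is_name <- if (!is.null(is_map) && an %in% names(is_map)) {
      is_map[[an]]
    } else "IS"
    has_is <- all(vapply(records[is_base], function(r) {
      is_name %in% names(r$integrated)
    }, TRUE))
    is_conc <- NA_real_
    for (sid in base_ids) {
      isc <- scheme$solvents[[sid]]$is
      if (is_name %in% names(isc)) is_conc <- unname(isc[[is_name]])
    }
    if (!has_is || !is.finite(is_conc)) {
      warning("no internal standard for ", an, "; qIS skipped",
              call. = FALSE)
      qis_m <- NA_real_; qis_sd <- NA_real_
      flags <- c(flags, "qIS:missing_is")
    } else {
      qis <- qis_concentration(
        vapply(records[is_base], function(r) r$integrated[[an]], 0),
        vapply(records[is_base], function(r) r$integrated[[is_name]], 0),
        is_conc)
      qis_m <- mean(qis$conc, na.rm = TRUE)
      qis_sd <- stats::sd(qis$conc, na.rm = TRUE)
      if (any(qis$flag != "ok")) flags <- c(flags, "qIS:non_quantifiable")
    }

    data.frame(analyte = an, qIS = qis_m, qIS_sd = qis_sd,
               qSA = qsa$conc, qSA_sd = qsa$sd,
               qEC = qec_m, qEC_sd = qec_sd,
               r2 = r2, lof_p = lof,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
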