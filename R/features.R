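#' Align centroid peaks into a common feature axis
#'
#' Pools every peak from every spectrum, sorts by m/z, and grows features by
#' greedy single-linkage clustering against the running intensity-weighted
#' centroid: a peak joins the open feature while it lies within
#' `tolerance_ppm` of the centroid and the feature does not already contain
#' a peak from the same spectrum (two peaks resolved within one spectrum are
#' distinct ions by definition). Feature centroids are the intensity-weighted
#' mean m/z of their members.
#'
#' @param spectra a list of centroid spectra (`rt`/`mz`/`intensity` lists)
#'   or a `line_scan_set` (all lines pooled).
#' @param tolerance_ppm alignment tolerance in ppm (default 5).
#' @return object of class `feature_axis`: sorted `centroids` (Th),
#'   `tolerance_ppm`, and per-feature member counts `n_members`.
#' @export
align_features <- function(spectra, tolerance_ppm = 5) {
  if (inherits(spectra, "line_scan_set")) {
    spectra <- unlist(lapply(spectra$lines, `[[`, "spectra"),
                      recursive = FALSE)
  }
  if (length(spectra) == 0) stop("no spectra to align", call. = FALSE)
  mz <- unlist(lapply(spectra, `[[`, "mz"))
  intensity <- unlist(lapply(spectra, `[[`, "intensity"))
  sid <- rep(seq_along(spectra),
             vapply(spectra, function(s) length(s$mz), 0L))
  if (length(mz) == 0) stop("spectra contain no peaks", call. = FALSE)

  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]; sid <- sid[o]

  n <- length(mz)
  centroids <- numeric(0)
  counts <- integer(0)
  seen <- logical(length(spectra))   # spectra already in the open feature
  members <- integer(n)              # member spectrum ids of the open feature
  cur_wsum <- mz[1] * intensity[1]
  cur_w <- intensity[1]
  cur_c <- if (cur_w > 0) cur_wsum / cur_w else mz[1]
  seen[sid[1]] <- TRUE
  members[1L] <- sid[1]
  cur_n <- 1L
  for (i in seq_len(n)[-1]) {
    if (ppm_diff(mz[i], cur_c) <= tolerance_ppm && !seen[sid[i]]) {
      cur_wsum <- cur_wsum + mz[i] * intensity[i]
      cur_w <- cur_w + intensity[i]
      cur_c <- if (cur_w > 0) cur_wsum / cur_w else mz[i]
      seen[sid[i]] <- TRUE
      cur_n <- cur_n + 1L
      members[cur_n] <- sid[i]
    } else {
      centroids <- c(centroids, cur_c)
      counts <- c(counts, cur_n)
      seen[members[seq_len(cur_n)]] <- FALSE
      cur_wsum <- mz[i] * intensity[i]
      cur_w <- intensity[i]
      cur_c <- if (cur_w > 0) cur_wsum / cur_w else mz[i]
      seen[sid[i]] <- TRUE
      members[1L] <- sid[i]
      cur_n <- 1L
    }
  }
  centroids <- c(centroids, cur_c)
  counts <- c(counts, cur_n)
  o2 <- order(centroids)
  structure(list(centroids = centroids[o2], tolerance_ppm = tolerance_ppm,
                 n_members = counts[o2]),
            class = "feature_axis")
}

#' @export
print.feature_axis <- function(x, ...) {
  cat("Feature axis:", length(x$centroids), "features at",
      x$tolerance_ppm, "ppm tolerance\n")
  cat("  m/z range:", sprintf("%.4f - %.4f", min(x$centroids),
                              max(x$centroids)), "\n")
  invisible(x)
}

# assign each peak m/z to the nearest feature within tolerance; ties in ppm
# distance go to the lower-m/z feature; 0 = unassigned
assign_features <- function(mz, axis) {
  cen <- axis$centroids
  idx <- findInterval(mz, cen)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(cen))
  d_lo <- abs(ppm_diff(mz, cen[lo]))
  d_hi <- abs(ppm_diff(mz, cen[hi]))
  pick <- ifelse(d_lo <= d_hi, lo, hi)   # <= : ties to the lower-m/z feature
  d <- pmin(d_lo, d_hi)
  ifelse(d <= axis$tolerance_ppm, pick, 0L)
}

#' TIC-normalize one centroid spectrum
#'
#' Divides every centroid intensity by the scan's total ion count so each
#' pixel's features are expressed as fractions of its TIC; the normalized
#' intensities of a non-empty scan sum to 1. A scan with zero TIC is an
#' empty pixel: an all-`NaN` vector flagged with attribute `empty = TRUE` is
#' returned, never an error.
#'
#' @param spectrum a centroid spectrum (list with `mz`, `intensity`).
#' @return numeric vector of normalized intensities.
#' @export
tic_normalize <- function(spectrum) {
  tic <- sum(spectrum$intensity)
  if (length(spectrum$intensity) == 0 || tic <= 0) {
    out <- rep(NaN, length(spectrum$intensity))
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- spectrum$intensity / tic
  attr(out, "empty") <- FALSE
  out
}

#' Assemble the TIC-normalized data cube
#'
#' Builds the `[line x scan x feature]` tensor of TIC-normalized feature
#' intensities from a line-scan set. The TIC of a scan is the sum over all
#' its centroids (aligned or not), so summing a pixel's features never
#' exceeds 1. Lines of unequal length are truncated to the common minimum
#' scan count with a warning; a feature absent from a scan contributes 0;
#' empty scans yield `NaN` rows.
#'
#' @param linescans a `line_scan_set`.
#' @param feature_axis a [align_features()] result.
#' @param scheme a [solvent_scheme()]; every line's solvent id must exist.
#' @param geometry optional [compute_geometry()] result stored with the cube.
#' @return object of class `data_cube`: `values` array, `feature_axis`,
#'   `line_meta` data frame (line_id, solvent_id, y_position), `geometry`,
#'   `units`.
#' @export
build_cube <- function(linescans, feature_axis, scheme, geometry = NULL) {
  stopifnot(inherits(linescans, "line_scan_set"),
            inherits(feature_axis, "feature_axis"),
            inherits(scheme, "solvent_scheme"))
  sids <- vapply(linescans$lines, `[[`, "", "solvent_id")
  unknown <- setdiff(sids, names(scheme$solvents))
  if (length(unknown)) {
    stop("line solvent id(s) not in scheme: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ns <- vapply(linescans$lines, function(l) length(l$spectra), 0L)
  n_scans <- min(ns)
  if (any(ns != n_scans)) {
    warning("lines have unequal scan counts (", paste(range(ns),
            collapse = "-"), "); truncating to ", n_scans, call. = FALSE)
  }
  n_lines <- length(linescans$lines)
  n_feat <- length(feature_axis$centroids)
  values <- array(0, dim = c(n_lines, n_scans, n_feat))
  for (l in seq_len(n_lines)) {
    for (s in seq_len(n_scans)) {
      sp <- linescans$lines[[l]]$spectra[[s]]
      tic <- sum(sp$intensity)
      if (length(sp$intensity) == 0 || tic <= 0) {
        values[l, s, ] <- NaN
        next
      }
      f <- assign_features(sp$mz, feature_axis)
      keep <- f > 0
      if (any(keep)) {
        sums <- rowsum(sp$intensity[keep], f[keep])
        values[l, s, as.integer(rownames(sums))] <- sums[, 1] / tic
      }
    }
  }
  if (is.null(geometry)) {
    geometry <- list(pixel_dx = NA_real_,
                     pixel_dy = if (!is.null(linescans$line_spacing)) {
                       linescans$line_spacing
                     } else NA_real_)
  }
  structure(
    list(values = values,
         feature_axis = feature_axis,
         line_meta = data.frame(
           line_id = vapply(linescans$lines, `[[`, "", "line_id"),
           solvent_id = sids,
           y_position = vapply(linescans$lines, `[[`, 0, "y_position"),
           stringsAsFactors = FALSE),
         geometry = geometry,
         units = scheme$units),
    class = "data_cube"
  )
}

#' @export
print.data_cube <- function(x, ...) {
  d <- dim(x$values)
  cat("Data cube:", d[1], "lines x", d[2], "scans x", d[3], "features\n")
  cat("  units:", x$units, " TIC-normalized\n")
  invisible(x)
}

#' @export
dim.data_cube <- function(x) dim(x$values)

#' Feature slice of a data cube
#'
#' Extracts the raw (TIC-normalized) ion image of one feature, selected by
#' index or by m/z within the axis tolerance.
#'
#' @param cube a `data_cube`.
#' @param feature feature index, or an m/z value matched within tolerance.
#' @return numeric matrix `[lines x scans]`.
#' @export
cube_slice <- function(cube, feature) {
  stopifnot(inherits(cube, "data_cube"))
  idx <- match_feature(cube$feature_axis, feature)
  cube$values[, , idx]
}

# resolve a feature index or m/z against the axis; whole numbers below the
# instrument mass range are treated as indices
match_feature <- function(axis, feature) {
  if (length(feature) != 1) stop("feature must be length 1", call. = FALSE)
  if (feature == round(feature) && feature >= 1 &&
      feature <= length(axis$centroids) && feature < min(axis$centroids)) {
    return(as.integer(feature))
  }
  idx <- assign_features(feature, axis)
  if (idx == 0) {
    stop(sprintf("no feature within %g ppm of m/z %.4f", axis$tolerance_ppm,
                 feature), call. = FALSE)
  }
  idx
}

#' Extracted ion chronogram
#'
#' Per-scan summed intensity of all centroids within `tolerance_ppm` of a
#' target m/z, against retention time — the trace used to locate touchdown
#' extraction peaks (e.g. creatine at m/z 132.0756).
#'
#' @param spectra list of centroid spectra (one line or acquisition), or a
#'   `line_scan_set` line element's `spectra`.
#' @param target_mz target m/z (Th).
#' @param tolerance_ppm matching tolerance (default 5 ppm).
#' @return data frame with columns `rt` and `intensity` (absent ion gives an
#'   all-zero series).
#' @export
extract_chronogram <- function(spectra, target_mz, tolerance_ppm = 5) {
  rt <- vapply(spectra, `[[`, 0, "rt")
  intensity <- vapply(spectra, function(sp) {
    if (length(sp$mz) == 0) return(0)
    hit <- abs(ppm_diff(sp$mz, target_mz)) <= tolerance_ppm
    sum(sp$intensity[hit])
  }, 0)
  data.frame(rt = rt, intensity = intensity)
}
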