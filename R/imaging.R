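#' QC flag bits of a quantitative image
#'
#' Per-pixel quality flags are a bitmask: `OK = 0`, `NEG_SLOPE = 1` (the
#' standard-addition slope was nonpositive), `NEG_CONC = 2` (negative
#' x-intercept), `LOF_FAIL = 4` (replicate-based lack-of-fit rejected
#' linearity; the concentration is still reported), `EMPTY = 8` (too few
#' valid pixels in a block).
#'
#' @format integer constants.
#' @name quant_flags
NULL

#' @rdname quant_flags
#' @export
FLAG_OK <- 0L
#' @rdname quant_flags
#' @export
FLAG_NEG_SLOPE <- 1L
#' @rdname quant_flags
#' @export
FLAG_NEG_CONC <- 2L
#' @rdname quant_flags
#' @export
FLAG_LOF_FAIL <- 4L
#' @rdname quant_flags
#' @export
FLAG_EMPTY <- 8L

new_quant_image <- function(conc, sd, flags, geometry, units,
                            y_positions = NULL) {
  structure(list(conc = conc, sd = sd, flags = flags,
                 geometry = geometry, units = units,
                 y_positions = y_positions),
            class = "quant_image")
}

#' @export
print.quant_image <- function(x, ...) {
  d <- dim(x$conc)
  ok <- sum(x$flags %in% c(FLAG_OK, FLAG_LOF_FAIL))
  cat("Quantitative image:", d[1], "x", d[2], "pixels (",
      sprintf("%g x %g um", x$geometry$out_dy, x$geometry$out_dx), ")\n")
  cat(sprintf("  units: %s; %d/%d quantified pixels\n", x$units, ok,
              length(x$flags)))
  if (ok > 0) {
    q <- stats::quantile(x$conc[x$flags %in% c(FLAG_OK, FLAG_LOF_FAIL)],
                         c(0.05, 0.5, 0.95), na.rm = TRUE)
    cat(sprintf("  conc 5/50/95%%: %.4g / %.4g / %.4g\n", q[1], q[2], q[3]))
  }
  invisible(x)
}

#' @export
summary.quant_image <- function(object, ...) {
  fl <- object$flags
  c(n_pixels = length(fl), ok = sum(fl == FLAG_OK),
    neg_slope = sum(bitwAnd(fl, FLAG_NEG_SLOPE) > 0),
    neg_conc = sum(bitwAnd(fl, FLAG_NEG_CONC) > 0),
    lof_fail = sum(bitwAnd(fl, FLAG_LOF_FAIL) > 0),
    empty = sum(bitwAnd(fl, FLAG_EMPTY) > 0))
}

#' @export
as.data.frame.quant_image <- function(x, ...) {
  d <- dim(x$conc)
  yy <- if (!is.null(x$y_positions)) x$y_positions
        else (seq_len(d[1]) - 1) * x$geometry$out_dy
  data.frame(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    x_um = rep((seq_len(d[2]) - 0.5) * x$geometry$out_dx, each = d[1]),
    y_um = rep(yy, d[2]),
    conc = as.vector(x$conc),
    sd = as.vector(x$sd),
    flag = as.vector(x$flags)
  )
}

#' @export
plot.quant_image <- function(x, pct = 99, main = NULL, ...) {
  disp <- percentile_clip(x, pct)
  d <- dim(disp)
  graphics::image(
    x = (seq_len(d[2]) - 0.5) * x$geometry$out_dx,
    y = if (!is.null(x$y_positions)) x$y_positions
        else (seq_len(d[1]) - 0.5) * x$geometry$out_dy,
    z = t(disp),
    col = grDevices::hcl.colors(64, "viridis"),
    xlab = "x (um)", ylab = "y (um)",
    main = if (is.null(main)) paste0("conc (", x$units, ")") else main, ...)
  invisible(x)
}

#' Mean response over a pixel block
#'
#' Arithmetic mean of the non-`NaN` TIC-normalized intensities over the
#' pixels `[start, start + width)` of one line — one calibration point of
#' the reading-frame regression. Blocks with fewer than `min_valid` usable
#' pixels are empty.
#'
#' @param pixel_values numeric vector of one line's TIC-normalized values.
#' @param start 1-based start pixel.
#' @param width block width in pixels (default 8).
#' @param min_valid minimum number of non-`NaN` pixels (default 4).
#' @return list with `mean` (`NaN` when empty), `values` (the non-`NaN`
#'   member pixels), and logical `empty`.
#' @export
block_average <- function(pixel_values, start, width = 8L, min_valid = 4L) {
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  idx <- start:min(start + width - 1, length(pixel_values))
  v <- pixel_values[idx]
  v <- v[is.finite(v)]
  if (length(v) < min_valid) {
    return(list(mean = NaN, values = v, empty = TRUE))
  }
  list(mean = mean(v), values = v, empty = FALSE)
}

#' Enumerate sliding solvent windows across lines
#'
#' Finds every window of `k` consecutive lines (k = number of scheme
#' solvents) containing exactly one line per solvent, sliding by one line
#' (overlapping windows, output row spacing = line spacing) or by `k`
#' (non-overlapping). Within each window the lines are ordered by ascending
#' added concentration so they map directly onto the standard-addition
#' x-axis.
#'
#' @param line_meta data frame with `solvent_id` per line (a cube's
#'   `line_meta`).
#' @param scheme a [solvent_scheme()].
#' @param analyte analyte name used to order the solvents (default: total
#'   addition).
#' @param overlap logical; slide by one line (default) or by the window
#'   height.
#' @return list of integer vectors (line indices in ascending-addition
#'   order); windows missing a solvent are skipped with one warning.
#' @export
window_triplets <- function(line_meta, scheme, analyte = NULL,
                            overlap = TRUE) {
  sids <- as.character(line_meta$solvent_id)
  ord <- solvent_order(scheme, analyte)
  k <- length(ord)
  n <- length(sids)
  if (n < k) return(list())
  starts <- if (overlap) seq_len(n - k + 1) else seq(1, n - k + 1, by = k)
  skipped <- 0L
  wins <- list()
  for (s in starts) {
    w <- s:(s + k - 1)
    if (setequal(sids[w], ord) && !anyDuplicated(sids[w])) {
      wins[[length(wins) + 1L]] <- w[match(ord, sids[w])]
    } else {
      skipped <- skipped + 1L
    }
  }
  if (skipped > 0) {
    warning(skipped, " window(s) skipped: incomplete solvent pattern",
            call. = FALSE)
  }
  wins
}

#' Quantitative ion image by sliding-reading-frame standard addition
#'
#' Converts the striped alternating-solvent data cube into a quantitative
#' image. For every window of adjacent lines (one per solvent, ascending
#' added concentration) and every X block, the block means of the
#' TIC-normalized feature form the calibration points of a
#' standard-addition line; the magnitude of its negative x-intercept is the
#' pixel's detected concentration and the x-extrapolation formula its
#' standard deviation. The individual block pixels serve as pure-error
#' replicates for a lack-of-fit F test at `alpha`; failing pixels keep
#' their concentration but carry the `LOF_FAIL` flag. Output resolution is
#' `block * pixel_dx` along the scan (160 µm at the 8 x 20 µm defaults) by
#' the line spacing across lines (150 µm).
#'
#' @param cube a [build_cube()] result.
#' @param feature feature index or m/z of the analyte channel.
#' @param scheme a [solvent_scheme()].
#' @param analyte analyte name in the scheme (maps solvents to added
#'   concentrations). Defaults to the single added analyte when unambiguous.
#' @param block block width in pixels (default 8).
#' @param stride_x X stride in pixels (default: the block width,
#'   non-overlapping blocks).
#' @param min_valid minimum valid pixels per block.
#' @param alpha lack-of-fit significance level.
#' @param overlap_y logical, overlapping line windows (default TRUE).
#' @return a `quant_image` with `conc`, `sd` and `flags` rasters.
#' @export
sliding_qsa <- function(cube, feature, scheme, analyte = NULL, block = 8L,
                        stride_x = block, min_valid = 4L, alpha = 0.05,
                        overlap_y = TRUE) {
  stopifnot(inherits(cube, "data_cube"), inherits(scheme, "solvent_scheme"))
  if (block < 2) stop("block must be >= 2 pixels", call. = FALSE)
  if (is.null(analyte)) {
    cand <- unique(unlist(lapply(scheme$solvents,
                                 function(s) names(s$added)[s$added > 0])))
    if (length(cand) != 1) {
      stop("analyte must be given when the scheme adds several analytes",
           call. = FALSE)
    }
    analyte <- cand
  }
  fidx <- match_feature(cube$feature_axis, feature)
  img <- cube$values[, , fidx]

  wins <- window_triplets(cube$line_meta, scheme, analyte,
                          overlap = overlap_y)
  if (length(wins) == 0) stop("no complete solvent window", call. = FALSE)
  ord <- solvent_order(scheme, analyte)
  xconc <- vapply(ord, function(id) added_conc(scheme, id, analyte), 0)
  if (length(unique(xconc)) < 3) {
    stop("need >= 3 distinct added concentrations", call. = FALSE)
  }

  n_scans <- dim(cube$values)[2]
  n_blocks <- (n_scans - block) %/% stride_x + 1L
  n_rows <- length(wins)
  conc <- matrix(NaN, n_rows, n_blocks)
  sdr <- matrix(NaN, n_rows, n_blocks)
  flags <- matrix(FLAG_EMPTY, n_rows, n_blocks)

  for (w in seq_len(n_rows)) {
    lines <- wins[[w]]
    for (b in seq_len(n_blocks)) {
      start <- (b - 1L) * stride_x + 1L
      bl <- lapply(lines, function(l) {
        block_average(img[l, ], start, block, min_valid)
      })
      if (any(vapply(bl, `[[`, TRUE, "empty"))) {
        flags[w, b] <- FLAG_EMPTY
        next
      }
      ymeans <- vapply(bl, `[[`, 0, "mean")
      fit <- fit_line(xconc, ymeans)
      est <- qsa_concentration(fit)
      fl <- FLAG_OK
      if (est$flag == "neg_slope") {
        fl <- FLAG_NEG_SLOPE
      } else if (est$flag == "neg_conc") {
        fl <- FLAG_NEG_CONC
      } else {
        conc[w, b] <- est$conc
        sdr[w, b] <- est$sd
        # lack-of-fit from the block's pixels as pure-error replicates
        px <- unlist(lapply(bl, `[[`, "values"))
        xr <- rep(xconc, vapply(bl, function(z) length(z$values), 0L))
        lof <- tryCatch(fit_line(xr, px)$lof_pvalue,
                        error = function(e) NA_real_)
        if (is.finite(lof) && lof < alpha) fl <- FLAG_LOF_FAIL
      }
      flags[w, b] <- fl
    }
  }
  ypos <- vapply(seq_len(n_rows), function(w) {
    mean(cube$line_meta$y_position[wins[[w]]])
  }, 0)
  new_quant_image(
    conc, sdr, flags,
    geometry = list(out_dx = block * cube$geometry$pixel_dx,
                    out_dy = if (overlap_y) {
                      cube$geometry$pixel_dy
                    } else 3 * cube$geometry$pixel_dy),
    units = cube$units, y_positions = ypos)
}

#' Cap a quantitative image at a display percentile
#'
#' Returns a display raster whose values above the `pct`-th percentile of
#' the quantified (OK) pixels are capped at that percentile — the usual way
#' ion images are displayed so a few hot pixels do not swamp the color
#' scale. The quantitative raster itself is untouched.
#'
#' @param image a `quant_image`.
#' @param pct percentile in (0, 100] (default 99).
#' @return numeric matrix for display.
#' @export
percentile_clip <- function(image, pct = 99) {
  stopifnot(inherits(image, "quant_image"))
  if (!(pct > 0 && pct <= 100)) stop("pct must be in (0, 100]", call. = FALSE)
  ok <- image$flags %in% c(FLAG_OK, FLAG_LOF_FAIL) & is.finite(image$conc)
  disp <- image$conc
  if (!any(ok)) return(disp[FALSE, FALSE, drop = FALSE])
  cap <- stats::quantile(image$conc[ok], pct / 100, names = FALSE)
  disp[is.finite(disp) & disp > cap] <- cap
  disp
}

#' Pixel-by-pixel internal-standard image
#'
#' One-point internal-standard quantification on the baseline-solvent
#' (zero-addition) lines of a cube: at each pixel the analyte /
#' internal-standard ratio times the IS concentration gives the detected
#' concentration at native pixel resolution. Pixels with nonpositive IS
#' signal are empty.
#'
#' @param cube a `data_cube`.
#' @param feature analyte feature (index or m/z).
#' @param is_feature internal-standard feature (index or m/z).
#' @param scheme a [solvent_scheme()].
#' @param is_name internal-standard name in the scheme (default `"IS"`).
#' @return a `quant_image` over the baseline lines (native resolution).
#' @export
qis_image <- function(cube, feature, is_feature, scheme, is_name = "IS") {
  stopifnot(inherits(cube, "data_cube"), inherits(scheme, "solvent_scheme"))
  base_ids <- baseline_solvents(scheme)
  rows <- which(cube$line_meta$solvent_id %in% base_ids)
  if (length(rows) == 0) stop("cube has no baseline-solvent lines",
                              call. = FALSE)
  is_conc <- NA_real_
  for (sid in base_ids) {
    isc <- scheme$solvents[[sid]]$is
    if (is_name %in% names(isc)) is_conc <- unname(isc[[is_name]])
  }
  if (!is.finite(is_conc)) {
    stop("internal standard '", is_name, "' not in scheme", call. = FALSE)
  }
  a <- cube$values[rows, , match_feature(cube$feature_axis, feature),
                   drop = FALSE]
  i <- cube$values[rows, , match_feature(cube$feature_axis, is_feature),
                   drop = FALSE]
  a <- matrix(a, length(rows)); i <- matrix(i, length(rows))
  q <- qis_concentration(a, i, is_conc)
  conc <- matrix(q$conc, length(rows))
  flags <- matrix(ifelse(q$flag == "ok", FLAG_OK, FLAG_EMPTY),
                  length(rows))
  conc[flags == FLAG_EMPTY] <- NaN
  new_quant_image(
    conc, sd = matrix(NA_real_, nrow(conc), ncol(conc)), flags,
    geometry = list(out_dx = cube$geometry$pixel_dx,
                    out_dy = cube$geometry$pixel_dy),
    units = cube$units,
    y_positions = cube$line_meta$y_position[rows])
}
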