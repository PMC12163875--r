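#' Noise model for simulated line-scan spectra
#'
#' Two-component noise: a multiplicative lognormal term parameterized by its
#' coefficient of variation (shot-like noise proportional to signal) and an
#' additive Gaussian floor (baseline/electronic noise). The lognormal factor
#' has mean exactly 1, so expected intensities are unchanged by noise.
#'
#' @param multiplicative_cv coefficient of variation of the multiplicative
#'   term (fraction, e.g. 0.10 for 10%).
#' @param additive_sd standard deviation of the additive floor, in intensity
#'   counts.
#' @param seed integer seed used by [simulate_linescans()].
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_cv = 0.1, additive_sd = 0, seed = 1L) {
  if (multiplicative_cv < 0 || additive_sd < 0) {
    stop("multiplicative_cv and additive_sd must be nonnegative", call. = FALSE)
  }
  structure(
    list(multiplicative_cv = multiplicative_cv,
         additive_sd = additive_sd,
         seed = as.integer(seed)),
    class = "noise_model"
  )
}

#' Construct a synthetic tissue phantom for line-scan MSI
#'
#' A phantom holds everything needed to simulate a liquid-extraction imaging
#' run with known ground truth: per-analyte detected-concentration maps
#' (concentration in the probe solvent, i.e. tissue concentration times the
#' unknown extraction efficiency), a per-pixel ion-suppression field acting
#' multiplicatively on analyte and internal-standard responses, an
#' internal-standard channel, and background matrix ions that dominate the
#' total ion count (TIC).
#'
#' Concentration maps are smooth blob-shaped fields whose correlation length
#' is physical (1.5-4 mm at the reference 20 x 150 µm pixel geometry, the
#' scale of anatomical structures), so adjacent 150 µm lines sample nearly
#' the same tissue whatever the raster size. The suppression field is such a
#' field rank-transformed so its values are uniformly distributed over
#' `suppression_range` (the spatial pattern stays smooth, the marginal is
#' exactly uniform).
#'
#' @param n_lines number of scan lines (image rows).
#' @param width_px number of pixels (scans) per line.
#' @param n_analytes number of target analytes (default 2; at most 4
#'   named presets are provided, further analytes get generic names).
#' @param suppression_range length-2 numeric `(low, high)` with
#'   `0 < low <= high <= 1`; per-pixel suppression factors span this range.
#' @param seed integer seed; phantoms are bit-identical for equal seeds.
#' @param conc_max peak detected concentration of the analyte maps (µM);
#'   maps span `[conc_max / 5, conc_max]` — endogenous amino acids are
#'   present throughout brain tissue, with white matter a few-fold below
#'   the gray-matter peak rather than absent.
#' @param gain analyte response gain, counts per µM at suppression 1; the
#'   default keeps single-analyte signals well below 1% of the TIC, as for
#'   trace metabolites in real spectra.
#' @param n_background number of background matrix ions carrying the TIC
#'   (default 40; real scans hold hundreds of features, so the TIC is much
#'   steadier than any single channel).
#' @return an object of class `msi_phantom` with fields `n_lines`,
#'   `width_px`, `analytes` (name, mz, gain, true_conc_map), the
#'   `suppression_map`, `background_ions`, and `is_channel`.
#' @examples
#' ph <- make_phantom(6, 32, seed = 7)
#' range(ph$suppression_map)
#' @export
make_phantom <- function(n_lines, width_px, n_analytes = 2L,
                         suppression_range = c(0.3, 1.0), seed = 1L,
                         conc_max = 20, gain = 200, n_background = 40L) {
  if (n_lines < 1 || width_px < 1) {
    stop("n_lines and width_px must be positive", call. = FALSE)
  }
  lo <- suppression_range[1]; hi <- suppression_range[2]
  if (!(lo > 0 && lo <= hi && hi <= 1)) {
    stop("suppression_range must satisfy 0 < low <= high <= 1", call. = FALSE)
  }
  if (n_analytes < 1) stop("n_analytes must be >= 1", call. = FALSE)

  # protonated amino-acid presets typical of brain tissue imaging
  preset <- data.frame(
    name = c("Glu", "Thr", "Ala", "Phe"),
    mz = c(148.0604, 120.0655, 90.0550, 166.0863),
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    analytes <- vector("list", n_analytes)
    for (i in seq_len(n_analytes)) {
      nm <- if (i <= nrow(preset)) preset$name[i] else paste0("A", i)
      mz <- if (i <= nrow(preset)) preset$mz[i] else 100 + 37.31 * i
      cmap <- smooth_field(n_lines, width_px)
      cmap <- range_rescale(cmap, conc_max / 5, conc_max)
      analytes[[i]] <- list(name = nm, mz = mz, gain = gain,
                            true_conc_map = cmap)
    }
    names(analytes) <- vapply(analytes, `[[`, "", "name")

    supp <- rank_rescale(smooth_field(n_lines, width_px), lo, hi)

    # background matrix ions carry the TIC: a few named landmarks (creatine,
    # choline, PC 34:1) plus random matrix channels with lognormal base
    # intensities; spatial modulation is mild, so the TIC varies ~+-10%
    # across pixels and its shot noise (many summed channels) stays small
    if (n_background < 3) stop("n_background must be >= 3", call. = FALSE)
    bg_mz <- c(132.0756, 104.1070, 760.5856)
    while (length(bg_mz) < n_background) {
      cand <- stats::runif(1, 70, 900)
      if (all(abs(cand - bg_mz) / cand * 1e6 > 50)) bg_mz <- c(bg_mz, cand)
    }
    bg_base <- stats::rlnorm(n_background, log(3e4), 0.8)
    bg_base[1:3] <- c(4e5, 2.5e5, 1e5)   # landmark ions stay prominent
    background <- lapply(seq_len(n_background), function(i) {
      list(mz = bg_mz[i], base_intensity = bg_base[i],
           modulation = rank_rescale(smooth_field(n_lines, width_px),
                                     0.9, 1.1))
    })

    structure(
      list(n_lines = as.integer(n_lines),
           width_px = as.integer(width_px),
           analytes = analytes,
           suppression_map = supp,
           background_ions = background,
           is_channel = list(name = "IS", mz = 149.0574, gain = gain,
                             conc = 10),
           seed = as.integer(seed)),
      class = "msi_phantom"
    )
  })
}

#' @export
print.msi_phantom <- function(x, ...) {
  cat("MSI phantom:", x$n_lines, "lines x", x$width_px, "px\n")
  cat("  analytes:",
      paste(sprintf("%s (m/z %.4f)", names(x$analytes),
                    vapply(x$analytes, `[[`, 0, "mz")), collapse = ", "),
      "\n")
  cat(sprintf("  suppression range: %.3f - %.3f\n",
              min(x$suppression_map), max(x$suppression_map)))
  cat(sprintf("  IS: m/z %.4f at %g uM\n", x$is_channel$mz, x$is_channel$conc))
  cat("  background ions:", length(x$background_ions), "\n")
  invisible(x)
}
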