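#' Simulate line-scan spectra from a phantom
#'
#' Generates centroided spectra for each line of the phantom under a solvent
#' scheme. At pixel p on a line acquired with solvent v the expected analyte
#' intensity is `gain * suppression(p) * (C_true(p) + C_added(v))` — added
#' standards ride in the extraction solvent, so they experience the same
#' per-pixel ion suppression as the endogenous analyte. The internal
#' standard responds as `gain_IS * suppression(p) * C_IS(v)`, and background
#' matrix ions (unsuppressed, mildly spatially modulated) carry the TIC.
#' Intensities receive mean-1 multiplicative lognormal noise and an additive
#' Gaussian floor; m/z values are jittered uniformly within
#' `mz_jitter_ppm` to exercise downstream feature alignment.
#'
#' @param phantom an [make_phantom()] object.
#' @param scheme a [solvent_scheme()]; analyte names are matched to the
#'   phantom's analytes, internal standards to its IS channel.
#' @param line_assignment character vector, one solvent id per line.
#' @param noise a [noise_model()].
#' @param scans_per_line number of scans per line (default: phantom width).
#' @param scan_rate scans per second (sets retention times).
#' @param line_spacing across-line spacing in µm (sets y positions).
#' @param mz_jitter_ppm half-width of the uniform m/z jitter (ppm).
#' @return an object of class `line_scan_set`; the generating phantom is
#'   kept in attribute `"phantom"` for ground-truth recovery tests.
#' @export
simulate_linescans <- function(phantom, scheme, line_assignment,
                               noise = noise_model(),
                               scans_per_line = phantom$width_px,
                               scan_rate = 1.96, line_spacing = 150,
                               mz_jitter_ppm = 2) {
  stopifnot(inherits(phantom, "msi_phantom"),
            inherits(scheme, "solvent_scheme"),
            inherits(noise, "noise_model"))
  line_assignment <- as.character(line_assignment)
  if (length(line_assignment) != phantom$n_lines) {
    stop("line_assignment must have one solvent id per phantom line",
         call. = FALSE)
  }
  unknown <- setdiff(line_assignment, names(scheme$solvents))
  if (length(unknown)) {
    stop("unknown solvent id(s) in line_assignment: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (scans_per_line < 1 || scans_per_line > phantom$width_px) {
    stop("scans_per_line must be in [1, phantom$width_px]", call. = FALSE)
  }

  cv <- noise$multiplicative_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2       # multiplicative factor has mean exactly 1
  is_name <- phantom$is_channel$name

  with_seed(noise$seed, {
    lines <- vector("list", phantom$n_lines)
    for (l in seq_len(phantom$n_lines)) {
      sid <- line_assignment[l]
      sol <- scheme$solvents[[sid]]
      is_conc <- if (is_name %in% names(sol$is)) {
        unname(sol$is[[is_name]])
      } else if (length(sol$is)) unname(sol$is[[1]]) else phantom$is_channel$conc

      # expected-intensity matrix [ion x scan] for the whole line
      S <- scans_per_line
      supp <- phantom$suppression_map[l, seq_len(S)]
      mz0 <- c(vapply(phantom$analytes, `[[`, 0, "mz"),
               phantom$is_channel$mz,
               vapply(phantom$background_ions, `[[`, 0, "mz"))
      ev <- rbind(
        t(vapply(phantom$analytes, function(a) {
          add <- if (a$name %in% names(sol$added)) {
            unname(sol$added[[a$name]])
          } else 0
          a$gain * supp * (a$true_conc_map[l, seq_len(S)] + add)
        }, numeric(S))),
        phantom$is_channel$gain * supp * is_conc,
        t(vapply(phantom$background_ions, function(b) {
          b$base_intensity * b$modulation[l, seq_len(S)]
        }, numeric(S))))
      n_ion <- length(mz0)
      intensity <- ev
      if (cv > 0) {
        intensity <- intensity *
          exp(matrix(stats::rnorm(n_ion * S, meanlog, sdlog), n_ion, S))
      }
      if (noise$additive_sd > 0) {
        intensity <- intensity +
          matrix(stats::rnorm(n_ion * S, 0, noise$additive_sd), n_ion, S)
      }
      mzm <- matrix(mz0, n_ion, S)
      if (mz_jitter_ppm > 0) {
        mzm <- mzm * (1 + matrix(stats::runif(n_ion * S, -mz_jitter_ppm,
                                              mz_jitter_ppm),
                                 n_ion, S) * 1e-6)
      }
      spectra <- lapply(seq_len(S), function(s) {
        keep <- intensity[, s] > 0
        o <- order(mzm[keep, s])
        list(rt = (s - 1) / scan_rate,
             mz = unname(mzm[keep, s][o]),
             intensity = unname(intensity[keep, s][o]))
      })
      lines[[l]] <- list(line_id = sprintf("line_%03d", l),
                         y_position = (l - 1) * line_spacing,
                         solvent_id = sid,
                         spectra = spectra)
    }
    structure(list(lines = lines, scan_rate = scan_rate,
                   line_spacing = line_spacing, seed = noise$seed),
              class = "line_scan_set",
              phantom = phantom)
  })
}

#' Export a line-scan set as centroided mzML files
#'
#' Writes one centroid-mode mzML file per line plus a `manifest.json`
#' sidecar recording line order, solvent ids, y positions, scan rate and the
#' simulation seed, so the set can be reassembled with [read_linescans()].
#'
#' @param linescans a `line_scan_set`.
#' @param out_dir output directory (created if missing).
#' @return character vector of mzML paths (invisibly adds the manifest path
#'   as attribute `"manifest"`); an empty set writes nothing and returns
#'   `character(0)`.
#' @export
export_mzml <- function(linescans, out_dir) {
  stopifnot(inherits(linescans, "line_scan_set"))
  if (length(linescans$lines) == 0) return(character(0))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)

  paths <- character(length(linescans$lines))
  for (i in seq_along(linescans$lines)) {
    ln <- linescans$lines[[i]]
    f <- file.path(out_dir, paste0(ln$line_id, ".mzML"))
    write_line_mzml(ln$spectra, f)
    paths[i] <- f
  }
  man <- list(
    files = basename(paths),
    line_ids = vapply(linescans$lines, `[[`, "", "line_id"),
    solvent_ids = vapply(linescans$lines, `[[`, "", "solvent_id"),
    y_positions = vapply(linescans$lines, `[[`, 0, "y_position"),
    scan_rate = linescans$scan_rate,
    line_spacing = linescans$line_spacing,
    seed = linescans$seed
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, mpath, auto_unbox = TRUE, digits = NA)
  attr(paths, "manifest") <- mpath
  paths
}

# write one line's centroid spectra through the mzML writer
write_line_mzml <- function(spectra, path) {
  n <- length(spectra)
  pks <- lapply(spectra, function(sp) {
    cbind(mz = as.numeric(sp$mz), intensity = as.numeric(sp$intensity))
  })
  npk <- vapply(pks, nrow, 0L)
  tic <- vapply(spectra, function(sp) sum(sp$intensity), 0)
  bpi <- vapply(spectra, function(sp) {
    if (length(sp$intensity)) max(sp$intensity) else 0
  }, 0)
  bpm <- vapply(spectra, function(sp) {
    if (length(sp$intensity)) sp$mz[which.max(sp$intensity)] else 0
  }, 0)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = npk, totIonCurrent = tic,
    retentionTime = vapply(spectra, `[[`, 0, "rt"),
    basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra, function(sp) {
      if (length(sp$mz)) min(sp$mz) else 0
    }, 0),
    highMZ = vapply(spectra, function(sp) {
      if (length(sp$mz)) max(sp$mz) else 0
    }, 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = 70, scanWindowUpperLimit = 1000
  )
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml",
                   rtime_seconds = TRUE)
  invisible(path)
}
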