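#' Define a solvent scheme
#'
#' A solvent scheme maps each solvent identity to the concentrations of
#' analyte standards added to it and the (constant) internal-standard
#' concentrations, plus the concentration unit. At least one solvent must be
#' the baseline solvent, i.e. carry zero added standard for every analyte;
#' internal standards only do not count as additions.
#'
#' @param solvents named list; each element is a list with numeric named
#'   vectors `added` (analyte -> added concentration) and optionally `is`
#'   (internal standard -> concentration).
#' @param units `"uM"` for absolute detected concentrations or
#'   `"mg_per_mL_relative"` for extract-based (relative) additions.
#' @return an object of class `solvent_scheme`.
#' @examples
#' solvent_scheme(list(
#'   s1 = list(added = c(Glu = 0), is = c(IS = 10)),
#'   s2 = list(added = c(Glu = 15), is = c(IS = 10)),
#'   s3 = list(added = c(Glu = 30), is = c(IS = 10))))
#' @export
solvent_scheme <- function(solvents, units = c("uM", "mg_per_mL_relative")) {
  units <- match.arg(units)
  if (length(solvents) < 1 || is.null(names(solvents)) ||
      any(names(solvents) == "")) {
    stop("solvents must be a non-empty named list", call. = FALSE)
  }
  solvents <- lapply(solvents, function(s) {
    added <- unlist(s$added)
    if (is.null(added)) added <- numeric(0)
    isc <- unlist(s$is)
    if (is.null(isc)) isc <- numeric(0)
    if (any(added < 0) || any(isc < 0)) {
      stop("concentrations must be nonnegative", call. = FALSE)
    }
    list(added = added, is = isc)
  })
  baseline <- vapply(solvents, function(s) all(s$added == 0), TRUE)
  if (!any(baseline)) {
    stop("scheme needs a baseline solvent with zero added standard",
         call. = FALSE)
  }
  structure(list(solvents = solvents, units = units),
            class = "solvent_scheme")
}

#' @export
print.solvent_scheme <- function(x, ...) {
  cat("Solvent scheme (", x$units, "), ", length(x$solvents),
      " solvents:\n", sep = "")
  for (id in names(x$solvents)) {
    s <- x$solvents[[id]]
    cat("  ", id, ": added [",
        paste(sprintf("%s=%g", names(s$added), s$added), collapse = ", "),
        "]", sep = "")
    if (length(s$is)) {
      cat("  IS [", paste(sprintf("%s=%g", names(s$is), s$is),
                          collapse = ", "), "]", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

# solvent ids ordered by ascending total addition (used to order the points
# of a standard-addition window)
solvent_order <- function(scheme, analyte = NULL) {
  tot <- vapply(scheme$solvents, function(s) {
    if (is.null(analyte)) sum(s$added)
    else if (analyte %in% names(s$added)) unname(s$added[[analyte]]) else 0
  }, 0)
  names(sort(tot))
}

# added concentration of `analyte` in solvent `id` (0 when absent)
added_conc <- function(scheme, id, analyte) {
  s <- scheme$solvents[[id]]
  if (is.null(s)) stop("unknown solvent id: ", id, call. = FALSE)
  if (analyte %in% names(s$added)) unname(s$added[[analyte]]) else 0
}

# ids of solvents with zero total addition
baseline_solvents <- function(scheme) {
  names(scheme$solvents)[vapply(scheme$solvents,
                                function(s) all(s$added == 0), TRUE)]
}

#' Load a solvent scheme (and optional run settings) from YAML or JSON
#'
#' The config maps solvent ids to added standard concentrations and internal
#' standard concentrations, with a single `units` entry. Optional top-level
#' keys `line_assignment`, `geometry` (`stage_speed`, `scan_rate`,
#' `line_spacing`) and `monitor_ion` are attached as attributes when present.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated [solvent_scheme()]; attributes `line_assignment`,
#'   `geometry`, `monitor_ion` when present in the file.
#' @export
load_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported scheme format: .", ext, call. = FALSE)
  }
  if (is.null(cfg$solvents)) stop("config lacks 'solvents'", call. = FALSE)
  units <- if (is.null(cfg$units)) "uM" else cfg$units
  if (!units %in% c("uM", "mg_per_mL_relative")) {
    stop("units must be 'uM' or 'mg_per_mL_relative', got: ", units,
         call. = FALSE)
  }
  sch <- solvent_scheme(cfg$solvents, units = units)
  if (!is.null(cfg$line_assignment)) {
    attr(sch, "line_assignment") <- as.character(unlist(cfg$line_assignment))
  }
  if (!is.null(cfg$geometry)) attr(sch, "geometry") <- cfg$geometry
  if (!is.null(cfg$monitor_ion)) attr(sch, "monitor_ion") <- cfg$monitor_ion
  sch
}

#' Pixel geometry of a line-scan acquisition
#'
#' In line-scan MSI the along-scan pixel width is set by the stage speed and
#' the mass spectrometer scan rate, and the across-line pixel height by the
#' line spacing. At the reference settings (0.04 mm/s, 1.96 scans/s, 150 µm)
#' the pixel is ~20 x 150 µm.
#'
#' @param stage_speed sample stage speed, mm/s.
#' @param scan_rate mass spectrometer scan rate, scans/s.
#' @param line_spacing spacing between adjacent lines, µm.
#' @return list with `pixel_dx` and `pixel_dy` in µm.
#' @examples
#' compute_geometry(0.04, 1.96, 150) # ~20.4 x 150 um
#' @export
compute_geometry <- function(stage_speed, scan_rate, line_spacing) {
  if (stage_speed <= 0 || scan_rate <= 0 || line_spacing <= 0) {
    stop("geometry inputs must be positive", call. = FALSE)
  }
  list(pixel_dx = 1000 * stage_speed / scan_rate,
       pixel_dy = line_spacing)
}

#' Read one centroided mzML line scan
#'
#' Reads all MS1 spectra of a centroided mzML file, ordered by retention
#' time. Profile-mode data are rejected; truncated files raise a parse error
#' rather than returning partial data.
#'
#' @param path path to a centroided mzML file.
#' @return list with `line_id` (file stem) and `spectra`, a list of
#'   centroid spectra, each a list with `rt` (s), `mz` (sorted Th) and
#'   `intensity`.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path, call. = FALSE)
  # cheap structural integrity check before handing to the parser: a valid
  # (indexed)mzML document ends with its closing root tag
  sz <- file.info(path)$size
  con <- file(path, "rb")
  tail_bytes <- rawToChar(
    {seek(con, max(0, sz - 200)); readBin(con, "raw", 200)})
  close(con)
  if (!grepl("</indexedmzML>|</mzML>", tail_bytes)) {
    stop("malformed or truncated mzML file: ", path, call. = FALSE)
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  if (nrow(hdr) == 0) stop("no spectra in ", path, call. = FALSE)
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    stop("profile-mode spectra are not supported: ", path, call. = FALSE)
  }
  ms1 <- which(hdr$msLevel == 1L)
  ord <- ms1[order(hdr$retentionTime[ms1])]
  pk <- mzR::peaks(fh)
  spectra <- lapply(ord, function(i) {
    p <- pk[[i]]
    o <- order(p[, 1])
    list(rt = hdr$retentionTime[i],
         mz = p[o, 1], intensity = p[o, 2])
  })
  list(line_id = tools::file_path_sans_ext(basename(path)),
       spectra = spectra)
}

#' Read an exported line-scan set back from disk
#'
#' Uses the JSON manifest written by [export_mzml()] to reassemble a
#' `line_scan_set` (line order, solvent ids, y positions) from the per-line
#' mzML files.
#'
#' @param dir directory containing `manifest.json` and the mzML files.
#' @return a `line_scan_set`.
#' @export
read_linescans <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("manifest.json not found in ", dir,
                                call. = FALSE)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  lines <- lapply(seq_along(man$files), function(i) {
    sc <- read_mzml(file.path(dir, man$files[i]))
    list(line_id = man$line_ids[i],
         y_position = man$y_positions[i],
         solvent_id = as.character(man$solvent_ids[i]),
         spectra = sc$spectra)
  })
  structure(list(lines = lines,
                 scan_rate = man$scan_rate,
                 line_spacing = man$line_spacing,
                 seed = man$seed),
            class = "line_scan_set")
}

#' @export
print.line_scan_set <- function(x, ...) {
  ns <- vapply(x$lines, function(l) length(l$spectra), 0L)
  cat("Line-scan set:", length(x$lines), "lines,",
      paste(range(ns), collapse = "-"), "scans/line\n")
  cat("  solvents:", paste(unique(vapply(x$lines, `[[`, "", "solvent_id")),
                           collapse = ", "), "\n")
  invisible(x)
}
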