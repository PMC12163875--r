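#' Run the imaging pipeline end to end
#'
#' Thin orchestration over the package's stages, driven by a YAML/JSON run
#' config. Stages: `"simulate"` (phantom -> line scans -> mzML + manifest),
#' `"quantify-image"` (mzML -> feature alignment -> TIC-normalized cube ->
#' sliding standard-addition image, plus the internal-standard comparator
#' image; CSV rasters and PNG previews), `"roi"` (ROI extraction + method
#' comparison table), or `"all"`. A machine-readable run manifest (seed,
#' parameter hash, outputs) is written to the output directory.
#'
#' Config keys (all optional unless noted): `scheme` (path to the solvent
#' scheme, required for quantification), `out_dir`, `seed`, `phantom`
#' (`n_lines`, `width_px`, `n_analytes`, `suppression`, `conc_max`),
#' `noise` (`cv`, `additive_sd`), `geometry` (`stage_speed`, `scan_rate`,
#' `line_spacing`), `tolerance_ppm`, `block`, `stride_x`, `alpha`,
#' `percentile`, `rois` (list of name/x0/y0/x1/y1).
#'
#' @param config path to a YAML/JSON config file, or an equivalent list.
#' @param stage one of `"simulate"`, `"quantify-image"`, `"roi"`, `"all"`.
#' @return (invisibly) list of produced artifact paths.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate",
                                           "quantify-image", "roi")) {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    ext <- tolower(tools::file_ext(config))
    if (ext %in% c("yaml", "yml")) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  } else config

  out_dir <- if (is.null(cfg$out_dir)) "qsa_out" else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  geom_cfg <- cfg$geometry
  geometry <- compute_geometry(
    stage_speed = if (is.null(geom_cfg$stage_speed)) 0.04
                  else geom_cfg$stage_speed,
    scan_rate = if (is.null(geom_cfg$scan_rate)) 1.96 else geom_cfg$scan_rate,
    line_spacing = if (is.null(geom_cfg$line_spacing)) 150
                   else geom_cfg$line_spacing)
  tol <- if (is.null(cfg$tolerance_ppm)) 5 else cfg$tolerance_ppm
  block <- if (is.null(cfg$block)) 8L else as.integer(cfg$block)
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  pct <- if (is.null(cfg$percentile)) 99 else cfg$percentile

  if (is.null(cfg$scheme)) stop("config lacks 'scheme'", call. = FALSE)
  scheme <- if (is.character(cfg$scheme)) load_scheme(cfg$scheme)
            else solvent_scheme(cfg$scheme$solvents,
                                units = if (is.null(cfg$scheme$units)) "uM"
                                        else cfg$scheme$units)
  artifacts <- list()
  mzml_dir <- file.path(out_dir, "mzml")

  if (stage %in% c("simulate", "all")) {
    pcfg <- cfg$phantom
    ph <- make_phantom(
      n_lines = if (is.null(pcfg$n_lines)) 12L else pcfg$n_lines,
      width_px = if (is.null(pcfg$width_px)) 64L else pcfg$width_px,
      n_analytes = if (is.null(pcfg$n_analytes)) 1L else pcfg$n_analytes,
      suppression_range = if (is.null(pcfg$suppression)) c(0.3, 1)
                          else unlist(pcfg$suppression),
      conc_max = if (is.null(pcfg$conc_max)) 20 else pcfg$conc_max,
      seed = seed)
    la <- attr(scheme, "line_assignment")
    if (is.null(la)) {
      la <- rep(names(scheme$solvents), length.out = ph$n_lines)
    }
    nz <- cfg$noise
    noise <- noise_model(
      multiplicative_cv = if (is.null(nz$cv)) 0.1 else nz$cv,
      additive_sd = if (is.null(nz$additive_sd)) 0 else nz$additive_sd,
      seed = seed)
    lss <- simulate_linescans(
      ph, scheme, la, noise,
      scan_rate = if (is.null(geom_cfg$scan_rate)) 1.96
                  else geom_cfg$scan_rate,
      line_spacing = geometry$pixel_dy)
    paths <- export_mzml(lss, mzml_dir)
    artifacts$mzml <- paths
    artifacts$truth <- file.path(out_dir, "truth_summary.json")
    jsonlite::write_json(
      list(mean_suppression = mean(ph$suppression_map),
           analytes = names(ph$analytes),
           mean_conc = vapply(ph$analytes,
                              function(a) mean(a$true_conc_map), 0)),
      artifacts$truth, auto_unbox = TRUE, digits = NA)
  }

  if (stage %in% c("quantify-image", "roi", "all")) {
    if (!dir.exists(mzml_dir)) {
      stop("no mzML input at ", mzml_dir, "; run the simulate stage first",
           call. = FALSE)
    }
    lss <- read_linescans(mzml_dir)
    axis <- align_features(lss, tolerance_ppm = tol)
    cube <- build_cube(lss, axis, scheme, geometry)
    analytes <- unique(unlist(lapply(scheme$solvents,
                                     function(s) names(s$added)[s$added > 0])))
    target_mz <- cfg$target_mz
    images <- list()
    for (an in analytes) {
      mz <- if (!is.null(target_mz) && an %in% names(target_mz)) {
        target_mz[[an]]
      } else NULL
      if (is.null(mz)) next
      qi <- sliding_qsa(cube, mz, scheme, analyte = an, block = block,
                        alpha = alpha)
      images[[an]] <- qi
      base <- file.path(out_dir, paste0("qsa_", an))
      utils::write.csv(qi$conc, paste0(base, "_conc.csv"), row.names = FALSE)
      utils::write.csv(qi$sd, paste0(base, "_sd.csv"), row.names = FALSE)
      utils::write.csv(qi$flags, paste0(base, "_flags.csv"),
                       row.names = FALSE)
      grDevices::png(paste0(base, ".png"), width = 640, height = 480)
      plot(qi, pct = pct, main = paste0(an, " (qSA)"))
      grDevices::dev.off()
      artifacts[[paste0("qsa_", an)]] <- paste0(base, "_conc.csv")
    }
    artifacts$images <- images
  }

  if (stage %in% c("roi", "all") && !is.null(cfg$rois) &&
      length(artifacts$images) > 0) {
    rois <- lapply(cfg$rois, function(r) {
      roi_rect(r$name, r$x0, r$y0, r$x1, r$y1)
    })
    an <- names(artifacts$images)[1]
    tab <- do.call(rbind, lapply(rois, function(r) {
      px <- roi_extract(artifacts$images[[an]], r)
      data.frame(roi = r$name, n = nrow(px),
                 median = stats::median(px$conc),
                 iqr = stats::IQR(px$conc))
    }))
    roi_path <- file.path(out_dir, "roi_table.csv")
    utils::write.csv(tab, roi_path, row.names = FALSE)
    artifacts$roi_table <- roi_path
  }

  # run manifest: seed + md5 of the canonicalized parameters (paths
  # excluded: the scheme file is hashed by content instead)
  par <- cfg[setdiff(names(cfg), c("out_dir", "scheme"))]
  par_json <- jsonlite::toJSON(par[order(names(par))], auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(par_json, tmp)
  manifest <- list(
    package = "qsaMSI",
    version = as.character(utils::packageVersion("qsaMSI")),
    stage = stage, seed = seed,
    parameter_md5 = unname(tools::md5sum(tmp)),
    scheme_md5 = if (is.character(cfg$scheme)) {
      unname(tools::md5sum(cfg$scheme))
    } else NULL,
    outputs = unlist(lapply(artifacts[names(artifacts) != "images"],
                            function(x) if (is.character(x)) x else NULL))
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(artifacts)
}
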