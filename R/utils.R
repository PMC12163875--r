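#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' simulation helpers do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Parts-per-million distance between m/z values
#'
#' @param mz observed m/z (Th).
#' @param ref reference m/z (Th); the denominator of the ppm ratio.
#' @return signed ppm difference `(mz - ref) / ref * 1e6`.
#' @keywords internal
ppm_diff <- function(mz, ref) (mz - ref) / ref * 1e6

#' Stock concentration of a tissue extract
#'
#' Concentration of an extract stock expressed as mg of wet tissue per mL of
#' solvent, the unit in which extract-based calibrant additions are dosed
#' when relative (nontargeted) quantification is performed.
#'
#' @param mass_g wet tissue mass placed in the solvent (g).
#' @param volume_mL solvent volume (mL).
#' @return concentration in mg/mL.
#' @examples
#' stock_concentration(1.17607, 33.976) # ~34.6 mg/mL
#' @export
stock_concentration <- function(mass_g, volume_mL) {
  if (!is.numeric(mass_g) || !is.numeric(volume_mL) ||
      any(mass_g <= 0) || any(volume_mL <= 0)) {
    stop("mass_g and volume_mL must be positive numbers", call. = FALSE)
  }
  mass_g * 1000 / volume_mL
}

# smooth 2-D random field: sum of `k` Gaussian bumps with random centres,
# widths and signed amplitudes; used for concentration, suppression and
# background-modulation rasters. Bump widths are drawn in raster units
# (lines / pixels) from `sy_range` / `sx_range`, so the field's correlation
# length is physical (anatomical structures are mm-scale) and does not
# shrink with smaller test rasters.
smooth_field <- function(n_lines, width_px, k = 6L,
                         sy_range = c(10, 27), sx_range = c(75, 200)) {
  ly <- seq_len(n_lines)
  lx <- seq_len(width_px)
  field <- matrix(0, n_lines, width_px)
  for (i in seq_len(k)) {
    cy <- stats::runif(1, 1 - 0.3 * n_lines, 1.3 * n_lines)
    cx <- stats::runif(1, 1 - 0.3 * width_px, 1.3 * width_px)
    sy <- stats::runif(1, sy_range[1], sy_range[2])
    sx <- stats::runif(1, sx_range[1], sx_range[2])
    amp <- stats::runif(1, 0.3, 1) * sample(c(-1, 1), 1)
    field <- field + amp * outer(exp(-(ly - cy)^2 / (2 * sy^2)),
                                 exp(-(lx - cx)^2 / (2 * sx^2)))
  }
  field
}

# rank-transform a field to the range [lo, hi]: preserves the spatial
# ordering (smoothness) while making the marginal distribution uniform on
# [lo, hi], so the field's mean and median equal (lo + hi) / 2
rank_rescale <- function(field, lo, hi) {
  n <- length(field)
  if (n == 1L || lo == hi) {
    field[] <- (lo + hi) / 2
    return(field)
  }
  u <- (rank(field, ties.method = "first") - 1) / (n - 1)
  field[] <- lo + u * (hi - lo)
  field
}

# linear min-max rescale to [lo, hi]
range_rescale <- function(field, lo, hi) {
  rng <- range(field)
  if (diff(rng) == 0) {
    field[] <- (lo + hi) / 2
    return(field)
  }
  lo + (field - rng[1]) / diff(rng) * (hi - lo)
}
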