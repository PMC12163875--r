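# shared fixtures: small phantoms, schemes and spectra built in code

# three-solvent scheme with additions 0 / lo / hi for one analyte
test_scheme <- function(analyte = "Glu", lo = 10, hi = 20, is_conc = 10) {
  solvent_scheme(list(
    s1 = list(added = stats::setNames(0, analyte), is = c(IS = is_conc)),
    s2 = list(added = stats::setNames(lo, analyte), is = c(IS = is_conc)),
    s3 = list(added = stats::setNames(hi, analyte), is = c(IS = is_conc))
  ))
}

# phantom + simulated line-scan set under a repeating s1/s2/s3 pattern
test_simulation <- function(n_lines = 12, width_px = 64, cv = 0,
                            seed = 7, suppression = c(0.3, 1),
                            n_background = 40) {
  ph <- make_phantom(n_lines, width_px, n_analytes = 1,
                     suppression_range = suppression, seed = seed,
                     n_background = n_background)
  sch <- test_scheme()
  la <- rep(c("s1", "s2", "s3"), length.out = n_lines)
  lss <- simulate_linescans(ph, sch, la, noise_model(cv, 0, seed = seed))
  list(phantom = ph, scheme = sch, assignment = la, linescans = lss)
}

# a hand-built centroid spectrum
spec1 <- function(rt, mz, intensity) list(rt = rt, mz = mz,
                                          intensity = intensity)

# phantom with user-supplied rasters (constant or piecewise-constant maps
# for exactness tests); single analyte + IS + one flat background ion
manual_phantom <- function(conc_map, supp_map, gain = 1, is_conc = 10,
                           bg_intensity = 1e9) {
  d <- dim(conc_map)
  structure(
    list(n_lines = d[1], width_px = d[2],
         analytes = list(Glu = list(name = "Glu", mz = 148.0604,
                                    gain = gain, true_conc_map = conc_map)),
         suppression_map = supp_map,
         background_ions = list(list(
           mz = 132.0756, base_intensity = bg_intensity,
           modulation = matrix(1, d[1], d[2]))),
         is_channel = list(name = "IS", mz = 149.0574, gain = gain,
                           conc = is_conc),
         seed = 0L),
    class = "msi_phantom")
}

# block/window-averaged ground truth matching a sliding_qsa raster
window_truth <- function(truth, wins, n_blocks, block = 8) {
  vapply(seq_len(n_blocks), function(b) {
    vapply(seq_along(wins), function(w) {
      mean(truth[wins[[w]], ((b - 1) * block + 1):(b * block)])
    }, 0)
  }, numeric(length(wins)))
}
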