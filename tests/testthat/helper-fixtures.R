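# Shared fixtures built in code.

flat_spec <- function(value, wl = spectral_grid(), kind = "reflectance") {
  spec(wl, rep(value, length(wl)), kind)
}

# flat (spectrally neutral) light field for constructed-control scenarios
flat_light_field <- function(wl = spectral_grid()) {
  light_field(flat_spec(1, wl, "irradiance"),
              flat_spec(1, wl, "irradiance"),
              flat_spec(0.05, wl, "radiance"))
}

# unit lens: no ocular filtering
unit_lens <- function(wl = spectral_grid()) flat_spec(1, wl, "transmission")

# logistic transmission curve with known midpoint
logistic_transmission <- function(midpoint, slope = 5, wl = spectral_grid()) {
  spec(wl, 1 / (1 + exp(-(wl - midpoint) / slope)), "transmission")
}

# brute-force piecewise-linear evaluation, the independent oracle for resample()
naive_interp <- function(s, x) {
  vapply(x, function(xi) {
    i <- max(which(s$wl <= xi + 1e-12))
    if (s$wl[i] == xi || i == nrow(s)) return(s$value[i])
    w <- (xi - s$wl[i]) / (s$wl[i + 1] - s$wl[i])
    (1 - w) * s$value[i] + w * s$value[i + 1]
  }, numeric(1))
}
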