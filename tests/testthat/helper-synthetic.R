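# shared fixtures: synthetic curves with known ground truth

default_grid <- function(...) curve_spec(...)

# noise_scale giving a target signal-to-noise ratio at the first-order
# peak (height over the counting-noise sd at that intensity)
noise_for_snr <- function(snr, height = 1000, cs = curve_spec(), q1 = 0.07) {
  bg <- cs$background_amplitude * q1^(-cs$background_exponent) +
    cs$background_constant
  height / (snr * sqrt(height + bg))
}

make_lamellar <- function(d, n_orders = 3, snr = Inf, seed = NULL, ...) {
  ph <- phase_spec("lamellar", d, n_orders = n_orders, ...)
  ns <- if (is.finite(snr)) noise_for_snr(snr, ph$amplitude,
                                          q1 = 2 * pi / d) else 0
  generate_pattern(ph, curve_spec(noise_scale = ns, seed = seed),
                   sample_label = sprintf("lam_d%.3g", d))
}

make_hexagonal <- function(a, n_orders = 5, snr = Inf, seed = NULL, ...) {
  ph <- phase_spec("hexagonal", a, n_orders = n_orders, ...)
  ns <- if (is.finite(snr)) noise_for_snr(snr, ph$amplitude,
                                          q1 = 4 * pi / (sqrt(3) * a)) else 0
  generate_pattern(ph, curve_spec(noise_scale = ns, seed = seed),
                   sample_label = sprintf("hex_a%.3g", a))
}

# curve -> peaks, with background removed
detect <- function(curve, ...) find_peaks(subtract_background(curve), ...)

grid_step <- function(curve) diff(curve$q[1:2])
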