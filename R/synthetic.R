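#' Lattice specification for a synthetic diffraction pattern
#'
#' Describes one lyotropic mesophase as a set of Bragg reflections. The
#' first-order position follows from the lattice parameter: q1 = 2*pi/d
#' for a lamellar stack, q1 = 4*pi/(sqrt(3)*a) for a 2D hexagonal
#' lattice, and q_hkl = 2*pi*sqrt(h^2+k^2+l^2)/a for a cubic lattice
#' (the cubic `ratio_set` holds the sqrt(h^2+k^2+l^2) values of the
#' allowed reflections themselves).
#'
#' @param phase_type `"lamellar"`, `"hexagonal"` or `"cubic"`.
#' @param lattice_parameter Repeat distance d (lamellar) or lattice
#'   parameter a (hexagonal/cubic), in Angstrom; > 0.
#' @param n_orders Number of reflections to emit (<= length of the
#'   ratio set).
#' @param relative_amplitudes Positive per-reflection height factors;
#'   default a geometric decay 0.6^(i-1). The relative intensities of
#'   higher orders are free parameters of the simulation, not a
#'   physical form-factor model.
#' @param amplitude Height of the first reflection in counts (a.u.).
#' @param peak_width Full width at half maximum of each peak, 1/Angstrom.
#' @param ratio_set Ordered positive reflection-position ratios.
#'   Defaults: `1:n_orders` (lamellar); `c(1, sqrt(3), 2, sqrt(7), 3)`
#'   (hexagonal); for cubic the set must be given explicitly, e.g. one
#'   of [cubic_ratio_sets()].
#' @param voigt_eta Pseudo-Voigt mixing parameter in [0, 1]
#'   (0 = Gaussian, 1 = Lorentzian); default 0.5.
#'
#' @return An object of class `phase_spec`.
#' @seealso [generate_pattern()], [cubic_ratio_sets()]
#' @export
phase_spec <- function(phase_type = c("lamellar", "hexagonal", "cubic"),
                       lattice_parameter,
                       n_orders = NULL,
                       relative_amplitudes = NULL,
                       amplitude = 1000,
                       peak_width = 0.004,
                       ratio_set = NULL,
                       voigt_eta = 0.5) {
  phase_type <- match.arg(phase_type)
  abort_if(!is_number(lattice_parameter) || lattice_parameter <= 0,
           "lattice_parameter must be a positive number")
  abort_if(!is_number(peak_width) || peak_width <= 0,
           "peak_width must be positive")
  abort_if(!is_number(voigt_eta) || voigt_eta < 0 || voigt_eta > 1,
           "voigt_eta must lie in [0, 1]")
  if (is.null(ratio_set)) {
    ratio_set <- switch(phase_type,
      lamellar   = seq_len(n_orders %||% 3L),
      hexagonal  = hexagonal_ratios(),
      cubic      = stop("cubic phase_spec needs an explicit ratio_set; ",
                        "see cubic_ratio_sets()", call. = FALSE))
  }
  abort_if(any(ratio_set <= 0) || any(diff(ratio_set) <= 0),
           "ratio_set must be positive and strictly increasing")
  n_orders <- n_orders %||% length(ratio_set)
  abort_if(n_orders < 1L || n_orders > length(ratio_set),
           "n_orders must be in 1..length(ratio_set)")
  ratio_set <- ratio_set[seq_len(n_orders)]
  if (is.null(relative_amplitudes))
    relative_amplitudes <- 0.6^(seq_len(n_orders) - 1L)
  abort_if(length(relative_amplitudes) != n_orders,
           "relative_amplitudes must have one entry per reflection")
  abort_if(any(relative_amplitudes <= 0),
           "relative_amplitudes must be positive")
  structure(list(phase_type = phase_type,
                 lattice_parameter = lattice_parameter,
                 n_orders = as.integer(n_orders),
                 relative_amplitudes = relative_amplitudes,
                 amplitude = amplitude,
                 peak_width = peak_width,
                 ratio_set = ratio_set,
                 voigt_eta = voigt_eta),
            class = "phase_spec")
}

#' Reflection-position ratios of the reversed hexagonal phase
#'
#' The first five allowed reflections of a 2D hexagonal lattice fall at
#' 1, sqrt(3), 2, sqrt(7), 3 times the first-order position.
#' @return Numeric vector of length 5.
#' @export
hexagonal_ratios <- function() c(1, sqrt(3), 2, sqrt(7), 3)

# position of the first emitted reflection for a phase_spec
first_order_q <- function(phase) {
  L <- phase$lattice_parameter
  switch(phase$phase_type,
         lamellar  = 2 * pi / L,
         hexagonal = 4 * pi / (sqrt(3) * L),
         cubic     = 2 * pi * phase$ratio_set[1] / L)
}

# ground-truth reflection centers of a phase_spec, 1/Angstrom
peak_centers <- function(phase) {
  first_order_q(phase) * phase$ratio_set / phase$ratio_set[1]
}

#' Acquisition grid and background for a synthetic curve
#'
#' @param q_min,q_max q range in 1/Angstrom (default 0.012-0.67, a
#'   typical laboratory SAXS window).
#' @param n_points Grid size (>= 50), default 800.
#' @param background_amplitude,background_exponent,background_constant
#'   Parameters of the smooth background A*q^(-p) + c.
#' @param noise_scale Counting-noise scale: Gaussian noise with standard
#'   deviation `noise_scale * sqrt(intensity)` (Poisson-like); 0 for a
#'   noiseless curve.
#' @param seed Integer seed making the noise reproducible; `NULL` draws
#'   from the ambient RNG stream.
#' @return An object of class `curve_spec`.
#' @export
curve_spec <- function(q_min = 0.012, q_max = 0.67, n_points = 800L,
                       background_amplitude = 0.1,
                       background_exponent = 2,
                       background_constant = 1,
                       noise_scale = 0, seed = NULL) {
  abort_if(!(q_min > 0 && q_max > q_min), "need 0 < q_min < q_max")
  abort_if(n_points < 50L, "n_points must be >= 50")
  abort_if(noise_scale < 0, "noise_scale must be nonnegative")
  structure(list(q_min = q_min, q_max = q_max,
                 n_points = as.integer(n_points),
                 background_amplitude = background_amplitude,
                 background_exponent = background_exponent,
                 background_constant = background_constant,
                 noise_scale = noise_scale, seed = seed),
            class = "curve_spec")
}

# unit-height pseudo-Voigt profile, FWHM w, mixing eta
pseudo_voigt <- function(q, q0, w, eta) {
  x <- (q - q0) / w
  G <- exp(-4 * log(2) * x^2)
  L <- 1 / (1 + 4 * x^2)
  eta * L + (1 - eta) * G
}

bg_eval <- function(q, A, p, c0) A * q^(-p) + c0

#' Generate a synthetic mesophase diffraction pattern
#'
#' Forward model for validation: a power-law background plus
#' pseudo-Voigt Bragg peaks at the reflection positions of the given
#' lattice, with optional Poisson-like counting noise. Ground-truth
#' peak centers and heights are recorded in the curve metadata.
#'
#' @param phase A [phase_spec()].
#' @param curve A [curve_spec()].
#' @inheritParams scattering_curve
#' @return A [scattering_curve()] with ground-truth metadata.
#' @export
#' @examples
#' lam <- phase_spec("lamellar", lattice_parameter = 94, n_orders = 3)
#' sc <- generate_pattern(lam, curve_spec())
generate_pattern <- function(phase, curve = curve_spec(),
                             sample_label = "synthetic",
                             hydration = NA_real_,
                             hydration_kind = c("wt_pct", "RH"),
                             temperature = NA_real_) {
  stopifnot(inherits(phase, "phase_spec"), inherits(curve, "curve_spec"))
  hydration_kind <- match.arg(hydration_kind)
  centers <- peak_centers(phase)
  bad <- which(centers < curve$q_min | centers > curve$q_max)
  abort_if(length(bad) > 0,
           paste0("reflection %d (ratio %.5g) falls at q = %.5g 1/A, ",
                  "outside the grid [%.4g, %.4g]"),
           bad[1], phase$ratio_set[bad[1]], centers[bad[1]],
           curve$q_min, curve$q_max)
  q <- seq(curve$q_min, curve$q_max, length.out = curve$n_points)
  heights <- phase$amplitude * phase$relative_amplitudes
  intensity <- bg_eval(q, curve$background_amplitude,
                       curve$background_exponent,
                       curve$background_constant)
  for (i in seq_along(centers))
    intensity <- intensity +
      heights[i] * pseudo_voigt(q, centers[i], phase$peak_width,
                                phase$voigt_eta)
  if (curve$noise_scale > 0) {
    noisify <- function() {
      intensity + stats::rnorm(length(q),
                               sd = curve$noise_scale * sqrt(intensity))
    }
    intensity <- if (is.null(curve$seed)) noisify() else
      withr::with_seed(curve$seed, noisify())
    intensity <- pmax(intensity, 0)
  }
  scattering_curve(q, intensity, sample_label = sample_label,
                   hydration = hydration, hydration_kind = hydration_kind,
                   temperature = temperature,
                   metadata = list(
                     true_centers = centers,
                     true_heights = heights,
                     phase_type = phase$phase_type,
                     lattice_parameter = phase$lattice_parameter,
                     background = c(A = curve$background_amplitude,
                                    p = curve$background_exponent,
                                    c0 = curve$background_constant),
                     noise_scale = curve$noise_scale))
}

#' Superpose scattering curves into a phase-coexistence pattern
#'
#' Pointwise weighted sum of curves sharing one q grid, emulating a
#' sample in which two lattices coexist and their reflection series
#' superpose. The union of the component ground-truth centers is
#' carried in the metadata.
#'
#' @param curves Nonempty list of [scattering_curve()]s on a common grid.
#' @param weights Positive weights, one per curve (default all 1).
#' @param sample_label Label of the composite curve.
#' @return A [scattering_curve()].
#' @export
compose_coexistence <- function(curves, weights = NULL,
                                sample_label = "coexistence") {
  abort_if(length(curves) == 0L, "curves must be a nonempty list")
  stopifnot(all(vapply(curves, inherits, logical(1), "scattering_curve")))
  weights <- weights %||% rep(1, length(curves))
  abort_if(length(weights) != length(curves),
           "need one weight per curve")
  abort_if(any(weights <= 0), "weights must be positive")
  q0 <- curves[[1]]$q
  for (cv in curves[-1])
    abort_if(length(cv$q) != length(q0) || any(cv$q != q0),
             "curves must share one q grid")
  intensity <- Reduce(`+`, Map(function(cv, w) w * cv$intensity,
                               curves, weights))
  centers <- sort(unique(unlist(
    lapply(curves, function(cv) cv$metadata$true_centers))))
  components <- lapply(curves, function(cv) {
    md <- cv$metadata
    list(phase_type = md$phase_type,
         lattice_parameter = md$lattice_parameter,
         true_centers = md$true_centers)
  })
  md1 <- curves[[1]]$metadata
  scattering_curve(q0, intensity, sample_label = sample_label,
                   hydration = md1$hydration,
                   hydration_kind = md1$hydration_kind,
                   temperature = md1$temperature,
                   metadata = list(
                     true_centers = if (length(centers)) centers else NULL,
                     component_phases = components))
}

#' Swelling law for a lamellar phase under varying water content
#'
#' With unit mass densities the hydrocarbon volume fraction at water
#' weight fraction w is phi_hc = (1 - w) * (1 - f_hg), where f_hg is
#' the headgroup volume fraction of the lipid. Ideal one-dimensional
#' dilution then gives d = d_hc / phi_hc. The bridging-capped law cuts
#' this off at d_hc + d_w_max, emulating adsorbed protein segments that
#' tether adjacent bilayers and arrest swelling at roughly the
#' connector length.
#'
#' @param law_type `"ideal_dilution"` or `"bridging_capped"`.
#' @param d_hc Hydrocarbon-layer thickness in Angstrom (> 0); default
#'   27.1, the POPC value used throughout.
#' @param headgroup_volume_fraction_of_lipid Fraction of the lipid
#'   volume in the polar headgroups, in [0, 1); default 0.26 (see the
#'   package vignette for the calibration).
#' @param d_w_max Cap on the aqueous + headgroup separation in Angstrom
#'   (`bridging_capped` only); default 67.
#' @return An object of class `swelling_law`.
#' @export
swelling_law <- function(law_type = c("ideal_dilution", "bridging_capped"),
                         d_hc = 27.1,
                         headgroup_volume_fraction_of_lipid = 0.26,
                         d_w_max = 67) {
  law_type <- match.arg(law_type)
  abort_if(!is_number(d_hc) || d_hc <= 0, "d_hc must be positive")
  f <- headgroup_volume_fraction_of_lipid
  abort_if(!is_number(f) || f < 0 || f >= 1,
           "headgroup_volume_fraction_of_lipid must lie in [0, 1)")
  if (law_type == "bridging_capped")
    abort_if(!is_number(d_w_max) || d_w_max <= 0, "d_w_max must be positive")
  structure(list(law_type = law_type, d_hc = d_hc,
                 headgroup_volume_fraction_of_lipid = f,
                 d_w_max = d_w_max),
            class = "swelling_law")
}

#' Evaluate a swelling law over a hydration series
#'
#' @param law A [swelling_law()].
#' @param hydrations Water contents in wt\%, each in [0, 100).
#' @return A data frame (`hydration`, `d`) with the law attached as the
#'   `"law"` attribute; `d` is monotonically nondecreasing in water
#'   content.
#' @export
#' @examples
#' generate_swelling_series(swelling_law("ideal_dilution",
#'   headgroup_volume_fraction_of_lipid = 0), c(25, 50, 75))
generate_swelling_series <- function(law, hydrations) {
  stopifnot(inherits(law, "swelling_law"))
  abort_if(any(hydrations < 0 | hydrations >= 100),
           "hydrations must lie in [0, 100) wt%% water")
  w <- hydrations / 100
  phi_hc <- (1 - w) * (1 - law$headgroup_volume_fraction_of_lipid)
  d <- law$d_hc / phi_hc
  if (law$law_type == "bridging_capped")
    d <- pmin(d, law$d_hc + law$d_w_max)
  out <- data.frame(hydration = hydrations, d = d)
  attr(out, "law") <- law
  out
}
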