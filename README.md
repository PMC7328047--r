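# mesoswell

Indexing and hydration analysis of lipid mesophase small-angle X-ray
scattering (SAXS), for membrane biophysicists studying how
multilamellar lipid systems — with or without bound proteins or
osmolytes — respond to changes in water content.

Lyotropic lipid phases announce themselves through the positions of
their Bragg reflections in a 1D scattering profile I(q):

* lamellar (L_α): q_n = 2πn/d for integer orders n, with repeat
  distance d;
* reversed hexagonal (H_II): reflections at 1 : √3 : 2 : √7 : 3 times
  q₁ = 4π/(√3·a);
* bicontinuous cubic (Q): q_hkl = 2π√(h²+k²+l²)/a for the allowed hkl
  of a candidate space group (candidates are ranked, never asserted).

`mesoswell` detects peaks (power-law background subtraction,
prominence filtering, parabolic sub-grid refinement), indexes them
against these lattices including two-phase coexistence, and estimates
lattice parameters with uncertainties: the lamellar d comes from the
slope of the q-versus-order regression (d = 2π/slope), with the
reported uncertainty the sample standard deviation of the
per-reflection estimates d_i = 2πn_i/q_i. Around that core it
provides:

* hydration analysis: Π_osm = −RT·ln(RH/100)/V_w converts relative
  humidity to osmotic pressure; the lamellar repeat decomposes as
  d = d_l + d_w with a fixed hydrocarbon thickness d_l (27.1 Å for
  POPC), so d_w tracks the headgroup-plus-water layer; swelling series
  get plateau detection and phase maps get coexistence intervals with
  honestly flagged boundaries;
* bridging geometry for disordered membrane-bound proteins: coil
  (3.26 Å/residue, back-derived) and contour (3.8 Å/residue) lengths
  of inter-anchor linkers versus d_w, plus electroneutral protein
  loading of anionic membranes;
* polarization-transfer solid-state NMR comparison: per-carbon
  CP/DP and rINEPT/DP ratios, mobility regimes, and flagging of
  carbons whose rINEPT ratio drops upon treatment;
* a synthetic SAXS generator (pseudo-Voigt peaks, power-law
  background, Poisson-like counting noise, seeded and bitwise
  reproducible) with ground truth carried in metadata, plus ideal and
  bridging-capped swelling laws;
* a manifest-driven pipeline (`run_pipeline()`) and a thin CLI
  (`inst/cli/mesoswell` with `simulate`, `findpeaks`, `index`,
  `swell`, `bridge`, `nmr-compare`, `run`).

## Worked example

Index a noisy synthetic lamellar pattern at the swelling plateau and
ask whether a dehydrin-like protein's linkers could bridge the water
gap:

```r
library(mesoswell)

sc <- generate_pattern(phase_spec("lamellar", 94, n_orders = 3),
                       curve_spec(noise_scale = 1.5, seed = 7))
peaks <- find_peaks(subtract_background(sc))
pa <- classify_phase(peaks)
pa
#> <phase_assignment> 1 fit(s), 2 unassigned peak(s)
#> <lamellar fit> d = 94.00 +/- 0.07 A (3 reflections, orders 1,2,3)

water_layer(pa$fits[[1]]$d)
#> [1] 66.90404

bridging_consistency(lti30_architecture(), d_w = 66.9)
#> <bridging_report> Lti30-like (synthetic representative) vs d_w = 66.9 A: extended_only
#>   n_res coil_A extended_A       verdict
#> 1     8  26.08       30.4      excluded
#> 2    11  35.86       41.8      excluded
#> 3    14  45.64       53.2      excluded
#> 4    17  55.42       64.6      excluded
#> 5    19  61.94       72.2 extended_only

osmotic_pressure(75)
#>   RH      T       V_w delta_mu_w   Pi_osm
#> 1 75 300.15 1.805e-05  -717.9353 39774811
```

Reading: the 94 Å repeat indexes cleanly on orders 1–3 (two weak
noise maxima are left unassigned rather than force-fitted), leaving a
66.9 Å headgroup-plus-water layer. Of the 8–19 residue linkers, only
the longest can span that gap, and only near full extension — the
geometric signature of a bridging-limited swelling plateau. A 75% RH
atmosphere at 27 °C corresponds to ≈4 × 10⁷ Pa of osmotic pressure.

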