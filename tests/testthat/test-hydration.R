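test_that("osmotic pressure follows -RT ln(a_w)/V_w with the right limits", {
  expect_equal(osmotic_pressure(100, 300.15)$Pi_osm, 0)
  expect_equal(osmotic_pressure(100, 250)$Pi_osm, 0)

  oc <- osmotic_pressure(75, 300.15)
  expect_equal(oc$Pi_osm, 3.977e7, tolerance = 1e-3)
  expect_equal(oc$delta_mu_w, 8.314462618 * 300.15 * log(0.75),
               tolerance = 1e-12)
  expect_lt(oc$delta_mu_w, 0)

  # strictly decreasing in RH; doubling V_w halves the pressure
  rh <- seq(20, 100, 5)
  pis <- osmotic_pressure(rh)$Pi_osm
  expect_true(all(diff(pis) < 0))
  expect_equal(osmotic_pressure(75, V_w = 2 * 1.805e-5)$Pi_osm,
               osmotic_pressure(75)$Pi_osm / 2)

  expect_error(osmotic_pressure(0), "RH")
  expect_error(osmotic_pressure(101), "RH")
  expect_error(osmotic_pressure(50, T = -1), "T")
})

test_that("the lamellar repeat decomposes exactly into d_l + d_w", {
  expect_equal(water_layer(94, 27.1), 66.9)
  expect_lt(abs(water_layer(94, 27.1) - 67), 0.5)
  expect_equal(water_layer(27.1, 27.1), 0) |> suppressWarnings()
  expect_warning(water_layer(20, 27.1), "not defined")
  expect_error(water_layer(-5, 27.1), "positive")

  # conservation over a whole series
  d <- c(54, 61, 73, 94)
  expect_equal(water_layer(d) + 27.1, d)

  # maximum swelling of the bare system: d_w ~ 6 x d_l
  expect_equal(floor(170 / 27.1), 6)
})

test_that("a bridging-capped series shows a plateau at d_hc + d_w_max", {
  law <- swelling_law("bridging_capped", d_hc = 27.1,
                      headgroup_volume_fraction_of_lipid = 0.26,
                      d_w_max = 67)
  pts <- generate_swelling_series(law, seq(30, 80, 5))
  ser <- build_swelling_series(pts)
  expect_false(is.na(ser$plateau_d))
  expect_lt(abs(ser$plateau_d - (27.1 + 67)) / (27.1 + 67), 0.02)
  # onset sits where the ideal law first exceeds the cap (~61 wt%)
  f <- 0.26
  w_cap <- 100 * (1 - 27.1 / ((27.1 + 67) * (1 - f)))
  expect_lt(abs(ser$plateau_onset_hydration - w_cap), 5)
  expect_true(ser$monotonic)
})

test_that("an ideally swelling series has no plateau", {
  law <- swelling_law("ideal_dilution",
                      headgroup_volume_fraction_of_lipid = 0.26)
  pts <- generate_swelling_series(law, seq(50, 80, 5))
  ser <- build_swelling_series(pts)
  expect_true(is.na(ser$plateau_d))
  expect_true(ser$monotonic)
})

test_that("two identical points form a plateau at the first", {
  ser <- build_swelling_series(data.frame(hydration = c(60, 70),
                                          d = c(94, 94)))
  expect_equal(ser$plateau_onset_hydration, 60)
  expect_equal(ser$plateau_d, 94)
  expect_error(build_swelling_series(data.frame(hydration = 60, d = 94)),
               "at least 2")
})

test_that("phase maps merge runs and flag interpolated boundaries", {
  df <- data.frame(hydration = c(97, 93, 85, 80, 75),
                   label = c("L_alpha", "L_alpha", "L_alpha+H_II",
                             "L_alpha+H_II", "L_alpha+H_II"))
  pm <- build_phase_map(df, hydration_kind = "RH")
  expect_equal(nrow(pm$intervals), 2)
  expect_equal(pm$intervals$label, c("L_alpha+H_II", "L_alpha"))
  # boundary midway between 85 and 93, not experimentally determined
  expect_equal(pm$intervals$end[1], 89)
  expect_equal(pm$intervals$start[2], 89)
  expect_false(pm$intervals$end_determined[1])
  expect_false(pm$intervals$start_determined[2])
  # outer edges are the observed range
  expect_equal(pm$intervals$start[1], 75)
  expect_equal(pm$intervals$end[2], 97)

  one <- build_phase_map(data.frame(hydration = c(10, 50, 90),
                                    label = "L_alpha"))
  expect_equal(nrow(one$intervals), 1)

  expect_error(build_phase_map(data.frame(hydration = c(80, 80),
                                          label = c("L_alpha", "H_II"))),
               "conflicting")
})

test_that("phase-map intervals partition the observed hydration range", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      n <- sample(4:9, 1)
      h <- sort(runif(n, 10, 95))
      lab <- sample(c("L_alpha", "H_II"), n, replace = TRUE)
      pm <- build_phase_map(data.frame(hydration = h, label = lab))
      iv <- pm$intervals
      expect_equal(iv$start[1], min(h))
      expect_equal(iv$end[nrow(iv)], max(h))
      if (nrow(iv) > 1)
        expect_equal(iv$start[-1], iv$end[-nrow(iv)])
    }
  })
})

test_that("a generated phase switch is located within one sampling step", {
  h <- seq(40, 90, 5)
  lab <- ifelse(h < 62, "H_II", "L_alpha")  # true boundary at 62
  pm <- build_phase_map(data.frame(hydration = h, label = lab))
  boundary <- pm$intervals$end[1]
  expect_lt(abs(boundary - 62), 5)
})
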