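test_that("lamellar and hexagonal reflection positions follow the lattice", {
  lam <- phase_spec("lamellar", 94, n_orders = 3)
  sc <- generate_pattern(lam, curve_spec())
  expect_equal(sc$metadata$true_centers, 2 * pi * (1:3) / 94)
  expect_equal(sc$metadata$true_centers,
               c(0.06684, 0.13368, 0.20053), tolerance = 1e-4)

  hex <- phase_spec("hexagonal", 4 * pi / (sqrt(3) * 0.10))
  sch <- generate_pattern(hex, curve_spec())
  expect_equal(sch$metadata$true_centers,
               0.10 * c(1, sqrt(3), 2, sqrt(7), 3), tolerance = 1e-12)
})

test_that("noiseless curves are deterministic and equal background + peaks", {
  ph <- phase_spec("lamellar", 80, n_orders = 3)
  cs <- curve_spec(noise_scale = 0)
  a <- generate_pattern(ph, cs)
  b <- generate_pattern(ph, cs)
  expect_identical(a$intensity, b$intensity)

  # subtracting the analytic background and peak sum leaves nothing
  bgp <- a$metadata$background
  bg <- bgp["A"] * a$q^(-bgp["p"]) + bgp["c0"]
  resid <- a$intensity - bg
  centers <- a$metadata$true_centers
  heights <- a$metadata$true_heights
  for (i in seq_along(centers)) {
    x <- (a$q - centers[i]) / ph$peak_width
    resid <- resid - heights[i] *
      (0.5 / (1 + 4 * x^2) + 0.5 * exp(-4 * log(2) * x^2))
  }
  expect_lt(max(abs(resid)), 1e-9 * max(a$intensity))
})

test_that("identical seeds give identical noisy curves, different seeds differ", {
  ph <- phase_spec("hexagonal", 70)
  a <- generate_pattern(ph, curve_spec(noise_scale = 2, seed = 11))
  b <- generate_pattern(ph, curve_spec(noise_scale = 2, seed = 11))
  c <- generate_pattern(ph, curve_spec(noise_scale = 2, seed = 12))
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("noiseless peak maxima fall within one grid step of the truth", {
  specs <- list(phase_spec("lamellar", 94, n_orders = 3),
                phase_spec("hexagonal", 72.55),
                phase_spec("cubic", 110,
                           ratio_set = cubic_ratio_sets()[["Pn3m-type"]]))
  for (ph in specs) {
    sc <- generate_pattern(ph, curve_spec())
    dq <- grid_step(sc)
    for (ctr in sc$metadata$true_centers) {
      # window narrow enough not to straddle a neighboring reflection
      win <- abs(sc$q - ctr) < 2 * ph$peak_width
      qmax <- sc$q[win][which.max(sc$intensity[win])]
      expect_lt(abs(qmax - ctr), dq)
    }
  }
})

test_that("reflections outside the q window raise an error naming them", {
  ph <- phase_spec("lamellar", 700, n_orders = 2)  # q1 below q_min
  expect_error(generate_pattern(ph, curve_spec()), "reflection 1")
  ph2 <- phase_spec("lamellar", 40, n_orders = 6)  # order 5 beyond q_max
  expect_error(generate_pattern(ph2, curve_spec()), "reflection 5")
})

test_that("coexistence composition sums curves and unions ground truth", {
  c1 <- make_lamellar(60)
  c2 <- make_hexagonal(72.552)

  single <- compose_coexistence(list(c1), weights = 1)
  expect_equal(single$intensity, c1$intensity)

  both <- compose_coexistence(list(c1, c2))
  expect_equal(both$intensity, c1$intensity + c2$intensity)
  expect_length(both$metadata$true_centers, 8)  # 3 + 5, no duplicates here
  expect_setequal(both$metadata$true_centers,
                  c(c1$metadata$true_centers, c2$metadata$true_centers))

  expect_error(compose_coexistence(list()), "nonempty")
  c3 <- scattering_curve(seq(0.02, 0.6, length.out = 100), rep(1, 100))
  expect_error(compose_coexistence(list(c1, c3)), "q grid")
  expect_error(compose_coexistence(list(c1, c2), weights = c(1, -1)),
               "positive")
})

test_that("swelling laws reproduce closed-form values and stay monotone", {
  ideal <- swelling_law("ideal_dilution", d_hc = 27.1,
                        headgroup_volume_fraction_of_lipid = 0)
  s <- generate_swelling_series(ideal, c(0, 50))
  expect_equal(s$d, c(27.1, 54.2))

  capped <- swelling_law("bridging_capped", d_hc = 27.1,
                         headgroup_volume_fraction_of_lipid = 0,
                         d_w_max = 67)
  s2 <- generate_swelling_series(capped, seq(10, 90, 10))
  expect_equal(max(s2$d), 27.1 + 67)
  expect_true(all(s2$d <= 27.1 + 67))

  # monotone nondecreasing under both laws, arbitrary headgroup fraction
  w <- sort(runif(20, 1, 99))
  for (law in list(ideal, capped,
                   swelling_law("ideal_dilution",
                                headgroup_volume_fraction_of_lipid = 0.26))) {
    d <- generate_swelling_series(law, w)$d
    expect_true(all(diff(d) >= -1e-12))
  }

  expect_error(generate_swelling_series(ideal, c(-5, 50)), "hydrations")
  expect_error(generate_swelling_series(ideal, 100), "hydrations")
})

test_that("curves round-trip through ASCII and CSV with ground truth sidecar", {
  sc <- make_lamellar(75)
  for (ext in c("dat", "csv")) {
    path <- file.path(withr::local_tempdir(), paste0("curve.", ext))
    write_scattering_curve(sc, path)
    back <- read_scattering_curve(path)
    expect_equal(back$q, sc$q, tolerance = 1e-10)
    expect_equal(back$intensity, sc$intensity, tolerance = 1e-10)
    sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                   simplifyVector = TRUE)
    expect_equal(sidecar$lattice_parameter, 75)
    expect_equal(sidecar$true_centers, sc$metadata$true_centers,
                 tolerance = 1e-10)
  }
})
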