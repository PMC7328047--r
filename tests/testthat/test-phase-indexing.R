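test_that("exact integer-order peaks index to d with zero uncertainty", {
  pk <- peak_list(2 * pi / 94 * (1:3))
  fit <- index_lamellar(pk)
  expect_true(fit$ok)
  expect_equal(fit$d, 94, tolerance = 1e-10)
  expect_lt(fit$d_uncertainty, 1e-9)
  expect_lt(abs(fit$intercept), 1e-12)
  expect_equal(fit$assigned_orders, 1:3)
  expect_false(fit$intercept_warning)
})

test_that("per-reflection d values and their spread match hand arithmetic", {
  pk <- peak_list(c(0.0670, 0.1335, 0.2010))
  fit <- index_lamellar(pk)
  per_d <- 2 * pi * (1:3) / c(0.0670, 0.1335, 0.2010)
  expect_equal(fit$per_reflection_d, per_d, tolerance = 1e-12)
  expect_equal(round(per_d, 2), c(93.78, 94.13, 93.78))
  expect_equal(fit$d_uncertainty, sd(per_d), tolerance = 1e-12)
  expect_equal(fit$d_uncertainty, 0.2028, tolerance = 1e-3)
})

test_that("a missing reflection order is bridged by integer assignment", {
  pk <- peak_list(2 * pi / 80 * c(1, 2, 4))
  fit <- index_lamellar(pk)
  expect_true(fit$ok)
  expect_equal(fit$assigned_orders, c(1L, 2L, 4L))
  expect_equal(fit$d, 80, tolerance = 1e-10)
})

test_that("hexagonal ratio peaks are rejected by the lamellar tolerance", {
  pk <- peak_list(0.1 * hexagonal_ratios())
  fit <- index_lamellar(pk, tolerance_rel = 0.01)
  expect_false(fit$ok)
})

test_that("ratio indexing recovers the hexagonal lattice parameter", {
  pk <- peak_list(0.10 * hexagonal_ratios())
  fit <- index_ratio_lattice(pk, hexagonal_ratios(), "hexagonal")
  expect_true(fit$ok)
  expect_equal(fit$q1, 0.10, tolerance = 1e-10)
  expect_equal(fit$a, 4 * pi / (sqrt(3) * 0.10), tolerance = 1e-10)
  expect_equal(fit$a, 72.55, tolerance = 1e-4)
  expect_equal(fit$n_matched, 5L)

  single <- peak_list(0.1)
  expect_false(index_ratio_lattice(single, type = "hexagonal")$ok)
})

test_that("integer-order peaks prefer the lamellar call over hexagonal", {
  pk <- peak_list(0.08 * (1:3))
  hexfit <- index_ratio_lattice(pk, hexagonal_ratios(), "hexagonal")
  # hexagonal can only absorb the 1, 2, 3 subset of its ratios
  expect_true(all(hexfit$matched_ratios %in% c(1, 2, 3)))
  pa <- classify_phase(pk, allow_coexistence = FALSE)
  expect_equal(pa$fits[[1]]$type, "lamellar")
  expect_equal(pa$fits[[1]]$d, 2 * pi / 0.08, tolerance = 1e-8)
  expect_false(pa$coexistence)
})

test_that("a pure lamellar pattern classifies as a single lamellar phase", {
  pa <- classify_phase(detect(make_lamellar(94)))
  expect_length(pa$fits, 1)
  expect_equal(pa$fits[[1]]$type, "lamellar")
  expect_equal(pa$fits[[1]]$d, 94, tolerance = 94 * 1e-3)
  expect_false(pa$coexistence)
  expect_equal(nrow(pa$unassigned), 0)
})

test_that("lamellar + hexagonal coexistence recovers both lattices", {
  co <- compose_coexistence(list(make_lamellar(60), make_hexagonal(72.552)))
  pa <- classify_phase(detect(co))
  expect_true(pa$coexistence)
  expect_length(pa$fits, 2)
  types <- vapply(pa$fits, `[[`, character(1), "type")
  expect_setequal(types, c("lamellar", "hexagonal"))
  lam <- pa$fits[[which(types == "lamellar")]]
  hex <- pa$fits[[which(types == "hexagonal")]]
  expect_lt(abs(lam$d - 60), 0.5)
  expect_lt(abs(hex$a - 72.552), 0.5)
})

test_that("every peak lands in exactly one fit or the unassigned list", {
  curves <- list(
    make_lamellar(94),
    compose_coexistence(list(make_lamellar(58), make_hexagonal(72.552))),
    generate_pattern(phase_spec("cubic", 110,
                                ratio_set = cubic_ratio_sets()[["Im3m-type"]]),
                     curve_spec()))
  for (sc in curves) {
    pk <- detect(sc)
    pa <- classify_phase(pk)
    counts <- integer(nrow(pk))
    for (k in seq_along(pa$fits)) counts[pa$fits[[k]]$matched] <-
        counts[pa$fits[[k]]$matched] + 1L
    counts[match(pa$unassigned$q, pk$q)] <-
      counts[match(pa$unassigned$q, pk$q)] + 1L
    expect_true(all(counts == 1L))
    expect_equal(sum(is.na(pa$assignment$fit)), nrow(pa$unassigned))
  }
})

test_that("cubic patterns yield ranked candidates with the generator set on top", {
  sets <- cubic_ratio_sets()
  for (nm in names(sets)) {
    ph <- phase_spec("cubic", 120, ratio_set = sets[[nm]])
    pa <- classify_phase(detect(generate_pattern(ph, curve_spec())))
    expect_equal(pa$fits[[1]]$type, "cubic")
    expect_equal(pa$fits[[1]]$space_group_label, nm)
    expect_equal(pa$fits[[1]]$a, 120, tolerance = 120 * 2e-3)
    expect_gte(length(pa$cubic_candidates), 2)
    expect_equal(pa$cubic_candidates[[1]]$space_group_label, nm)
    # candidates are ranked: non-increasing matched counts
    nm_counts <- vapply(pa$cubic_candidates, `[[`, integer(1), "n_matched")
    expect_true(all(diff(nm_counts) <= 0))
    expect_true(all(nm_counts >= 3))
  }
})

test_that("noiseless round trips recover lattice parameters to < 0.1%", {
  for (d in c(52.3, 77.7, 94)) {
    pa <- classify_phase(detect(make_lamellar(d)))
    expect_equal(pa$fits[[1]]$type, "lamellar")
    expect_lt(abs(pa$fits[[1]]$d - d) / d, 1e-3)
  }
  for (a in c(60.5, 72.552, 88.1)) {
    pa <- classify_phase(detect(make_hexagonal(a)))
    expect_equal(pa$fits[[1]]$type, "hexagonal")
    expect_lt(abs(pa$fits[[1]]$a - a) / a, 1e-3)
  }
})

test_that("degenerate peak lists give no-fit results, not errors", {
  expect_false(index_lamellar(peak_list(0.1))$ok)
  expect_error(classify_phase(peak_list(numeric(0))), "empty")
  # an unindexable pair: huge relative mismatch with every lattice
  pk <- peak_list(c(0.05, 0.137))
  pa <- classify_phase(pk, tolerance_rel = 0.001)
  expect_length(pa$fits, 0)
  expect_equal(nrow(pa$unassigned), 2)
  expect_false(pa$coexistence)
})
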