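make_table <- function(df, label = "sample") carbon_peak_table(df, label)

ref_table <- function() make_table(data.frame(
  carbon = c("g1", "g2", "g3", "C2", "methyl"),
  cp    = c(0.5, 0.6, 0.6, 0.4, 0.2),
  dp    = c(1.0, 1.0, 1.0, 1.0, 1.0),
  inept = c(0.8, 0.9, 1.0, 0.7, 1.2)), "reference")

test_that("DP-normalized ratios assign mobility regimes", {
  tb <- make_table(data.frame(
    carbon = c("mobile_c", "rigid_c", "silent_c", "mid_c"),
    cp    = c(0.2, 0.9, 0, 0.4),
    dp    = c(1.0, 1.0, 0, 1.0),
    inept = c(0.9, 0.0, 0, 0.2)))
  rep <- normalize_ratios(tb)
  expect_equal(rep$regime[rep$carbon == "mobile_c"], "mobile")
  expect_equal(rep$regime[rep$carbon == "rigid_c"], "rigid")
  expect_equal(rep$regime[rep$carbon == "silent_c"], "undetected")
  expect_equal(rep$regime[rep$carbon == "mid_c"], "intermediate")
  expect_equal(rep$r_inept[rep$carbon == "mobile_c"], 0.9)
  expect_equal(rep$r_cp[rep$carbon == "rigid_c"], 0.9)
})

test_that("rows with a zero DP reference but live signal are dropped", {
  tb <- make_table(data.frame(carbon = c("ok", "bad"),
                              cp = c(0.5, 0.8), dp = c(1, 0),
                              inept = c(0.5, 0.4)))
  expect_warning(rep <- normalize_ratios(tb), "bad")
  expect_equal(rep$carbon, "ok")
})

test_that("ratios and flags are invariant to overall intensity scaling", {
  tb <- ref_table()
  scaled <- make_table(transform(as.data.frame(tb), cp = cp * 37,
                                 dp = dp * 37, inept = inept * 37),
                       "scaled")
  r1 <- normalize_ratios(tb)
  r2 <- normalize_ratios(scaled)
  expect_equal(r1$r_inept, r2$r_inept)
  expect_equal(r1$r_cp, r2$r_cp)
  expect_equal(r1$regime, r2$regime)
  cmp <- compare_samples(tb, scaled)
  expect_equal(cmp$per_carbon$delta_r_inept, rep(0, 5))
  expect_false(any(cmp$per_carbon$flagged))
})

test_that("identical tables compare with zero deltas and no flags", {
  cmp <- compare_samples(ref_table(), ref_table())
  expect_true(all(cmp$per_carbon$delta_r_inept == 0))
  expect_false(any(cmp$per_carbon$flagged))
  expect_length(cmp$unshared_reference, 0)
})

test_that("a reduced rINEPT ratio beyond the threshold is flagged", {
  treated_df <- as.data.frame(ref_table())
  treated_df$inept[treated_df$carbon == "g3"] <- 0.6  # 40% reduction
  treated_df$inept[treated_df$carbon == "g2"] <- 0.8  # ~11%, below 20%
  cmp <- compare_samples(ref_table(), make_table(treated_df, "treated"),
                         flag_threshold = 0.2)
  pc <- cmp$per_carbon
  expect_true(pc$flagged[pc$carbon == "g3"])
  expect_false(pc$flagged[pc$carbon == "g2"])
  expect_equal(pc$delta_r_inept[pc$carbon == "g3"], -0.4)
  expect_equal(pc$rel_reduction[pc$carbon == "g3"], 0.4)
})

test_that("swapping reference and treated negates every delta", {
  treated_df <- as.data.frame(ref_table())
  treated_df$inept <- treated_df$inept * c(1, 0.6, 0.5, 1.1, 0.9)
  treated <- make_table(treated_df, "treated")
  fwd <- compare_samples(ref_table(), treated)
  bwd <- compare_samples(treated, ref_table())
  m <- match(fwd$per_carbon$carbon, bwd$per_carbon$carbon)
  expect_equal(fwd$per_carbon$delta_r_inept,
               -bwd$per_carbon$delta_r_inept[m])
})

test_that("unshared carbon labels are reported, never flagged", {
  treated_df <- as.data.frame(ref_table())
  treated_df <- treated_df[treated_df$carbon != "C2", ]
  cmp <- compare_samples(ref_table(), make_table(treated_df, "treated"))
  expect_equal(cmp$unshared_reference, "C2")
  expect_false("C2" %in% cmp$per_carbon$carbon)

  disjoint <- make_table(data.frame(carbon = "zzz", cp = 1, dp = 1,
                                    inept = 1))
  expect_error(compare_samples(ref_table(), disjoint), "shared")
})

test_that("tables read from CSV behave identically", {
  path <- file.path(withr::local_tempdir(), "carbons.csv")
  write.csv(as.data.frame(ref_table()), path, row.names = FALSE)
  tb <- carbon_peak_table(path, "from_csv")
  expect_equal(normalize_ratios(tb)$r_inept,
               normalize_ratios(ref_table())$r_inept)
})
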