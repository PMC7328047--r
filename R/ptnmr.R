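#' Per-carbon CP/DP/rINEPT peak-intensity table
#'
#' Holds peak intensities from the three polarization-transfer
#' experiments for each resolved lipid carbon of one sample. All three
#' experiments must share acquisition scaling, so that the direct
#' polarization (DP) intensity can serve as the per-carbon reference.
#' Crowded spectral regions that cannot be resolved carbon by carbon
#' may be entered as one pooled label (e.g. `"C4-C13"`).
#'
#' @param x Data frame (or CSV path) with columns `carbon`, `cp`, `dp`,
#'   `inept`.
#' @param sample_label Sample name.
#' @return A data frame of class `carbon_peak_table`.
#' @export
carbon_peak_table <- function(x, sample_label = "sample") {
  if (is.character(x) && length(x) == 1L) x <- utils::read.csv(x)
  abort_if(!is.data.frame(x), "x must be a data frame or CSV path")
  names(x) <- tolower(names(x))
  abort_if(!all(c("carbon", "cp", "dp", "inept") %in% names(x)),
           "need columns carbon, cp, dp, inept")
  abort_if(anyDuplicated(x$carbon) > 0, "duplicate carbon labels")
  abort_if(any(x$cp < 0 | x$dp < 0 | x$inept < 0),
           "intensities must be nonnegative")
  out <- x[, c("carbon", "cp", "dp", "inept")]
  out$carbon <- as.character(out$carbon)
  attr(out, "sample_label") <- sample_label
  class(out) <- c("carbon_peak_table", "data.frame")
  out
}

#' Per-carbon mobility ratios and regimes
#'
#' Normalizes the CP and rINEPT intensities of each carbon by its DP
#' intensity (r_cp = I_CP/I_DP, r_inept = I_INEPT/I_DP) and assigns a
#' qualitative mobility regime: `"mobile"` when the rINEPT ratio is
#' substantial and dominates CP, `"rigid"` when CP dominates and
#' rINEPT is below the detection floor, `"intermediate"` otherwise,
#' and `"undetected"` when no experiment gave signal. Ratios, not
#' absolute intensities, carry the information; they are insensitive
#' to overall scaling but remain qualitative (they depend on both the
#' rate and the anisotropy of C-H reorientation).
#'
#' Rows with zero DP but nonzero CP or rINEPT have no usable reference
#' and are dropped with a warning.
#'
#' @param table A [carbon_peak_table()].
#' @param m_thresh Minimum r_inept for the mobile regime; default 0.3.
#' @param c_thresh Minimum r_cp for the rigid regime; default 0.3.
#' @param floor Detection floor on ratios and (relative to the largest
#'   DP intensity) on raw intensities; default 0.05.
#' @return A data frame of class `mobility_report` with columns
#'   `carbon`, `r_cp`, `r_inept`, `regime`.
#' @export
normalize_ratios <- function(table, m_thresh = 0.3, c_thresh = 0.3,
                             floor = 0.05) {
  stopifnot(inherits(table, "carbon_peak_table"))
  ref <- max(table$dp, table$cp, table$inept, 1e-300)
  silent <- table$dp <= 0 & table$cp < floor * ref & table$inept < floor * ref
  bad <- table$dp <= 0 & !silent
  if (any(bad)) {
    warning(sprintf("dropping carbon(s) with zero DP reference: %s",
                    paste(table$carbon[bad], collapse = ", ")),
            call. = FALSE)
    table <- table[!bad, , drop = FALSE]
    silent <- silent[!bad]
  }
  r_cp <- ifelse(table$dp > 0, table$cp / table$dp, NA_real_)
  r_inept <- ifelse(table$dp > 0, table$inept / table$dp, NA_real_)
  regime <- rep("intermediate", nrow(table))
  regime[!is.na(r_inept) & r_inept >= m_thresh & r_inept > r_cp] <- "mobile"
  regime[!is.na(r_cp) & r_cp >= c_thresh & !is.na(r_inept) &
           r_inept < floor] <- "rigid"
  regime[silent] <- "undetected"
  out <- data.frame(carbon = table$carbon, r_cp = r_cp,
                    r_inept = r_inept, regime = regime)
  attr(out, "sample_label") <- attr(table, "sample_label")
  attr(out, "thresholds") <- c(m_thresh = m_thresh, c_thresh = c_thresh,
                               floor = floor)
  class(out) <- c("mobility_report", "data.frame")
  out
}

#' Compare per-carbon mobility between two samples
#'
#' Computes the change in the rINEPT/DP ratio per shared carbon
#' (`delta_r_inept = treated - reference`) and flags carbons whose
#' relative rINEPT reduction exceeds `flag_threshold` -- the signature
#' of reduced segmental mobility at that position, e.g. upon protein
#' binding at the bilayer interface. Carbons present in only one table
#' are listed separately and never flagged.
#'
#' @param reference,treated [carbon_peak_table()]s sharing at least one
#'   carbon label.
#' @param flag_threshold Relative rINEPT reduction that triggers a
#'   flag; default 0.2.
#' @inheritParams normalize_ratios
#' @return An object of class `mobility_comparison`: list with
#'   `per_carbon` (carbon, reference/treated ratios and regimes,
#'   `delta_r_inept`, `rel_reduction`, `flagged`),
#'   `unshared_reference`, `unshared_treated` and `flag_threshold`.
#' @export
compare_samples <- function(reference, treated, flag_threshold = 0.2,
                            m_thresh = 0.3, c_thresh = 0.3, floor = 0.05) {
  r <- normalize_ratios(reference, m_thresh, c_thresh, floor)
  t <- normalize_ratios(treated, m_thresh, c_thresh, floor)
  shared <- intersect(r$carbon, t$carbon)
  abort_if(length(shared) == 0L, "no shared carbon labels")
  ri <- r[match(shared, r$carbon), ]
  ti <- t[match(shared, t$carbon), ]
  delta <- ti$r_inept - ri$r_inept
  rel_red <- ifelse(ri$r_inept > 0, (ri$r_inept - ti$r_inept) / ri$r_inept,
                    NA_real_)
  per_carbon <- data.frame(
    carbon = shared,
    r_inept_reference = ri$r_inept, r_inept_treated = ti$r_inept,
    r_cp_reference = ri$r_cp, r_cp_treated = ti$r_cp,
    regime_reference = ri$regime, regime_treated = ti$regime,
    delta_r_inept = delta, rel_reduction = rel_red,
    flagged = !is.na(rel_red) & rel_red >= flag_threshold)
  structure(list(per_carbon = per_carbon,
                 unshared_reference = setdiff(r$carbon, shared),
                 unshared_treated = setdiff(t$carbon, shared),
                 flag_threshold = flag_threshold),
            class = "mobility_comparison")
}

#' @export
print.mobility_comparison <- function(x, ...) {
  nf <- sum(x$per_carbon$flagged)
  cat(sprintf("<mobility_comparison> %d shared carbon(s), %d flagged (threshold %.0f%%)\n",
              nrow(x$per_carbon), nf, 100 * x$flag_threshold))
  if (nf)
    cat("  reduced rINEPT/DP:",
        paste(x$per_carbon$carbon[x$per_carbon$flagged], collapse = ", "),
        "\n")
  if (length(x$unshared_reference) || length(x$unshared_treated))
    cat("  unshared labels:",
        paste(union(x$unshared_reference, x$unshared_treated),
              collapse = ", "), "\n")
  invisible(x)
}
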