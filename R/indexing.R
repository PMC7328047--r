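#' Candidate reflection-ratio sets for bicontinuous cubic phases
#'
#' Ratio sets are the sqrt(h^2 + k^2 + l^2) values of the low-order
#' allowed reflections of three common bicontinuous cubic space groups.
#' The labels are conventional; an indexing against these sets ranks
#' candidates and never asserts a space-group assignment, since
#' low-resolution powder patterns rarely determine one uniquely.
#'
#' @return Named list of numeric ratio vectors.
#' @export
cubic_ratio_sets <- function() {
  list("Pn3m-type" = sqrt(c(2, 3, 4, 6, 8, 9)),
       "Im3m-type" = sqrt(c(2, 4, 6, 8, 10)),
       "Ia3d-type" = sqrt(c(6, 8, 14, 16)))
}

no_fit <- function(type, reason) {
  structure(list(ok = FALSE, type = type, reason = reason,
                 n_matched = 0L),
            class = c(paste0(type, "_fit"), "phase_fit"))
}

#' @export
print.phase_fit <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat(sprintf("<%s fit> no fit (%s)\n", x$type, x$reason))
    return(invisible(x))
  }
  if (x$type == "lamellar") {
    cat(sprintf("<lamellar fit> d = %.2f +/- %.2f A (%d reflections, orders %s)\n",
                x$d, x$d_uncertainty, x$n_matched,
                paste(x$assigned_orders, collapse = ",")))
    if (isTRUE(x$intercept_warning))
      cat("  warning: regression intercept significant; possible mis-indexing\n")
  } else if (x$type == "hexagonal") {
    cat(sprintf("<hexagonal fit> a = %.2f A (q1 = %.5f, %d reflections)\n",
                x$a, x$q1, x$n_matched))
  } else {
    cat(sprintf("<cubic candidate> %s: a = %.2f A (%d reflections, rms %.2e)\n",
                x$space_group_label, x$a, x$n_matched, x$residual_rms))
  }
  invisible(x)
}

# assign each peak to its nearest integer order (lamellar) given a
# first-order candidate; duplicates keep the closest peak
assign_orders <- function(qs, q1_cand, tol) {
  m <- qs / q1_cand
  n <- pmax(round(m), 1)
  ok <- abs(qs - n * q1_cand) / qs <= tol
  n[!ok] <- NA
  for (k in unique(stats::na.omit(n))) {
    js <- which(!is.na(n) & n == k)
    if (length(js) > 1L) {
      resid <- abs(qs[js] - k * q1_cand)
      n[js[-which.min(resid)]] <- NA
    }
  }
  n
}

# assign peaks to entries of a normalized ratio set given a candidate
# first-ratio position
assign_ratios <- function(qs, ratios_norm, q1_cand, tol) {
  assign <- rep(NA_integer_, length(qs))
  for (j in seq_along(qs)) {
    m <- qs[j] / q1_cand
    k <- which.min(abs(ratios_norm - m))
    if (abs(m - ratios_norm[k]) / ratios_norm[k] <= tol)
      assign[j] <- k
  }
  for (k in unique(stats::na.omit(assign))) {
    js <- which(!is.na(assign) & assign == k)
    if (length(js) > 1L) {
      resid <- abs(qs[js] / q1_cand - ratios_norm[k])
      assign[js[-which.min(resid)]] <- NA
    }
  }
  assign
}

# evidence weight per peak: prominence where measured, else 1, so that
# hand-built peak lists degrade gracefully to match counting
peak_weights <- function(peaks) {
  w <- peaks$prominence
  ifelse(is.na(w) | w <= 0, 1, w)
}

peaks_q_range <- function(peaks)
  attr(peaks, "q_range") %||% range(peaks$q)

# completeness of a candidate lattice: fraction of reflections it
# predicts inside the searched q window that are actually matched by a
# peak (a de Wolff-style penalty against lattices inventing unobserved
# low-order reflections)
lattice_completeness <- function(predicted, qr, n_matched) {
  n_pred <- sum(predicted > qr[1] & predicted < qr[2])
  n_matched / max(n_pred, n_matched, 1L)
}

# candidate base peaks: the lowest-q peaks plus the most prominent ones
# (on noisy curves weak spurious maxima can precede the first reflection)
base_indices <- function(peaks) {
  n <- nrow(peaks)
  idx <- seq_len(min(3L, n))
  if (any(!is.na(peaks$prominence)))
    idx <- union(idx, order(peaks$prominence,
                            decreasing = TRUE)[seq_len(min(3L, n))])
  sort(idx)
}

# least-squares lamellar fit on an assigned subset
fit_lamellar_orders <- function(peaks, orders, tolerance_rel,
                                matched_idx = which(!is.na(orders))) {
  qs <- peaks$q[matched_idx]
  ns <- orders[matched_idx]
  if (length(qs) < 2L) return(no_fit("lamellar", "fewer than 2 matchable peaks"))
  fit <- stats::lm(qs ~ ns)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) return(no_fit("lamellar", "nonpositive regression slope"))
  resid <- qs - (slope * ns + intercept)
  rrms_abs <- sqrt(mean(resid^2))
  rrms_rel <- sqrt(mean((resid / qs)^2))
  per_d <- 2 * pi * ns / qs
  weight_sum <- sum(peak_weights(peaks)[matched_idx])
  completeness <- lattice_completeness(
    slope * seq_len(max(ns)) + intercept, peaks_q_range(peaks), length(ns))
  structure(list(
    ok = TRUE, type = "lamellar",
    d = 2 * pi / slope,
    d_uncertainty = sd0(per_d),
    assigned_orders = as.integer(ns),
    slope = slope, intercept = intercept,
    per_reflection_d = per_d,
    residual_rms = rrms_abs,
    residual_rms_rel = rrms_rel,
    matched = matched_idx,
    n_matched = length(matched_idx),
    weight_sum = weight_sum,
    completeness = completeness,
    eff_weight = weight_sum * completeness,
    intercept_warning = abs(intercept) > max(3 * rrms_abs, 1e-3 * slope),
    tolerance_rel = tolerance_rel),
    class = c("lamellar_fit", "phase_fit"))
}

# least-squares ratio-lattice fit on an assigned subset
fit_ratio_subset <- function(peaks, ratio_set, assign, type, label,
                             matched_idx = which(!is.na(assign))) {
  ratios_norm <- ratio_set / ratio_set[1]
  qs <- peaks$q[matched_idx]
  rs <- ratios_norm[assign[matched_idx]]
  min_n <- if (type == "cubic") 3L else 2L
  if (length(unique(assign[matched_idx])) < min_n)
    return(no_fit(type, sprintf("fewer than %d ratios matched", min_n)))
  q1 <- sum(qs * rs) / sum(rs^2)
  rel_resid <- (qs - rs * q1) / (rs * q1)
  weight_sum <- sum(peak_weights(peaks)[matched_idx])
  completeness <- lattice_completeness(
    q1 * ratios_norm, peaks_q_range(peaks),
    length(unique(assign[matched_idx])))
  out <- list(
    ok = TRUE, type = type,
    q1 = q1,
    matched_ratios = ratio_set[assign[matched_idx]],
    residual_rms = sqrt(mean(rel_resid^2)),
    residual_rms_rel = sqrt(mean(rel_resid^2)),
    matched = matched_idx,
    n_matched = length(matched_idx),
    weight_sum = weight_sum,
    completeness = completeness,
    eff_weight = weight_sum * completeness)
  if (type == "hexagonal") {
    out$a <- 4 * pi / (sqrt(3) * q1)
    # a hexagonal call is only credible if a non-integer ratio (sqrt(3)
    # or sqrt(7)) is matched; a pure 1:2:3 subset is indistinguishable
    # from a lamellar series and must lose the tie to parsimony
    rn <- out$matched_ratios / ratio_set[1]
    out$distinctive <- any(abs(rn - round(rn)) > 1e-6)
    class(out) <- c("hexagonal_fit", "phase_fit")
  } else {
    out$a <- 2 * pi * ratio_set[1] / q1
    out$space_group_label <- label
    out$ratio_set <- ratio_set
    class(out) <- c("cubic_candidate", "phase_fit")
  }
  out
}

#' Index a peak list as a lamellar stack
#'
#' Implements the classical d-spacing regression: each reflection is
#' assigned the nearest integer order n to q_i/q_first (gaps allowed),
#' q is regressed linearly on n with a free intercept, and the repeat
#' distance is taken from the slope, d = 2*pi/slope. Each reflection
#' also yields its own estimate d_i = 2*pi*n_i/q_i; the reported
#' uncertainty is the sample standard deviation of these per-reflection
#' values. A significant intercept (relative to the residual scatter)
#' flags likely mis-indexing.
#'
#' The fit is rejected (no-fit result) if any relative regression
#' residual exceeds `tolerance_rel`, which weeds out non-integer
#' reflection series such as the hexagonal 1 : sqrt(3) : 2 sequence.
#'
#' @param peaks A [peak_list()] with at least 2 peaks.
#' @param tolerance_rel Maximum allowed relative residual per
#'   reflection; default 0.01.
#' @return An object of class `lamellar_fit` (check `$ok`).
#' @export
#' @examples
#' pk <- peak_list(2 * pi / 94 * (1:3))
#' index_lamellar(pk)$d
index_lamellar <- function(peaks, tolerance_rel = 0.01) {
  stopifnot(inherits(peaks, "peak_list"))
  if (nrow(peaks) < 2L)
    return(no_fit("lamellar", "fewer than 2 peaks"))
  qs <- peaks$q
  orders <- pmax(round(qs / qs[1]), 1)
  fit <- fit_lamellar_orders(peaks, orders, tolerance_rel,
                             matched_idx = seq_along(qs))
  if (!fit$ok) return(fit)
  resid_rel <- abs(qs - (fit$slope * orders + fit$intercept)) / qs
  if (any(resid_rel > tolerance_rel))
    return(no_fit("lamellar",
                  sprintf("relative residual %.3g exceeds tolerance %.3g",
                          max(resid_rel), tolerance_rel)))
  fit
}

#' Index a peak list against a reflection-ratio set
#'
#' Fits peak positions to q_i = r_i * q1 for a hexagonal
#' (1, sqrt(3), 2, sqrt(7), 3) or cubic ratio set. Peaks within
#' `tolerance_rel` of a ratio position are matched (at most one peak
#' per ratio); q1 is then estimated by least squares over the matched
#' peaks. The lattice parameter is a = 4*pi/(sqrt(3)*q1) for a
#' hexagonal lattice and a = 2*pi*r_1/q1 for a cubic set whose entries
#' are sqrt(h^2+k^2+l^2) values.
#'
#' @param peaks A [peak_list()] with at least 2 peaks.
#' @param ratio_set Ordered positive ratios; default [hexagonal_ratios()].
#' @param type `"hexagonal"` or `"cubic"`.
#' @param tolerance_rel Relative matching tolerance; default 0.01.
#' @param label Candidate label for cubic sets.
#' @return A `hexagonal_fit` or `cubic_candidate` (check `$ok`). A
#'   cubic candidate is reportable only with >= 3 matched reflections;
#'   a hexagonal fit needs >= 2.
#' @export
index_ratio_lattice <- function(peaks, ratio_set = hexagonal_ratios(),
                                type = c("hexagonal", "cubic"),
                                tolerance_rel = 0.01,
                                label = "cubic") {
  stopifnot(inherits(peaks, "peak_list"))
  type <- match.arg(type)
  if (nrow(peaks) < 2L) return(no_fit(type, "fewer than 2 peaks"))
  best <- NULL
  ratios_norm <- ratio_set / ratio_set[1]
  for (b in base_indices(peaks)) {
    for (k in seq_len(min(2L, length(ratios_norm)))) {
      q1_cand <- peaks$q[b] / ratios_norm[k]
      assign <- assign_ratios(peaks$q, ratios_norm, q1_cand, tolerance_rel)
      fit <- fit_ratio_subset(peaks, ratio_set, assign, type, label)
      if (fit$ok && (is.null(best) || better_fit(fit, best)))
        best <- fit
    }
  }
  best %||% no_fit(type, "fewer than 2 ratios matched within tolerance")
}

# ranking: most matched scattered intensity (prominence-weighted; with
# counting noise weak spurious maxima must not outvote true Bragg
# reflections), then matched count, then lower relative residual, then
# fewer structural assumptions (lamellar < hexagonal < cubic)
fit_complexity <- function(fit)
  match(fit$type, c("lamellar", "hexagonal", "cubic"))

better_fit <- function(a, b) {
  wa <- a$eff_weight; wb <- b$eff_weight
  if (abs(wa - wb) > 1e-6 * max(wa, wb, 1)) return(wa > wb)
  if (a$n_matched != b$n_matched) return(a$n_matched > b$n_matched)
  da <- !isFALSE(a$distinctive); db <- !isFALSE(b$distinctive)
  if (da != db) return(da)
  ra <- a$residual_rms_rel; rb <- b$residual_rms_rel
  if (!isTRUE(all.equal(ra, rb, tolerance = 1e-10)) && ra != rb)
    return(ra < rb)
  fit_complexity(a) < fit_complexity(b)
}

# best lamellar fit over several first-order candidates, subset matching
best_lamellar_subset <- function(peaks, tolerance_rel) {
  best <- NULL
  for (b in base_indices(peaks)) {
    for (k in 1:2) {
      q1_cand <- peaks$q[b] / k
      orders <- assign_orders(peaks$q, q1_cand, tolerance_rel)
      if (sum(!is.na(orders)) < 2L) next
      fit <- fit_lamellar_orders(peaks, orders, tolerance_rel)
      if (fit$ok && (is.null(best) || better_fit(fit, best)))
        best <- fit
    }
  }
  best %||% no_fit("lamellar", "fewer than 2 matchable peaks")
}

all_candidate_fits <- function(peaks, tolerance_rel, cubic_sets) {
  fits <- list(best_lamellar_subset(peaks, tolerance_rel),
               index_ratio_lattice(peaks, hexagonal_ratios(), "hexagonal",
                                   tolerance_rel))
  for (nm in names(cubic_sets))
    fits <- c(fits, list(index_ratio_lattice(peaks, cubic_sets[[nm]],
                                             "cubic", tolerance_rel,
                                             label = nm)))
  fits[vapply(fits, function(f) isTRUE(f$ok), logical(1))]
}

rank_fits <- function(fits) {
  if (length(fits) < 2L) return(fits)
  ord <- seq_along(fits)
  for (i in seq_along(fits)) {
    for (j in seq_along(fits)) {
      if (i < j && better_fit(fits[[ord[j]]], fits[[ord[i]]])) {
        tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
      }
    }
  }
  fits[ord]
}

#' Classify a peak list into mesophase assignments
#'
#' Fits lamellar, hexagonal, and all configured cubic candidate
#' lattices to the peak list and ranks them by the prominence-weighted
#' amount of scattered intensity they explain, then by number of
#' matched reflections, then residual, then parsimony (lamellar before
#' hexagonal before cubic). Prominence weighting keeps weak spurious
#' maxima, which counting noise produces on steep backgrounds, from
#' outvoting the true Bragg reflections. If peaks remain unmatched and
#' `allow_coexistence` is `TRUE`, a second lattice is fitted greedily
#' to the residual peaks, yielding a two-phase (coexistence)
#' assignment. Every input peak ends up matched to exactly one fit or
#' listed as unassigned.
#'
#' @param peaks A nonempty [peak_list()].
#' @param allow_coexistence Attempt a second lattice on leftover peaks
#'   (default `TRUE`). At most two coexisting lattices are considered.
#' @param tolerance_rel Relative matching tolerance; default 0.01.
#' @param cubic_sets Named list of cubic ratio sets; default
#'   [cubic_ratio_sets()].
#' @return An object of class `phase_assignment`: list with `fits`
#'   (one or two phase fits), `assignment` (data frame q / fit index),
#'   `unassigned` ([peak_list()]), `coexistence` (logical) and
#'   `cubic_candidates` (all reportable cubic candidates, ranked).
#' @export
classify_phase <- function(peaks, allow_coexistence = TRUE,
                           tolerance_rel = 0.01,
                           cubic_sets = cubic_ratio_sets()) {
  stopifnot(inherits(peaks, "peak_list"))
  abort_if(nrow(peaks) == 0L, "peak list is empty")
  cands <- all_candidate_fits(peaks, tolerance_rel, cubic_sets)
  cubic_cands <- rank_fits(Filter(function(f) f$type == "cubic", cands))
  fit_of <- rep(NA_integer_, nrow(peaks))
  fits <- list()
  if (length(cands)) {
    best <- rank_fits(cands)[[1]]
    fits[[1]] <- best
    fit_of[best$matched] <- 1L
    remaining <- which(is.na(fit_of))
    if (allow_coexistence && length(remaining) >= 2L) {
      sub <- peak_list(peaks$q[remaining], peaks$height[remaining],
                       peaks$prominence[remaining], peaks$width[remaining],
                       source_label = attr(peaks, "source_label"),
                       q_range = attr(peaks, "q_range"))
      cands2 <- all_candidate_fits(sub, tolerance_rel, cubic_sets)
      if (length(cands2)) {
        second <- rank_fits(cands2)[[1]]
        # a second phase must carry appreciable scattered intensity;
        # this stops constellations of residual noise maxima from
        # masquerading as coexistence
        if (second$weight_sum >= 0.05 * best$weight_sum) {
          second$matched <- remaining[second$matched]
          fits[[2]] <- second
          fit_of[second$matched] <- 2L
        }
      }
    }
  }
  un <- which(is.na(fit_of))
  structure(list(
    fits = fits,
    assignment = data.frame(q = peaks$q, fit = fit_of),
    unassigned = peak_list(peaks$q[un], peaks$height[un],
                           peaks$prominence[un], peaks$width[un],
                           source_label = attr(peaks, "source_label")),
    coexistence = length(fits) == 2L,
    cubic_candidates = cubic_cands),
    class = "phase_assignment")
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat(sprintf("<phase_assignment> %d fit(s)%s, %d unassigned peak(s)\n",
              length(x$fits),
              if (x$coexistence) " (coexistence)" else "",
              nrow(x$unassigned)))
  for (f in x$fits) print(f)
  invisible(x)
}

# compact text label for a phase assignment, e.g. "L_alpha+H_II"
phase_label <- function(assignment) {
  if (!length(assignment$fits)) return("unassigned")
  lab <- vapply(assignment$fits, function(f) {
    switch(f$type, lamellar = "L_alpha", hexagonal = "H_II",
           cubic = "Q")
  }, character(1))
  paste(lab, collapse = "+")
}

# principal lattice parameter of the top-ranked fit (d or a, Angstrom)
primary_lattice_parameter <- function(assignment) {
  if (!length(assignment$fits)) return(NA_real_)
  f <- assignment$fits[[1]]
  if (f$type == "lamellar") f$d else f$a
}
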