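#' Osmotic pressure from relative humidity
#'
#' At equilibrium with a vapor of relative humidity RH, the chemical
#' potential of water is delta_mu_w = R*T*ln(RH/100) (<= 0), and the
#' osmotic pressure exerted on the sample is
#' Pi_osm = -delta_mu_w / V_w, reported here with the nonnegative sign
#' convention (Pi_osm = 0 exactly at RH = 100, growing as the vapor
#' dries).
#'
#' @param RH Relative humidity in percent, in (0, 100]; vectorized.
#' @param T Temperature in kelvin; default 300.15 (27 C, a common
#'   equilibration temperature for humidity-chamber work).
#' @param V_w Molar volume of water in m^3/mol; default 1.805e-5.
#' @return A data frame of class `osmotic_conditions` with columns
#'   `RH`, `T`, `V_w`, `delta_mu_w` (J/mol) and `Pi_osm` (Pa).
#' @export
#' @examples
#' osmotic_pressure(75, 300.15)$Pi_osm  # ~4e7 Pa
osmotic_pressure <- function(RH, T = 300.15, V_w = 1.805e-5) {
  abort_if(any(RH <= 0 | RH > 100), "RH must lie in (0, 100]")
  abort_if(any(T <= 0), "T must be positive (kelvin)")
  abort_if(any(V_w <= 0), "V_w must be positive")
  R <- 8.314462618  # J/(mol K)
  delta_mu_w <- R * T * log(RH / 100)
  out <- data.frame(RH = RH, T = T, V_w = V_w,
                    delta_mu_w = delta_mu_w,
                    Pi_osm = -delta_mu_w / V_w)
  class(out) <- c("osmotic_conditions", "data.frame")
  out
}

#' Aqueous-layer thickness of a lamellar repeat
#'
#' Decomposes a lamellar repeat distance d into a fixed hydrocarbon
#' layer d_l and the remainder d_w = d - d_l. The hydrocarbon
#' thickness is assumed constant across hydration; d_w therefore
#' contains both the polar headgroup region and the interbilayer water.
#'
#' @param d Lamellar repeat distance, Angstrom (> 0); vectorized.
#' @param d_l Hydrocarbon-layer thickness, Angstrom (> 0); default
#'   27.1, the POPC value.
#' @return d - d_l in Angstrom. A warning is emitted where d <= d_l
#'   (the decomposition is then meaningless but the arithmetic value is
#'   still returned).
#' @export
#' @examples
#' water_layer(94, 27.1)  # 66.9
water_layer <- function(d, d_l = 27.1) {
  abort_if(any(d <= 0) || any(d_l <= 0), "d and d_l must be positive")
  if (any(d <= d_l))
    warning("d <= d_l for some points: aqueous layer is not defined there",
            call. = FALSE)
  d - d_l
}

#' Assemble hydration points into a swelling series
#'
#' Sorts lamellar (hydration, d) points along the hydration axis,
#' decomposes each repeat into d_l + d_w, flags non-monotonic series,
#' and detects a swelling plateau: the first point beyond which d
#' changes by less than `plateau_tolerance` (relative) at every
#' subsequent step. A plateau marks the maximum swelling, e.g. when
#' bridging molecules arrest the lamellar expansion.
#'
#' @param points Data frame with columns `hydration` and `d`
#'   (Angstrom); optional column `d_l`.
#' @param d_l Hydrocarbon thickness used where the `d_l` column is
#'   absent; default 27.1 Angstrom.
#' @param hydration_kind `"wt_pct"` or `"RH"`; one axis per series.
#' @param plateau_tolerance Maximum relative step change within the
#'   plateau; default 0.02.
#' @param sample_label Series label.
#' @return An object of class `swelling_series`: list with sorted
#'   `points` (hydration, d, d_l, d_w), `plateau_d`,
#'   `plateau_onset_hydration` (both `NA` when no plateau is reached)
#'   and `monotonic`.
#' @export
build_swelling_series <- function(points, d_l = 27.1,
                                  hydration_kind = c("wt_pct", "RH"),
                                  plateau_tolerance = 0.02,
                                  sample_label = "series") {
  hydration_kind <- match.arg(hydration_kind)
  abort_if(!is.data.frame(points) ||
             !all(c("hydration", "d") %in% names(points)),
           "points must be a data frame with columns hydration and d")
  abort_if(nrow(points) < 2L, "need at least 2 lamellar points")
  pts <- points[order(points$hydration), , drop = FALSE]
  if (is.null(pts$d_l)) pts$d_l <- d_l
  pts$d_w <- water_layer(pts$d, pts$d_l)
  rownames(pts) <- NULL
  n <- nrow(pts)
  step_rel <- diff(pts$d) / pts$d[-n]
  monotonic <- all(step_rel >= -plateau_tolerance)
  flat <- abs(step_rel) < plateau_tolerance
  onset <- NA_integer_
  for (i in seq_len(n - 1L)) {
    if (all(flat[i:(n - 1L)])) { onset <- i; break }
  }
  plateau_d <- if (!is.na(onset)) mean(pts$d[onset:n]) else NA_real_
  structure(list(points = pts,
                 sample_label = sample_label,
                 hydration_kind = hydration_kind,
                 plateau_d = plateau_d,
                 plateau_onset_hydration =
                   if (!is.na(onset)) pts$hydration[onset] else NA_real_,
                 plateau_tolerance = plateau_tolerance,
                 monotonic = monotonic),
            class = "swelling_series")
}

#' @export
print.swelling_series <- function(x, ...) {
  cat(sprintf("<swelling_series> %s: %d points (%s axis)\n",
              x$sample_label, nrow(x$points),
              if (x$hydration_kind == "RH") "%RH" else "wt% water"))
  if (!is.na(x$plateau_d))
    cat(sprintf("  plateau: d = %.1f A from %.4g onward\n",
                x$plateau_d, x$plateau_onset_hydration))
  else cat("  no plateau detected (still swelling)\n")
  if (!x$monotonic) cat("  warning: series not monotonic in hydration\n")
  invisible(x)
}

#' Assemble phase calls into a one-dimensional phase map
#'
#' Orders per-sample phase assignments along the hydration axis and
#' merges consecutive points with the same phase call into intervals.
#' Boundaries between intervals are placed midway between the adjacent
#' measured points and flagged as not experimentally determined, since
#' the true transition lies somewhere between the two measurements.
#'
#' @param series Data frame with columns `hydration` and either
#'   `assignment` (a list column of [classify_phase()] results) or
#'   `label` (character phase labels).
#' @param hydration_kind `"wt_pct"` or `"RH"`.
#' @return An object of class `phase_map`: list with `points`
#'   (hydration, label) and `intervals` (start, end, label,
#'   boundary_determined flags).
#' @export
build_phase_map <- function(series, hydration_kind = c("wt_pct", "RH")) {
  hydration_kind <- match.arg(hydration_kind)
  abort_if(!is.data.frame(series) || !"hydration" %in% names(series),
           "series must be a data frame with a hydration column")
  if (!is.null(series$assignment)) {
    lab <- vapply(series$assignment, phase_label, character(1))
  } else {
    abort_if(is.null(series$label),
             "series needs an assignment or label column")
    lab <- as.character(series$label)
  }
  abort_if(nrow(series) < 2L, "need at least 2 assignments")
  ord <- order(series$hydration)
  h <- series$hydration[ord]; lab <- lab[ord]
  dup <- duplicated(h)
  if (any(dup)) {
    for (hv in unique(h[dup]))
      abort_if(length(unique(lab[h == hv])) > 1L,
               "conflicting phase calls at hydration %.4g", hv)
    keep <- !duplicated(h)
    h <- h[keep]; lab <- lab[keep]
  }
  runs <- rle(lab)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1L) + 1L)
  k <- length(runs$values)
  start <- numeric(k); end <- numeric(k)
  start[1] <- h[1]
  end[k] <- h[length(h)]
  if (k > 1L) {
    start[2:k] <- (h[starts_idx[2:k]] + h[starts_idx[2:k] - 1L]) / 2
    end[1:(k - 1L)] <- (h[ends_idx[1:(k - 1L)]] +
                          h[ends_idx[1:(k - 1L)] + 1L]) / 2
  }
  intervals <- data.frame(start = start, end = end, label = runs$values,
                          start_determined = starts_idx == 1L,
                          end_determined = ends_idx == length(h))
  structure(list(points = data.frame(hydration = h, label = lab),
                 intervals = intervals,
                 hydration_kind = hydration_kind),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d interval(s) along the %s axis\n",
              nrow(x$intervals),
              if (x$hydration_kind == "RH") "%RH" else "wt% water"))
  for (i in seq_len(nrow(x$intervals))) {
    iv <- x$intervals[i, ]
    cat(sprintf("  [%.4g%s, %.4g%s] %s\n",
                iv$start, if (iv$start_determined) "" else "?",
                iv$end, if (iv$end_determined) "" else "?",
                iv$label))
  }
  cat("  ('?' marks boundaries placed midway between measurements,\n",
      "  not experimentally determined)\n", sep = "")
  invisible(x)
}
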