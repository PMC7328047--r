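#' Construct a Bragg peak list
#'
#' @param q_center Peak centers in 1/Angstrom, strictly increasing.
#' @param height Peak heights (a.u.).
#' @param prominence Topographic prominences (a.u., > 0).
#' @param width Full widths at half prominence (1/Angstrom).
#' @param source_label Label of the originating curve.
#' @param q_range q window that was searched for peaks (1/Angstrom);
#'   defaults to the span of the peaks themselves. Indexing uses it to
#'   tell whether a predicted reflection falling inside the window
#'   should have been observed.
#' @return A data frame of class `peak_list` with columns `q`, `height`,
#'   `prominence`, `width`.
#' @export
peak_list <- function(q_center, height = NA_real_, prominence = NA_real_,
                      width = NA_real_, source_label = "peaks",
                      q_range = NULL) {
  n <- length(q_center)
  if (n > 1L)
    abort_if(any(diff(q_center) <= 0), "q_center must be strictly increasing")
  out <- data.frame(q = as.numeric(q_center),
                    height = rep_len(as.numeric(height), n),
                    prominence = rep_len(as.numeric(prominence), n),
                    width = rep_len(as.numeric(width), n))
  attr(out, "source_label") <- source_label
  attr(out, "q_range") <- q_range %||% if (n) range(out$q) else NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %s: %d peak(s)\n",
              attr(x, "source_label") %||% "peaks", nrow(x)))
  if (nrow(x)) print.data.frame(format(as.data.frame(x), digits = 5))
  invisible(x)
}

# starting values for the power-law background fit, estimated from the
# lower intensity envelope so that Bragg peaks do not bias them
bg_start_values <- function(q, I) {
  c0 <- max(min(I), 0)
  low <- I <= stats::quantile(I, 0.5)
  y <- pmax(I[low] - 0.9 * c0, max(I) * 1e-9)
  fit <- stats::lm(log(y) ~ log(q[low]))
  p0 <- max(min(-stats::coef(fit)[2], 6), 0.1)
  A0 <- max(exp(stats::coef(fit)[1]), max(I) * 1e-9)
  list(A = unname(A0), p = unname(p0), c0 = c0 * 0.9)
}

fit_power_background <- function(q, I, n_iter = 5L) {
  keep <- rep(TRUE, length(q))
  fit <- NULL
  for (it in seq_len(n_iter)) {
    df <- data.frame(q = q[keep], I = I[keep])
    if (nrow(df) < 10L) break
    start <- tryCatch(bg_start_values(df$q, df$I), error = function(e) NULL)
    if (is.null(start)) return(NULL)
    fit <- tryCatch(
      minpack.lm::nlsLM(I ~ A * q^(-p) + c0, data = df, start = start,
                        lower = c(A = 0, p = 0, c0 = -Inf),
                        upper = c(A = Inf, p = 8, c0 = Inf),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, maxfev = 2000)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    pred <- stats::predict(fit, newdata = data.frame(q = q))
    r <- I - pred
    s <- stats::mad(r[keep])
    thr <- stats::quantile(r[keep], 0.85)
    keep_new <- r <= pmax(thr, 3 * s, 1e-12)
    if (all(keep_new == keep)) break
    keep <- keep_new
  }
  if (is.null(fit)) return(NULL)
  stats::predict(fit, newdata = data.frame(q = q))
}

#' Subtract a smooth power-law background from a curve
#'
#' Fits A*q^(-p) + c to the peak-free part of the curve by iteratively
#' refitting while excluding points lying above a running quantile of
#' the residuals (Bragg peaks are excluded within a few iterations),
#' then subtracts the fitted background everywhere. The result may
#' contain small negative values; this is flagged in the metadata
#' rather than clipped, so that downstream statistics see the data
#' unaltered.
#'
#' @param curve A [scattering_curve()].
#' @return A background-subtracted [scattering_curve()] with metadata
#'   flags `background_subtracted`, `has_negative` and, on fit failure,
#'   `background_fit_failed` (in which case the input is returned
#'   unchanged, with a warning).
#' @export
subtract_background <- function(curve) {
  stopifnot(inherits(curve, "scattering_curve"))
  bg <- fit_power_background(curve$q, curve$intensity)
  if (is.null(bg)) {
    warning("background fit failed; returning curve unchanged",
            call. = FALSE)
    curve$metadata$background_fit_failed <- TRUE
    return(curve)
  }
  res <- curve$intensity - bg
  curve$intensity <- res
  curve$metadata$background_subtracted <- TRUE
  curve$metadata$has_negative <- any(res < 0)
  curve
}

# topographic prominence of local maxima at indices idx (scipy convention:
# height above the higher of the two bases, each base being the minimum
# between the peak and the nearest higher point, or the signal edge)
peak_prominences <- function(y, idx) {
  n <- length(y)
  vapply(idx, function(i) {
    h <- y[i]
    lmin <- h; j <- i
    while (j > 1L) {
      j <- j - 1L
      if (y[j] > h) break
      if (y[j] < lmin) lmin <- y[j]
    }
    rmin <- h; j <- i
    while (j < n) {
      j <- j + 1L
      if (y[j] > h) break
      if (y[j] < rmin) rmin <- y[j]
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

# width at half prominence, by linear interpolation on both flanks
peak_half_widths <- function(q, y, idx, prom) {
  n <- length(y)
  mapply(function(i, p) {
    ref <- y[i] - p / 2
    jl <- i
    while (jl > 1L && y[jl] > ref) jl <- jl - 1L
    ql <- if (y[jl] <= ref && jl < i) {
      stats::approx(y[c(jl, jl + 1L)], q[c(jl, jl + 1L)], xout = ref)$y
    } else q[jl]
    jr <- i
    while (jr < n && y[jr] > ref) jr <- jr + 1L
    qr <- if (y[jr] <= ref && jr > i) {
      stats::approx(y[c(jr - 1L, jr)], q[c(jr - 1L, jr)], xout = ref)$y
    } else q[jr]
    max(qr - ql, (q[min(i + 1L, n)] - q[max(i - 1L, 1L)]) / 2)
  }, idx, prom)
}

# parabolic (three-point) refinement of a grid maximum
refine_parabolic <- function(q, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(q[i])
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  den <- y0 - 2 * y1 + y2
  if (den >= 0) return(q[i])
  delta <- 0.5 * (y0 - y2) / den
  if (abs(delta) > 1) return(q[i])
  q[i] + delta * (q[i + 1L] - q[i - 1L]) / 2
}

#' Locate Bragg peaks in a background-subtracted curve
#'
#' Finds local maxima after light Savitzky-Golay smoothing, computes
#' topographic prominences, keeps maxima whose prominence reaches
#' `min_prominence_rel` times the largest prominence and which are at
#' least `min_separation` apart (keeping the more prominent of any
#' close pair), and refines each center by parabolic interpolation
#' through the three raw-intensity points around the maximum.
#'
#' Negative intensities are clipped at zero for the prominence
#' computation only; heights are reported from the unclipped data.
#'
#' @param curve A background-subtracted [scattering_curve()].
#' @param min_prominence_rel Minimum prominence relative to the largest
#'   prominence in the curve; default 0.02.
#' @param min_separation Minimum distance between accepted peaks,
#'   1/Angstrom; default 0.005.
#' @param smooth Apply Savitzky-Golay smoothing (window 5, order 2)
#'   before the maxima search; default `TRUE`.
#' @param refine Parabolic sub-grid refinement of centers; default
#'   `TRUE`.
#' @return A [peak_list()] (empty if no peak qualifies).
#' @export
find_peaks <- function(curve, min_prominence_rel = 0.02,
                       min_separation = 0.005, smooth = TRUE,
                       refine = TRUE) {
  stopifnot(inherits(curve, "scattering_curve"))
  q <- curve$q
  raw <- curve$intensity
  y <- if (smooth && length(raw) >= 5L) {
    signal::sgolayfilt(raw, p = 2, n = 5)
  } else raw
  yc <- pmax(y, 0)
  n <- length(yc)
  empty <- peak_list(numeric(0),
                     source_label = curve$metadata$sample_label)
  if (n < 3L || all(yc == 0)) return(empty)
  i <- 2:(n - 1L)
  cand <- i[yc[i] > yc[i - 1L] & yc[i] >= yc[i + 1L] & yc[i] > 0]
  if (!length(cand)) return(empty)
  prom <- peak_prominences(yc, cand)
  # absolute floor guards against numerically flat curves where
  # smoothing leaves O(eps) wiggles
  ok <- prom > 1e-9 * max(yc)
  cand <- cand[ok]; prom <- prom[ok]
  if (!length(cand)) return(empty)
  keepable <- prom >= min_prominence_rel * max(prom)
  cand <- cand[keepable]; prom <- prom[keepable]
  # enforce separation, most prominent first
  ord <- order(prom, decreasing = TRUE)
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(abs(q[cand[j]] - q[cand[kept]]) >= min_separation))
      kept <- c(kept, j)
  }
  cand <- cand[sort(kept)]; prom <- prom[sort(kept)]
  centers <- if (refine) {
    vapply(cand, function(i) refine_parabolic(q, raw, i), numeric(1))
  } else q[cand]
  widths <- peak_half_widths(q, yc, cand, prom)
  ord2 <- order(centers)
  peak_list(centers[ord2], height = raw[cand][ord2],
            prominence = prom[ord2], width = widths[ord2],
            source_label = curve$metadata$sample_label,
            q_range = range(q))
}
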