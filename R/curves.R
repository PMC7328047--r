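#' One-dimensional scattering curve
#'
#' Container for an azimuthally integrated small-angle X-ray scattering
#' profile: intensity (arbitrary units) versus the magnitude of the
#' scattering vector q (in inverse Angstrom). Hydration metadata travels
#' with the curve so that downstream swelling analysis can assemble
#' series without re-reading sample sheets.
#'
#' @param q Numeric vector of q values in 1/Angstrom, strictly increasing.
#' @param intensity Numeric vector of intensities (a.u.), same length as
#'   `q`, all finite.
#' @param sample_label Character scalar naming the sample.
#' @param hydration Numeric scalar: water content (wt\%) or relative
#'   humidity (\%), interpreted according to `hydration_kind`; `NA` if
#'   unknown.
#' @param hydration_kind Either `"wt_pct"` or `"RH"`; which axis
#'   `hydration` lives on. The two are never mixed within one series.
#' @param temperature Temperature in kelvin (`NA` if unknown).
#' @param metadata Optional named list of extra metadata (e.g. ground
#'   truth peak centers for synthetic curves).
#'
#' @return An object of class `scattering_curve`: a list with elements
#'   `q`, `intensity` and `metadata`.
#' @export
#' @examples
#' sc <- scattering_curve(seq(0.02, 0.5, length.out = 100),
#'                        rep(1, 100), sample_label = "flat")
scattering_curve <- function(q, intensity, sample_label = "sample",
                             hydration = NA_real_,
                             hydration_kind = c("wt_pct", "RH"),
                             temperature = NA_real_,
                             metadata = list()) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  abort_if(length(q) != length(intensity),
           "q and intensity must have equal length (%d vs %d)",
           length(q), length(intensity))
  abort_if(length(q) < 2L, "a curve needs at least 2 points")
  abort_if(any(!is.finite(q)), "q contains non-finite values")
  abort_if(any(diff(q) <= 0), "q must be strictly increasing")
  abort_if(any(!is.finite(intensity)), "intensity contains non-finite values")
  hydration_kind <- match.arg(hydration_kind)
  md <- utils::modifyList(
    list(sample_label = as.character(sample_label),
         hydration = as.numeric(hydration),
         hydration_kind = hydration_kind,
         temperature = as.numeric(temperature)),
    metadata)
  structure(list(q = q, intensity = intensity, metadata = md),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<scattering_curve> %s: %d points, q in [%.4g, %.4g] 1/A\n",
              md$sample_label, length(x$q), min(x$q), max(x$q)))
  if (!is.na(md$hydration))
    cat(sprintf("  hydration: %.4g %s\n", md$hydration,
                if (md$hydration_kind == "RH") "%RH" else "wt% water"))
  if (!is.null(md$true_centers))
    cat(sprintf("  synthetic; %d ground-truth reflections\n",
                length(md$true_centers)))
  invisible(x)
}

#' Write a scattering curve to disk
#'
#' Writes the generic two-column exchange format: either whitespace
#' separated ASCII with `#` comment lines, or CSV with headers
#' `q,intensity`. For synthetic curves the ground-truth metadata
#' (true peak centers, lattice type and parameter) is written to a JSON
#' sidecar file `<path>.json` so simulated fixtures remain
#' self-describing.
#'
#' @param curve A [scattering_curve()].
#' @param path Output file path; a `.csv` extension selects CSV.
#' @param format `"ascii"` or `"csv"`; defaults from the extension.
#' @param sidecar Write the JSON ground-truth sidecar when the curve
#'   carries `true_centers` metadata (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_scattering_curve <- function(curve, path, format = NULL,
                                   sidecar = TRUE) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "ascii"
  format <- match.arg(format, c("ascii", "csv"))
  if (format == "csv") {
    utils::write.csv(data.frame(q = curve$q, intensity = curve$intensity),
                     path, row.names = FALSE)
  } else {
    md <- curve$metadata
    hdr <- c(sprintf("# sample: %s", md$sample_label),
             sprintf("# hydration: %s (%s)", md$hydration, md$hydration_kind),
             sprintf("# temperature_K: %s", md$temperature),
             "# q[1/A] I[a.u.]")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(cbind(curve$q, curve$intensity), con,
                       row.names = FALSE, col.names = FALSE)
  }
  if (sidecar && !is.null(curve$metadata$true_centers)) {
    gt <- curve$metadata[intersect(
      c("sample_label", "phase_type", "lattice_parameter", "true_centers",
        "true_heights", "component_phases"),
      names(curve$metadata))]
    jsonlite::write_json(gt, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a scattering curve from disk
#'
#' Accepts the two dialects written by [write_scattering_curve()]:
#' two-column ASCII with `#` comments, or CSV with `q`/`intensity`
#' headers (any extra columns are ignored).
#'
#' @param path Input file.
#' @inheritParams scattering_curve
#' @return A [scattering_curve()].
#' @export
read_scattering_curve <- function(path, sample_label = NULL,
                                  hydration = NA_real_,
                                  hydration_kind = c("wt_pct", "RH"),
                                  temperature = NA_real_) {
  abort_if(!file.exists(path), "file not found: %s", path)
  hydration_kind <- match.arg(hydration_kind)
  is_csv <- grepl("\\.csv$", path, ignore.case = TRUE)
  if (!is_csv) {
    first <- readLines(path, n = 1L, warn = FALSE)
    is_csv <- grepl(",", first, fixed = TRUE)
  }
  if (is_csv) {
    df <- utils::read.csv(path, comment.char = "#")
    qcol <- grep("^q$", names(df), ignore.case = TRUE)[1]
    icol <- grep("^(intensity|i)$", names(df), ignore.case = TRUE)[1]
    abort_if(is.na(qcol) || is.na(icol),
             "%s: need columns q and intensity", path)
    q <- df[[qcol]]; intensity <- df[[icol]]
  } else {
    df <- utils::read.table(path, comment.char = "#")
    abort_if(ncol(df) < 2L, "%s: expected two columns", path)
    q <- df[[1]]; intensity <- df[[2]]
  }
  scattering_curve(q, intensity,
                   sample_label = sample_label %||% basename(path),
                   hydration = hydration, hydration_kind = hydration_kind,
                   temperature = temperature)
}
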