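#' Default pipeline configuration
#'
#' All tunable parameters of the curve-to-report pipeline with their
#' package defaults. A YAML file with any subset of these keys
#' overrides the defaults.
#'
#' @param path Optional YAML configuration file.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- list(
    d_l = 27.1,                 # hydrocarbon thickness, Angstrom
    tolerance_rel = 0.01,       # indexing match tolerance
    min_prominence_rel = 0.02,  # peak prominence threshold
    min_separation = 0.005,     # peak separation, 1/Angstrom
    smooth = TRUE,              # Savitzky-Golay pre-smoothing
    refine = TRUE,              # parabolic center refinement
    allow_coexistence = TRUE,
    plateau_tolerance = 0.02,   # relative step within a plateau
    temperature = 300.15,       # kelvin, for osmotic pressure
    V_w = 1.805e-5)             # molar volume of water, m^3/mol
  if (!is.null(path)) {
    abort_if(!file.exists(path), "config file not found: %s", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    abort_if(length(unknown) > 0, "unknown config key(s): %s",
             paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' Read a run manifest
#'
#' A manifest CSV lists one scattering curve per row with columns
#' `sample`, `curve_file`, `hydration`, `hydration_kind` ("wt_pct" or
#' "RH") and optionally `temperature_K` and `d_l`. Relative curve paths
#' are resolved against the manifest's directory.
#'
#' @param path Manifest CSV file.
#' @return A data frame (one row per curve).
#' @export
read_manifest <- function(path) {
  abort_if(!file.exists(path), "manifest not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(nrow(m) == 0L, "manifest is empty")
  need <- c("sample", "curve_file", "hydration", "hydration_kind")
  missing <- setdiff(need, names(m))
  abort_if(length(missing) > 0, "manifest lacks column(s): %s",
           paste(missing, collapse = ", "))
  abort_if(anyDuplicated(m[, c("sample", "hydration")]) > 0,
           "duplicate (sample, hydration) pairs in manifest")
  abort_if(!all(m$hydration_kind %in% c("wt_pct", "RH")),
           "hydration_kind must be 'wt_pct' or 'RH'")
  rel <- !file.exists(m$curve_file)
  m$curve_file[rel] <- file.path(dirname(path), m$curve_file[rel])
  m
}

analyze_one_curve <- function(row, cfg) {
  curve <- read_scattering_curve(row$curve_file,
                                 sample_label = row$sample,
                                 hydration = row$hydration,
                                 hydration_kind = row$hydration_kind,
                                 temperature = row$temperature_K %||% NA_real_)
  sub <- subtract_background(curve)
  peaks <- find_peaks(sub, min_prominence_rel = cfg$min_prominence_rel,
                      min_separation = cfg$min_separation,
                      smooth = cfg$smooth, refine = cfg$refine)
  abort_if(nrow(peaks) == 0L, "no peaks detected")
  assignment <- classify_phase(peaks,
                               allow_coexistence = cfg$allow_coexistence,
                               tolerance_rel = cfg$tolerance_rel)
  abort_if(length(assignment$fits) == 0L, "no lattice could be indexed")
  top <- assignment$fits[[1]]
  d_l <- if (!is.null(row$d_l) && !is.na(row$d_l)) row$d_l else cfg$d_l
  is_lam <- top$type == "lamellar"
  list(sample = row$sample,
       hydration = row$hydration,
       hydration_kind = row$hydration_kind,
       phase = phase_label(assignment),
       coexistence = assignment$coexistence,
       lattice_parameter = primary_lattice_parameter(assignment),
       d = if (is_lam) top$d else NA_real_,
       d_uncertainty = if (is_lam) top$d_uncertainty else NA_real_,
       d_w = if (is_lam) suppressWarnings(water_layer(top$d, d_l))
             else NA_real_,
       d_l = d_l,
       n_peaks = nrow(peaks),
       assignment = assignment)
}

#' Run the full curve-to-report pipeline
#'
#' For every manifest entry: read the curve, subtract the background,
#' find peaks, index the phase(s), and decompose lamellar repeats into
#' d_l + d_w. Per-sample series (grouped by sample label) are then
#' assembled into swelling series (wt\% axis) and phase maps, and RH
#' entries are converted to osmotic pressures. Failures are recorded
#' per curve without stopping the batch; the run errors only if every
#' curve fails (or the manifest is empty).
#'
#' @param manifest Manifest data frame or CSV path (see
#'   [read_manifest()]).
#' @param config Configuration list from [pipeline_config()].
#' @param output_dir Directory for the JSON report and CSV tables;
#'   `NULL` writes nothing.
#' @return An object of class `run_report`: list with `samples`
#'   (per-curve results data frame), `failures`, `series` (per-sample
#'   [build_swelling_series()] results), `phase_maps`, `osmotic`
#'   (per-RH-entry pressures) and `provenance`. Identical inputs and
#'   configuration yield identical reports.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         output_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  abort_if(!is.data.frame(manifest) || nrow(manifest) == 0L,
           "manifest is empty")
  results <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- as.list(manifest[i, , drop = FALSE])
    res <- tryCatch(analyze_one_curve(row, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(sample = row$sample, hydration = row$hydration,
                   reason = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  abort_if(length(results) == 0L, "all %d sample(s) failed", nrow(manifest))
  samples <- do.call(rbind, lapply(results, function(r)
    data.frame(r[setdiff(names(r), "assignment")])))
  samples <- samples[order(samples$sample, samples$hydration), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(sample = character(0), hydration = numeric(0),
               reason = character(0))

  series <- list(); phase_maps <- list()
  for (lab in unique(samples$sample)) {
    sub <- samples[samples$sample == lab, , drop = FALSE]
    lam <- sub[!is.na(sub$d), , drop = FALSE]
    if (nrow(lam) >= 2L)
      series[[lab]] <- build_swelling_series(
        lam[, c("hydration", "d", "d_l")],
        hydration_kind = lam$hydration_kind[1],
        plateau_tolerance = config$plateau_tolerance,
        sample_label = lab)
    if (nrow(sub) >= 2L)
      phase_maps[[lab]] <- build_phase_map(
        data.frame(hydration = sub$hydration, label = sub$phase),
        hydration_kind = sub$hydration_kind[1])
  }
  rh <- samples[samples$hydration_kind == "RH" & !is.na(samples$hydration), ]
  osmotic <- if (nrow(rh)) {
    oc <- osmotic_pressure(rh$hydration, T = config$temperature,
                           V_w = config$V_w)
    cbind(sample = rh$sample, oc)
  } else NULL

  report <- structure(list(
    samples = samples, failures = failures, series = series,
    phase_maps = phase_maps, osmotic = osmotic,
    assignments = lapply(results, `[[`, "assignment"),
    provenance = list(
      package = "mesoswell",
      version = as.character(utils::packageVersion("mesoswell")),
      config = config,
      n_curves = nrow(manifest))),
    class = "run_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(samples, file.path(output_dir, "samples.csv"),
                     row.names = FALSE)
    if (nrow(failures))
      utils::write.csv(failures, file.path(output_dir, "failures.csv"),
                       row.names = FALSE)
    swell <- do.call(rbind, lapply(names(series), function(lab)
      cbind(sample = lab, series[[lab]]$points)))
    if (!is.null(swell))
      utils::write.csv(swell, file.path(output_dir, "swelling.csv"),
                       row.names = FALSE)
    json <- list(
      samples = samples, failures = failures,
      series = lapply(series, function(s)
        list(sample_label = s$sample_label, plateau_d = s$plateau_d,
             plateau_onset_hydration = s$plateau_onset_hydration,
             monotonic = s$monotonic, points = s$points)),
      phase_maps = lapply(phase_maps, function(pm)
        list(points = pm$points, intervals = pm$intervals)),
      osmotic = osmotic,
      provenance = report$provenance)
    jsonlite::write_json(json, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d sample(s) analyzed, %d failed\n",
              nrow(x$samples), nrow(x$failures)))
  print.data.frame(format(x$samples, digits = 4))
  for (s in x$series) print(s)
  invisible(x)
}
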