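#' Pipeline configuration
#'
#' Every tunable of the end-to-end chain with its default. CLI flags and
#' callers override individual entries.
#'
#' @param backend Segmentation backend, `"classical"` or `"neural"`.
#' @param seg_params [classical_params()] for the classical backend.
#' @param model Trained model for the neural backend.
#' @param trim_frac Lateral edge trim used by [roughness_report()].
#' @param profile_smooth Moving-average window of the mean depth profile.
#' @param min_prominence Extremum prominence threshold of the epidermal
#'   peak/valley detection.
#' @param attenuation_window Optional fixed fit window (um) for the
#'   attenuation fit; `NULL` derives it from the DEJ valley.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(backend = "classical",
                            seg_params = classical_params(),
                            model = NULL,
                            trim_frac = 0.05,
                            profile_smooth = 1L,
                            min_prominence = 0.1,
                            attenuation_window = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full roughness + optics pipeline on a volume
#'
#' Executes segmentation, boundary extraction, quadratic flattening, Ra/Rz
#' computation and the optical metrics, collecting per-stage provenance.
#' Deterministic: rerunning with the same volume and config reproduces the
#' reports exactly.
#'
#' @param vol An [oct_volume()].
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `roughness`
#'   (`roughness_report`), `optics` (`optics_report`), `boundary_raw`,
#'   `boundary_detrended`, `mask_backend`.
#' @export
run_pipeline <- function(vol, config = pipeline_config()) {
  stopifnot(inherits(vol, "oct_volume"), inherits(config, "pipeline_config"))
  mask <- segment_volume(vol, backend = config$backend,
                         params = config$seg_params, model = config$model)
  raw <- extract_boundary(mask, axial_pitch = vol$axial_pitch,
                          lateral_pitch = vol$lateral_pitch,
                          slice_pitch = vol$slice_pitch)
  det <- flatten(raw)
  rough <- roughness_report(det, trim_frac = config$trim_frac)
  rough$provenance$backend <- config$backend
  rough$provenance$missing_columns <- sum(raw$missing)
  opt <- optics_report(vol, raw, smooth = config$profile_smooth,
                       min_prominence = config$min_prominence,
                       window = config$attenuation_window)
  structure(list(roughness = rough, optics = opt,
                 boundary_raw = raw, boundary_detrended = det,
                 mask_backend = config$backend),
            class = "pipeline_result")
}

#' Serialize a pipeline result as JSON
#'
#' Floats are written with six decimal places so reruns are byte-identical.
#'
#' @param result A `pipeline_result` (or `roughness_report`).
#' @param path JSON path.
#' @export
write_report <- function(result, path) {
  to_list <- function(r) {
    if (inherits(r, "pipeline_result")) {
      list(roughness = to_list(r$roughness),
           optics = list(
             epidermal_thickness_um = .round6(r$optics$epidermal_thickness_um),
             attenuation_mu_mm = .round6(r$optics$attenuation_mu_mm),
             slope_per_mm = .round6(r$optics$slope_per_mm),
             fit_r2 = .round6(r$optics$fit_r2),
             fit_window_um = .round6(r$optics$fit_window_um)))
    } else {
      list(Ra_um = .round6(r$Ra), Rz_um = .round6(r$Rz),
           n_x = r$n_x, n_y = r$n_y, region = r$region,
           provenance = r$provenance)
    }
  }
  jsonlite::write_json(to_list(result), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

.round6 <- function(x) round(x, 6)

#' Cohort correlation analysis
#'
#' Pearson correlation between age and every available metric, overall and
#' stratified by sex, flagging `|r| > 0.6` as a strong correlation (the
#' conventional threshold for a strong positive association). Metrics with
#' zero variance in a stratum are reported as `NA`.
#'
#' @param records A data.frame with columns `subject_id`, `age`, optionally
#'   `sex` (`"M"`, `"F"`, `"unspecified"`), and one or more of `Ra`, `Rz`,
#'   `epidermal_thickness`, `attenuation_mu`.
#' @param metrics Character vector of metric columns to correlate; default:
#'   all of the above that are present.
#' @param min_n Minimum records per stratum (default 3).
#' @return A data.frame with columns `metric`, `stratum`, `n`, `r`,
#'   `strong`.
#' @export
cohort_analysis <- function(records,
                            metrics = intersect(
                              c("Ra", "Rz", "epidermal_thickness",
                                "attenuation_mu"), names(records)),
                            min_n = 3L) {
  stopifnot(is.data.frame(records), "age" %in% names(records),
            length(metrics) > 0)
  if (!"sex" %in% names(records)) records$sex <- "unspecified"
  strata <- c(list(overall = records),
              split(records, records$sex))
  out <- do.call(rbind, lapply(names(strata), function(nm) {
    df <- strata[[nm]]
    do.call(rbind, lapply(metrics, function(mt) {
      ok <- is.finite(df$age) & is.finite(df[[mt]])
      n <- sum(ok)
      r <- if (n < min_n || stats::sd(df[[mt]][ok]) == 0 ||
               stats::sd(df$age[ok]) == 0) {
        NA_real_
      } else {
        stats::cor(df$age[ok], df[[mt]][ok])
      }
      data.frame(metric = mt, stratum = nm, n = n, r = r,
                 strong = !is.na(r) & abs(r) > 0.6,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Process a rendered cohort end-to-end into a record table
#'
#' Runs [run_pipeline()] on every subject volume of a [make_cohort()] result
#' and assembles the per-subject metric table that [cohort_analysis()]
#' consumes.
#'
#' @param cohort A list from [make_cohort()].
#' @param config A [pipeline_config()].
#' @return A data.frame with one row per subject: `subject_id`, `age`,
#'   `true_Ra`, `Ra`, `Rz`, `epidermal_thickness`, `attenuation_mu`.
#' @export
process_cohort <- function(cohort, config = pipeline_config()) {
  rows <- lapply(cohort, function(rec) {
    res <- run_pipeline(rec$volume, config)
    data.frame(subject_id = rec$subject_id,
               age = rec$age,
               true_Ra = rec$truth$true_Ra,
               Ra = res$roughness$Ra,
               Rz = res$roughness$Rz,
               epidermal_thickness = res$optics$epidermal_thickness_um,
               attenuation_mu = res$optics$attenuation_mu_mm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
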