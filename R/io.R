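#' Read a device / model configuration file
#'
#' JSON configuration with the keys `span_l_mm`, `spring_length_mm`,
#' `sensor_section_end_mm`, `tape_width_mm` (geometry) and
#' `segment_ratio`, `spring_coeff`, `small_angle_deg` (model parameters).
#' Missing keys fall back to the Sensopro Luna defaults.
#'
#' @param path Path to a JSON file.
#' @return List with elements `geom` ([device_geometry()]) and `params`
#'   ([model_params()]).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  pick <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  geom <- device_geometry(
    span_l_mm = pick("span_l_mm", 1726),
    spring_length_mm = pick("spring_length_mm", 200),
    sensor_section_end_mm = pick("sensor_section_end_mm",
                                 pick("spring_length_mm", 200)),
    tape_width_mm = pick("tape_width_mm", 200)
  )
  params <- model_params(
    segment_ratio = pick("segment_ratio", 0.85),
    spring_coeff = pick("spring_coeff", 1),
    small_angle_deg = pick("small_angle_deg", 0.1)
  )
  list(geom = geom, params = params)
}

#' Write a trial bundle to a directory
#'
#' Writes the CSV interchange files of a simulated (or recorded) trial:
#' `angles_mocap.csv`, `angles_imu.csv`, `truth.csv`, optionally
#' `markers.csv`, plus `provenance.json` recording the seed, rates, and
#' package version so the run can be re-created. All units are mm,
#' degrees, and seconds; column names carry unit suffixes.
#'
#' @param bundle A `trial_bundle` from [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "trial_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wcsv(bundle$angles_mocap, "angles_mocap.csv")
  wcsv(bundle$angles_imu, "angles_imu.csv")
  wcsv(bundle$truth, "truth.csv")
  if (!is.null(bundle$markers)) wcsv(bundle$markers, "markers.csv")
  prov <- list(seed = bundle$seed, rate_hz = bundle$rate_hz,
               spring_coeff = bundle$spring_coeff,
               yaw_multiplier = bundle$yaw_multiplier,
               package = "tapekin",
               version = as.character(utils::packageVersion("tapekin")))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Read a trial bundle from a directory
#'
#' @param dir Directory written by [write_trial_bundle()].
#' @return A `trial_bundle` list.
#' @export
read_trial_bundle <- function(dir) {
  rcsv <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  prov <- jsonlite::fromJSON(file.path(dir, "provenance.json"))
  tr <- rcsv("truth.csv")
  if (!is.null(tr$airborne)) tr$airborne <- as.logical(tr$airborne)
  structure(
    list(angles_mocap = rcsv("angles_mocap.csv"),
         angles_imu = rcsv("angles_imu.csv"),
         truth = tr, markers = rcsv("markers.csv"),
         rate_hz = prov$rate_hz, spring_coeff = prov$spring_coeff,
         yaw_multiplier = prov$yaw_multiplier, seed = prov$seed),
    class = "trial_bundle"
  )
}

#' Read a simulation scenario file
#'
#' JSON with fields `rate_hz`, `keyframes` (array of objects with
#' `time_s`, `x_mm`, `depth_mm` and optional `flat_mm`, `y_mm`,
#' `roll_deg`, `airborne`), and optional `spring_coeff`, `yaw_multiplier`,
#' `noise` (fields of [drift_spec()]), `seed`, and geometry keys as in
#' [read_config()].
#'
#' @param path Path to the scenario JSON.
#' @return List ready to splice into [simulate_trial()].
#' @export
read_scenario <- function(path) {
  sc <- jsonlite::fromJSON(path)
  if (is.null(sc$keyframes) || is.null(sc$rate_hz)) {
    stop("scenario must define rate_hz and keyframes")
  }
  noise <- if (is.null(sc$noise)) drift_spec(seed = sc$seed) else
    drift_spec(
      pitch_drift_rate_dps = if (is.null(sc$noise$pitch_drift_rate_dps))
        -0.05 else sc$noise$pitch_drift_rate_dps,
      yaw_walk_sd = if (is.null(sc$noise$yaw_walk_sd)) 0.02 else
        sc$noise$yaw_walk_sd,
      roll_drift_rate_dps = if (is.null(sc$noise$roll_drift_rate_dps)) 0 else
        sc$noise$roll_drift_rate_dps,
      noise_sigma_deg = if (is.null(sc$noise$noise_sigma_deg)) 0.1 else
        sc$noise$noise_sigma_deg,
      seed = sc$seed
    )
  geom <- device_geometry(
    span_l_mm = if (is.null(sc$span_l_mm)) 1726 else sc$span_l_mm,
    spring_length_mm = if (is.null(sc$spring_length_mm)) 200 else
      sc$spring_length_mm,
    tape_width_mm = if (is.null(sc$tape_width_mm)) 200 else sc$tape_width_mm
  )
  list(script = as.data.frame(sc$keyframes), rate_hz = sc$rate_hz,
       geom = geom,
       spring_coeff = if (is.null(sc$spring_coeff)) 1 else sc$spring_coeff,
       yaw_multiplier = if (is.null(sc$yaw_multiplier)) 1 else
         sc$yaw_multiplier,
       noise = noise, seed = sc$seed)
}
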