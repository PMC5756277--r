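# Readers and writers: YAML network/scenario specs, CSV trajectories,
# JSON feature reports and run manifests.

.SCHEMA_VERSION <- 1L

#' Write a network spec to YAML
#'
#' @param spec A [network_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  doc <- list(
    schema_version = .SCHEMA_VERSION,
    states = lapply(seq_len(nrow(spec$states)), function(i)
      as.list(spec$states[i, ])),
    connections = lapply(seq_len(nrow(spec$connections)), function(i)
      as.list(spec$connections[i, ])),
    hebbian = lapply(spec$hebbian, function(h)
      Filter(Negate(is.null), h[c("learning_rate", "extinction_rate",
                                  "initial_weight")]))
  )
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Read a network spec from YAML
#'
#' Counterpart of [write_spec()]; `read_spec(write_spec(spec))` is
#' structurally equal to `spec`. Schema violations raise an error naming the
#' offending key; validation diagnostics of severity `"error"` are surfaced.
#'
#' @param path YAML file with top-level keys `schema_version`, `states`,
#'   `connections`, and optionally `hebbian`.
#' @return A [network_spec()].
#' @export
read_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  sv <- doc$schema_version
  if (is.null(sv)) stop("spec file missing key: schema_version", call. = FALSE)
  if (sv != .SCHEMA_VERSION)
    stop("unsupported schema_version: ", sv, call. = FALSE)
  for (key in c("states", "connections")) {
    if (is.null(doc[[key]])) stop("spec file missing key: ", key, call. = FALSE)
  }
  states <- lapply(doc$states, function(s) {
    if (is.null(s$name)) stop("state entry missing key: name", call. = FALSE)
    state_spec(name = s$name,
               initial_value = s$initial_value %||% 0,
               speed_factor = s$speed_factor %||% 0.17,
               steepness = s$steepness %||% 5,
               threshold = s$threshold %||% 0.5,
               clamped = isTRUE(s$clamped))
  })
  conns <- lapply(doc$connections, function(cc) {
    for (key in c("source", "target", "weight")) {
      if (is.null(cc[[key]]))
        stop("connection entry missing key: ", key, call. = FALSE)
    }
    connection_spec(cc$source, cc$target, cc$weight,
                    label = cc$label %||% NA_character_,
                    adaptive = isTRUE(cc$adaptive))
  })
  hebb <- lapply(doc$hebbian %||% list(), function(h)
    hebbian_params(h$learning_rate %||% 0.5, h$extinction_rate %||% 0.5,
                   h$initial_weight))
  spec <- network_spec(states, conns, hebb)
  diag <- validate_spec(spec)
  if (any(diag$severity == "error")) {
    stop("invalid network spec in '", path, "':\n",
         paste0("  ", diag$element, ": ", diag$message, collapse = "\n"),
         call. = FALSE)
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario profile to YAML
#' @param profile A [scenario_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(profile, path) {
  stopifnot(inherits(profile, "scenario_profile"))
  doc <- list(schema_version = .SCHEMA_VERSION, name = profile$name,
              notes = profile$notes,
              weight_overrides = as.list(profile$weight_overrides),
              stimulus_levels = as.list(profile$stimulus_levels),
              initial_values = as.list(profile$initial_values),
              state_params = profile$state_params,
              hebbian_overrides = profile$hebbian_overrides)
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Read a scenario profile from YAML
#' @param path YAML file written by [write_scenario()].
#' @return A [scenario_profile()].
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version))
    stop("scenario file missing key: schema_version", call. = FALSE)
  if (doc$schema_version != .SCHEMA_VERSION)
    stop("unsupported schema_version: ", doc$schema_version, call. = FALSE)
  if (is.null(doc$name)) stop("scenario file missing key: name", call. = FALSE)
  num <- function(x) if (length(x)) unlist(x) else numeric()
  scenario_profile(doc$name,
                   weight_overrides = num(doc$weight_overrides),
                   stimulus_levels = num(doc$stimulus_levels),
                   initial_values = num(doc$initial_values),
                   state_params = doc$state_params %||% list(),
                   hebbian_overrides = doc$hebbian_overrides %||% list(),
                   notes = doc$notes %||% "")
}

#' Write a trajectory to CSV
#'
#' First column `t`, one column per state in spec declaration order, then one
#' column per recorded adaptive label. Full double precision, lossless on
#' round trip.
#'
#' @param trajectory A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  df <- data.frame(t = trajectory$times, trajectory$activations,
                   check.names = FALSE)
  if (!is.null(trajectory$weights)) {
    df <- cbind(df, as.data.frame(trajectory$weights))
  }
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path File written by [write_trajectory_csv()].
#' @param adaptive_labels Columns to treat as adaptive-weight series (by
#'   default, columns matching the `w<label>.<valence>` pattern).
#' @return A `trajectory`.
#' @export
read_trajectory_csv <- function(path, adaptive_labels = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"t" %in% names(df)) stop("trajectory file missing column: t", call. = FALSE)
  cols <- setdiff(names(df), "t")
  if (is.null(adaptive_labels)) {
    adaptive_labels <- grep("^w[0-9]+[a-z]?\\.[12]$", cols, value = TRUE)
  }
  state_cols <- setdiff(cols, adaptive_labels)
  times <- df$t
  out <- list(times = times,
              activations = as.matrix(df[state_cols]),
              weights = if (length(adaptive_labels))
                as.matrix(df[adaptive_labels]) else NULL,
              dt = if (length(times) > 1L) times[2L] - times[1L] else NA_real_,
              state_names = state_cols, adaptive_labels = adaptive_labels)
  class(out) <- "trajectory"
  out
}

#' Serialise a feature report to JSON
#' @param report A [feature_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_report <- function(report, path) {
  jsonlite::write_json(
    list(onset_threshold = attr(report, "onset_threshold"),
         eq_tol = attr(report, "eq_tol"),
         features = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: spec path and content hash,
#' scenario name, simulation settings, package version and timestamp.
#'
#' @param path Output JSON path.
#' @param spec_path Path of the spec file used (hashed), or `NA` for the
#'   built-in canonical model.
#' @param scenario Scenario name or `NA`.
#' @param config A [simulation_config()].
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, spec_path = NA_character_,
                               scenario = NA_character_,
                               config = simulation_config()) {
  manifest <- list(
    spec_path = spec_path,
    spec_md5 = if (!is.na(spec_path)) unname(tools::md5sum(spec_path))
               else NA_character_,
    scenario = scenario,
    dt = config$dt, n_steps = config$n_steps,
    record_weights = config$record_weights,
    tool = "tcnet",
    version = as.character(utils::packageVersion("tcnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(manifest)
}
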