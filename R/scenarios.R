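# The six published scenario profiles and the shared simulation settings.

#' Scenario profile
#'
#' A named, immutable set of parameter overrides realising one simulated
#' person. Weight overrides are keyed by connection label (valence-suffixed
#' or not), stimulus levels by clamped world-state name, initial values by
#' state name.
#'
#' @param name Scenario name.
#' @param weight_overrides Named numeric vector, label -> weight.
#' @param stimulus_levels Named numeric vector, world state -> level in \[0,1\].
#' @param initial_values Named numeric vector, state -> initial activation.
#' @param state_params Named list, state -> list(steepness/threshold/
#'   speed_factor) overrides.
#' @param hebbian_overrides Named list, adaptive label -> list(learning_rate/
#'   extinction_rate/initial_weight).
#' @param notes Free-text provenance note.
#' @return A `scenario_profile` object.
#' @export
scenario_profile <- function(name, weight_overrides = numeric(),
                             stimulus_levels = numeric(),
                             initial_values = numeric(),
                             state_params = list(),
                             hebbian_overrides = list(), notes = "") {
  out <- list(name = name, weight_overrides = weight_overrides,
              stimulus_levels = stimulus_levels,
              initial_values = initial_values, state_params = state_params,
              hebbian_overrides = hebbian_overrides, notes = notes)
  class(out) <- "scenario_profile"
  out
}

#' @export
print.scenario_profile <- function(x, ...) {
  cat("<scenario_profile> '", x$name, "': ",
      length(x$weight_overrides), " weight overrides, ",
      length(x$stimulus_levels), " stimulus levels, ",
      length(x$initial_values), " initial values\n", sep = "")
  if (nzchar(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Names of the shipped scenarios
#' @return Character vector of the six scenario names.
#' @export
scenario_names <- function() {
  c("neutral", "empathic", "disempathic", "asd", "atheist", "fundamentalist")
}

# Expand a tag rule to explicit per-label overrides on the canonical model.
# `mech` matches the edge mechanism tags, `labels` matches label stems.
.edges_by <- function(edge_info, mech = NULL, stems = NULL, valence = NULL) {
  sel <- rep(TRUE, nrow(edge_info))
  if (!is.null(mech))
    sel <- sel & vapply(strsplit(edge_info$mech, " "), function(m)
      any(m %in% mech), logical(1))
  if (!is.null(stems)) sel <- sel & edge_info$stem %in% stems
  if (!is.null(valence)) sel <- sel & edge_info$valence %in% valence
  edge_info$label[sel]
}

#' Retrieve one of the six frozen scenario profiles
#'
#' The canonical default weights are the neutral person (sensing 0.8,
#' internal 0.7, effector 0.55, valence-symmetric), so `neutral` is the empty
#' profile. The others override, per the published parameterisations:
#' `empathic` sets every empathic-valence weight to 0.8 and every
#' dis-empathic one to 0.1; `disempathic` is its exact valence swap; `asd`
#' weakens the mirroring and as-if (mentalizing) connections to 0.3, sets
#' dis-empathic God-image edges to 1.0 vs empathic 0.8, and drives the
#' dis-empathic stimuli at 1.0 vs 0.5; `atheist` strengthens the
#' Self-ownership path to 1.0, weakens the God-ownership path to 0.3 and the
#' religious-source couplings to 0.3, and lowers the goal state to 0.8;
#' `fundamentalist` sets dis-empathic weights 1.0 vs empathic 0.1,
#' God-ownership 0.8 (empathic) / 0.3 (dis-empathic), Self-ownership 0.1,
#' and God-image-to-preparation and preparation-to-execution links to 1.0.
#'
#' @param name One of [scenario_names()].
#' @return A [scenario_profile()].
#' @export
get_scenario <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% scenario_names()) {
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid names: ", paste(scenario_names(), collapse = ", "),
         call. = FALSE)
  }
  ei <- build_religion_network()$edge_info
  valenced <- ei[!is.na(ei$valence), ]
  ov <- numeric()
  set <- function(ov, labels, value) {
    ov[labels] <- value
    ov
  }
  switch(name,
    neutral = scenario_profile(
      "neutral",
      notes = "valence-symmetric medium-strength connections (canonical defaults)"),
    empathic = {
      ov <- set(ov, .edges_by(valenced, valence = 1), 0.8)
      ov <- set(ov, .edges_by(valenced, valence = 2), 0.1)
      scenario_profile("empathic", weight_overrides = ov,
        notes = "empathic God-image: empathic connections 0.8, dis-empathic 0.1")
    },
    disempathic = {
      p <- valence_swap(get_scenario("empathic"))
      p$name <- "disempathic"
      p$notes <- "dis-empathic God-image: valence swap of the empathic profile"
      p
    },
    asd = {
      ov <- set(ov, .edges_by(valenced, mech = "god_image_edge", valence = 1), 0.8)
      ov <- set(ov, .edges_by(valenced, mech = "god_image_edge", valence = 2), 1.0)
      ov <- set(ov, .edges_by(valenced, mech = c("mirroring", "as_if")), 0.3)
      scenario_profile("asd", weight_overrides = ov,
        stimulus_levels = c(ws_god_action_1 = 0.5, ws_god_image_1 = 0.5,
                            ws_god_emotion_1 = 0.5, ws_god_action_2 = 1.0,
                            ws_god_image_2 = 1.0, ws_god_emotion_2 = 1.0),
        notes = "ASD with social-domain impairment: weak mirroring/mentalizing (0.3), dis-empathic God-image and stimuli dominant")
    },
    atheist = {
      ov <- set(ov, .edges_by(valenced, mech = "self_ownership_path"), 1.0)
      ov <- set(ov, .edges_by(valenced, mech = "god_ownership_path"), 0.3)
      ov <- set(ov, .edges_by(valenced,
                              stems = c("w1", "w2", "w3", "w4")), 0.3)
      scenario_profile("atheist", weight_overrides = ov,
        initial_values = c(gs = 0.8),
        notes = "avoidant attachment: Self-ownership 1.0, God-ownership 0.3, weak religious-source couplings, goal state 0.8")
    },
    fundamentalist = {
      ov <- set(ov, .edges_by(valenced, valence = 1), 0.1)
      ov <- set(ov, .edges_by(valenced, valence = 2), 1.0)
      ov <- set(ov, .edges_by(valenced, mech = "god_ownership_path",
                              valence = 1), 0.8)
      ov <- set(ov, .edges_by(valenced, mech = "god_ownership_path",
                              valence = 2), 0.3)
      ov <- set(ov, .edges_by(valenced, mech = "self_ownership_path"), 0.1)
      ov <- set(ov, .edges_by(valenced, mech = "mirroring", valence = 2), 1.0)
      ov <- set(ov, .edges_by(valenced, mech = "prep_exec"), 1.0)
      scenario_profile("fundamentalist", weight_overrides = ov,
        notes = "anxious attachment + dis-empathic God-image: dis-empathic 1.0 vs empathic 0.1, God-ownership dominant, Self-ownership 0.1")
    }
  )
}

#' Run a named scenario
#'
#' Composes [get_scenario()], [apply_parameter_profile()] and
#' [simulate_network()] under the shared published settings (dt = 0.25,
#' 500 steps, speed factor 0.17 everywhere, Hebbian learning and extinction
#' rates 0.5). Fully deterministic.
#'
#' @param name One of [scenario_names()].
#' @param config A [simulation_config()].
#' @return A `trajectory`.
#' @export
run_scenario <- function(name, config = simulation_config()) {
  inst <- apply_parameter_profile(build_religion_network(),
                                  get_scenario(name))
  simulate_network(inst$spec, config)
}
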