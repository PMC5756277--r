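# Canonical religion-empathy network: the mirror-neuron / ownership-state
# architecture duplicated over an empathic (1) and dis-empathic (2) valence,
# with shared goal machinery and four adaptive God-image connections per
# valence.

# Combination-function parameters per state role; calibrated once for the
# canonical model and frozen (see the methods vignette for rationale).
.ROLE_PARAMS <- data.frame(
  role      = c("world", "sensor", "sensory_representation",
                "body_representation", "preparation", "ownership",
                "execution", "feeling", "goal", "goal_fulfilment"),
  steepness = c(5,  8,  5,  5,  3,  5,  20,  5,  10,  6),
  threshold = c(0.3, 0.55, 1.05, 0.35, 0.95, 1.4, 1.6, 0.3, 0.35, 1.4)
)

# Default weight per edge role: sensing / internal / effector / inhibiting.
.ROLE_WEIGHTS <- c(sensing = 0.8, internal = 0.7, effector = 0.55,
                   inhibiting = -0.4)

.ADAPTIVE_W0 <- 0.5

# One valence's edges: label stem, source stem, target stem, edge role, and
# mechanism tags used by the scenario profiles. State stems get the valence
# suffix appended unless the state is shared (gs, gfs).
.EDGE_TABLE <- local({
  e <- function(label, source, target, role, mech = "")
    data.frame(label = label, source = source, target = target,
               role = role, mech = mech)
  rbind(
    e("w1",   "ws_god_action",  "ss_god_action",  "sensing",  "god_image_edge"),
    e("w2",   "ws_god_image",   "ss_god_image",   "sensing",  "god_image_edge"),
    e("w3",   "ws_god_emotion", "ss_god_emotion", "sensing",  "god_image_edge"),
    e("w4",   "ws_prayer",      "ss_prayer",      "sensing",  "religious_source"),
    e("w5",   "ws_emotion",     "ss_emotion",     "sensing",  "body_loop"),
    e("w6",   "ss_emotion",     "srs_emotion",    "sensing",  "body_loop"),
    e("w7a",  "ss_god_action",  "srs_god_action", "sensing",  "god_image_edge"),
    e("w7b",  "srs_god_image",  "srs_god_action", "adaptive", "god_image_edge"),
    e("w7c",  "srs_god_emotion","srs_god_action", "adaptive", "god_image_edge"),
    e("w7d",  "ps_prayer",      "srs_god_action", "internal", "god_image_edge prayer_internal"),
    e("w8a",  "ss_god_image",   "srs_god_image",  "sensing",  "god_image_edge"),
    e("w8b",  "ss_prayer",      "srs_god_image",  "sensing",  "god_image_edge"),
    e("w8c",  "ps_prayer",      "srs_god_image",  "internal", "god_image_edge prayer_internal"),
    e("w9a",  "ss_god_emotion", "srs_god_emotion","sensing",  "god_image_edge"),
    e("w9b",  "srs_god_image",  "srs_god_emotion","adaptive", "god_image_edge"),
    e("w9c",  "srs_god_action", "srs_god_emotion","adaptive", "god_image_edge"),
    e("w9d",  "ps_prayer",      "srs_god_emotion","internal", "god_image_edge prayer_internal"),
    e("w10",  "ps_behaviour",   "srs_effect",     "internal", "as_if"),
    e("w11a", "os_self_action", "ps_behaviour",   "internal", "self_ownership_path"),
    e("w11b", "os_god_action",  "ps_behaviour",   "internal", "god_ownership_path"),
    e("w11c", "srs_god_action", "ps_behaviour",   "internal", "mirroring"),
    e("w11d", "fs_emotion",     "ps_behaviour",   "internal", ""),
    e("w11e", "gs",             "ps_behaviour",   "internal", "goal_drive"),
    e("w12a", "os_self_emotion","ps_emotion",     "internal", "self_ownership_path"),
    e("w12b", "os_god_emotion", "ps_emotion",     "internal", "god_ownership_path"),
    e("w12c", "srs_god_emotion","ps_emotion",     "internal", "mirroring"),
    e("w12d", "srs_effect",     "ps_emotion",     "internal", ""),
    e("w12e", "fs_emotion",     "ps_emotion",     "internal", ""),
    e("w12f", "gs",             "ps_emotion",     "internal", "goal_drive"),
    e("w13a", "srs_god_image",  "ps_prayer",      "internal", "mirroring"),
    e("w13b", "srs_god_emotion","ps_prayer",      "internal", "mirroring"),
    e("w13c", "srs_god_action", "ps_prayer",      "internal", "mirroring"),
    e("w13d", "gs",             "ps_prayer",      "internal", "goal_drive"),
    e("w15a", "srs_god_action", "gfs",            "internal", "goal_drive"),
    e("w15b", "srs_god_image",  "gfs",            "internal", "goal_drive"),
    e("w15c", "srs_god_emotion","gfs",            "internal", "goal_drive"),
    e("w16a", "ps_emotion",     "srs_emotion",    "internal", "as_if"),
    e("w16b", "srs_emotion",    "fs_emotion",     "internal", "body_loop"),
    e("w17a", "srs_god_action", "os_self_action", "internal", "self_ownership_path"),
    e("w17b", "srs_effect",     "os_self_action", "internal", "self_ownership_path"),
    e("w17c", "fs_emotion",     "os_self_action", "internal", "self_ownership_path"),
    e("w18a", "srs_god_action", "os_god_action",  "internal", "god_ownership_path"),
    e("w18b", "srs_god_image",  "os_god_action",  "internal", "god_ownership_path"),
    e("w19a", "srs_god_emotion","os_self_emotion","internal", "self_ownership_path"),
    e("w19b", "srs_effect",     "os_self_emotion","internal", "self_ownership_path"),
    e("w20a", "srs_god_image",  "os_god_emotion", "internal", "god_ownership_path"),
    e("w20b", "srs_god_emotion","os_god_emotion", "internal", "god_ownership_path"),
    e("w21a", "os_god_action",  "es_behaviour",   "effector", "god_ownership_path"),
    e("w21b", "os_self_action", "es_behaviour",   "effector", "self_ownership_path"),
    e("w21c", "ps_behaviour",   "es_behaviour",   "effector", "prep_exec"),
    e("w22a", "os_self_emotion","es_emotion",     "effector", "self_ownership_path"),
    e("w22b", "os_god_emotion", "es_emotion",     "effector", "god_ownership_path"),
    e("w22c", "ps_emotion",     "es_emotion",     "effector", "prep_exec"),
    e("w23",  "ps_prayer",      "es_prayer",      "effector", "prep_exec"),
    e("w24",  "es_prayer",      "ws_prayer",      "effector", "world_feedback"),
    e("w25",  "es_emotion",     "ws_emotion",     "effector", "world_feedback")
  )
})

# Shared goal-machinery edges (between shared states only).
.SHARED_EDGES <- data.frame(
  label  = c("w14a", "w14b"),
  source = c("gfs", "gs"),
  target = c("gs", "gs"),
  role   = c("inhibiting", "internal"),
  mech   = c("goal_inhibition", "goal_self")
)

# State stems per valence with their roles; gs/gfs are shared across valences.
.STATE_TABLE <- data.frame(
  stem = c("ws_god_action", "ws_god_image", "ws_god_emotion", "ws_prayer",
           "ws_emotion",
           "ss_god_action", "ss_god_image", "ss_god_emotion", "ss_prayer",
           "ss_emotion",
           "srs_god_image", "srs_god_action", "srs_god_emotion", "srs_emotion",
           "srs_effect",
           "ps_behaviour", "ps_emotion", "ps_prayer",
           "os_god_action", "os_self_action", "os_god_emotion",
           "os_self_emotion",
           "es_behaviour", "es_emotion", "es_prayer",
           "fs_emotion"),
  role = c(rep("world", 5), rep("sensor", 5),
           rep("sensory_representation", 3), rep("body_representation", 2),
           rep("preparation", 3),
           rep("ownership", 4), rep("execution", 3), "feeling")
)

.SHARED_STATES <- data.frame(stem = c("gs", "gfs"),
                             role = c("goal", "goal_fulfilment"))

# World stimuli without inbound connections; clamped at their stimulus level.
.STIMULUS_STEMS <- c("ws_god_action", "ws_god_image", "ws_god_emotion")

.vname <- function(stem, valence) {
  ifelse(stem %in% .SHARED_STATES$stem, stem, paste0(stem, "_", valence))
}

#' Build the canonical religion-empathy network
#'
#' Constructs the full two-valence model: for each valence (1 = empathic,
#' 2 = dis-empathic) five world states, five sensor states, five sensory
#' representations (general God-image, God's action, God's emotion, own
#' emotion, predicted effect), three preparation states (behaviour, emotion,
#' prayer), four ownership states (God/Self x action/emotion), three
#' execution states and one feeling state; plus a shared goal state `gs`
#' (initially 1) and goal-fulfilment state `gfs`. The four God-image
#' connections per valence (general image to action representation, general
#' image to emotion representation, and action/emotion representations to
#' each other) adapt by Hebbian learning. Goal fulfilment inhibits the goal
#' state (weight -0.4). Default weights are the neutral profile (sensing 0.8,
#' internal 0.7, effector 0.55); default stimulus level for the three
#' God-related world states is 1.
#'
#' @return A `religion_model`: list with `spec` (a [network_spec()]),
#'   `role_index` (data frame `name`, `role`, `valence`), `edge_info`
#'   (per-edge label/role/mechanism metadata) and `adaptive_labels`.
#' @export
build_religion_network <- function() {
  states <- list()
  for (v in 1:2) {
    for (i in seq_len(nrow(.STATE_TABLE))) {
      stem <- .STATE_TABLE$stem[i]
      role <- .STATE_TABLE$role[i]
      p <- .ROLE_PARAMS[.ROLE_PARAMS$role == role, ]
      init <- if (stem %in% .STIMULUS_STEMS) 1 else 0
      states[[length(states) + 1L]] <- state_spec(
        name = paste0(stem, "_", v), initial_value = init,
        speed_factor = 0.17, steepness = p$steepness, threshold = p$threshold,
        clamped = stem %in% .STIMULUS_STEMS)
    }
  }
  for (i in seq_len(nrow(.SHARED_STATES))) {
    role <- .SHARED_STATES$role[i]
    p <- .ROLE_PARAMS[.ROLE_PARAMS$role == role, ]
    states[[length(states) + 1L]] <- state_spec(
      name = .SHARED_STATES$stem[i],
      initial_value = if (role == "goal") 1 else 0,
      speed_factor = 0.17, steepness = p$steepness, threshold = p$threshold)
  }

  conns <- list()
  edge_info <- list()
  hebb <- list()
  for (v in 1:2) {
    for (i in seq_len(nrow(.EDGE_TABLE))) {
      row <- .EDGE_TABLE[i, ]
      adaptive <- row$role == "adaptive"
      lab <- paste0(row$label, ".", v)
      w <- if (adaptive) .ADAPTIVE_W0 else .ROLE_WEIGHTS[[row$role]]
      conns[[length(conns) + 1L]] <- connection_spec(
        source = .vname(row$source, v), target = .vname(row$target, v),
        weight = w, label = lab, adaptive = adaptive)
      edge_info[[length(edge_info) + 1L]] <- data.frame(
        label = lab, stem = row$label, valence = v,
        role = if (adaptive) "internal" else row$role, mech = row$mech,
        adaptive = adaptive)
      if (adaptive) hebb[[lab]] <- hebbian_params(0.5, 0.5)
    }
  }
  for (i in seq_len(nrow(.SHARED_EDGES))) {
    row <- .SHARED_EDGES[i, ]
    conns[[length(conns) + 1L]] <- connection_spec(
      source = row$source, target = row$target,
      weight = .ROLE_WEIGHTS[[row$role]], label = row$label, adaptive = FALSE)
    edge_info[[length(edge_info) + 1L]] <- data.frame(
      label = row$label, stem = row$label, valence = NA_integer_,
      role = row$role, mech = row$mech, adaptive = FALSE)
  }

  spec <- network_spec(states, conns, hebb)
  role_index <- rbind(
    do.call(rbind, lapply(1:2, function(v)
      data.frame(name = paste0(.STATE_TABLE$stem, "_", v),
                 role = .STATE_TABLE$role, valence = v))),
    data.frame(name = .SHARED_STATES$stem, role = .SHARED_STATES$role,
               valence = NA_integer_))
  out <- list(spec = spec,
              role_index = role_index,
              edge_info = do.call(rbind, edge_info),
              adaptive_labels = names(hebb))
  class(out) <- "religion_model"
  out
}

#' @export
print.religion_model <- function(x, ...) {
  cat("<religion_model> ", nrow(x$spec$states), " states, ",
      nrow(x$spec$connections), " connections (",
      length(x$adaptive_labels), " adaptive)\n", sep = "")
  invisible(x)
}

#' Apply a scenario profile to a model instance
#'
#' Overrides weights (by label), stimulus levels (clamped world states),
#' state initial values, combination-function parameters and Hebbian rates.
#' Weight-override keys may carry a valence suffix (`"w11c.1"`) or not
#' (`"w11c"`, applied to both valences). Overriding an adaptive connection's
#' weight sets its initial weight.
#'
#' @param instance A `religion_model` from [build_religion_network()].
#' @param profile A [scenario_profile()].
#' @return A new `religion_model` with overrides applied; unlisted parameters
#'   keep their canonical values.
#' @export
apply_parameter_profile <- function(instance, profile) {
  stopifnot(inherits(instance, "religion_model"),
            inherits(profile, "scenario_profile"))
  spec <- instance$spec
  labs <- spec$connections$label
  for (key in names(profile$weight_overrides)) {
    val <- profile$weight_overrides[[key]]
    hit <- if (grepl("\\.", key)) labs == key
           else labs == key | labs %in% paste0(key, c(".1", ".2"))
    if (!any(hit)) stop("unknown weight label: ", key, call. = FALSE)
    spec$connections$weight[hit] <- val
  }
  all_states <- spec$states$name
  for (key in names(profile$stimulus_levels)) {
    if (!key %in% all_states) stop("unknown world state: ", key, call. = FALSE)
    spec$states$initial_value[all_states == key] <- profile$stimulus_levels[[key]]
  }
  for (key in names(profile$initial_values)) {
    if (!key %in% all_states) stop("unknown state: ", key, call. = FALSE)
    spec$states$initial_value[all_states == key] <- profile$initial_values[[key]]
  }
  for (key in names(profile$state_params)) {
    if (!key %in% all_states) stop("unknown state: ", key, call. = FALSE)
    p <- profile$state_params[[key]]
    i <- which(all_states == key)
    if (!is.null(p$steepness)) spec$states$steepness[i] <- p$steepness
    if (!is.null(p$threshold)) spec$states$threshold[i] <- p$threshold
    if (!is.null(p$speed_factor)) spec$states$speed_factor[i] <- p$speed_factor
  }
  for (key in names(profile$hebbian_overrides)) {
    if (!key %in% names(spec$hebbian))
      stop("unknown adaptive label: ", key, call. = FALSE)
    h <- profile$hebbian_overrides[[key]]
    for (f in intersect(names(h), c("learning_rate", "extinction_rate",
                                    "initial_weight")))
      spec$hebbian[[key]][[f]] <- h[[f]]
  }
  instance$spec <- spec
  instance
}

.swap_valence_key <- function(keys) {
  swapped <- keys
  swapped <- sub("\\.1$", ".SWAPTMP", swapped)
  swapped <- sub("\\.2$", ".1", swapped)
  swapped <- sub("\\.SWAPTMP$", ".2", swapped)
  swapped <- sub("_1$", "_SWAPTMP", swapped)
  swapped <- sub("_2$", "_1", swapped)
  swapped <- sub("_SWAPTMP$", "_2", swapped)
  swapped
}

#' Exchange the empathic and dis-empathic valences of a profile
#'
#' Every valence-annotated override key (suffix `.1`/`.2` for weight labels,
#' `_1`/`_2` for state names) is mapped to its opposite-valence twin; keys
#' without a valence annotation are left alone. Applying the swapped profile
#' yields trajectories that are the exact mirror image of the original's.
#'
#' @param profile A [scenario_profile()].
#' @return The valence-swapped profile.
#' @export
valence_swap <- function(profile) {
  stopifnot(inherits(profile, "scenario_profile"))
  swap_names <- function(x) {
    if (length(x)) names(x) <- .swap_valence_key(names(x))
    x
  }
  profile$weight_overrides <- swap_names(profile$weight_overrides)
  profile$stimulus_levels <- swap_names(profile$stimulus_levels)
  profile$initial_values <- swap_names(profile$initial_values)
  profile$state_params <- swap_names(profile$state_params)
  profile$hebbian_overrides <- swap_names(profile$hebbian_overrides)
  profile
}

#' Pairing of empathic and dis-empathic states
#'
#' @param instance A `religion_model`; defaults to the canonical network.
#' @return Named character vector mapping every valence-1 state to its
#'   valence-2 twin.
#' @export
valence_pairing <- function(instance = build_religion_network()) {
  v1 <- instance$role_index$name[instance$role_index$valence %in% 1]
  stats::setNames(sub("_1$", "_2", v1), v1)
}
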