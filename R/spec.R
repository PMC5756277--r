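# Declarative network specification: states, connections, Hebbian parameters.

#' Declare a state of a temporal-causal network
#'
#' @param name State identifier.
#' @param initial_value Activation at t = 0, in \[0,1\].
#' @param speed_factor Speed factor \eqn{\eta_Y \ge 0} per unit model time.
#' @param steepness Combination-function steepness \eqn{\sigma > 0}.
#' @param threshold Combination-function threshold \eqn{\tau}.
#' @param clamped If `TRUE` the state holds its initial value for the whole
#'   run, ignoring inbound impact (used for external world stimuli). States
#'   without inbound connections are implicitly clamped.
#' @return A `state_spec` list.
#' @export
state_spec <- function(name, initial_value = 0, speed_factor = 0.17,
                       steepness = 5, threshold = 0.5, clamped = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  out <- list(name = name, initial_value = as.numeric(initial_value),
              speed_factor = as.numeric(speed_factor),
              steepness = as.numeric(steepness),
              threshold = as.numeric(threshold), clamped = isTRUE(clamped))
  class(out) <- "state_spec"
  out
}

#' Declare a directed weighted connection
#'
#' @param source,target State identifiers.
#' @param weight Connection weight \eqn{\omega_{X,Y}}; normally in \[0,1\],
#'   negative for inhibiting connections. For an adaptive connection this is
#'   the initial weight \eqn{\omega(0) \in [0,1]}.
#' @param label Weight label used by scenario overrides (e.g. `"w13a.1"`).
#' @param adaptive If `TRUE` the weight evolves by Hebbian learning and must
#'   have [hebbian_params()] registered under its label.
#' @return A `connection_spec` list.
#' @export
connection_spec <- function(source, target, weight, label = NA_character_,
                            adaptive = FALSE) {
  out <- list(source = source, target = target, weight = as.numeric(weight),
              label = as.character(label), adaptive = isTRUE(adaptive))
  class(out) <- "connection_spec"
  out
}

#' Hebbian learning parameters for one adaptive connection
#'
#' @param learning_rate \eqn{\eta_H > 0}.
#' @param extinction_rate \eqn{\zeta_H \ge 0}.
#' @param initial_weight Optional \eqn{\omega(0) \in [0,1]}; when given it
#'   overrides the connection's declared weight at the start of a run.
#' @return A `hebbian_params` list.
#' @export
hebbian_params <- function(learning_rate = 0.5, extinction_rate = 0.5,
                           initial_weight = NULL) {
  out <- list(learning_rate = as.numeric(learning_rate),
              extinction_rate = as.numeric(extinction_rate),
              initial_weight = if (is.null(initial_weight)) NULL
                               else as.numeric(initial_weight))
  class(out) <- "hebbian_params"
  out
}

#' Assemble a network specification
#'
#' Bundles states, connections and Hebbian parameters into the declarative
#' model a run operates on. States and connections are stored as data frames
#' (one row each), `hebbian` as a list keyed by adaptive-connection label.
#'
#' @param states List of [state_spec()] objects (or an equivalent data frame).
#' @param connections List of [connection_spec()] objects (or a data frame).
#' @param hebbian Named list of [hebbian_params()], keyed by the labels of the
#'   adaptive connections.
#' @return A `network_spec` object.
#' @seealso [validate_spec()], [simulate_network()]
#' @export
network_spec <- function(states, connections, hebbian = list()) {
  if (is.data.frame(states)) {
    st <- states
  } else {
    st <- do.call(rbind, lapply(states, function(s)
      data.frame(name = s$name, initial_value = s$initial_value,
                 speed_factor = s$speed_factor, steepness = s$steepness,
                 threshold = s$threshold, clamped = s$clamped)))
  }
  if (is.data.frame(connections)) {
    cn <- connections
  } else {
    cn <- do.call(rbind, lapply(connections, function(cc)
      data.frame(source = cc$source, target = cc$target, weight = cc$weight,
                 label = cc$label, adaptive = cc$adaptive)))
  }
  rownames(st) <- NULL
  rownames(cn) <- NULL
  out <- list(states = st, connections = cn, hebbian = hebbian)
  class(out) <- "network_spec"
  out
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> ", nrow(x$states), " states, ",
      nrow(x$connections), " connections (",
      sum(x$connections$adaptive), " adaptive)\n", sep = "")
  diag <- validate_spec(x)
  if (nrow(diag)) {
    cat("  ", sum(diag$severity == "error"), " validation error(s), ",
        sum(diag$severity == "warning"), " warning(s)\n", sep = "")
  }
  invisible(x)
}

.diag <- function(severity, element, message) {
  data.frame(severity = severity, element = element, message = message)
}

#' Validate a network specification
#'
#' Checks structural well-formedness: declared endpoints, unique names and
#' edges, parameter ranges, and Hebbian parameters for every adaptive
#' connection. Problems are returned as diagnostics, not raised.
#'
#' @param spec A [network_spec()].
#' @return A data frame with columns `severity` (`"error"`/`"warning"`),
#'   `element` (offending state/connection) and `message`; zero rows iff the
#'   spec is well-formed.
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  st <- spec$states
  cn <- spec$connections
  d <- list()
  dup <- unique(st$name[duplicated(st$name)])
  for (nm in dup) d[[length(d) + 1L]] <- .diag("error", nm, "duplicate state name")
  bad <- st$name[st$initial_value < 0 | st$initial_value > 1]
  for (nm in bad) d[[length(d) + 1L]] <- .diag("error", nm, "initial_value outside [0,1]")
  bad <- st$name[st$steepness <= 0]
  for (nm in bad) d[[length(d) + 1L]] <- .diag("error", nm, "steepness must be > 0")
  bad <- st$name[st$speed_factor < 0]
  for (nm in bad) d[[length(d) + 1L]] <- .diag("error", nm, "speed_factor must be >= 0")
  if (nrow(cn)) {
    key <- paste(cn$source, cn$target, sep = " -> ")
    for (k in unique(key[duplicated(key)]))
      d[[length(d) + 1L]] <- .diag("error", k, "duplicate connection")
    for (s in setdiff(cn$source, st$name))
      d[[length(d) + 1L]] <- .diag("error", s, "connection source not a declared state")
    for (s in setdiff(cn$target, st$name))
      d[[length(d) + 1L]] <- .diag("error", s, "connection target not a declared state")
    ad <- cn[cn$adaptive, , drop = FALSE]
    if (nrow(ad)) {
      for (i in seq_len(nrow(ad))) {
        lab <- ad$label[i]
        hp <- spec$hebbian[[lab]]
        el <- paste(ad$source[i], "->", ad$target[i])
        if (is.na(lab) || is.null(hp)) {
          d[[length(d) + 1L]] <- .diag("error", el,
                                       "adaptive connection lacks hebbian params")
        } else {
          if (hp$learning_rate <= 0)
            d[[length(d) + 1L]] <- .diag("error", lab, "learning_rate must be > 0")
          if (hp$extinction_rate < 0)
            d[[length(d) + 1L]] <- .diag("error", lab, "extinction_rate must be >= 0")
          w0 <- if (!is.null(hp$initial_weight)) hp$initial_weight else ad$weight[i]
          if (w0 < 0 || w0 > 1)
            d[[length(d) + 1L]] <- .diag("error", lab,
                                         "adaptive initial weight outside [0,1]")
        }
      }
    }
  }
  if (length(d)) do.call(rbind, d) else
    data.frame(severity = character(), element = character(),
               message = character())
}
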