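# Trajectory feature extraction: peaks, onsets, equilibria, mirror symmetry.

.traj_series <- function(trajectory, state) {
  stopifnot(inherits(trajectory, "trajectory"))
  cols <- colnames(trajectory$activations)
  if (!state %in% cols) stop("unknown state: ", state, call. = FALSE)
  trajectory$activations[, state]
}

#' Peak activation of a state
#'
#' @param trajectory A `trajectory`.
#' @param state State name.
#' @return List with `peak_value` (maximum over all recorded times) and
#'   `peak_time` (earliest time attaining it).
#' @export
peak_activation <- function(trajectory, state) {
  y <- .traj_series(trajectory, state)
  i <- which.max(y)
  list(peak_value = y[i], peak_time = trajectory$times[i])
}

#' Onset time of a state
#'
#' First recorded time at which the activation reaches `threshold`.
#'
#' @param trajectory A `trajectory`.
#' @param state State name.
#' @param threshold Onset level in (0,1); default 0.05.
#' @return The onset time, or `NA` if the threshold is never reached.
#' @export
onset_time <- function(trajectory, state, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  y <- .traj_series(trajectory, state)
  i <- which(y >= threshold)
  if (!length(i)) NA_real_ else trajectory$times[i[1L]]
}

#' Equilibrium time and value of a state
#'
#' Earliest recorded time after which the activation stays within `eq_tol`
#' of its final value for the rest of the run; the equilibrium value is the
#' final value by construction.
#'
#' @param trajectory A `trajectory`.
#' @param state State name.
#' @param eq_tol Equilibrium band half-width; default 0.01.
#' @return List with `time` and `value`, or `NULL` when even the final point
#'   alone does not qualify (cannot happen with `eq_tol > 0`).
#' @export
equilibrium <- function(trajectory, state, eq_tol = 0.01) {
  stopifnot(eq_tol > 0)
  y <- .traj_series(trajectory, state)
  final <- y[length(y)]
  dev <- abs(y - final) <= eq_tol
  # last index before which some point still leaves the band
  out_of_band <- which(!dev)
  first <- if (!length(out_of_band)) 1L else max(out_of_band) + 1L
  list(time = trajectory$times[first], value = final)
}

#' Maximum mirror asymmetry between two trajectories
#'
#' Maximum absolute activation difference, over time and state pairs, between
#' trajectory `a` at the pairing's names and trajectory `b` at its values
#' (e.g. empathic states paired with their dis-empathic twins).
#'
#' @param traj_a,traj_b `trajectory` objects sharing the same time grid.
#' @param pairing Named character vector: names are states of `traj_a`,
#'   values the corresponding states of `traj_b`.
#' @return The maximum absolute difference.
#' @export
mirror_asymmetry <- function(traj_a, traj_b, pairing) {
  if (length(traj_a$times) != length(traj_b$times) ||
      any(traj_a$times != traj_b$times)) {
    stop("trajectories are on different time grids", call. = FALSE)
  }
  a <- traj_a$activations[, names(pairing), drop = FALSE]
  b <- traj_b$activations[, unname(pairing), drop = FALSE]
  max(abs(a - b))
}

#' Per-state feature report
#'
#' Aggregates [peak_activation()], [onset_time()] and [equilibrium()] for
#' every recorded state.
#'
#' @param trajectory A `trajectory`.
#' @param onset_threshold Onset level; default 0.05.
#' @param eq_tol Equilibrium band; default 0.01.
#' @return A `feature_report`: data frame with one row per state and columns
#'   `state`, `onset_time`, `peak_value`, `peak_time`, `equilibrium_time`,
#'   `final_value`.
#' @export
feature_report <- function(trajectory, onset_threshold = 0.05, eq_tol = 0.01) {
  states <- colnames(trajectory$activations)
  rows <- lapply(states, function(s) {
    pk <- peak_activation(trajectory, s)
    eq <- equilibrium(trajectory, s, eq_tol)
    data.frame(state = s,
               onset_time = onset_time(trajectory, s, onset_threshold),
               peak_value = pk$peak_value, peak_time = pk$peak_time,
               equilibrium_time = eq$time, final_value = eq$value)
  })
  out <- do.call(rbind, rows)
  attr(out, "onset_threshold") <- onset_threshold
  attr(out, "eq_tol") <- eq_tol
  class(out) <- c("feature_report", class(out))
  out
}
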