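# Random small-network generator used by the engine-oracle property tests.

#' Generate a random small network specification
#'
#' Deterministic in `seed`. States get random initial values, steepness in
#' (0.5, 10], threshold in \[0, 2\] and a common speed factor; each ordered
#' state pair receives a connection with probability `density`, with weight
#' drawn from \[-1, 1\] (negative weights exercise the 0-clipping of the
#' combination function). Each connection independently becomes adaptive with
#' probability `density / 2`, with weight redrawn from \[0, 1\] and random
#' Hebbian rates.
#'
#' @param seed Integer seed.
#' @param n_states Number of states (>= 2).
#' @param density Connection probability in (0, 1].
#' @return A valid [network_spec()].
#' @export
generate_fixture_network <- function(seed, n_states = 5, density = 0.5) {
  stopifnot(n_states >= 2, density > 0, density <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nms <- paste0("s", seq_len(n_states))
  states <- lapply(nms, function(nm)
    state_spec(nm, initial_value = stats::runif(1),
               speed_factor = stats::runif(1, 0.05, 0.5),
               steepness = stats::runif(1, 0.5, 10),
               threshold = stats::runif(1, 0, 2)))
  conns <- list()
  hebb <- list()
  k <- 0L
  for (s in nms) for (t in nms) {
    if (stats::runif(1) > density) next
    k <- k + 1L
    lab <- paste0("e", k)
    adaptive <- stats::runif(1) < density / 2
    w <- if (adaptive) stats::runif(1) else stats::runif(1, -1, 1)
    conns[[length(conns) + 1L]] <-
      connection_spec(s, t, w, label = lab, adaptive = adaptive)
    if (adaptive) {
      hebb[[lab]] <- hebbian_params(learning_rate = stats::runif(1, 0.1, 1),
                                    extinction_rate = stats::runif(1, 0, 1))
    }
  }
  if (!length(conns)) {
    conns[[1L]] <- connection_spec(nms[1L], nms[2L],
                                   stats::runif(1, -1, 1), label = "e1")
  }
  network_spec(states, conns, hebb)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
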