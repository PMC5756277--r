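# Synchronous Euler engine for adaptive temporal-causal networks.

#' Simulation settings
#'
#' @param dt Time step \eqn{\Delta t > 0} in model-time units.
#' @param n_steps Number of Euler steps (the trajectory has `n_steps + 1`
#'   rows including t = 0).
#' @param record_weights Record adaptive-connection weights alongside state
#'   activations.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(dt = 0.25, n_steps = 500, record_weights = TRUE) {
  stopifnot(dt > 0, n_steps >= 1)
  out <- list(dt = as.numeric(dt), n_steps = as.integer(n_steps),
              record_weights = isTRUE(record_weights))
  class(out) <- "simulation_config"
  out
}

#' Simulate an adaptive temporal-causal network
#'
#' Advances all states and adaptive weights synchronously: at each step every
#' aggregated impact and every Hebbian increment is computed from the time-t
#' values, then states and weights move together. Clamped states and states
#' without inbound connections stay at their initial value.
#'
#' @param spec A [network_spec()]; must pass [validate_spec()] without errors.
#' @param config A [simulation_config()].
#' @return A `trajectory` object: list with `times` (length `n_steps + 1`),
#'   `activations` (time x state matrix, named columns), and `weights`
#'   (time x adaptive-label matrix, `NULL` unless recorded).
#' @export
simulate_network <- function(spec, config = simulation_config()) {
  diag <- validate_spec(spec)
  if (any(diag$severity == "error")) {
    stop("invalid network spec:\n",
         paste0("  ", diag$element, ": ", diag$message, collapse = "\n"),
         call. = FALSE)
  }
  st <- spec$states
  cn <- spec$connections
  n <- nrow(st)
  idx <- stats::setNames(seq_len(n), st$name)

  W <- matrix(0, n, n, dimnames = list(st$name, st$name))
  if (nrow(cn)) {
    W[cbind(idx[cn$source], idx[cn$target])] <- cn$weight
  }
  has_inbound <- st$name %in% cn$target
  active <- !st$clamped & has_inbound
  eta_dt <- st$speed_factor * config$dt
  if (any(eta_dt[active] > 1)) {
    warning("speed_factor * dt > 1 for some states: overshoot possible",
            call. = FALSE)
  }
  sigma <- st$steepness
  tau <- st$threshold

  ad <- cn[cn$adaptive, , drop = FALSE]
  n_ad <- nrow(ad)
  if (n_ad) {
    ad_cells <- cbind(idx[ad$source], idx[ad$target])
    hp <- lapply(ad$label, function(l) spec$hebbian[[l]])
    eta_h <- vapply(hp, `[[`, numeric(1), "learning_rate")
    zeta_h <- vapply(hp, `[[`, numeric(1), "extinction_rate")
    w0 <- vapply(seq_len(n_ad), function(i) {
      iw <- hp[[i]]$initial_weight
      if (!is.null(iw)) iw else ad$weight[i]
    }, numeric(1))
    W[ad_cells] <- w0
  }

  n_rec <- config$n_steps + 1L
  acts <- matrix(NA_real_, n_rec, n, dimnames = list(NULL, st$name))
  wts <- if (config$record_weights && n_ad)
    matrix(NA_real_, n_rec, n_ad, dimnames = list(NULL, ad$label)) else NULL

  y <- st$initial_value
  acts[1L, ] <- y
  if (!is.null(wts)) wts[1L, ] <- W[ad_cells]

  for (k in seq_len(config$n_steps)) {
    agg <- alogistic_sum(as.vector(crossprod(W, y)), sigma, tau)
    y_new <- y
    y_new[active] <- y[active] + eta_dt[active] * (agg[active] - y[active])
    if (n_ad) {
      w_cur <- W[ad_cells]
      W[ad_cells] <- w_cur +
        (eta_h * y[ad_cells[, 1L]] * y[ad_cells[, 2L]] * (1 - w_cur) -
           zeta_h * w_cur) * config$dt
    }
    y <- y_new
    acts[k + 1L, ] <- y
    if (!is.null(wts)) wts[k + 1L, ] <- W[ad_cells]
  }

  out <- list(times = seq(0, by = config$dt, length.out = n_rec),
              activations = acts, weights = wts,
              dt = config$dt, state_names = st$name,
              adaptive_labels = if (n_ad) ad$label else character())
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points (t = 0 ... ",
      format(x$times[length(x$times)]), "), ",
      ncol(x$activations), " states",
      if (!is.null(x$weights)) paste0(", ", ncol(x$weights),
                                      " adaptive weights"),
      "\n", sep = "")
  invisible(x)
}

#' Plot state trajectories
#'
#' @param x A `trajectory`.
#' @param states Character vector of states to draw (default all).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.trajectory <- function(x, states = NULL, ...) {
  a <- x$activations
  if (!is.null(states)) a <- a[, states, drop = FALSE]
  graphics::matplot(x$times, a, type = "l", lty = 1, xlab = "model time t",
                    ylab = "activation", ylim = c(0, 1), ...)
  invisible(x)
}
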