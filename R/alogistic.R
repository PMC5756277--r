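# Advanced logistic sum combination function and elementary update steps.

# Largest double strictly below 1; alogistic() never returns more than this,
# so the mathematical property sup < 1 survives rounding at large sigma.
.ALOG_SUP <- 1 - .Machine$double.eps / 2

#' Advanced logistic sum combination function
#'
#' Aggregates a set of (already weighted) causal impacts into a single target
#' activation:
#' \deqn{\mathrm{alogistic}_{\sigma,\tau}(V_1,\dots,V_k) =
#'   \left(\frac{1}{1+e^{-\sigma(\sum_i V_i-\tau)}} -
#'         \frac{1}{1+e^{\sigma\tau}}\right)(1+e^{-\sigma\tau})}
#' Negative values of the expression are clipped to exactly 0, so an all-zero
#' input maps to exactly 0; the supremum of the function is 1 and is never
#' attained (the return value is capped at the largest double below 1).
#'
#' @param values Numeric vector of weighted impacts \eqn{V_1,\dots,V_k}.
#' @param steepness Steepness \eqn{\sigma > 0}.
#' @param threshold Threshold \eqn{\tau} (any real).
#' @return A single activation in \eqn{[0, 1)}.
#' @examples
#' alogistic(c(0, 0, 0), 5, 0.5)   # exactly 0
#' alogistic(1, 5, 0.5)            # 0.9179150...
#' @export
alogistic <- function(values, steepness, threshold) {
  if (!is.numeric(steepness) || length(steepness) != 1L || steepness <= 0) {
    stop("`steepness` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(values)) {
    stop("`values` must be numeric", call. = FALSE)
  }
  alogistic_sum(sum(values), steepness, threshold)
}

# Vectorised over pre-summed impacts; the engine's inner kernel.
# Computed in the direct two-term form so that sum == 0 returns exactly 0
# (both logistic terms are then the identical expression).
alogistic_sum <- function(sums, steepness, threshold) {
  lhs <- 1 / (1 + exp(-steepness * (sums - threshold)))
  low <- 1 / (1 + exp(steepness * threshold))
  val <- (lhs - low) * (1 + exp(-steepness * threshold))
  pmin(pmax(val, 0), .ALOG_SUP)
}

#' Aggregated impact on one state
#'
#' Forms the weighted sum of the current source activations over a target's
#' inbound connections and applies the target's combination function.
#'
#' @param target Name of the target state.
#' @param source_activations Named numeric vector of current activations; must
#'   cover every source of the target's inbound connections.
#' @param spec A [network_spec()] (current, possibly adapted, weights are
#'   taken from its connection table).
#' @return The aggregated impact, a value in \eqn{[0, 1)}.
#' @export
aggregate_impact <- function(target, source_activations, spec) {
  stopifnot(inherits(spec, "network_spec"))
  conn <- spec$connections[spec$connections$target == target, , drop = FALSE]
  if (nrow(conn) == 0L) {
    stop("state '", target, "' has no inbound connections; treat it as clamped",
         call. = FALSE)
  }
  missing_src <- setdiff(conn$source, names(source_activations))
  if (length(missing_src)) {
    stop("missing source activations: ", paste(missing_src, collapse = ", "),
         call. = FALSE)
  }
  st <- spec$states[spec$states$name == target, ]
  alogistic(conn$weight * source_activations[conn$source],
            st$steepness, st$threshold)
}

#' Euler update of one state activation
#'
#' \eqn{Y(t+\Delta t) = Y(t) + \eta_Y\,[\mathrm{aggimpact}_Y(t) - Y(t)]\,\Delta t}.
#' For \eqn{\eta_Y \Delta t \le 1} this is a convex interpolation, so the
#' result stays in \eqn{[0,1]} whenever its inputs do.
#'
#' @param current Current activation in \eqn{[0,1]}.
#' @param agg Aggregated impact in \eqn{[0,1)}.
#' @param speed Speed factor \eqn{\eta_Y \ge 0} per unit model time.
#' @param dt Time step \eqn{\Delta t > 0}.
#' @return Updated activation.
#' @export
step_state <- function(current, agg, speed, dt) {
  if (any(speed * dt > 1)) {
    warning("speed * dt > 1: Euler update may overshoot [0,1]", call. = FALSE)
  }
  current + speed * (agg - current) * dt
}

#' Hebbian update of an adaptive connection weight
#'
#' Simultaneity-based Hebbian learning with extinction:
#' \eqn{\omega(t+\Delta t) = \omega(t) + [\eta_H X(t) Y(t) (1-\omega(t)) -
#' \zeta_H \omega(t)]\,\Delta t}. The factor \eqn{1-\omega} keeps the weight
#' below its maximal strength 1; for constant \eqn{X, Y} the weight converges
#' to \eqn{\eta_H X Y / (\eta_H X Y + \zeta_H)}.
#'
#' @param weight Current weight in \eqn{[0,1]}.
#' @param x,y Activations of the connected states, in \eqn{[0,1]}.
#' @param learning_rate \eqn{\eta_H > 0}.
#' @param extinction_rate \eqn{\zeta_H \ge 0}.
#' @param dt Time step \eqn{\Delta t > 0}.
#' @return Updated weight, in \eqn{[0,1]} for \eqn{\eta_H\Delta t \le 1} and
#'   \eqn{\zeta_H\Delta t \le 1}.
#' @export
step_hebbian <- function(weight, x, y, learning_rate, extinction_rate, dt) {
  weight + (learning_rate * x * y * (1 - weight) -
              extinction_rate * weight) * dt
}
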