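# Naive reference implementation of the update equations, written as plain
# per-connection loops, independent of the vectorised engine. Used as the
# oracle in the equivalence property tests.

ref_alogistic <- function(values, sigma, tau) {
  s <- sum(values)
  v <- (1 / (1 + exp(-sigma * (s - tau))) - 1 / (1 + exp(sigma * tau))) *
    (1 + exp(-sigma * tau))
  if (v < 0) v <- 0
  sup <- 1 - .Machine$double.eps / 2
  if (v > sup) v <- sup
  v
}

ref_simulate <- function(spec, config) {
  st <- spec$states
  cn <- spec$connections
  n <- nrow(st)
  y <- stats::setNames(st$initial_value, st$name)
  w <- cn$weight
  for (i in seq_len(nrow(cn))) {
    if (cn$adaptive[i]) {
      hp <- spec$hebbian[[cn$label[i]]]
      if (!is.null(hp$initial_weight)) w[i] <- hp$initial_weight
    }
  }
  ad_idx <- which(cn$adaptive)
  acts <- matrix(NA_real_, config$n_steps + 1L, n,
                 dimnames = list(NULL, st$name))
  wts <- matrix(NA_real_, config$n_steps + 1L, length(ad_idx),
                dimnames = list(NULL, cn$label[ad_idx]))
  acts[1L, ] <- y
  if (length(ad_idx)) wts[1L, ] <- w[ad_idx]
  for (k in seq_len(config$n_steps)) {
    y_new <- y
    for (j in seq_len(n)) {
      inb <- which(cn$target == st$name[j])
      if (!length(inb) || st$clamped[j]) next
      vals <- w[inb] * y[cn$source[inb]]
      agg <- ref_alogistic(vals, st$steepness[j], st$threshold[j])
      y_new[j] <- y[j] + st$speed_factor[j] * (agg - y[j]) * config$dt
    }
    w_new <- w
    for (i in ad_idx) {
      hp <- spec$hebbian[[cn$label[i]]]
      w_new[i] <- w[i] + (hp$learning_rate * y[[cn$source[i]]] *
                            y[[cn$target[i]]] * (1 - w[i]) -
                            hp$extinction_rate * w[i]) * config$dt
    }
    y <- y_new
    w <- w_new
    acts[k + 1L, ] <- y
    if (length(ad_idx)) wts[k + 1L, ] <- w[ad_idx]
  }
  list(activations = acts, weights = wts)
}

# Small two-state spec used across unit tests.
two_state_spec <- function(w = 0.8, eta = 0.17, clamp_first = TRUE) {
  network_spec(
    states = list(
      state_spec("src", initial_value = 1, speed_factor = eta,
                 clamped = clamp_first),
      state_spec("dst", initial_value = 0, speed_factor = eta,
                 steepness = 5, threshold = 0.5)),
    connections = list(connection_spec("src", "dst", w, label = "e1")))
}
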