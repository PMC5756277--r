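test_that("trajectory has the declared shape and time grid", {
  tr <- simulate_network(two_state_spec(), simulation_config(0.25, 40))
  expect_length(tr$times, 41L)
  expect_equal(diff(tr$times), rep(0.25, 40))
  expect_identical(colnames(tr$activations), c("src", "dst"))
})

test_that("zero speed factors freeze every state", {
  spec <- generate_fixture_network(3, n_states = 5, density = 0.6)
  spec$states$speed_factor <- 0
  tr <- simulate_network(spec, simulation_config(0.25, 30))
  for (j in seq_len(ncol(tr$activations))) {
    expect_identical(unname(tr$activations[, j]),
                     rep(spec$states$initial_value[j], 31L))
  }
})

test_that("clamped and inbound-free states hold their initial value", {
  spec <- network_spec(
    states = list(state_spec("stim", initial_value = 0.8),
                  state_spec("held", initial_value = 0.3, clamped = TRUE),
                  state_spec("y")),
    connections = list(connection_spec("stim", "y", 0.9, label = "e1"),
                       connection_spec("y", "held", 0.9, label = "e2")))
  tr <- simulate_network(spec, simulation_config(0.25, 50))
  expect_identical(unname(tr$activations[, "stim"]), rep(0.8, 51L))
  expect_identical(unname(tr$activations[, "held"]), rep(0.3, 51L))
  expect_gt(tr$activations[51L, "y"], 0)
})

test_that("a fully silent network stays identically zero", {
  spec <- generate_fixture_network(9, n_states = 6, density = 0.5)
  spec$states$initial_value <- 0
  spec$hebbian <- lapply(spec$hebbian, function(h) {
    h$initial_weight <- NULL
    h
  })
  tr <- simulate_network(spec, simulation_config(0.25, 40))
  expect_identical(max(abs(tr$activations)), 0)
})

test_that("activations and adaptive weights stay inside [0,1]", {
  for (seed in 1:20) {
    spec <- generate_fixture_network(seed, n_states = sample(3:8, 1),
                                     density = 0.6)
    tr <- simulate_network(spec, simulation_config(0.25, 50))
    expect_gte(min(tr$activations), 0)
    expect_lte(max(tr$activations), 1)
    if (!is.null(tr$weights)) {
      expect_gte(min(tr$weights), 0)
      expect_lte(max(tr$weights), 1)
    }
  }
})

test_that("simulation is deterministic", {
  spec <- generate_fixture_network(13, n_states = 6, density = 0.7)
  a <- simulate_network(spec, simulation_config(0.25, 60))
  b <- simulate_network(spec, simulation_config(0.25, 60))
  expect_identical(a, b)
})

test_that("an invalid spec is rejected before stepping", {
  spec <- network_spec(
    states = list(state_spec("a")),
    connections = list(connection_spec("a", "ghost", 0.5, label = "e1")))
  expect_error(simulate_network(spec), "invalid network spec")
})

test_that("engine matches the naive reference on random networks", {
  for (seed in 101:130) {
    spec <- generate_fixture_network(seed, n_states = sample(3:8, 1),
                                     density = 0.6)
    cfg <- simulation_config(0.25, 50)
    fast <- simulate_network(spec, cfg)
    ref <- ref_simulate(spec, cfg)
    expect_lt(max(abs(fast$activations - ref$activations)), 1e-12)
    if (!is.null(fast$weights) && ncol(ref$weights)) {
      expect_lt(max(abs(fast$weights - ref$weights)), 1e-12)
    }
  }
})

test_that("updates are synchronous: impacts use only time-t values", {
  # In a two-link chain a -> b -> c starting from a = 1, b = c = 0, state c
  # must remain 0 after the first step: b's fresh value may not leak into
  # c's update within the same step (threshold 0 would let any positive
  # impact through).
  spec <- network_spec(
    states = list(state_spec("a", initial_value = 1),
                  state_spec("b", steepness = 5, threshold = 0),
                  state_spec("c", steepness = 5, threshold = 0)),
    connections = list(connection_spec("a", "b", 1, label = "e1"),
                       connection_spec("b", "c", 1, label = "e2")))
  tr <- simulate_network(spec, simulation_config(0.25, 1))
  expect_gt(tr$activations[2L, "b"], 0)
  expect_identical(tr$activations[2L, "c"][[1L]], 0)
})
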