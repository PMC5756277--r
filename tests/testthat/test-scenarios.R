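test_that("the six scenarios are named and unknown names are rejected", {
  expect_length(scenario_names(), 6L)
  expect_error(get_scenario("nonsense"), "valid names")
  expect_error(get_scenario("nonsense"), "neutral")
})

test_that("scenario profiles realise the published parameter choices", {
  # neutral: valence-symmetric medium strengths straight from the defaults
  m <- build_religion_network()
  cn <- m$spec$connections
  for (stem in unique(sub("\\.[12]$", "", grep("\\.", cn$label,
                                               value = TRUE)))) {
    expect_identical(cn$weight[cn$label == paste0(stem, ".1")],
                     cn$weight[cn$label == paste0(stem, ".2")], info = stem)
  }
  expect_setequal(unique(abs(cn$weight)), c(0.8, 0.7, 0.55, 0.5, 0.4))

  emp <- get_scenario("empathic")
  expect_true(all(emp$weight_overrides[grep("\\.1$",
    names(emp$weight_overrides))] == 0.8))
  expect_true(all(emp$weight_overrides[grep("\\.2$",
    names(emp$weight_overrides))] == 0.1))

  asd <- get_scenario("asd")
  expect_identical(unname(asd$weight_overrides[c("w11c.1", "w12c.2",
                                                 "w10.1", "w16a.2")]),
                   c(0.3, 0.3, 0.3, 0.3))
  expect_identical(unname(asd$stimulus_levels["ws_god_action_2"]), 1.0)
  expect_identical(unname(asd$stimulus_levels["ws_god_action_1"]), 0.5)

  ath <- get_scenario("atheist")
  expect_identical(unname(ath$initial_values["gs"]), 0.8)
  expect_identical(unname(ath$weight_overrides[c("w17a.1", "w18a.1")]),
                   c(1.0, 0.3))

  fun <- get_scenario("fundamentalist")
  expect_identical(unname(fun$weight_overrides[c("w21c.1", "w18a.1",
                                                 "w18a.2", "w17a.2")]),
                   c(1.0, 0.8, 0.3, 0.1))
})

test_that("disempathic is exactly the valence swap of empathic", {
  emp <- get_scenario("empathic")
  dis <- get_scenario("disempathic")
  sw <- valence_swap(emp)
  expect_mapequal(as.list(dis$weight_overrides), as.list(sw$weight_overrides))
})

test_that("scenario runs are deterministic", {
  a <- run_scenario("neutral", simulation_config(0.25, 120))
  b <- run_scenario("neutral", simulation_config(0.25, 120))
  expect_identical(a, b)
})

test_that("shipped YAML profiles equal the programmatic ones", {
  for (nm in scenario_names()) {
    path <- system.file("extdata", paste0("scenario_", nm, ".yaml"),
                        package = "tcnet")
    expect_true(nzchar(path), info = nm)
    shipped <- read_scenario(path)
    built <- get_scenario(nm)
    expect_equal(shipped$weight_overrides, built$weight_overrides, info = nm)
    expect_equal(shipped$stimulus_levels, built$stimulus_levels, info = nm)
    expect_equal(shipped$initial_values, built$initial_values, info = nm)
  }
})

test_that("the shipped canonical spec equals the built one", {
  path <- system.file("extdata", "religion_empathy.yaml", package = "tcnet")
  expect_true(nzchar(path))
  shipped <- read_spec(path)
  built <- build_religion_network()$spec
  expect_equal(shipped$states, built$states)
  expect_equal(shipped$connections, built$connections)
  expect_equal(shipped$hebbian, built$hebbian)
})

test_that("neutral trajectories are identical across valences", {
  tr <- run_scenario("neutral", simulation_config(0.25, 250))
  pairing <- valence_pairing()
  expect_identical(max(abs(tr$activations[, names(pairing)] -
                             tr$activations[, unname(pairing)])), 0)
})
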