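test_that("canonical model is well-formed with the expected architecture", {
  m <- build_religion_network()
  expect_identical(nrow(validate_spec(m$spec)), 0L)
  expect_identical(nrow(m$spec$states), 54L)
  expect_length(m$adaptive_labels, 8L)
  # four adaptive God-image connections per valence
  ad <- m$spec$connections[m$spec$connections$adaptive, ]
  for (v in 1:2) {
    adv <- ad[endsWith(ad$label, paste0(".", v)), ]
    expect_setequal(
      paste(sub("_[12]$", "", adv$source), sub("_[12]$", "", adv$target)),
      c("srs_god_image srs_god_action", "srs_god_image srs_god_emotion",
        "srs_god_action srs_god_emotion", "srs_god_emotion srs_god_action"))
  }
  # every non-shared state exists in both valences
  v1 <- sub("_1$", "", grep("_1$", m$spec$states$name, value = TRUE))
  v2 <- sub("_2$", "", grep("_2$", m$spec$states$name, value = TRUE))
  expect_setequal(v1, v2)
  expect_setequal(setdiff(m$spec$states$name,
                          c(paste0(v1, "_1"), paste0(v2, "_2"))),
                  c("gs", "gfs"))
})

test_that("edge list equals the hand-transcribed golden fixture", {
  m <- build_religion_network()
  golden <- utils::read.csv(test_path("fixtures", "golden_edges.csv"))
  expand <- do.call(rbind, lapply(1:2, function(v) {
    g <- golden[golden$valenced == "yes", ]
    data.frame(label = paste0(g$label, ".", v),
               source = ifelse(g$source %in% c("gs", "gfs"), g$source,
                               paste0(g$source, "_", v)),
               target = ifelse(g$target %in% c("gs", "gfs"), g$target,
                               paste0(g$target, "_", v)))
  }))
  shared <- golden[golden$valenced == "no", c("label", "source", "target")]
  want <- rbind(expand, shared)
  got <- m$spec$connections[c("label", "source", "target")]
  expect_identical(nrow(got), nrow(want))
  key <- function(d) sort(paste(d$label, d$source, d$target))
  expect_identical(key(got), key(want))
})

test_that("Self-ownership for behaviour is wired per the ownership model", {
  m <- build_religion_network()
  cn <- m$spec$connections
  src <- cn$source[cn$target == "os_self_action_1"]
  expect_setequal(src, c("srs_god_action_1", "srs_effect_1", "fs_emotion_1"))
  # ownership states gate both preparation and execution
  expect_true(all(c("os_god_action_1", "os_self_action_1") %in%
                    cn$source[cn$target == "ps_behaviour_1"]))
  expect_true(all(c("os_god_action_1", "os_self_action_1") %in%
                    cn$source[cn$target == "es_behaviour_1"]))
})

test_that("every Self preparation state sees ownership and the God-image", {
  m <- build_religion_network()
  cn <- m$spec$connections
  for (v in 1:2) {
    for (ps in paste0(c("ps_behaviour_", "ps_emotion_"), v)) {
      src <- cn$source[cn$target == ps]
      expect_true(any(startsWith(src, "os_")), info = ps)
      expect_true(any(startsWith(src, "srs_god_")), info = ps)
    }
  }
})

test_that("profile application overrides exactly what it names", {
  m <- build_religion_network()
  same <- apply_parameter_profile(m, scenario_profile("empty"))
  expect_identical(same$spec, m$spec)
  p <- scenario_profile("x", weight_overrides = c("w11c.1" = 0.42),
                        initial_values = c(gs = 0.3))
  out <- apply_parameter_profile(m, p)
  cn <- out$spec$connections
  expect_identical(cn$weight[cn$label == "w11c.1"], 0.42)
  expect_identical(cn$weight[cn$label == "w11c.2"],
                   m$spec$connections$weight[
                     m$spec$connections$label == "w11c.2"])
  expect_identical(out$spec$states$initial_value[
    out$spec$states$name == "gs"], 0.3)
  # an unsuffixed label hits both valences
  p2 <- scenario_profile("y", weight_overrides = c(w1 = 0.05))
  out2 <- apply_parameter_profile(m, p2)
  expect_identical(out2$spec$connections$weight[
    out2$spec$connections$label %in% c("w1.1", "w1.2")], c(0.05, 0.05))
  expect_error(apply_parameter_profile(m,
    scenario_profile("z", weight_overrides = c(nope = 1))), "nope")
})

test_that("severing the God-action input silences its sensor state", {
  m <- build_religion_network()
  p <- scenario_profile("cut", weight_overrides = c("w1.1" = 0),
                        stimulus_levels = c(ws_god_action_1 = 0))
  tr <- simulate_network(apply_parameter_profile(m, p)$spec,
                         simulation_config(0.25, 100))
  expect_identical(max(abs(tr$activations[, "ss_god_action_1"])), 0)
})

test_that("valence swap is an involution and swaps key valences", {
  p <- get_scenario("empathic")
  expect_identical(valence_swap(valence_swap(p)), p)
  swapped <- valence_swap(p)
  expect_identical(unname(swapped$weight_overrides["w11c.2"]),
                   unname(p$weight_overrides["w11c.1"]))
  # the neutral profile is symmetric, hence invariant
  expect_identical(valence_swap(get_scenario("neutral"))$weight_overrides,
                   get_scenario("neutral")$weight_overrides)
})

test_that("mirror property: swapped profiles give mirrored trajectories", {
  m <- build_religion_network()
  set.seed(31)
  labs <- sample(grep("\\.1$", m$spec$connections$label, value = TRUE), 6)
  p <- scenario_profile("rand",
                        weight_overrides = stats::setNames(
                          round(runif(6), 3), labs))
  cfg <- simulation_config(0.25, 200)
  a <- simulate_network(apply_parameter_profile(m, p)$spec, cfg)
  b <- simulate_network(apply_parameter_profile(m, valence_swap(p))$spec, cfg)
  pairing <- valence_pairing(m)
  expect_lt(mirror_asymmetry(a, b, pairing), 1e-12)
  reverse <- stats::setNames(names(pairing), pairing)
  expect_lt(mirror_asymmetry(a, b, reverse), 1e-12)
  shared <- stats::setNames(c("gs", "gfs"), c("gs", "gfs"))
  expect_lt(mirror_asymmetry(a, b, shared), 1e-12)
})
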