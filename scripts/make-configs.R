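#!/usr/bin/env Rscript
# Regenerates the shipped YAML configuration files in inst/extdata from the
# package's programmatic constructors. Run from the repository root after
# changing the canonical model or a scenario profile.
suppressMessages(devtools::load_all(".", quiet = TRUE))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_spec(build_religion_network()$spec, "inst/extdata/religion_empathy.yaml")
for (nm in scenario_names()) {
  write_scenario(get_scenario(nm),
                 file.path("inst/extdata", paste0("scenario_", nm, ".yaml")))
}
cat("wrote", length(scenario_names()) + 1L, "files to inst/extdata\n")
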