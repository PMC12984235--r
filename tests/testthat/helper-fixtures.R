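# shared fixtures; fits are cached per test session to avoid refitting
.fixture_cache <- new.env(parent = emptyenv())

cm_data <- function(seed = 2) {
  key <- paste0("cm_data_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- observe(simulate_population(sim_config(seed = seed)))
  .fixture_cache[[key]]
}

cm_fit <- function(seed = 2, refpoints = TRUE) {
  key <- paste0("cm_fit_", seed, "_", refpoints)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- fit_spm(
      cm_data(seed), scenario = "CM",
      control = spm_control(report_refpoints = refpoints))
  .fixture_cache[[key]]
}

est_of <- function(fit, par) fit$estimates$estimate[fit$estimates$parameter == par]

all_shapes <- function() list(
  schaefer = production_shape("schaefer"),
  fox = production_shape("fox"),
  pt15 = production_shape("pella_tomlinson", n = 1.5),
  pt3 = production_shape("pella_tomlinson", n = 3)
)

# tiny 3-year toy dataset used by the objective oracle tests
toy_data <- function() {
  assessment_data(
    data.frame(year = 2001:2003, catch = c(900, 1100, 1000)),
    data.frame(fleet = "f1", year = 2001:2003,
               index = c(0.11, 0.10, 0.095))
  )
}
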