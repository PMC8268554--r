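# Shared fixtures, built once per test session. All fixtures are generated
# in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# mid-size phantom with electrodes, pattern and baseline forward solution
fx_phantom <- function() fx_get("phantom", function() {
  ph <- build_phantom(phantom_spec(target_elements = 8000))
  mesh <- place_electrodes(ph$mesh)
  pattern <- build_pattern(16L, 7L)
  vref <- solve_forward(mesh, ph$sigma, pattern)
  list(mesh = mesh, sigma = ph$sigma, pattern = pattern, vref = vref,
       spec = phantom_spec(target_elements = 8000))
})

# P1 heated state on the shared phantom
fx_p1 <- function() fx_get("p1", function() {
  fx <- fx_phantom()
  sc <- scenario_fixture("P1")
  sigma_true <- apply_gaussian_heating(fx$sigma, sc, fx$mesh)
  list(scenario = sc, sigma_true = sigma_true,
       v = solve_forward(fx$mesh, sigma_true, fx$pattern),
       mask = scenario_prior_mask(fx$mesh, sc),
       dtrue = ifelse(fx$sigma > 0,
                      100 * (sigma_true - fx$sigma) / fx$sigma, NA_real_))
})

# small 8-electrode phantom for derivative checks
fx_tiny <- function() fx_get("tiny", function() {
  ph <- build_phantom(phantom_spec(target_elements = 1500))
  mesh <- place_electrodes(ph$mesh, 8L, 2L)
  pattern <- build_pattern(8L, 3L)
  list(mesh = mesh, sigma = ph$sigma, pattern = pattern)
})

# Scenario-2 two-frequency treatment run (shared by the pipeline tests)
fx_ht2 <- function() fx_get("ht2", function() {
  run_scenario(ht_config(spec = phantom_spec(target_elements = 12000),
                         grid_spacing = 0.008))
})
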