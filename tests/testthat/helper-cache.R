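# shared cache so expensive simulations run once per test session
.test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

silico_series_for <- function(set_id, config = run_config()) {
  cache_get(paste0("silico_", set_id, "_", config$n_levels), {
    midwall_stress_series(silico_aortas()[silico_aortas()$set == set_id, ],
                          config)
  })
}

refit_report <- function() {
  cache_get("refit_report", run_full_evaluation(mode = "refit", seed = 1))
}

membrane_truth_series <- function(set_id = 15) {
  cache_get(paste0("mem_series_", set_id), {
    p <- membrane_parameters()
    generate_membrane_series(p[p$set == set_id, ])
  })
}
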