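# Heavy simulation results shared across test files, computed once per run.
.sim_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- compute()
  .sim_cache[[key]]
}

# the full-scale stylized circle used by the study design
study_circle <- function() {
  cache_get("circle", function() make_circle_landscape(1000, 4.84))
}

# 32 control replicates at full scale (the study's control block)
control_outcomes <- function(n = 32L, base_seed = 1L) {
  cache_get(sprintf("controls_%d_%d", n, base_seed), function() {
    design <- build_design(functions = "linear", landscape_levels = 0.25,
                           cell_levels = 1, replicates = 0L,
                           base_seed = base_seed, controls = n)
    design <- design[design$experiment_id == 0L, ]
    run_experiment_suite(design, sim_config(landscape = study_circle()))
  })
}

# reduced factorial subset: 2 functions x 3 landscape levels x 2 cell levels
subset_outcomes <- function(replicates = 8L, base_seed = 1L) {
  cache_get(sprintf("subset_%d_%d", replicates, base_seed), function() {
    design <- build_design(functions = c("linear", "random"),
                           landscape_levels = c(0.05, 0.15, 0.25),
                           cell_levels = c(0.25, 1),
                           replicates = replicates, base_seed = base_seed,
                           controls = 0L)
    design <- design[design$experiment_id != 0L, ]
    run_experiment_suite(design, sim_config(landscape = study_circle()))
  })
}
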