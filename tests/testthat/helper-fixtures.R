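# Shared fixtures, built in code. Sizes are kept small: the point of a
# fixture is to exercise a contract, not to reproduce study-scale noise.

# A small three-hospital cohort with a moderate protective effect at
# hospital 1 and a case-mix shift at hospital 3.
small_sim <- function(seed = 42, sizes = c(350, 400, 450),
                      shifts = c(-0.7, 0, 0), casemix = c(0, 0, 1.5)) {
  simulate_cohort(sim_config(
    n_hospitals = 3, sizes = sizes, n_covariates = 6,
    hospital_logit_shifts = shifts, casemix_shifts = casemix,
    target_prevalence = 0.08, seed = seed
  ))
}

# Feature columns of a simulated cohort.
xcols <- function(cohort) grep("^x[0-9]+$", names(cohort), value = TRUE)

# A quick pair of risk models (hospital scope + overall) on a cohort.
quick_models <- function(cohort, h = "1", num_trees = 60, seed = 9,
                         min_node_size = 10) {
  list(
    h = fit_risk_model(cohort, scope = h, num_trees = num_trees,
                       min_node_size = min_node_size, seed = seed),
    o = fit_risk_model(cohort, scope = "overall", num_trees = num_trees,
                       min_node_size = min_node_size, seed = seed + 1)
  )
}
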