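# Small configurations used across test files. Kept deliberately tiny so a
# full suite run stays fast; statistically demanding checks scale n up
# locally within their own test.

small_config <- function(n = 100, seed = 421, ...) {
  sim_config(n_per_arm = n, seed = seed, ...)
}

# complete -> design missingness -> dropout, in one call
masked_trial <- function(cfg) {
  apply_dropout(apply_design_missingness(generate_trial(cfg)), cfg)
}

healthcare_vars <- function() {
  c("eq5d_index", "cost_community", "cost_prescribed",
    "cost_admitted", "cost_outpatient")
}
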