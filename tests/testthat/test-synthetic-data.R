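test_that("generator handles the empty trial and is deterministic", {
  cfg <- small_config(n = 0)
  d <- generate_trial(cfg)
  expect_s3_class(d, "trial_data")
  expect_equal(nrow(d), 0)
  expect_true(all(c("patient_id", "arm", "timepoint", "eq5d_index",
                    "cost_mammogram", "quest_status") %in% names(d)))
  cfg2 <- small_config(n = 80)
  d1 <- generate_trial(cfg2)
  d2 <- generate_trial(cfg2)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_error(sim_config(n_per_arm = -1), "non-negative")
  expect_error(sim_config(dropout = c(0.1, 0.2, 1.5, 0.1, 0.1)), "\\[0, 1\\]")
})

test_that("generated data satisfy the structural invariants", {
  cfg <- small_config(n = 400, death_hazard = 0.05, seed = 99)
  d <- generate_trial(cfg)
  cost_cols <- grep("^cost_", names(d), value = TRUE)
  expect_true(all(as.matrix(as.data.frame(d)[cost_cols]) >= 0))
  expect_true(all(d$eq5d_index <= 1))
  expect_true(all(is.na(d$death_time) | d$years < d$death_time))
  # one row per patient-timepoint, arm constant within patient
  expect_false(anyDuplicated(d[c("patient_id", "timepoint")]) > 0)
  expect_true(all(tapply(d$arm, d$patient_id,
                         function(a) length(unique(a))) == 1))
})

test_that("large-sample arm difference matches the configured truth", {
  cfg <- sim_config(n_per_arm = 20000, death_hazard = 0, seed = 2024)
  pt <- patient_totals(generate_trial(cfg), "healthcare")
  truth <- configured_effects(cfg)$delta_cost_healthcare
  means <- tapply(pt$total_cost, pt$arm, mean)
  vars <- tapply(pt$total_cost, pt$arm, var)
  ns <- tapply(pt$total_cost, pt$arm, length)
  emp <- means[["less_frequent"]] - means[["annual"]]
  mc_se <- sqrt(sum(vars / ns))
  expect_lt(abs(emp - truth), 3 * mc_se)
  expect_equal(truth, -544, tolerance = 1e-9)
})

test_that("design missingness follows the 2-yearly / 3-yearly schedule", {
  cfg <- small_config(n = 200, seed = 31,
                      request_prob = rep(0, 6), dropout = rep(0, 6))
  d <- apply_design_missingness(generate_trial(cfg))
  ann <- d[d$arm == "annual", ]
  expect_true(all(ann$quest_status == "observed"))
  expect_false(anyNA(ann$eq5d_index))
  # mastectomy, less frequent: observed only at timepoint 6 within 4..8
  mast <- d[d$arm == "less_frequent" & d$surgery == "mastectomy", ]
  expect_setequal(unique(mast$timepoint[mast$quest_status == "observed"]), 6)
  expect_true(all(is.na(mast$eq5d_index[mast$timepoint != 6])))
  # conservation, less frequent: timepoints 5 and 7
  cons <- d[d$arm == "less_frequent" & d$surgery == "conservation", ]
  expect_setequal(unique(cons$timepoint[cons$quest_status == "observed"]),
                  c(5, 7))
  # idempotent re-application
  d2 <- apply_design_missingness(d)
  expect_identical(as.data.frame(d), as.data.frame(d2))
})

test_that("dropout boundaries behave and return rates decline over time", {
  cfg0 <- small_config(n = 150, seed = 8, dropout = rep(0, 6),
                       hes_final_missing = 0)
  d0 <- apply_design_missingness(generate_trial(cfg0))
  expect_identical(as.data.frame(apply_dropout(d0, cfg0)), as.data.frame(d0))
  cfg1 <- small_config(n = 150, seed = 8,
                       dropout = c(0, 0, 0, 0, 1, 1))
  d1 <- apply_dropout(apply_design_missingness(generate_trial(cfg1)), cfg1)
  tp8 <- d1[d1$timepoint == 8, ]
  expect_true(all(tp8$quest_status != "observed"))
  expect_true(all(is.na(tp8$eq5d_index)))
  # monotone dropout profile -> non-increasing annual-arm return rates
  cfg2 <- sim_config(n_per_arm = 10000, seed = 12, death_hazard = 0)
  d2 <- masked_trial(cfg2)
  ann <- d2[d2$arm == "annual", ]
  ret <- tapply(ann$quest_status == "observed", ann$timepoint, mean)
  tol <- 3 * sqrt(0.25 / 10000)
  expect_true(all(diff(ret) <= tol))
})

test_that("combined design and dropout missingness matches the trial pattern", {
  cfg <- sim_config(n_per_arm = 10000, seed = 77)
  d <- masked_trial(cfg)
  lf <- d[d$arm == "less_frequent", ]
  missing_frac <- tapply(is.na(lf$eq5d_index), lf$timepoint, mean)
  expect_equal(as.numeric(missing_frac[c("4", "6", "8")]), c(0.94, 0.86, 0.99),
               tolerance = 0.02)
})

test_that("simulation configs round-trip through YAML", {
  cfg <- small_config(n = 25, seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n_per_arm, cfg$n_per_arm)
  expect_equal(back$cost_models, cfg$cost_models)
  expect_equal(back$dropout, cfg$dropout)
  expect_identical(as.data.frame(generate_trial(back)),
                   as.data.frame(generate_trial(cfg)))
})
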