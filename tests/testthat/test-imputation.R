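test_that("PMM donors come from the nearest observed fitted values", {
  # exact fitted match with k = 1 returns that donor's observed value
  set.seed(1)
  expect_equal(pmm_draw(observed_y = c(10, 20, 30),
                        fitted_obs = c(1, 2, 3),
                        fitted_mis = 2, k_donors = 1), 20)
  # constant donor pool imputes the constant
  expect_true(all(pmm_draw(rep(7, 5), fitted_obs = 1:5,
                           fitted_mis = c(0, 2.2, 9), k_donors = 3) == 7))
  # k = 3 of 5 donors: brute-force enumeration of the admissible donor set
  y_obs <- c(100, 200, 300, 400, 500)
  f_obs <- c(1, 2, 3, 5, 9)
  for (fm in c(0, 2.4, 4.1, 20)) {
    admissible <- y_obs[order(abs(f_obs - fm))[1:3]]
    draws <- replicate(50, pmm_draw(y_obs, f_obs, fm, k_donors = 3))
    expect_true(all(draws %in% admissible))
  }
  expect_error(pmm_draw(1:3, 1:3, 1, k_donors = 5), "donors")
})

test_that("imputation is the identity on complete data and is deterministic", {
  cfg <- small_config(n = 60, seed = 14)
  d <- generate_trial(cfg)  # complete
  spec <- imputation_spec(m = 3, max_iterations = 2, seed = 5)
  imp <- impute(d, spec)
  for (k in 1:3) {
    expect_identical(as.data.frame(imp$imputations[[k]]), as.data.frame(d))
  }
  dm <- masked_trial(cfg)
  i1 <- impute(dm, spec)
  i2 <- impute(dm, spec)
  expect_identical(lapply(i1$imputations, as.data.frame),
                   lapply(i2$imputations, as.data.frame))
})

test_that("observed cells are untouched and imputed costs are non-negative", {
  cfg <- small_config(n = 120, seed = 3)
  dm <- masked_trial(cfg)
  imp <- impute(dm, imputation_spec(m = 4, max_iterations = 2, seed = 2))
  for (v in c("eq5d_index", "cost_community", "cost_informal_care")) {
    obs <- !is.na(dm[[v]])
    for (k in seq_along(imp$imputations)) {
      comp <- imp$imputations[[k]]
      expect_identical(comp[[v]][obs], dm[[v]][obs])
      expect_false(anyNA(comp[[v]]))
      if (startsWith(v, "cost_")) expect_true(all(comp[[v]] >= 0))
      else expect_true(all(comp[[v]] <= 1))
    }
  }
})

test_that("a variable with no donors in an arm fails loudly", {
  cfg <- small_config(n = 30, seed = 6)
  d <- generate_trial(cfg)
  d$cost_community[d$arm == "annual"] <- NA
  expect_error(impute(d, imputation_spec(m = 2, max_iterations = 1)),
               "cost_community")
})

test_that("MAR-masked cost means are recovered within Monte-Carlo error", {
  # n = 2,000 patients; ~40% MAR missingness in one cost variable, driven
  # by the observed EQ-5D index (worse health -> more missingness)
  cfg <- sim_config(n_per_arm = 1000, death_hazard = 0, seed = 505)
  d <- generate_trial(cfg)
  truth <- mean(d$cost_community)
  set.seed(42)
  p_miss <- plogis(-0.4 + 2 * (0.8 - d$eq5d_index))
  d_masked <- d
  d_masked$cost_community[runif(nrow(d)) < p_miss] <- NA
  frac <- mean(is.na(d_masked$cost_community))
  expect_gt(frac, 0.3)
  imp <- impute(d_masked, imputation_spec(m = 5, max_iterations = 3,
                                          variables = "cost_community",
                                          seed = 9))
  pooled <- mean(vapply(imp$imputations,
                        function(x) mean(x$cost_community), numeric(1)))
  mc_se <- sd(d$cost_community) / sqrt(nrow(d))
  expect_lt(abs(pooled - truth), 3 * mc_se)
})

test_that("diagnostics summarise chains and flag the trivial case", {
  cfg <- small_config(n = 80, seed = 21)
  d <- generate_trial(cfg)
  imp0 <- impute(d, imputation_spec(m = 2, max_iterations = 1, seed = 1))
  dg0 <- diagnostics(imp0, d)
  expect_true(dg0$trivially_valid)
  # MCAR masking: observed and imputed means agree within 3 SEs
  set.seed(11)
  dm <- d
  mask <- runif(nrow(d)) < 0.3
  dm$eq5d_index[mask] <- NA
  imp <- impute(dm, imputation_spec(m = 5, max_iterations = 3,
                                    variables = "eq5d_index", seed = 4))
  dg <- diagnostics(imp, dm)
  expect_false(dg$trivially_valid)
  row <- dg$summary[dg$summary$variable == "eq5d_index", ]
  se <- row$observed_sd / sqrt(nrow(d) - row$n_missing)
  expect_lt(abs(row$imputed_mean - row$observed_mean), 3 * se)
  # traces exist for every imputed variable x chain x iteration
  tr <- dg$traces
  expect_setequal(unique(tr$chain), 1:5)
  expect_setequal(unique(tr$iteration), 1:3)
  expect_true(all(table(tr$chain, tr$iteration) > 0))
  expect_true(row$fmi >= 0 && row$fmi <= 1)
})
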