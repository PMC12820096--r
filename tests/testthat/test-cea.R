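test_that("SUR with shared regressors reproduces per-equation OLS", {
  cfg <- small_config(n = 100, seed = 17)  # 200 patients
  pt <- patient_totals(generate_trial(cfg), "healthcare")
  fit <- fit_sur(pt)
  df <- pt
  df$arm <- factor(df$arm, levels = c("annual", "less_frequent"))
  ols_c <- lm(total_cost ~ arm + age_band + disease_type + surgery +
                hormone_therapy + er_status, df)
  ols_q <- lm(qaly ~ arm + age_band + disease_type + surgery +
                hormone_therapy + er_status, df)
  expect_equal(fit$delta_cost, unname(coef(ols_c)["armless_frequent"]),
               tolerance = 1e-8)
  expect_equal(fit$delta_qaly, unname(coef(ols_q)["armless_frequent"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[, "cost"]), unname(coef(ols_c)),
               tolerance = 1e-8)
  # residual covariance symmetric positive semi-definite
  expect_equal(fit$sigma[1, 2], fit$sigma[2, 1])
  expect_true(all(eigen(fit$sigma)$values >= 0))
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  cfg <- small_config(n = 40, seed = 2)
  pt <- patient_totals(generate_trial(cfg), "healthcare")
  pt$er_status <- pt$hormone_therapy  # perfectly collinear factor
  expect_error(fit_sur(pt), "collinear")
})

test_that("cross-equation residual correlation is estimated without bias", {
  set.seed(88)
  n <- 5000
  fake <- data.frame(
    patient_id = 1:n,
    arm = rep(c("annual", "less_frequent"), each = n / 2),
    age_band = "56-75", disease_type = "invasive", surgery = "conservation",
    hormone_therapy = "yes", er_status = "positive",
    total_cost = rnorm(n, 5000, 1000),  # independent of qaly by construction
    qaly = rnorm(n, 4, 0.5)
  )
  fit <- fit_sur(fake)
  expect_lt(abs(fit$residual_correlation), 3 / sqrt(n))
})

test_that("INMB arithmetic and CEAC identities hold on enumerated draws", {
  expect_equal(inmb(100, 0.01, 20000), 100)
  expect_equal(inmb(-543.88, 0, 0), 543.88)
  expect_equal(inmb(0, 0, 12345), 0)
  draws <- structure(
    data.frame(imputation = 1L, replicate = 1:4,
               delta_cost = c(-1, -1, 1, 1),
               delta_qaly = c(0.1, -0.1, 0.1, -0.1)),
    class = c("ce_draws", "data.frame"))
  # at lambda = 20: INMB = (3, -1, 1, -3) -> exactly half the draws positive
  expect_equal(ceac(draws, 20)$probability, 0.5)
  expect_equal(ceac(draws, 0)$probability, mean(draws$delta_cost < 0))
  expect_equal(ceac(draws, 1e9)$probability, mean(draws$delta_qaly > 0))
  grid <- c(0, 20, 1e9)
  cc <- ceac(draws, grid)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_error(ceac(draws, numeric(0)), "empty")
  # ties at zero INMB count as not cost-effective
  tie <- structure(data.frame(imputation = 1L, replicate = 1L,
                              delta_cost = 2, delta_qaly = 0.1),
                   class = c("ce_draws", "data.frame"))
  expect_equal(ceac(tie, 20)$probability, 0)
})

test_that("bootstrap draws are reproducible, counted, and degenerate correctly", {
  cfg <- small_config(n = 80, seed = 10)
  d <- generate_trial(cfg)
  dr1 <- bootstrap_cea(d, B = 50, seed = 123, perspective = "healthcare")
  dr2 <- bootstrap_cea(d, B = 50, seed = 123, perspective = "healthcare")
  expect_identical(as.data.frame(dr1), as.data.frame(dr2))
  expect_equal(nrow(dr1), 50)
  expect_true(all(is.finite(dr1$delta_cost)) && all(is.finite(dr1$delta_qaly)))
  # constant data: resampling cannot move the estimate off the point
  dc <- generate_trial(small_config(n = 80, seed = 10, death_hazard = 0))
  for (cc in grep("^cost_", names(dc), value = TRUE)) dc[[cc]] <- 100
  dc$eq5d_index <- 0.75
  drc <- bootstrap_cea(dc, B = 1, seed = 1, perspective = "healthcare",
                       covariates = character(0))
  pt <- patient_totals(dc, "healthcare")
  point <- fit_sur(pt, covariates = character(0))
  expect_equal(drc$delta_qaly, point$delta_qaly, tolerance = 1e-9)
})

test_that("pooled summaries respect symmetry, width and quadrant identities", {
  sym <- structure(
    data.frame(imputation = 1L, replicate = 1:1000,
               delta_cost = c(seq(-500, -1, length.out = 500),
                              seq(1, 500, length.out = 500)),
               delta_qaly = rep(c(-0.01, 0.01), 500)),
    class = c("ce_draws", "data.frame"))
  s <- summary(sym, lambda_grid = c(0, 20000))
  expect_equal(s$p_cost_saving, 0.5)
  expect_equal(sum(s$quadrants), 1)
  same <- structure(data.frame(imputation = 1L, replicate = 1:10,
                               delta_cost = -100, delta_qaly = 0.05),
                    class = c("ce_draws", "data.frame"))
  s2 <- summary(same, lambda_grid = c(0, 20000))
  expect_equal(unname(s2$delta_cost_ci), c(-100, -100))
  expect_equal(s2$delta_cost, -100)
  # CEAC ordering: CEAC(0) = P(dC<0) and the large-lambda limit = P(dQ>0)
  cfg <- small_config(n = 120, seed = 44)
  dr <- bootstrap_cea(generate_trial(cfg), B = 200, seed = 3,
                      perspective = "healthcare")
  cc <- ceac(dr, c(0, 20000, 1e9))
  expect_equal(cc$probability[1], mean(dr$delta_cost < 0))
  expect_equal(cc$probability[3], mean(dr$delta_qaly > 0))
})

test_that("subgroup analyses localise a planted mastectomy-only QALY decrement", {
  cfg <- sim_config(n_per_arm = 2500, death_hazard = 0, seed = 60,
                    true_effects = list(delta_cost = -544, delta_qaly = 0))
  d <- generate_trial(cfg)
  hit <- d$arm == "less_frequent" & d$surgery == "mastectomy"
  d$eq5d_index[hit] <- pmax(d$eq5d_index[hit] - 0.06, -0.594)
  res <- subgroup_cea(d, imputation_spec(m = 2, max_iterations = 1, seed = 1),
                      "surgery", B = 100, seed = 5,
                      perspective = "healthcare")
  expect_named(res, c("conservation", "mastectomy"))
  expect_true(res$mastectomy$estimated)
  expect_lt(res$mastectomy$delta_qaly, res$conservation$delta_qaly)
  expect_lt(res$mastectomy$delta_qaly, -0.1)  # ~ -0.06 x 5 years planted
  expect_lt(abs(res$conservation$delta_qaly), 0.1)
  # small subgroups are flagged, not estimated
  res2 <- subgroup_cea(d, imputation_spec(m = 2, max_iterations = 1, seed = 1),
                       "surgery", B = 10, seed = 5, min_n = 10^7,
                       perspective = "healthcare")
  expect_false(isTRUE(res2$mastectomy$estimated))
  expect_match(res2$mastectomy$reason, "fewer than")
})

test_that("INMB rises with the mammogram unit cost when fewer mammograms occur", {
  cfg <- small_config(n = 500, seed = 70, death_hazard = 0)
  d <- generate_trial(cfg)
  sens <- unit_cost_sensitivity(d, unit_costs = c(0, 33, 115.25, 115.25, 272),
                                B = 60, seed = 9, perspective = "healthcare")
  expect_true(all(diff(sens$inmb[c(1, 2, 3, 5)]) > 0))
  # equal unit costs under the same seed give identical results
  expect_equal(sens$inmb[3], sens$inmb[4], tolerance = 1e-12)
  # the incremental cost is linear in the unit cost, with slope equal to
  # the adjusted arm difference in mammogram counts
  pt0 <- patient_totals(d, "healthcare", mammogram_unit_cost = 0)
  ptb <- patient_totals(d, "healthcare")
  ptm <- ptb
  ptm$total_cost <- ptm$mammograms
  slope <- fit_sur(ptm)$delta_cost
  expect_lt(slope, 0)  # fewer mammograms in the less-frequent arm
  expect_equal(fit_sur(ptb)$delta_cost,
               fit_sur(pt0)$delta_cost + 115.25 * slope, tolerance = 1e-8)
})
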