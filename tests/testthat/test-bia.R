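test_that("cohort projection conserves, absorbs and thins as specified", {
  # lossless cohort: same count in every eligible year
  inp <- bia_inputs(horizon_years = 5, new_diagnoses = 0,
                    initial_population = c(100, rep(0, 7)),
                    survival = 1, attrition = 0)
  ct <- project_population(inp)
  n_by_year <- tapply(ct$n, ct$year, sum)
  expect_equal(as.numeric(n_by_year), rep(100, 5))
  # lethal boundary: nobody left from year 2
  inp0 <- bia_inputs(horizon_years = 3, new_diagnoses = 0,
                     initial_population = c(50, rep(0, 7)), survival = 0)
  ct0 <- project_population(inp0)
  expect_equal(as.numeric(tapply(ct0$n, ct0$year, sum)), c(50, 0, 0))
  # hand arithmetic of the thinning rule: 1000 x 0.95 x 0.95 after one year
  inp1 <- bia_inputs(horizon_years = 2, new_diagnoses = 0,
                     initial_population = c(1000, rep(0, 7)),
                     survival = 0.95, attrition = 0.05)
  ct1 <- project_population(inp1)
  y2 <- ct1[ct1$year == 2025 & ct1$years_since_diagnosis == 2, ]
  expect_equal(y2$n, 902.5)
  # population non-increasing per cohort when thinning <= 1
  inp2 <- bia_inputs(horizon_years = 6, new_diagnoses = 0)
  ct2 <- project_population(inp2)
  expect_true(all(diff(tapply(ct2$n, ct2$year, sum)) <= 1e-9))
})

test_that("savings and mammograms-avoided arithmetic match the schedules", {
  # 100 conservation patients in the saving phase for one year
  inp <- bia_inputs(horizon_years = 1, new_diagnoses = 0,
                    initial_population = c(0, 0, 0, 100, 0, 0, 0, 0),
                    survival = 1, attrition = 0, p_conservation = 1)
  r <- bia_run(inp)
  expect_equal(r$per_year$savings, 100 * 0.5 * 115.25)  # 5762.50
  expect_equal(r$per_year$mammograms_saved, 50)
  # 90 mastectomy patient-years avoid 60 mammograms (1 - 1/3 per year)
  inp_m <- bia_inputs(horizon_years = 1, new_diagnoses = 0,
                      initial_population = c(0, 0, 0, 90, 0, 0, 0, 0),
                      survival = 1, attrition = 0, p_conservation = 0)
  expect_equal(bia_run(inp_m)$per_year$mammograms_saved, 60)
  # empty population, empty savings
  inp_e <- bia_inputs(horizon_years = 2, new_diagnoses = 0,
                      initial_population = rep(0, 8))
  expect_equal(bia_run(inp_e)$cumulative_savings, 0)
  # years 1-3 since diagnosis never contribute
  inp_y <- bia_inputs(horizon_years = 1, new_diagnoses = 0,
                      initial_population = c(1000, 1000, 1000, 0, 0, 0, 0, 0))
  expect_equal(bia_run(inp_y)$per_year$savings, 0)
})

test_that("savings scale linearly in the unit cost and equal counts x cost", {
  inp <- bia_inputs()
  r1 <- bia_run(inp)
  expect_equal(r1$per_year$savings,
               r1$per_year$mammograms_saved * inp$unit_cost)
  expect_equal(r1$cumulative_savings, sum(r1$per_year$savings))
  expect_equal(r1$cumulative_savings_y3, sum(r1$per_year$savings[1:3]))
  inp2 <- inp
  inp2$unit_cost <- 2 * inp$unit_cost
  r2 <- bia_run(inp2)
  expect_equal(r2$per_year$savings, 2 * r1$per_year$savings)
  expect_equal(r2$per_year$mammograms_saved, r1$per_year$mammograms_saved)
  sc <- scenario_unit_cost(inp, c(0, 115.25, 230.5))
  expect_equal(sc$cumulative_savings[1], 0)
  expect_equal(sc$cumulative_savings[2], r1$cumulative_savings)
  expect_equal(sc$cumulative_savings[3], 2 * r1$cumulative_savings)
  expect_equal(sc$cumulative_mammograms_saved,
               rep(r1$cumulative_mammograms_saved, 3))
})

test_that("one-way sensitivity analysis is monotone, complete and sorted", {
  inp <- bia_inputs()
  ranges <- data.frame(
    parameter = c("survival", "attrition", "unit_cost", "new_diagnoses",
                  "initial_population_scale", "phase_of_the_moon"),
    low = c(0.90, 0.02, 33, 40000, 0.8, 0),
    high = c(0.99, 0.10, 272, 60000, 1.2, 1))
  tor <- one_way_dsa(inp, ranges)
  expect_equal(nrow(tor), 6)
  expect_true(all(diff(tor$range) <= 0))  # sorted by decreasing range
  sv <- tor[tor$parameter == "survival", ]
  expect_gt(sv$savings_high, sv$savings_low)  # higher survival, more savings
  moon <- tor[tor$parameter == "phase_of_the_moon", ]
  expect_true(moon$inactive)
  expect_equal(moon$range, 0)
  # degenerate range collapses to zero
  deg <- one_way_dsa(inp, data.frame(parameter = "survival",
                                     low = 0.95, high = 0.95))
  expect_equal(deg$range, 0)
})

test_that("both population tallies are emitted and internally consistent", {
  inp <- bia_inputs()
  r <- bia_run(inp)
  expect_equal(r$population_patient_years, sum(r$per_year$total_population))
  expect_equal(r$saving_patient_years, sum(r$per_year$saving_population))
  expect_equal(r$population_unique,
               sum(inp$initial_population) + sum(inp$new_diagnoses[-1]))
  expect_lte(r$saving_unique, r$population_unique)
  expect_gt(r$saving_unique, 0)
  # default inputs load from the shipped placeholder file identically
  csv <- read_bia_inputs(system.file("extdata", "bia_inputs_default.csv",
                                     package = "ceasurv"))
  expect_equal(bia_run(csv)$cumulative_savings, r$cumulative_savings)
})
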