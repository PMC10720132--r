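test_that("null truth with no noise gives equal counts everywhere", {
  truth <- truth_null(noise_cv = 0)
  for (dose in c(0, 2, 20)) {
    counts <- simulate_coculture(
      coculture_design(doses = dose, replicates = 1), truth, seed = 1)
    by_well <- split(counts$count,
                     interaction(counts$mixture, counts$timepoint, drop = TRUE))
    for (w in by_well) expect_equal(w[1], w[2])
  }
})

test_that("altruism-on generator matches the hand-derived expectations", {
  truth <- truth_params(B = 0.5, k = 0.05, h = 1, c = 0.3, s_A = 0.9,
                        noise_cv = 0)
  design <- coculture_design(doses = 2, replicates = 1)
  counts <- simulate_coculture(design, truth, seed = 1)
  e <- oracle_coculture_expectation(truth, design, dose = 2)
  day4 <- subset(counts, timepoint == "post_treatment_day4")
  het4 <- subset(day4, mixture == "heterogeneous")
  hom4 <- subset(day4, mixture == "homogeneous")
  # heterogeneous control fraction outsurvives its homogeneous counterpart
  expect_gt(het4$count[het4$fraction_identity == "control_m"],
            hom4$count[1])
  expect_equal(het4$count[het4$fraction_identity == "control_m"],
               unname(e$het_day4[["def"]]))
  expect_equal(het4$count[het4$fraction_identity == "mir125b_m"],
               unname(e$het_day4[["prod"]]))
  # regrown heterogeneous population is dominated by control-derived cells
  reg <- subset(counts, timepoint == "regrown_confluent" &
                  mixture == "heterogeneous")
  expect_gt(reg$count[reg$fraction_identity == "control_m"],
            reg$count[reg$fraction_identity == "mir125b_m"])
  expect_equal(reg$count[reg$fraction_identity == "control_m"],
               unname(e$het_regrown[["def"]]))
})

test_that("regrowth conserves the confluency target exactly", {
  counts <- simulate_coculture(
    coculture_design(doses = c(0, 2, 5), replicates = 2,
                     confluency_target = 123456),
    truth_params(noise_cv = 0), seed = 7)
  reg <- subset(counts, timepoint == "regrown_confluent")
  totals <- tapply(reg$count, interaction(reg$mixture, reg$dose_nM, reg$replicate),
                   sum)
  expect_equal(as.numeric(totals), rep(123456, length(totals)), tolerance = 1e-9)
})

test_that("Monte-Carlo mean RS matches the closed form within 5%", {
  truth <- truth_params(B = 0.5, k = 0.05, h = 1, c = 0.3, s_A = 0.9,
                        noise_cv = 0.1)
  design <- coculture_design(doses = 2, replicates = 100)
  counts <- simulate_coculture(design, truth, seed = 42)
  rs <- relative_survival(counts)
  expected <- oracle_rs_rf_from_truth(truth, design, dose = 2)[["rs_alpha"]]
  expect_equal(mean(rs$rs_alpha), expected, tolerance = 0.05)
})

test_that("identical seeds give byte-identical exports; errors are raised on bad input", {
  d <- coculture_design(doses = c(0, 2))
  tr <- truth_params(noise_cv = 0.1)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_coculture_csv(simulate_coculture(d, tr, seed = 9), f1, seed = 9)
  write_coculture_csv(simulate_coculture(d, tr, seed = 9), f2, seed = 9)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_coculture_csv(f1)
  expect_equal(nrow(back), 2 * 2 * 3 * 2 * 2)  # mixtures x doses x reps x timepoints x tags
  expect_equal(attr(back, "truth")$noise_cv, 0.1)
  expect_error(truth_params(noise_cv = -0.1), class = "coopcell_error_param")
  expect_error(coculture_design(altruist_fraction = NA), class = "coopcell_error_param")
  expect_error(coculture_design(doses = -1), class = "coopcell_error_param")
})

test_that("benefit series is monotone in expectation and anchored at the baseline", {
  truth <- truth_params(noise_cv = 0)
  ser <- simulate_benefit_series(c(0, 0.5), truth, replicates = 1, seed = 1)
  expect_gte(ser$viability[ser$fraction == 0.5],
             ser$viability[ser$fraction == 0])
  # all-zero fractions: readouts equal the sigma0-driven baseline
  ser0 <- simulate_benefit_series(c(0, 0, 0), truth, dose_nM = 2,
                                  replicates = 1, seed = 1)
  expect_equal(ser0$viability, rep(2^(-2 / truth$dose_half), 3))
  # super-linear early rise of the percentage benefit
  pb10 <- (expected_viability(0.10, truth) - expected_viability(0, truth))
  pb50 <- (expected_viability(0.50, truth) - expected_viability(0, truth))
  expect_gt(pb10 / pb50, 0.10 / 0.50)
  expect_error(simulate_benefit_series(c(-0.1, 0.5)), class = "coopcell_error_param")
})
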