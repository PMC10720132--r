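make_counts <- function(hom_tagged, hom_untagged, het_tagged, het_untagged,
                        timepoint = "post_treatment_day4",
                        tag_assignment = "tag_control") {
  ident <- if (tag_assignment == "tag_control") {
    c(tagged = "control_m", untagged = "mir125b_m")
  } else {
    c(tagged = "mir125b_m", untagged = "control_m")
  }
  out <- tibble::tibble(
    mixture = rep(c("homogeneous", "heterogeneous"), each = 2),
    dose_nM = 2, replicate = 1L,
    timepoint = timepoint,
    tag = rep(c("tagged", "untagged"), 2),
    fraction_identity = c("control_m", "control_m", unname(ident)),
    count = c(hom_tagged, hom_untagged, het_tagged, het_untagged))
  class(out) <- c("coop_coculture", class(out))
  out
}

test_that("relative survival follows the homogeneous 1:1 normalization rule", {
  # identical survival everywhere
  expect_equal(relative_survival(make_counts(500, 500, 500, 500))$rs_alpha, 1)
  # hand-derived normalization example
  rs <- relative_survival(make_counts(450, 550, 600, 200))
  expect_equal(rs$rs_alpha, (600 * 550 / 450) / 550)
  expect_equal(rs$rs_alpha, 600 / 450)
  expect_equal(rs$normalization_factor, 550 / 450)
  expect_equal(rs$rs_beta, 200 / 550)
})

test_that("relative fitness applies the regrown normalization factor", {
  expect_equal(relative_fitness(make_counts(500, 500, 500, 500,
                                            "regrown_confluent"))$rf_alpha, 1)
  rf <- relative_fitness(make_counts(400, 600, 480, 360, "regrown_confluent"))
  expect_equal(rf$rf_alpha, (480 * 1.5) / 360)
  # reciprocal tagging: control in the untagged channel
  rf2 <- relative_fitness(make_counts(400, 600, 360, 480, "regrown_confluent",
                                      tag_assignment = "tag_altruist"))
  expect_equal(rf2$rf_alpha, 480 / (360 * 1.5))
})

test_that("relative fitness from the generator matches the compounded-cost closed form", {
  truth <- truth_params(c = 0.3, noise_cv = 0)
  design <- coculture_design(doses = 0, replicates = 1)
  counts <- simulate_coculture(design, truth, seed = 1)
  rf <- relative_fitness(counts)
  expected <- oracle_rs_rf_from_truth(truth, design, dose = 0)[["rf_alpha"]]
  expect_equal(rf$rf_alpha, expected, tolerance = 1e-9)
  expect_gt(rf$rf_alpha, 1)
})

test_that("reciprocal tagging and count rescaling leave RS and RF unchanged", {
  truth <- truth_params(noise_cv = 0)
  for (dose in c(0.8, 2)) {
    a <- simulate_coculture(coculture_design(doses = dose, replicates = 1,
                                             tag_assignment = "tag_control"),
                            truth, seed = 1)
    b <- simulate_coculture(coculture_design(doses = dose, replicates = 1,
                                             tag_assignment = "tag_altruist"),
                            truth, seed = 1)
    expect_equal(relative_survival(a)$rs_alpha, relative_survival(b)$rs_alpha)
    expect_equal(relative_fitness(a)$rf_alpha, relative_fitness(b)$rf_alpha)
    a_scaled <- a
    a_scaled$count <- a_scaled$count * 7.3
    expect_equal(relative_survival(a_scaled)$rs_alpha,
                 relative_survival(a)$rs_alpha)
    expect_equal(relative_fitness(a_scaled)$rf_alpha,
                 relative_fitness(a)$rf_alpha)
  }
})

test_that("degenerate and unmatched inputs raise typed errors; zero progeny is an Inf sentinel", {
  expect_error(relative_survival(make_counts(0, 500, 500, 500)),
               class = "coopcell_error_degenerate")
  solo <- make_counts(500, 500, 500, 500)[1:2, ]
  expect_error(relative_survival(solo), class = "coopcell_error_pairing")
  expect_warning(
    relative_fitness(make_counts(500, 500, 500, 0, "regrown_confluent")),
    "Inf sentinel")
  rf <- suppressWarnings(
    relative_fitness(make_counts(500, 500, 500, 0, "regrown_confluent")))
  expect_identical(rf$rf_alpha, Inf)
})

test_that("xenograft relative survival matches direct substitution", {
  expect_equal(rs_alpha_xenograft(0.7, 2e8, 0.5, 2e8), 1.4)
  expect_equal(rs_alpha_xenograft(0.5, 1e8, 0.5, 1e8), 1)
})

test_that("social-behaviour matrix follows the Hamilton sign convention", {
  expect_equal(classify_social_behavior(1.4, 1.6)$label, "altruism")
  expect_equal(classify_social_behavior(1.4, 0.7)$label, "mutual_benefit")
  expect_equal(classify_social_behavior(0.7, 0.6)$label, "selfishness")
  expect_equal(classify_social_behavior(0.7, 1.5)$label, "spite")
  expect_equal(classify_social_behavior(1.01, 0.99, tol = 0.05)$label, "neutral")
  # t-test mode: tight replicates around (1.2, 1.3) classify as altruism
  rs <- c(1.19, 1.21, 1.2); rf <- c(1.29, 1.31, 1.3)
  expect_equal(classify_social_behavior(rs, rf, method = "t_test")$label,
               "altruism")
  expect_error(classify_social_behavior(-1, 1), class = "coopcell_error_param")
})

test_that("percentage and marginal benefit match direct substitution", {
  pb <- percentage_benefit(data.frame(percent = c(0, 10, 50),
                                      viability = c(0.40, 0.75, 0.90)))
  expect_equal(pb$percentage_benefit[pb$percent == 10], 70)
  expect_equal(pb$percentage_benefit[pb$percent == 0], 0)
  expect_equal(pb$percentage_benefit[pb$percent == 50], 100)
  mb <- marginal_benefit(data.frame(percent = c(0, 1),
                                    percentage_benefit = c(0, 30)))
  expect_equal(mb$marginal_benefit, 15)
  expect_equal(mb$category, 0.5)
  mb2 <- marginal_benefit(data.frame(percent = c(10, 30),
                                     percentage_benefit = c(80, 95)))
  expect_equal(mb2$marginal_benefit, 15 / 21)
  expect_equal(mb2$category, 20)
  expect_equal(marginal_benefit(data.frame(
    percent = c(10, 30), percentage_benefit = c(50, 50)))$marginal_benefit, 0)
  expect_error(percentage_benefit(data.frame(percent = c(0, 50),
                                             viability = c(0.4, 0.4))),
               class = "coopcell_error_degenerate")
  expect_error(marginal_benefit(data.frame(percent = c(10, 10),
                                           percentage_benefit = c(1, 2))),
               class = "coopcell_error_param")
})

test_that("rescue, viability-change, reporter and CRISPRi formulas match their oracles", {
  expect_equal(percent_rescue(1.6, 1.3, 1.0), 50)
  expect_equal(percent_rescue(1.6, 1.6, 1.0), 0)
  expect_equal(percent_rescue(1.6, 1.0, 1.0), 100)
  expect_error(percent_rescue(1.2, 1.1, 1.2), class = "coopcell_error_degenerate")
  expect_equal(percent_change_viability(0.5, 1.0, 0.9, 1.0), -40)
  expect_equal(percent_change_viability(1.2, 1.0, 1.2, 1.0), 0)
  expect_error(percent_change_viability(1, 0, 1, 1), class = "coopcell_error_degenerate")
  expect_equal(percent_reduction_nfkb(2.0, 1.4, 1.0), 60)
  expect_equal(percent_reduction_nfkb(2.0, 2.0, 1.0), 0)
  expect_equal(percent_reduction_nfkb(2.0, 1.0, 1.0), 100)
  expect_error(percent_reduction_nfkb(1.0, 0.9, 1.0), class = "coopcell_error_degenerate")
  expect_equal(percent_effect_crispri(0.6, 0.8), -25)
  expect_equal(percent_effect_crispri(1.0, 0.8), 25)
  expect_equal(percent_effect_crispri(0.8, 0.8), 0)
  expect_error(percent_effect_crispri(1, 0), class = "coopcell_error_degenerate")
})

test_that("every formula matches its independent oracle on randomized inputs", {
  set.seed(99)
  n <- 1000
  for (i in seq_len(n)) {
    r <- runif(8, 0.1, 10)
    expect_equal(percent_rescue(r[1] + 1, r[2], r[3]),
                 oracle_percent_rescue(r[1] + 1, r[2], r[3]), tolerance = 1e-12)
    expect_equal(percent_change_viability(r[1], r[2], r[3], r[4]),
                 oracle_percent_change_viability(r[1], r[2], r[3], r[4]),
                 tolerance = 1e-12)
    expect_equal(percent_effect_crispri(r[5], r[6]),
                 oracle_percent_effect_crispri(r[5], r[6]), tolerance = 1e-12)
  }
})

test_that("mixture expectation is the weighted mean, with a sane one-sample test", {
  e <- expected_mixture_viability(c(0.4, 0.8), c(0.1, 0.9))
  expect_equal(e$expectation, 0.76)
  e1 <- expected_mixture_viability(c(0.5, 0.9), c(1, 0))
  expect_equal(e1$expectation, 0.5)
  obs <- rep(0.76, 3)
  et <- expected_mixture_viability(c(0.4, 0.8), c(0.1, 0.9), observed = obs)
  expect_equal(et$t, 0)
  expect_error(expected_mixture_viability(c(0.4, 0.8), c(0.2, 0.9)),
               class = "coopcell_error_param")
})
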