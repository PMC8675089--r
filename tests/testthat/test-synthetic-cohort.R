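test_that("cohort simulation is reproducible and structurally complete", {
  d <- generate_design(seed = 61)
  cfg <- cohort_config(n_per_sex = 5)
  c1 <- simulate_cohort(d, cfg, seed = 62)
  c2 <- simulate_cohort(d, cfg, seed = 62)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$choices, c2$choices)
  p <- c1$participants
  expect_equal(nrow(p), 10)
  expect_equal(sum(p$sex == "male"), 5)
  # every participant has every trial exactly once, in randomized order
  for (pid in p$pid) {
    sub <- c1$choices[c1$choices$pid == pid, ]
    expect_setequal(sub$trial_id, d$trial_id)
  }
  orders <- split(c1$choices$trial_id, c1$choices$pid)
  expect_gt(length(unique(orders)), 1)
  expect_true(all(unlist(p[c("q_a", "q_b", "q_c")]) %in% 1:5))
  expect_true(all(p$true_gamma > 0 & p$true_alpha > 0))
})

test_that("degenerate selfish cohorts cooperate at the closed-form rate", {
  d <- generate_design(seed = 63)
  # gamma = alpha = 0, fixed reward weight, no intercept noise
  cfg <- cohort_config(n_per_sex = 150,
                       gamma_base_meanlog = log(1e-12),
                       gamma_resid_sdlog = 0, med_b = 0, med_a = 0,
                       agreeableness_effect = 0,
                       conscientiousness_male_effect = 0,
                       alpha_base_meanlog = log(1e-12), alpha_sdlog = 0,
                       alpha_female_shift = 0,
                       reward_meanlog = log(0.003), reward_sdlog = 0,
                       intercept_sd = 0)
  cohort <- simulate_cohort(d, cfg, seed = 64)
  expected <- mean(plogis(0.003 * compute_regressors(d)$reward))
  observed <- mean(cohort$choices$choice)
  # Monte-Carlo SE of the mean over 300 x 45 Bernoulli draws is < 0.005
  expect_lt(abs(observed - expected), 3 * 0.005)
})

test_that("the configured sex shift in gamma is realized and detectable", {
  d <- generate_design(seed = 65)
  cfg <- cohort_config(n_per_sex = 400)
  cohort <- simulate_cohort(d, cfg, seed = 66)
  p <- cohort$participants
  shift <- mean(log(p$true_gamma[p$sex == "male"])) -
    mean(log(p$true_gamma[p$sex == "female"]))
  # implied shift = a*b + c' = 0.5; SE of the difference ~ 0.047
  expect_lt(abs(shift - (cfg$med_a * cfg$med_b + cfg$med_c_prime)), 0.15)
})

test_that("questionnaire items track gamma at about the configured correlation", {
  gamma <- trustgame:::with_seed(67, rlnorm(1000, log(0.002), 0.6))
  items <- trustgame:::with_seed(68, simulate_questionnaire(gamma, rho = 0.35))
  for (j in 1:3) {
    r <- cor(gamma, items[, j], method = "spearman")
    expect_lt(abs(r - 0.35), 0.1)
  }
  expect_true(all(items %in% 1:5))
})

test_that("covariate sample means match the reference table within 3 SE", {
  d <- generate_design(seed = 69)
  cohort <- simulate_cohort(d, cohort_config(n_per_sex = 1000), seed = 70)
  p <- cohort$participants
  ref <- covariate_reference()
  for (i in seq_len(nrow(ref))) {
    v <- ref$variable[i]
    for (sx in c("male", "female")) {
      mu <- if (sx == "male") ref$male_mean[i] else ref$female_mean[i]
      sd_ <- if (sx == "male") ref$male_sd[i] else ref$female_sd[i]
      xb <- mean(p[[v]][p$sex == sx])
      # rounding/clipping of ordinal items adds < 1 SE-unit of slack
      expect_lt(abs(xb - mu), 3 * sd_ / sqrt(1000) + 0.05 * sd_)
    }
  }
})

test_that("mediator construction follows M = a*sex + noise", {
  sex <- rep(c(1, 0), each = 2000)
  m <- trustgame:::with_seed(71, simulate_mediator(sex, a = 1.0,
                                                   noise_sd = 1.0))
  expect_lt(abs(mean(m[sex == 1]) - mean(m[sex == 0]) - 1.0), 0.1)
  expect_lt(abs(sd(m[sex == 0]) - 1.0), 0.07)
})

test_that("cohort CSV pair round-trips", {
  d <- generate_design(seed = 72)
  cohort <- simulate_cohort(d, cohort_config(n_per_sex = 4), seed = 73)
  prefix <- file.path(withr::local_tempdir(), "cohort")
  write_cohort(cohort, prefix)
  back <- read_cohort(prefix)
  expect_identical(back$choices$choice, cohort$choices$choice)
  expect_identical(back$choices$trial_id, cohort$choices$trial_id)
  expect_equal(back$participants$true_gamma, cohort$participants$true_gamma,
               tolerance = 1e-12)
  expect_identical(back$participants$sex, cohort$participants$sex)
  expect_error(read_cohort(file.path(tempdir(), "nonexistent")),
               "missing cohort file")
})
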