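test_that("Firth estimates maximize the Jeffreys-penalized likelihood (grid oracle)", {
  X <- cbind(1, c(-1.2, -0.5, 0.3, 0.8, 1.5, 2.1))
  y <- c(0, 1, 0, 1, 1, 1)
  oracle <- oracle_grid_max(function(b) oracle_penalized_loglik(b, X, y))
  fit <- fit_logistic(X, y, method = "firth")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$coefficients - oracle)), 1e-3)
})

test_that("Firth stays finite under complete separation where the MLE diverges", {
  X <- cbind(1, c(-2, -1, -0.5, 0.5, 1, 2))
  y <- c(0, 0, 0, 1, 1, 1)
  firth <- fit_logistic(X, y, method = "firth")
  mle <- fit_logistic(X, y, method = "mle")
  expect_true(firth$converged)
  expect_lt(abs(firth$coefficients[2]), 5)
  expect_false(mle$converged)
  expect_gt(abs(mle$coefficients[2]), 10)
})

test_that("the intercept-only MLE is the empirical logit", {
  for (k in c(3, 7)) {
    y <- c(rep(1, k), rep(0, 10 - k))
    fit <- fit_logistic(matrix(1, 10, 1), y, method = "mle")
    expect_equal(unname(fit$coefficients), qlogis(k / 10), tolerance = 1e-7)
  }
})

test_that("MLE agrees with stats::glm, and with Firth on ample separation-free data", {
  d <- generate_design(seed = 31)
  big <- replicate_design(d, 10)  # 450 trials
  p <- choice_prob(big, agent_params(gamma = 0.002, alpha = 0.001,
                                     reward_weight = 0.003))
  y <- trustgame:::with_seed(32, rbinom(nrow(big), 1, p))
  reg <- compute_regressors(big)
  X <- regressor_matrix(reg, "RwGuIq")
  mle <- fit_logistic(X, y, method = "mle")
  ref <- glm(y ~ reward + guilt + inequity, family = binomial(), data = reg)
  expect_equal(unname(mle$coefficients), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(mle$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  firth <- fit_logistic(X, y, method = "firth")
  expect_true(all(abs(firth$coefficients - mle$coefficients) < 2 * mle$se))
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  d <- generate_design(seed = 33)
  reg <- compute_regressors(d)
  X <- regressor_matrix(reg, "RwGuIq")
  X <- cbind(X, Dup = X[, "Gu"])
  y <- rep(c(0, 1), length.out = nrow(X))
  expect_error(fit_logistic(X, y), "collinear.*Dup")
})

test_that("BIC follows k ln(n) - 2 loglik and is ordered with the likelihood ratio", {
  expect_equal(bic_value(0, 4, 45), 4 * log(45))
  expect_equal(4 * log(45), 15.228, tolerance = 1e-3)
  # adding a useless parameter at equal likelihood always worsens BIC
  expect_gt(bic_value(-20, 5, 45), bic_value(-20, 4, 45))
  d <- generate_design(seed = 34)
  p <- choice_prob(d, agent_params(gamma = 0.004, alpha = 0.002,
                                   reward_weight = 0.003))
  y <- trustgame:::with_seed(35, rbinom(45, 1, p))
  full <- fit_model(d, y, "RwGuIq", method = "mle")
  null <- fit_model(d, y, "Rw", method = "mle")
  expect_gte(full$loglik, null$loglik)  # nested
  expect_equal(full$bic - null$bic,
               2 * log(45) - 2 * (full$loglik - null$loglik))
  expect_gte(full$mcfadden_r2, 0)
})

test_that("fit_model aligns shuffled per-trial choice tables by trial id", {
  d <- generate_design(seed = 36)
  p <- choice_prob(d, agent_params(gamma = 0.003, reward_weight = 0.003))
  y <- trustgame:::with_seed(37, rbinom(45, 1, p))
  shuffled <- trustgame:::with_seed(38, sample(45))
  tab <- data.frame(trial_id = d$trial_id[shuffled],
                    choice = ifelse(y[shuffled] == 1, "Cooperate", "Defect"))
  f1 <- fit_model(d, y)
  f2 <- fit_model(d, tab)
  expect_equal(f1$betas, f2$betas)
})

test_that("cross-validated selection is reproducible and generalizes worse than training", {
  d <- generate_design(seed = 41)
  p <- choice_prob(d, agent_params(gamma = 0.004, alpha = 0.002,
                                   reward_weight = 0.003))
  y <- trustgame:::with_seed(42, rbinom(45, 1, p))
  cv1 <- cv_model_select(d, y, n_repeats = 10, seed = 43)
  cv2 <- cv_model_select(d, y, n_repeats = 10, seed = 43)
  expect_identical(cv1$heldout_nll, cv2$heldout_nll)
  expect_identical(cv1$best_model, cv2$best_model)
  # held-out NLL exceeds training NLL on the same per-observation scale
  expect_true(all(cv1$table$mean_pred_nll >= cv1$table$mean_train_nll))
  # bootstrap resampling flavor runs and is also seeded
  cb <- cv_model_select(d, y, n_repeats = 5, seed = 44,
                        resample = "bootstrap")
  expect_identical(cb$table$mean_pred_nll,
                   cv_model_select(d, y, n_repeats = 5, seed = 44,
                                   resample = "bootstrap")$table$mean_pred_nll)
})

test_that("noise-only agents select the parsimonious reward model", {
  d <- generate_design(seed = 45)
  wins <- trustgame:::with_seed(46, {
    vapply(1:8, function(i) {
      y <- rbinom(45, 1, choice_prob(d, agent_params(reward_weight = 0.003)))
      cv <- cv_model_select(d, y, n_repeats = 20,
                            seed = 4600 + i)
      cv$best_model
    }, character(1))
  })
  # Rw (or a guilt-free sibling) should dominate; the 5-parameter
  # Fehr-Schmidt-plus-guilt model should not win for these selfish agents
  expect_gte(sum(wins == "Rw"), 3)
  expect_lt(sum(wins == "RwGuIpIn"), 4)
})

test_that("uneven trial counts split into largest equal folds plus round-robin", {
  expect_equal(trustgame:::fold_sizes(45, 3), c(15, 15, 15))
  expect_equal(trustgame:::fold_sizes(46, 3), c(16, 15, 15))
  expect_equal(trustgame:::fold_sizes(47, 3), c(16, 16, 15))
  d <- generate_design(seed = 47)
  d44 <- trust_design(as.data.frame(d)[1:44, ], validate = FALSE)
  y <- trustgame:::with_seed(48,
    rbinom(44, 1, choice_prob(d44, agent_params(reward_weight = 0.003))))
  cv <- cv_model_select(d44, y, n_repeats = 3, seed = 49,
                        models = model_space()[c("Rw", "RwGuIq")])
  expect_true(all(is.finite(cv$table$mean_pred_nll)))
})

test_that("fit_cohort tabulates one row per participant plus the pooled fit", {
  d <- generate_design(seed = 51)
  cohort <- simulate_cohort(d, cohort_config(n_per_sex = 3), seed = 52)
  tab <- fit_cohort(cohort$choices, d, "RwGuIq", pooled = TRUE)
  expect_equal(nrow(tab), 7)
  expect_true("pooled" %in% tab$pid)
  expect_true(all(is.finite(tab$beta_guilt)))
  expect_true(all(is.na(tab$beta_iq_pos)))  # not in RwGuIq
  tab2 <- fit_cohort(cohort$choices, d, "RwGuIpIn")
  expect_true(all(is.finite(tab2$beta_iq_pos)))
  expect_true(all(is.na(tab2$beta_inequity)))
})
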