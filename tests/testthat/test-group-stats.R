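test_that("Welch statistic matches the hand-computed Satterthwaite formulae", {
  x <- c(1.1, 2.3, 0.7)
  y <- c(2.0, 2.2, 3.9)
  w <- welch_test(x, y)
  # closed-form oracle
  se2 <- var(x) / 3 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(w$statistic, t_hand, tolerance = 1e-10)
  expect_equal(w$df, df_hand, tolerance = 1e-10)
  expect_equal(w$p_value, p_hand, tolerance = 1e-10)
})

test_that("Welch edge cases: identical groups and the equal-variance df limit", {
  x <- c(1, 2, 3, 4)
  w <- welch_test(x, x)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  # equal variances and equal n give df = 2n - 2 exactly
  y <- x + 10  # same variance, shifted mean
  expect_equal(welch_test(x, y)$df, 2 * 4 - 2)
  # Satterthwaite df bounds
  a <- rnorm(8); b <- rnorm(20, sd = 4)
  w2 <- trustgame:::with_seed(81, welch_test(a, b))
  expect_gte(w2$df, min(8, 20) - 1)
  expect_lte(w2$df, 8 + 20 - 2)
})

test_that("questionnaire correlations match cor.test in both flavors", {
  set.seed(82)
  bg <- rnorm(60)
  items <- data.frame(q_a = round(pmin(pmax(bg + rnorm(60), -2), 2)) + 3,
                      q_b = sample(1:5, 60, replace = TRUE),
                      q_c = round(pmin(pmax(0.5 * bg + rnorm(60), -2), 2)) + 3)
  out <- questionnaire_correlation(bg, items)
  for (i in 1:3) {
    ref <- cor.test(bg, items[[i]])
    expect_equal(out$r[i], unname(ref$estimate))
    expect_equal(out$p[i], ref$p.value)
  }
  outs <- questionnaire_correlation(bg, items, method = "spearman")
  ref <- cor.test(bg, items$q_a, method = "spearman", exact = FALSE)
  expect_equal(outs$r[1], unname(ref$estimate))
})

simulate_regression_cohort <- function(n, agree_effect = 0,
                                       consc_male_effect = 0,
                                       noise_sd = 1, seed = 1) {
  trustgame:::with_seed(seed, {
    sex <- rep(c("male", "female"), length.out = n)
    male <- as.numeric(sex == "male")
    covs <- as.data.frame(replicate(11, rnorm(n)))
    names(covs) <- c("Neuroticism", "Extraversion", "Openness",
                     "Agreeableness", "Conscientiousness", "age",
                     "SelfEduHistory", "ParentsEduHistory", "Income",
                     "Occupation", "SubjectiveSES")
    y <- agree_effect * covs$Agreeableness +
      consc_male_effect * male * covs$Conscientiousness +
      rnorm(n, 0, noise_sd)
    list(covariates = cbind(data.frame(sex = sex), covs), y = y)
  })
}

test_that("interaction regression agrees with stats::lm on the same model matrix", {
  dat <- simulate_regression_cohort(300, agree_effect = 0.3, seed = 83)
  rep_ <- interaction_regression(dat$covariates, dat$y, standardize = FALSE)
  male <- as.numeric(dat$covariates$sex == "male")
  df <- dat$covariates[-1]
  names(df) <- paste0("c", seq_along(df))
  df_int <- df * male
  names(df_int) <- paste0("i", seq_along(df))
  ref <- lm(dat$y ~ ., data = cbind(df, df_int))
  s <- summary(ref)
  expect_equal(unname(rep_$coefficients$estimate),
               unname(coef(ref)[c(1, 2:23)]), tolerance = 1e-10)
  expect_equal(unname(rep_$coefficients$se), unname(s$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(rep_$adj_r2, s$adj.r.squared, tolerance = 1e-10)
})

test_that("configured covariate effects are recovered with correct specificity", {
  hits_agree <- 0; false_int <- 0; reps <- 10
  for (i in seq_len(reps)) {
    dat <- simulate_regression_cohort(400, agree_effect = 0.4,
                                      seed = 840 + i)
    rep_ <- interaction_regression(dat$covariates, dat$y)
    tab <- rep_$coefficients
    a_row <- tab[tab$term == "Agreeableness", ]
    expect_lt(abs(a_row$estimate - 0.4), 2.5 * a_row$se + 0.05)
    if (a_row$p < 0.05) hits_agree <- hits_agree + 1
    ints <- tab[grepl("^Sex:", tab$term), ]
    false_int <- false_int + sum(ints$p < 0.05)
  }
  expect_gte(hits_agree, 9)              # configured effect is detected
  expect_lte(false_int / (11 * reps), 0.12)  # interactions stay near null rate
  # a men-only conscientiousness effect loads on the interaction term
  dat2 <- simulate_regression_cohort(3000, consc_male_effect = 0.3,
                                     seed = 85)
  tab2 <- interaction_regression(dat2$covariates, dat2$y)$coefficients
  sc <- tab2[tab2$term == "Sex:Conscientiousness", ]
  expect_gt(sc$estimate, 0)
  expect_lt(sc$p, 0.01)
})

test_that("interaction regression input contracts are enforced", {
  dat <- simulate_regression_cohort(40, seed = 86)
  expect_error(interaction_regression(dat$covariates[-2], dat$y),
               "lack column")
  # duplicated covariate triggers the collinearity error path
  bad <- dat$covariates
  bad$Openness <- bad$Neuroticism
  expect_error(suppressWarnings(interaction_regression(bad, dat$y)))
  # more coefficients than observations
  expect_error(interaction_regression(dat$covariates[1:20, ], dat$y[1:20]),
               "cannot identify")
  # listwise deletion is reported
  datm <- dat$covariates
  datm$Income[3] <- NA
  rep_ <- interaction_regression(datm, dat$y)
  expect_equal(rep_$n_dropped, 1)
  expect_equal(rep_$n_obs, 39)
})

test_that("mediation decomposition c - c' = a*b holds exactly on any dataset", {
  for (s in 87:89) {
    dat <- trustgame:::with_seed(s, {
      x <- rep(0:1, each = 15)
      m <- 0.8 * x + rnorm(30)
      y <- 0.5 * m + 0.2 * x + rnorm(30)
      list(x = x, m = m, y = y)
    })
    med <- mediate(dat$x, dat$m, dat$y, n_boot = 200, seed = s)
    expect_equal(med$path_c$estimate - med$path_c_prime$estimate,
                 med$indirect$estimate, tolerance = 1e-12)
  }
})

test_that("mediation bootstrap is seeded and the null indirect effect is covered", {
  x <- rep(0:1, each = 20)
  dat <- trustgame:::with_seed(90, list(m = rnorm(40) + x,
                                        y = rnorm(40) + 0.5 * x))  # b = 0
  m1 <- mediate(x, dat$m, dat$y, n_boot = 500, seed = 91)
  m2 <- mediate(x, dat$m, dat$y, n_boot = 500, seed = 91)
  expect_identical(m1$indirect, m2$indirect)
  expect_true(m1$indirect$ci[1] <= 0 && m1$indirect$ci[2] >= 0)
  expect_gt(m1$indirect$p, 0.05)
  expect_false(m1$three_test_significant)
  # BCa flavor runs and gives a similar interval
  mb <- mediate(x, dat$m, dat$y, n_boot = 500, seed = 91, type = "bca")
  expect_lt(abs(mb$indirect$ci[1] - m1$indirect$ci[1]), 0.3)
})

test_that("mediation rejects degenerate inputs", {
  x <- rep(0:1, each = 10)
  expect_error(mediate(x, rep(1, 20), rnorm(20), n_boot = 10),
               "nonzero variance")
  expect_error(mediate(x[1:5], rnorm(5), rnorm(5), n_boot = 10),
               "at least 10")
})
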