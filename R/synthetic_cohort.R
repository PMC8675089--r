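#' Reference covariate descriptives for a large online cohort
#'
#' Per-sex means and standard deviations used as the default generative
#' targets for the demographic, Big Five and socioeconomic covariates of a
#' simulated cohort. The values emulate the descriptive statistics of a
#' large Japanese online sample (about 2000 men and 2700 women): Big Five
#' scores on the raw inventory scale, educational-history, income,
#' occupation and subjective socioeconomic-status items on their ordinal
#' scales.
#'
#' @return Data frame with columns \code{variable}, \code{male_mean},
#'   \code{male_sd}, \code{female_mean}, \code{female_sd}.
#' @export
covariate_reference <- function() {
  data.frame(
    variable = c("age", "Neuroticism", "Extraversion", "Openness",
                 "Agreeableness", "Conscientiousness", "SelfEduHistory",
                 "ParentsEduHistory", "Income", "Occupation",
                 "SubjectiveSES"),
    male_mean = c(39.585, 47.433, 45.426, 50.699, 42.780, 49.068,
                  5.3197, 4.6511, 2.7296, 2.2477, 5.2513),
    male_sd = c(15.318, 9.7900, 9.1431, 9.4570, 10.636, 9.3706,
                1.1422, 1.4190, 1.4772, 1.6859, 2.0408),
    female_mean = c(36.751, 46.731, 46.244, 47.640, 44.333, 48.076,
                    5.0431, 4.7947, 1.6153, 3.4439, 5.2700),
    female_sd = c(15.273, 9.9606, 9.2942, 9.3566, 10.448, 9.3299,
                  1.0410, 1.3323, 0.9299, 1.8253, 1.7901)
  )
}

#' Configuration of the synthetic-cohort generator
#'
#' Defines the ground-truth population from which simulated trustees are
#' drawn. Guilt sensitivity \eqn{\gamma} and inequity sensitivity
#' \eqn{\alpha} are log-normal (guaranteeing positivity); their scales are
#' set so that the fitted choice-model coefficients land in the
#' per-yen magnitudes typical of this task (a few times \eqn{10^{-3}}).
#' The sex difference in \eqn{\gamma} flows through a scalar connectivity
#' mediator: \eqn{M = a \cdot \mathrm{male} + \epsilon}, and
#' \eqn{\log\gamma = \mu_\gamma + b M + c' \cdot \mathrm{male} + \kappa_A
#' z(\mathrm{Agreeableness}) + \kappa_C \cdot \mathrm{male} \cdot
#' z(\mathrm{Conscientiousness}) + \epsilon}, so the male-female shift in
#' mean \eqn{\log\gamma} equals \eqn{ab + c'} (complete mediation when
#' \eqn{c' = 0}, the default). Women are shifted upward in \eqn{\alpha}.
#' The default shift of 0.5 on the log scale (about a factor 1.65)
#' corresponds to a moderate standardized group difference, the size at
#' which a 26-versus-26 contrast reaches significance at about the 0.05
#' level with moderate power.
#'
#' @param n_per_sex Participants per sex (default 26).
#' @param gamma_base_meanlog Mean of \eqn{\log\gamma} for women at average
#'   covariates (default \code{log(0.0015)}).
#' @param gamma_resid_sdlog Residual SD of \eqn{\log\gamma} (default 0.45;
#'   together with the mediator path this gives a total spread of about
#'   0.65 on the log scale).
#' @param alpha_base_meanlog Mean \eqn{\log\alpha} for men (default
#'   \code{log(0.0008)}).
#' @param alpha_female_shift Upward shift of female \eqn{\log\alpha}
#'   (default 0.5).
#' @param alpha_sdlog SD of \eqn{\log\alpha} (default 0.6).
#' @param reward_meanlog,reward_sdlog Log-normal parameters of the reward
#'   weight (defaults \code{log(0.003)}, 0.3).
#' @param intercept_mean,intercept_sd Normal parameters of the choice bias
#'   (defaults 0, 0.3).
#' @param agreeableness_effect Effect of one SD of Agreeableness on
#'   \eqn{\log\gamma}, both sexes (default 0.08).
#' @param conscientiousness_male_effect Effect of one SD of
#'   Conscientiousness on \eqn{\log\gamma}, men only (default 0.12).
#' @param med_a,med_b,med_c_prime,med_noise_sd Mediation paths: sex-to-
#'   mediator \eqn{a}, mediator-to-\eqn{\log\gamma} \eqn{b}, direct effect
#'   \eqn{c'}, and mediator noise SD (defaults 1, 0.5, 0, 1).
#' @param questionnaire_rho Latent correlation between \eqn{\log\gamma} and
#'   each post-task questionnaire item (default 0.35).
#' @param covariates Per-sex covariate means/SDs
#'   (default [covariate_reference()]).
#' @return A \code{cohort_config} list.
#' @export
cohort_config <- function(n_per_sex = 26L,
                          gamma_base_meanlog = log(0.0015),
                          gamma_resid_sdlog = 0.45,
                          alpha_base_meanlog = log(0.0008),
                          alpha_female_shift = 0.5,
                          alpha_sdlog = 0.6,
                          reward_meanlog = log(0.003),
                          reward_sdlog = 0.3,
                          intercept_mean = 0,
                          intercept_sd = 0.3,
                          agreeableness_effect = 0.08,
                          conscientiousness_male_effect = 0.12,
                          med_a = 1.0,
                          med_b = 0.5,
                          med_c_prime = 0.0,
                          med_noise_sd = 1.0,
                          questionnaire_rho = 0.35,
                          covariates = covariate_reference()) {
  cfg <- list(n_per_sex = as.integer(n_per_sex),
              gamma_base_meanlog = gamma_base_meanlog,
              gamma_resid_sdlog = gamma_resid_sdlog,
              alpha_base_meanlog = alpha_base_meanlog,
              alpha_female_shift = alpha_female_shift,
              alpha_sdlog = alpha_sdlog,
              reward_meanlog = reward_meanlog,
              reward_sdlog = reward_sdlog,
              intercept_mean = intercept_mean,
              intercept_sd = intercept_sd,
              agreeableness_effect = agreeableness_effect,
              conscientiousness_male_effect = conscientiousness_male_effect,
              med_a = med_a, med_b = med_b, med_c_prime = med_c_prime,
              med_noise_sd = med_noise_sd,
              questionnaire_rho = questionnaire_rho,
              covariates = covariates)
  stopifnot(cfg$n_per_sex >= 1L,
            cfg$gamma_resid_sdlog >= 0, cfg$alpha_sdlog >= 0,
            cfg$med_noise_sd >= 0,
            abs(cfg$questionnaire_rho) <= 1)
  structure(cfg, class = "cohort_config")
}

# Ordinal covariates are rounded and clipped to plausible scale ranges;
# Big Five scores stay continuous.
covariate_post <- list(
  age = function(x) pmin(pmax(round(x), 18), 80),
  SelfEduHistory = function(x) pmin(pmax(round(x), 1), 9),
  ParentsEduHistory = function(x) pmin(pmax(round(x), 1), 9),
  Income = function(x) pmin(pmax(round(x), 0), 12),
  Occupation = function(x) pmin(pmax(round(x), 1), 9),
  SubjectiveSES = function(x) pmin(pmax(round(x), 1), 10)
)

#' Simulate post-task questionnaire items correlated with guilt sensitivity
#'
#' Generates three ordinal items (1-5) through a latent Gaussian copula:
#' each item's latent score is \code{rho} times the standardized
#' \eqn{\log(\gamma + \epsilon)} plus independent noise, thresholded at the
#' standard-normal quintiles. The three items mirror post-task probes of
#' (a) understanding the partner's intention, (b) awareness that defecting
#' reduces the partner's expected payoff, and (c) felt guilt about doing
#' so.
#'
#' @param gamma Vector of guilt sensitivities (positive).
#' @param rho Target latent correlation with \eqn{\log\gamma}.
#' @return Integer matrix with columns \code{q_a}, \code{q_b}, \code{q_c}.
#' @export
simulate_questionnaire <- function(gamma, rho = 0.35) {
  n <- length(gamma)
  z <- as.numeric(scale(log(gamma + 1e-12)))
  if (n < 2L || !is.finite(stats::sd(log(gamma + 1e-12))) ||
      stats::sd(log(gamma + 1e-12)) == 0) {
    z <- rep(0, n)
  }
  cuts <- stats::qnorm(c(0.2, 0.4, 0.6, 0.8))
  items <- vapply(1:3, function(j) {
    latent <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    findInterval(latent, cuts) + 1L
  }, integer(n))
  if (n == 1L) items <- matrix(items, nrow = 1L)
  colnames(items) <- c("q_a", "q_b", "q_c")
  items
}

#' Simulate the scalar connectivity mediator
#'
#' \eqn{M = a \cdot \mathrm{sex} + \epsilon}, \eqn{\epsilon \sim N(0,
#' \sigma^2)}: a per-participant scalar surrogate for the functional
#' connectivity that mediates the sex difference in guilt sensitivity.
#'
#' @param sex_indicator 0/1 vector (1 = the sex with the larger mediator
#'   mean).
#' @param a Sex-to-mediator path coefficient.
#' @param noise_sd Residual SD.
#' @return Numeric vector of mediator values.
#' @export
simulate_mediator <- function(sex_indicator, a = 1.0, noise_sd = 1.0) {
  a * sex_indicator + stats::rnorm(length(sex_indicator), 0, noise_sd)
}

#' Simulate a ground-truth cohort of trustees
#'
#' Draws participants with sex-specific guilt and inequity sensitivities,
#' covariates matching the configured per-sex means/SDs, questionnaire
#' items correlated with \eqn{\log\gamma}, a connectivity mediator carrying
#' the sex difference in \eqn{\gamma}, and per-trial Cooperate/Defect
#' choices drawn Bernoulli from the logistic choice rule. Each
#' participant's trial presentation order is independently randomized (the
#' choice table rows are in presentation order; \code{trial_id} links back
#' to the design).
#'
#' @param design A trust-game design.
#' @param config A [cohort_config()].
#' @param seed Integer seed; equal seeds give identical cohorts.
#' @return A \code{trust_cohort} list with elements \code{participants}
#'   (one row per participant: identifiers, sex, covariates, questionnaire
#'   items, mediator, and the true generative parameters \code{true_gamma},
#'   \code{true_alpha}, \code{true_reward_weight}, \code{true_intercept})
#'   and \code{choices} (\code{pid}, \code{trial_id}, \code{choice} with
#'   0 = Defect, 1 = Cooperate).
#' @export
simulate_cohort <- function(design, config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    n <- 2L * config$n_per_sex
    sex <- rep(c("male", "female"), each = config$n_per_sex)
    male <- as.numeric(sex == "male")
    pid <- sprintf("P%03d", seq_len(n))
    ref <- config$covariates
    cov <- sapply(seq_len(nrow(ref)), function(i) {
      mu <- ifelse(male == 1, ref$male_mean[i], ref$female_mean[i])
      sd <- ifelse(male == 1, ref$male_sd[i], ref$female_sd[i])
      x <- stats::rnorm(n, mu, sd)
      post <- covariate_post[[ref$variable[i]]]
      if (!is.null(post)) post(x) else x
    })
    colnames(cov) <- ref$variable
    cov <- as.data.frame(cov)
    zscore <- function(v) {
      mu <- ifelse(male == 1,
                   ref$male_mean[ref$variable == v],
                   ref$female_mean[ref$variable == v])
      sd <- ifelse(male == 1,
                   ref$male_sd[ref$variable == v],
                   ref$female_sd[ref$variable == v])
      (cov[[v]] - mu) / sd
    }
    mediator <- simulate_mediator(male, config$med_a, config$med_noise_sd)
    log_gamma <- config$gamma_base_meanlog +
      config$med_b * mediator +
      config$med_c_prime * male +
      config$agreeableness_effect * zscore("Agreeableness") +
      config$conscientiousness_male_effect * male *
        zscore("Conscientiousness") +
      stats::rnorm(n, 0, config$gamma_resid_sdlog)
    gamma <- exp(log_gamma)
    alpha <- exp(config$alpha_base_meanlog +
                   config$alpha_female_shift * (1 - male) +
                   stats::rnorm(n, 0, config$alpha_sdlog))
    reward_weight <- exp(stats::rnorm(n, config$reward_meanlog,
                                      config$reward_sdlog))
    intercept <- stats::rnorm(n, config$intercept_mean, config$intercept_sd)
    quest <- simulate_questionnaire(gamma, config$questionnaire_rho)
    participants <- cbind(
      data.frame(pid = pid, sex = sex, stringsAsFactors = FALSE),
      cov, as.data.frame(quest),
      data.frame(mediator = mediator,
                 true_gamma = gamma, true_alpha = alpha,
                 true_reward_weight = reward_weight,
                 true_intercept = intercept)
    )
    n_trials <- nrow(design)
    choice_blocks <- lapply(seq_len(n), function(i) {
      p <- choice_prob(design, agent_params(gamma = gamma[i],
                                            alpha = alpha[i],
                                            reward_weight = reward_weight[i],
                                            intercept = intercept[i]))
      ch <- stats::rbinom(n_trials, 1L, p)
      ord <- sample.int(n_trials)
      data.frame(pid = pid[i],
                 trial_id = design$trial_id[ord],
                 choice = ch[ord],
                 stringsAsFactors = FALSE)
    })
    structure(list(participants = participants,
                   choices = do.call(rbind, choice_blocks),
                   config = config, seed = seed),
              class = "trust_cohort")
  })
}

#' @export
print.trust_cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf("Synthetic cohort: %d participants (%d male, %d female), %d choices\n",
              nrow(p), sum(p$sex == "male"), sum(p$sex == "female"),
              nrow(x$choices)))
  cat(sprintf("cooperation rate %.3f; median true gamma %.2e, alpha %.2e\n",
              mean(x$choices$choice), stats::median(p$true_gamma),
              stats::median(p$true_alpha)))
  invisible(x)
}

#' Read and write cohorts as a CSV pair
#'
#' \code{write_cohort} writes \code{<prefix>_choices.csv} (\code{pid,
#' trial_id, choice} with 0 = Defect, 1 = Cooperate) and
#' \code{<prefix>_covariates.csv} (identifiers, sex, covariates,
#' questionnaire items, mediator, and the ground-truth parameters when
#' present). \code{read_cohort} reads the pair back.
#'
#' @param cohort A \code{trust_cohort}.
#' @param prefix Path prefix for the two files.
#' @return \code{write_cohort} returns the two paths invisibly;
#'   \code{read_cohort} returns a \code{trust_cohort} (without the
#'   generating config).
#' @export
write_cohort <- function(cohort, prefix) {
  paths <- paste0(prefix, c("_choices.csv", "_covariates.csv"))
  utils::write.csv(cohort$choices, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$participants, paths[2], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(prefix) {
  paths <- paste0(prefix, c("_choices.csv", "_covariates.csv"))
  for (p in paths) if (!file.exists(p)) stop_fmt("missing cohort file: %s", p)
  choices <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  participants <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  if (!all(c("pid", "trial_id", "choice") %in% names(choices))) {
    stop_fmt("%s lacks pid/trial_id/choice columns", paths[1])
  }
  structure(list(participants = participants, choices = choices,
                 config = NULL, seed = NULL),
            class = "trust_cohort")
}
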