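# Group-level inference: contrasts, correlations, covariate regression,
# and the three-variable bootstrap mediation model.

#' Welch two-sample t test
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom, the
#' standard contrast for comparing per-participant sensitivities (e.g.
#' beta(Guilt)) between groups of unequal spread. The fractional df always
#' lies between \code{min(n1, n2) - 1} and \code{n1 + n2 - 2}.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{mean_diff} (mean of \code{x} minus mean of \code{y}),
#'   \code{conf_int}.
#' @export
welch_test <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_diff = unname(ht$estimate[1] - ht$estimate[2]),
       conf_int = unname(ht$conf.int))
}

#' Correlate guilt sensitivity with questionnaire items
#'
#' Pearson (default) or Spearman correlation of per-participant
#' beta(Guilt) with each post-task questionnaire item, the ordinal items
#' treated numerically.
#'
#' @param beta_guilt Numeric vector of per-participant guilt coefficients.
#' @param items Data frame or matrix of item scores (one column per item).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return Data frame with one row per item: \code{item}, \code{r},
#'   \code{p}, \code{n}.
#' @export
questionnaire_correlation <- function(beta_guilt, items,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  items <- as.data.frame(items)
  out <- lapply(names(items), function(nm) {
    ok <- stats::complete.cases(beta_guilt, items[[nm]])
    ct <- suppressWarnings(
      stats::cor.test(beta_guilt[ok], items[[nm]][ok], method = method,
                      exact = FALSE))
    data.frame(item = nm, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

interaction_covariates <- c("Neuroticism", "Extraversion", "Openness",
                            "Agreeableness", "Conscientiousness", "age",
                            "SelfEduHistory", "ParentsEduHistory", "Income",
                            "Occupation", "SubjectiveSES")

#' Covariate-by-sex interaction regression of guilt sensitivity
#'
#' Ordinary least squares of per-participant beta(Guilt) on eleven
#' covariates (five Big Five scores, age, and five socioeconomic items)
#' plus their interactions with a binary sex indicator:
#' \deqn{\beta(\mathrm{Guilt})_i = \sum_k \beta_k C_{ki} + \sum_k
#'   \beta_{11+k}\, \mathrm{Sex}_i \times C_{ki} + \varepsilon_i.}
#' Covariates are z-scored by default (raw mode available); an intercept is
#' included by default and the main sex term excluded (both toggleable,
#' mirroring the displayed form of the reference regression). Rows with
#' missing values are dropped listwise and the count reported. No multiple-
#' testing correction is applied by default; \code{p_adjust = TRUE} adds
#' Benjamini-Hochberg adjusted p values.
#'
#' @param covariates Data frame with a \code{sex} column
#'   (\code{"male"}/\code{"female"}) and the eleven covariate columns.
#' @param beta_guilt Outcome vector, aligned with \code{covariates} rows.
#' @param sex_positive Which sex is coded 1 (default \code{"male"}, the
#'   coding used for guilt analyses; use \code{"female"} for inequity).
#' @param include_main_sex Include a main sex term.
#' @param include_intercept Include an intercept.
#' @param standardize Z-score the covariates (pooled) before fitting.
#' @param p_adjust Add Benjamini-Hochberg adjusted p values.
#' @return A \code{trust_glm_report}: coefficient table (in the order
#'   mains then interactions), \code{adj_r2}, \code{n_obs},
#'   \code{n_dropped}, \code{condition_number}.
#' @export
interaction_regression <- function(covariates, beta_guilt,
                                   sex_positive = c("male", "female"),
                                   include_main_sex = FALSE,
                                   include_intercept = TRUE,
                                   standardize = TRUE,
                                   p_adjust = FALSE) {
  sex_positive <- match.arg(sex_positive)
  missing_cols <- setdiff(c("sex", interaction_covariates), names(covariates))
  if (length(missing_cols) > 0) {
    stop_fmt("covariates lack column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  stopifnot(length(beta_guilt) == nrow(covariates))
  dat <- covariates[c("sex", interaction_covariates)]
  keep <- stats::complete.cases(dat, beta_guilt)
  n_dropped <- sum(!keep)
  dat <- dat[keep, ]
  y <- beta_guilt[keep]
  sexv <- as.numeric(dat$sex == sex_positive)
  C <- as.matrix(dat[interaction_covariates])
  if (standardize) C <- scale(C)
  X <- cbind(C, sexv * C)
  colnames(X) <- c(interaction_covariates,
                   paste0("Sex:", interaction_covariates))
  if (include_main_sex) X <- cbind(Sex = sexv, X)
  if (include_intercept) X <- cbind(`(Intercept)` = 1, X)
  if (nrow(X) <= ncol(X)) {
    stop_fmt("%d observations cannot identify %d coefficients",
             nrow(X), ncol(X))
  }
  Xs <- scale(X[, colnames(X) != "(Intercept)", drop = FALSE])
  cn <- kappa(Xs, exact = TRUE)
  if (!is.finite(cn) || cn > 1e8) {
    rr <- abs(stats::cor(X[, colnames(X) != "(Intercept)"]))
    diag(rr) <- 0
    worst <- which(rr == max(rr), arr.ind = TRUE)[1, ]
    warning(sprintf(
      "near-collinear design (condition number %.3g); e.g. columns %s and %s",
      cn, rownames(rr)[worst[1]], colnames(rr)[worst[2]]))
  }
  fit <- stats::lm.fit(X, y)
  if (any(is.na(fit$coefficients))) {
    stop_fmt("collinear column(s): %s",
             paste(names(fit$coefficients)[is.na(fit$coefficients)],
                   collapse = ", "))
  }
  rdf <- fit$df.residual
  sigma2 <- sum(fit$residuals^2) / rdf
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  est <- fit$coefficients
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), rdf)
  tab <- data.frame(term = colnames(X), estimate = unname(est),
                    se = se, t = unname(tval), p = unname(pval),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (p_adjust) {
    sel <- tab$term != "(Intercept)"
    tab$p_adj <- NA_real_
    tab$p_adj[sel] <- stats::p.adjust(tab$p[sel], method = "BH")
  }
  tss <- if (include_intercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- 1 - sum(fit$residuals^2) / tss
  adj_r2 <- 1 - (1 - r2) * (length(y) - include_intercept) / rdf
  structure(list(coefficients = tab, adj_r2 = adj_r2,
                 n_obs = length(y), n_dropped = n_dropped,
                 condition_number = cn,
                 sex_positive = sex_positive),
            class = "trust_glm_report")
}

#' @export
print.trust_glm_report <- function(x, ...) {
  cat(sprintf("Covariate-by-sex regression (n = %d, %d dropped, sex = 1 for %s)\n",
              x$n_obs, x$n_dropped, x$sex_positive))
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 4)
  tab$t <- round(tab$t, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("adjusted R2 = %.4f\n", x$adj_r2))
  invisible(x)
}

#' Three-variable mediation with bootstrap indirect effect
#'
#' Standard path model for whether a relationship between \code{x} (e.g. a
#' sex indicator) and \code{y} (e.g. beta(Guilt)) runs through a mediator
#' \code{m} (e.g. a connectivity measure): path \eqn{a} from the OLS of
#' \eqn{m} on \eqn{x}; paths \eqn{b} and \eqn{c'} from the OLS of \eqn{y}
#' on \eqn{x} and \eqn{m}; total effect \eqn{c} from the OLS of \eqn{y} on
#' \eqn{x}. The indirect (mediation) effect is \eqn{a \times b}, which for
#' these linear fits equals \eqn{c - c'} exactly; its confidence interval
#' and two-sided p value come from a case-resampling bootstrap (percentile
#' by default, bias-corrected-accelerated optional). The conventional
#' three-test criterion (\eqn{a}, \eqn{b}, and \eqn{a \times b} all
#' significant) is evaluated and reported; complete mediation additionally
#' shows a nonsignificant \eqn{c'}.
#'
#' @param x Predictor (e.g. 0/1 group indicator).
#' @param m Mediator (nonzero variance).
#' @param y Outcome (nonzero variance).
#' @param n_boot Bootstrap iterations (default 10000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @param type \code{"percentile"} (default) or \code{"bca"}.
#' @return A \code{trust_mediation} with per-path estimates, SEs and p
#'   values, the indirect effect with bootstrap CI and p, and the
#'   three-test / complete-mediation verdicts.
#' @export
mediate <- function(x, m, y, n_boot = 10000L, seed = NULL,
                    conf_level = 0.95, type = c("percentile", "bca")) {
  type <- match.arg(type)
  stopifnot(length(x) == length(m), length(m) == length(y))
  ok <- stats::complete.cases(x, m, y)
  x <- as.numeric(x[ok]); m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop_fmt("mediation needs at least 10 complete cases")
  if (stats::var(m) == 0 || stats::var(y) == 0) {
    stop_fmt("mediator and outcome must have nonzero variance")
  }
  path_fit <- function(X, yy) {
    fit <- stats::lm.fit(cbind(1, X), yy)
    k <- ncol(X) + 1L
    sigma2 <- sum(fit$residuals^2) / fit$df.residual
    XtXinv <- chol2inv(chol(crossprod(cbind(1, X))))
    se <- sqrt(diag(XtXinv) * sigma2)
    tt <- fit$coefficients / se
    list(est = fit$coefficients, se = se,
         p = 2 * stats::pt(-abs(tt), fit$df.residual))
  }
  fa <- path_fit(cbind(x), m)           # m ~ x
  fb <- path_fit(cbind(x, m), y)        # y ~ x + m
  fc <- path_fit(cbind(x), y)           # y ~ x
  a <- fa$est[2]; b <- fb$est[3]; c_prime <- fb$est[2]; c_tot <- fc$est[2]
  indirect <- a * b
  boot_ab <- function(idx) {
    xb <- x[idx]; mb <- m[idx]; yb <- y[idx]
    ab_a <- stats::cov(xb, mb) / stats::var(xb)
    f <- stats::lm.fit(cbind(1, xb, mb), yb)
    ab_a * f$coefficients[3]
  }
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      # redraw degenerate resamples (zero variance in x or m)
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::var(x[idx]) > 0 && stats::var(m[idx]) > 0) break
      }
      boot_ab(idx)
    }, numeric(1))
  })
  alpha2 <- (1 - conf_level) / 2
  if (type == "percentile") {
    ci <- unname(stats::quantile(boot, c(alpha2, 1 - alpha2), type = 6))
  } else {
    z0 <- stats::qnorm(mean(boot < indirect))
    jack <- vapply(seq_len(n), function(i) boot_ab(setdiff(seq_len(n), i)),
                   numeric(1))
    jm <- mean(jack)
    acc <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
    adj <- function(q) {
      zq <- stats::qnorm(q)
      stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
    }
    ci <- unname(stats::quantile(boot, c(adj(alpha2), adj(1 - alpha2)),
                                 type = 6))
  }
  p_boot <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p_boot <- min(max(p_boot, 2 / n_boot), 1)
  alpha_level <- 1 - conf_level
  structure(list(
    path_a = list(estimate = unname(a), se = unname(fa$se[2]),
                  p = unname(fa$p[2])),
    path_b = list(estimate = unname(b), se = unname(fb$se[3]),
                  p = unname(fb$p[3])),
    path_c = list(estimate = unname(c_tot), se = unname(fc$se[2]),
                  p = unname(fc$p[2])),
    path_c_prime = list(estimate = unname(c_prime), se = unname(fb$se[2]),
                        p = unname(fb$p[2])),
    indirect = list(estimate = unname(indirect), ci = ci, p = p_boot),
    three_test_significant = unname(fa$p[2] < alpha_level &&
                                      fb$p[3] < alpha_level &&
                                      p_boot < alpha_level),
    complete_mediation = unname(fa$p[2] < alpha_level &&
                                  fb$p[3] < alpha_level &&
                                  p_boot < alpha_level &&
                                  fb$p[2] >= alpha_level),
    n = n, n_boot = n_boot, conf_level = conf_level, type = type,
    seed = seed), class = "trust_mediation")
}

#' @export
print.trust_mediation <- function(x, ...) {
  cat(sprintf("Mediation (n = %d, %d bootstrap iterations, %s CI)\n",
              x$n, x$n_boot, x$type))
  show <- function(lbl, p) {
    cat(sprintf("  %-9s %10.4f (SE %.4f), p = %.4g\n", lbl, p$estimate,
                p$se, p$p))
  }
  show("a (X->M)", x$path_a)
  show("b (M->Y)", x$path_b)
  show("c (total)", x$path_c)
  show("c' (direct)", x$path_c_prime)
  cat(sprintf("  a x b   %10.4f, %.0f%% CI [%.4f, %.4f], bootstrap p = %.4g\n",
              x$indirect$estimate, 100 * x$conf_level, x$indirect$ci[1],
              x$indirect$ci[2], x$indirect$p))
  cat(sprintf("  three-test criterion: %s; complete mediation: %s\n",
              x$three_test_significant, x$complete_mediation))
  invisible(x)
}
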