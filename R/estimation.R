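# Bias-reduced logistic estimation and model selection.

# Stable log(1 + exp(eta)).
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

logistic_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1pexp(eta))
}

# Jeffreys-penalized log-likelihood: l(beta) + 0.5 log det(X'WX).
penalized_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  XtWX <- crossprod(X * sqrt(w))
  logistic_loglik(X, y, beta) +
    0.5 * determinant(XtWX, logarithm = TRUE)$modulus[1]
}

#' Fit a logistic choice model by Firth's bias-reduced method or plain MLE
#'
#' The Firth method maximizes the Jeffreys-prior penalized log-likelihood
#' \eqn{\ell(\beta) + \frac{1}{2} \log \det I(\beta)} by iteratively
#' reweighted least squares with the hat-value score correction
#' \eqn{U^*(\beta) = X^\top\{y - p + h (1/2 - p)\}}, where \eqn{h} are the
#' diagonal elements of the weighted hat matrix. Estimates stay finite even
#' under complete separation, where ordinary maximum likelihood diverges.
#' Plain MLE (\code{method = "mle"}) maximizes \eqn{\ell(\beta)} with the
#' same Newton scheme; under separation it stops at \code{max_iter} with
#' \code{converged = FALSE} rather than raising an error.
#'
#' @param X Numeric design matrix (include the intercept column).
#' @param y Binary response, coded 0/1 (1 = Cooperate).
#' @param method \code{"firth"} (default) or \code{"mle"}.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the relative change of the
#'   (penalized) log-likelihood.
#' @return List with \code{coefficients}, \code{se} (from the inverse
#'   Fisher information at the estimate), \code{loglik} (unpenalized, at
#'   the estimate), \code{penalized_loglik}, \code{fitted}, \code{converged},
#'   \code{iterations}, \code{method}.
#' @export
fit_logistic <- function(X, y, method = c("firth", "mle"),
                         max_iter = 100L, tol = 1e-8) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (nrow(X) < ncol(X)) {
    stop_fmt("need at least %d observations to fit %d parameters",
             ncol(X), ncol(X))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]] %||% "unknown"
    stop_fmt("design matrix is rank-deficient; collinear column(s): %s",
             paste(dropped, collapse = ", "))
  }
  firth <- method == "firth"
  k <- ncol(X)
  beta <- numeric(k)
  objective <- function(b) {
    if (firth) penalized_loglik(X, y, b) else logistic_loglik(X, y, b)
  }
  obj <- objective(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    Xw <- X * sqrt(w)
    XtWX <- crossprod(Xw)
    info_inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(info_inv)) break  # numerically singular information
    resid <- y - p
    if (firth) {
      h <- w * rowSums((X %*% info_inv) * X)
      resid <- resid + h * (0.5 - p)
    }
    score <- drop(crossprod(X, resid))
    step <- drop(info_inv %*% score)
    # step-halving keeps the objective non-decreasing
    new_obj <- objective(beta + step)
    halvings <- 0L
    while ((!is.finite(new_obj) || new_obj < obj) && halvings < 25L) {
      step <- step / 2
      new_obj <- objective(beta + step)
      halvings <- halvings + 1L
    }
    beta <- beta + step
    if (is.finite(new_obj) && abs(new_obj - obj) <
        tol * (abs(obj) + 0.1)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  # a perfect fit of binary data signals (quasi-)separation: the MLE does
  # not exist and the coefficients are diverging, not converged
  if (!firth && all(abs(y - p) < 1e-6)) converged <- FALSE
  w <- p * (1 - p)
  XtWX <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, k, k))
  names(beta) <- colnames(X)
  list(coefficients = beta,
       se = sqrt(pmax(diag(vcov), 0)),
       vcov = vcov,
       loglik = logistic_loglik(X, y, beta),
       penalized_loglik = penalized_loglik(X, y, beta),
       fitted = p,
       converged = converged,
       iterations = iter,
       method = method)
}

#' Bayesian information criterion
#'
#' \eqn{\mathrm{BIC} = k \ln(n) - 2\hat\ell}; lower is better.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters (including the intercept).
#' @param n_obs Number of observations.
#' @return The BIC value.
#' @export
bic_value <- function(loglik, n_params, n_obs) {
  n_params * log(n_obs) - 2 * loglik
}

# Normalize a choice coding to integer 0/1 (1 = Cooperate).
normalize_choices <- function(choice) {
  if (is.factor(choice)) choice <- as.character(choice)
  if (is.character(choice)) {
    lc <- tolower(choice)
    out <- ifelse(lc %in% c("cooperate", "c", "1"), 1L,
                  ifelse(lc %in% c("defect", "d", "0"), 0L, NA_integer_))
  } else {
    out <- as.integer(choice)
    out[!out %in% c(0L, 1L)] <- NA_integer_
  }
  if (anyNA(out)) stop_fmt("choices must be 0/1 or Cooperate/Defect")
  out
}

# Align a per-participant choice table (trial_id, choice) with a design,
# returning y in design row order. A plain vector is taken as already
# aligned.
align_choices <- function(choices, design) {
  if (is.data.frame(choices)) {
    stopifnot(all(c("trial_id", "choice") %in% names(choices)))
    idx <- match(design$trial_id, choices$trial_id)
    if (anyNA(idx)) stop_fmt("choices are missing trial(s) present in design")
    normalize_choices(choices$choice[idx])
  } else {
    if (length(choices) != nrow(design)) {
      stop_fmt("choice vector length %d does not match %d design trials",
               length(choices), nrow(design))
    }
    normalize_choices(choices)
  }
}

#' Fit one candidate model to one participant's choices
#'
#' Builds the model's regressor matrix from the design, fits the logistic
#' model (Firth bias-reduced by default) and returns the per-participant
#' estimates together with fit indices: the log-likelihood, BIC
#' (\eqn{k \ln n - 2\hat\ell}) and McFadden's \eqn{R^2 = 1 -
#' \hat\ell/\hat\ell_0} against the intercept-only null fitted by the same
#' method.
#'
#' @param design A trust-game design.
#' @param choices Either a vector of choices aligned to the design rows or
#'   a data frame with \code{trial_id} and \code{choice} columns
#'   (0 = Defect, 1 = Cooperate, or the labels themselves).
#' @param spec A [model_spec()] or model name (default \code{"RwGuIq"}).
#' @param method Estimation method, \code{"firth"} or \code{"mle"}.
#' @return A \code{trust_fit} object.
#' @export
fit_model <- function(design, choices, spec = "RwGuIq",
                      method = c("firth", "mle")) {
  method <- match.arg(method)
  if (is.character(spec)) spec <- model_spec(spec)
  y <- align_choices(choices, design)
  reg <- compute_regressors(design, validate = FALSE)
  X <- regressor_matrix(reg, spec)
  fit <- fit_logistic(X, y, method = method)
  null_fit <- fit_logistic(matrix(1, nrow(X), 1,
                                  dimnames = list(NULL, "(Intercept)")),
                           y, method = method)
  n <- length(y)
  structure(list(
    spec = spec,
    betas = fit$coefficients,
    se = fit$se,
    loglik = fit$loglik,
    loglik_null = null_fit$loglik,
    bic = bic_value(fit$loglik, spec$n_params, n),
    mcfadden_r2 = 1 - fit$loglik / null_fit$loglik,
    converged = fit$converged,
    iterations = fit$iterations,
    method = method,
    n_obs = n
  ), class = "trust_fit")
}

#' @export
print.trust_fit <- function(x, ...) {
  cat(sprintf("Logistic choice model %s (%s, n = %d%s)\n", x$spec$name,
              x$method, x$n_obs,
              if (x$converged) "" else ", NOT converged"))
  tab <- data.frame(estimate = x$betas, se = x$se,
                    z = x$betas / x$se,
                    p = 2 * stats::pnorm(-abs(x$betas / x$se)))
  print(round(tab, 6))
  cat(sprintf("logLik %.3f  BIC %.3f  McFadden R2 %.4f\n",
              x$loglik, x$bic, x$mcfadden_r2))
  invisible(x)
}

# fold assignment: largest equal folds, remainder spread round-robin
fold_sizes <- function(n, k) {
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  sizes
}

#' Select among candidate models by repeated cross-validated prediction
#'
#' For each repeat, the participant's trials are randomly divided into
#' \code{n_folds} (near-)equal folds; each model is fitted on the remaining
#' folds and its negative log-likelihood accumulated on the held-out fold,
#' rotating through all folds (45 canonical trials give three folds of 15:
#' fit on 30, predict 15). The per-model criterion is the mean held-out NLL
#' across repeats, and the selected model minimizes it, with ties broken
#' toward fewer parameters and then lexicographic name. Held-out
#' probabilities are clipped away from 0/1 (at \code{clip}) so saturated
#' fits cannot contribute infinite NLL. \code{resample = "bootstrap"}
#' instead draws a with-replacement resample of the trials each repeat
#' before partitioning it; the default repeats random partitions of the
#' original trials.
#'
#' @inheritParams fit_model
#' @param models Candidate list from [model_space()] (any subset).
#' @param n_folds Number of folds (default 3).
#' @param n_repeats Number of repeated partitions (the reference analysis
#'   uses 500; tests commonly use 50).
#' @param resample \code{"partition"} or \code{"bootstrap"}.
#' @param seed Integer seed; equal seeds give bit-identical results.
#' @param clip Probability clipping bound for the held-out NLL.
#' @return A \code{trust_cv} object: per-model table of mean held-out NLL,
#'   the winning model, and per-repeat NLL matrices.
#' @export
cv_model_select <- function(design, choices, models = model_space(),
                            n_folds = 3L, n_repeats = 500L,
                            method = c("firth", "mle"),
                            resample = c("partition", "bootstrap"),
                            seed = NULL, clip = 1e-12) {
  method <- match.arg(method)
  resample <- match.arg(resample)
  stopifnot(is_count(n_folds), is_count(n_repeats))
  y_full <- align_choices(choices, design)
  reg <- compute_regressors(design, validate = FALSE)
  Xs <- lapply(models, function(m) regressor_matrix(reg, m))
  n <- length(y_full)
  if (n_folds > n) stop_fmt("more folds (%d) than trials (%d)", n_folds, n)
  mnames <- unname(vapply(models, function(m) m$name, character(1)))
  heldout <- matrix(NA_real_, n_repeats, length(models),
                    dimnames = list(NULL, mnames))
  train <- heldout
  with_seed(seed, {
    fold_of <- rep(seq_len(n_folds), fold_sizes(n, n_folds))
    for (r in seq_len(n_repeats)) {
      rows <- if (resample == "bootstrap") {
        sample(n, n, replace = TRUE)
      } else {
        seq_len(n)
      }
      assign_f <- sample(fold_of)
      for (j in seq_along(models)) {
        ho_nll <- 0
        tr_nll <- 0
        tr_obs <- 0L
        for (f in seq_len(n_folds)) {
          tr <- rows[assign_f != f]
          te <- rows[assign_f == f]
          fit <- fit_logistic(Xs[[j]][tr, , drop = FALSE], y_full[tr],
                              method = method)
          p_te <- stats::plogis(drop(Xs[[j]][te, , drop = FALSE] %*%
                                       fit$coefficients))
          p_te <- pmin(pmax(p_te, clip), 1 - clip)
          ho_nll <- ho_nll - sum(y_full[te] * log(p_te) +
                                   (1 - y_full[te]) * log(1 - p_te))
          tr_nll <- tr_nll - fit$loglik
          tr_obs <- tr_obs + length(tr)
        }
        heldout[r, j] <- ho_nll
        train[r, j] <- tr_nll / tr_obs * n  # per-obs train NLL, n-trial scale
      }
    }
  })
  mean_nll <- colMeans(heldout)
  n_params <- unname(vapply(models, function(m) m$n_params, integer(1)))
  o <- order(mean_nll, n_params, mnames)
  tab <- data.frame(model = mnames, n_params = n_params,
                    mean_pred_nll = mean_nll,
                    mean_train_nll = colMeans(train),
                    row.names = NULL)
  structure(list(table = tab,
                 best_model = mnames[o[1L]],
                 heldout_nll = heldout,
                 n_folds = n_folds, n_repeats = n_repeats,
                 resample = resample, method = method, seed = seed),
            class = "trust_cv")
}

#' @export
print.trust_cv <- function(x, ...) {
  cat(sprintf("Model selection by %d x %d-fold cross-validation (%s, %s)\n",
              x$n_repeats, x$n_folds, x$resample, x$method))
  tab <- x$table[order(x$table$mean_pred_nll), ]
  tab$mean_pred_nll <- round(tab$mean_pred_nll, 3)
  tab$mean_train_nll <- round(tab$mean_train_nll, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("best model: %s\n", x$best_model))
  invisible(x)
}

#' Per-participant model fits for a whole cohort
#'
#' Fits one model to every participant's choices and tabulates the
#' estimates. With \code{pooled = TRUE} a single regression over all
#' participants' trials is appended (row \code{pid = "pooled"}), the
#' all-participant fit whose coefficients are comparable across cohorts of
#' different sizes.
#'
#' @param choices Cohort choice table with columns \code{pid},
#'   \code{trial_id}, \code{choice}.
#' @inheritParams fit_model
#' @param pooled Also fit the pooled all-participant regression.
#' @return Data frame with one row per participant: \code{pid},
#'   \code{model}, \code{beta_constant}, \code{beta_reward},
#'   \code{beta_guilt}, \code{beta_inequity}, \code{beta_iq_pos},
#'   \code{beta_iq_neg} (NA for terms absent from the model),
#'   \code{loglik}, \code{bic}, \code{mcfadden_r2}, \code{converged}.
#' @export
fit_cohort <- function(choices, design, spec = "RwGuIq",
                       method = c("firth", "mle"), pooled = FALSE) {
  method <- match.arg(method)
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(all(c("pid", "trial_id", "choice") %in% names(choices)))
  beta_cols <- c("(Intercept)" = "beta_constant", Reward = "beta_reward",
                 Guilt = "beta_guilt", Inequity = "beta_inequity",
                 `Inequity-positive` = "beta_iq_pos",
                 `Inequity-negative` = "beta_iq_neg")
  row_for <- function(pid, fit) {
    out <- as.list(stats::setNames(rep(NA_real_, length(beta_cols)),
                                   unname(beta_cols)))
    present <- names(fit$betas)
    # regressor_matrix names columns Rw/Gu/Iq/Ip/In by display label
    map <- c("(Intercept)" = "beta_constant", Rw = "beta_reward",
             Gu = "beta_guilt", Iq = "beta_inequity",
             Ip = "beta_iq_pos", In = "beta_iq_neg")
    for (nm in present) out[[map[[nm]]]] <- unname(fit$betas[nm])
    c(list(pid = pid, model = fit$spec$name), out,
      list(loglik = fit$loglik, bic = fit$bic,
           mcfadden_r2 = fit$mcfadden_r2, converged = fit$converged))
  }
  pids <- unique(choices$pid)
  rows <- lapply(pids, function(p) {
    sub <- choices[choices$pid == p, c("trial_id", "choice")]
    row_for(as.character(p), fit_model(design, sub, spec, method))
  })
  if (pooled) {
    reg <- compute_regressors(design, validate = FALSE)
    idx <- match(choices$trial_id, design$trial_id)
    X <- regressor_matrix(reg, spec)[idx, , drop = FALSE]
    y <- normalize_choices(choices$choice)
    fit <- fit_logistic(X, y, method = method)
    null_fit <- fit_logistic(matrix(1, length(y), 1), y, method = method)
    pooled_fit <- structure(list(
      spec = spec, betas = fit$coefficients, se = fit$se,
      loglik = fit$loglik,
      bic = bic_value(fit$loglik, spec$n_params, length(y)),
      mcfadden_r2 = 1 - fit$loglik / null_fit$loglik,
      converged = fit$converged), class = "trust_fit")
    rows <- c(rows, list(row_for("pooled", pooled_fit)))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' Cohort-level model-selection report
#'
#' Runs per-participant cross-validated selection and BIC over the model
#' space and aggregates both ways: the mean criterion across participants
#' per model, and the count of participants for which each model wins.
#'
#' @inheritParams fit_cohort
#' @inheritParams cv_model_select
#' @param seed Master seed; each participant gets a derived sub-seed.
#' @return A \code{trust_selection} object with the per-model summary
#'   table, per-participant winners, and the best model under each
#'   aggregation.
#' @export
cohort_model_select <- function(choices, design, models = model_space(),
                                n_folds = 3L, n_repeats = 500L,
                                method = c("firth", "mle"),
                                resample = c("partition", "bootstrap"),
                                seed = NULL) {
  method <- match.arg(method)
  resample <- match.arg(resample)
  pids <- unique(choices$pid)
  mnames <- unname(vapply(models, function(m) m$name, character(1)))
  n_params <- unname(vapply(models, function(m) m$n_params, integer(1)))
  cv_nll <- matrix(NA_real_, length(pids), length(models),
                   dimnames = list(as.character(pids), mnames))
  bic_mat <- cv_nll
  for (i in seq_along(pids)) {
    sub <- choices[choices$pid == pids[i], c("trial_id", "choice")]
    pseed <- if (is.null(seed)) NULL else derive_seed(seed, i)
    cv <- cv_model_select(design, sub, models, n_folds = n_folds,
                          n_repeats = n_repeats, method = method,
                          resample = resample, seed = pseed)
    cv_nll[i, ] <- cv$table$mean_pred_nll[match(mnames, cv$table$model)]
    bic_mat[i, ] <- vapply(models, function(m) {
      fit_model(design, sub, m, method)$bic
    }, numeric(1))
  }
  winner <- function(row) {
    o <- order(row, n_params, mnames)
    mnames[o[1L]]
  }
  cv_winners <- apply(cv_nll, 1L, winner)
  bic_winners <- apply(bic_mat, 1L, winner)
  tab <- data.frame(
    model = mnames, n_params = n_params,
    mean_pred_nll = colMeans(cv_nll),
    mean_bic = colMeans(bic_mat),
    cv_wins = as.integer(table(factor(cv_winners, levels = mnames))),
    bic_wins = as.integer(table(factor(bic_winners, levels = mnames))),
    row.names = NULL)
  structure(list(table = tab,
                 best_cv = winner(colMeans(cv_nll)),
                 best_bic = winner(colMeans(bic_mat)),
                 cv_winners = cv_winners,
                 bic_winners = bic_winners,
                 n_folds = n_folds, n_repeats = n_repeats,
                 method = method, resample = resample, seed = seed),
            class = "trust_selection")
}

#' @export
print.trust_selection <- function(x, ...) {
  cat(sprintf("Cohort model selection (%d participants, %d x %d-fold CV)\n",
              length(x$cv_winners), x$n_repeats, x$n_folds))
  tab <- x$table[order(x$table$mean_pred_nll), ]
  tab$mean_pred_nll <- round(tab$mean_pred_nll, 3)
  tab$mean_bic <- round(tab$mean_bic, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("best by mean predictive NLL: %s; best by mean BIC: %s\n",
              x$best_cv, x$best_bic))
  invisible(x)
}
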