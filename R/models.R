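#' Ground-truth parameters of a simulated trustee
#'
#' Bundles the generative parameters of one agent: \code{gamma}, the guilt
#' sensitivity (disutility per yen of the expectation shortfall
#' \eqn{\tau (x_A - y_A)} inflicted by defecting); \code{alpha}, the
#' inequity sensitivity (disutility per yen of absolute payoff gap);
#' \code{reward_weight}, the multiplier on the monetary reward difference
#' in the choice logit (1 recovers the raw utility difference; smaller
#' values play the role of an inverse temperature on the yen scale); and
#' \code{intercept}, an additive choice bias on the logit. The narrowly
#' self-interested agent is \code{gamma = alpha = 0}.
#'
#' @param gamma Guilt sensitivity, \eqn{\ge 0}.
#' @param alpha Inequity sensitivity, \eqn{\ge 0}.
#' @param reward_weight Multiplier on the reward difference.
#' @param intercept Additive logit bias.
#' @return An \code{agent_params} list.
#' @export
agent_params <- function(gamma = 0, alpha = 0, reward_weight = 1,
                         intercept = 0) {
  vals <- c(gamma = gamma, alpha = alpha, reward_weight = reward_weight,
            intercept = intercept)
  if (!all(is.finite(vals))) stop_fmt("agent parameters must be finite")
  if (gamma < 0 || alpha < 0) stop_fmt("gamma and alpha must be non-negative")
  structure(as.list(vals), class = "agent_params")
}

#' Trustee utility of an action
#'
#' The trustee's utility integrates guilt aversion and inequity aversion:
#' \deqn{u_B = x_B - \alpha |x_A - x_B|} for Cooperate and
#' \deqn{u_B = y_B - \gamma \tau (x_A - y_A) - \alpha |y_A - y_B|} for
#' Defect. Defecting yields the larger monetary payoff \eqn{y_B} but incurs
#' a guilt cost proportional to the expectation shortfall it inflicts on
#' the truster; both actions incur inequity costs proportional to the
#' resulting payoff gap.
#'
#' @param trials A design or single trial (named list).
#' @param action \code{"cooperate"} or \code{"defect"} (case-insensitive).
#' @param params An [agent_params()] (only \code{gamma} and \code{alpha}
#'   enter the utility).
#' @return Numeric vector of utilities on the yen scale, one per trial.
#' @examples
#' fig1 <- list(x_A = 780, x_B = 650, y_A = 220, y_B = 910,
#'              z_A = 400, z_B = 300, tau = 0.8)
#' utility(fig1, "defect", agent_params(gamma = 1))  # 910 - 448 = 462
#' @export
utility <- function(trials, action, params = agent_params()) {
  if (!is.data.frame(trials)) trials <- as.data.frame(trials)
  action <- match.arg(tolower(action), c("cooperate", "defect"))
  g <- params$gamma
  a <- params$alpha
  if (action == "cooperate") {
    trials$x_B - a * abs(trials$x_A - trials$x_B)
  } else {
    trials$y_B - g * trials$tau * (trials$x_A - trials$y_A) -
      a * abs(trials$y_A - trials$y_B)
  }
}

#' Probability that the trustee cooperates
#'
#' Logistic (softmax with inverse temperature 1) choice rule on the utility
#' difference, parameterized through the derived regressors:
#' \deqn{\mathrm{logit}\, P(\mathrm{Cooperate}) = \beta_0 +
#'   w \cdot \mathrm{Reward} + \gamma \cdot \mathrm{Guilt} +
#'   \alpha \cdot \mathrm{Inequity}.}
#' With \code{reward_weight = 1} and \code{intercept = 0} the logit equals
#' \code{utility(trial, "cooperate") - utility(trial, "defect")} exactly.
#'
#' @inheritParams utility
#' @return Probabilities strictly inside (0, 1), one per trial; 0.5 when
#'   the utilities tie.
#' @export
choice_prob <- function(trials, params = agent_params()) {
  reg <- compute_regressors(trials, validate = FALSE)
  eta <- params$intercept + params$reward_weight * reg$reward +
    params$gamma * reg$guilt + params$alpha * reg$inequity
  stats::plogis(eta)
}

model_component_map <- c(
  Rw = "reward", Gu = "guilt", Iq = "inequity",
  Ip = "inequity_pos", In = "inequity_neg"
)

#' Define one candidate choice model
#'
#' A model is named by the concatenation of its components: \code{Rw}
#' (Reward), \code{Gu} (Guilt), \code{Iq} (combined absolute-difference
#' Inequity), \code{Ip} (Inequity-positive) and \code{In}
#' (Inequity-negative). Every model contains an intercept. The combined
#' \code{Iq} term never co-occurs with its Fehr-Schmidt split \code{Ip} /
#' \code{In}.
#'
#' @param name Model name, e.g. \code{"RwGuIq"}.
#' @return A \code{model_spec} list with \code{name}, \code{components}
#'   and \code{n_params} (component count plus intercept).
#' @export
model_spec <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  parts <- regmatches(name, gregexpr("[A-Z][a-z]", name))[[1]]
  if (paste(parts, collapse = "") != name ||
      !all(parts %in% names(model_component_map)) ||
      anyDuplicated(parts)) {
    stop_fmt("cannot parse model name '%s' (components are Rw,Gu,Iq,Ip,In)",
             name)
  }
  if ("Iq" %in% parts && any(c("Ip", "In") %in% parts)) {
    stop_fmt("model '%s': Iq cannot co-occur with Ip or In", name)
  }
  structure(list(name = name, components = parts,
                 n_params = length(parts) + 1L),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %s: intercept + %s (%d parameters)\n", x$name,
              paste(model_component_map[x$components], collapse = " + "),
              x$n_params))
  invisible(x)
}

#' Enumerate the candidate model space
#'
#' The ten candidate models cross the always-present Reward term with the
#' presence of Guilt and one of four inequity codings (none, combined,
#' positive-only, negative-only, or the full Fehr-Schmidt split): \code{Rw,
#' RwGu, RwIq, RwIp, RwIn, RwGuIq, RwGuIp, RwGuIn, RwIpIn, RwGuIpIn}.
#' \code{RwGuIq} (reward + guilt + combined inequity) is flagged as the
#' reference best-supported model and \code{RwGuIpIn} (the Fehr-Schmidt
#' type model) as the runner-up.
#'
#' @return Named list of 10 [model_spec()] objects with attributes
#'   \code{best} (\code{"RwGuIq"}) and \code{runner_up} (\code{"RwGuIpIn"}).
#' @export
model_space <- function() {
  names <- c("Rw", "RwGu", "RwIq", "RwIp", "RwIn",
             "RwGuIq", "RwGuIp", "RwGuIn", "RwIpIn", "RwGuIpIn")
  specs <- lapply(names, model_spec)
  names(specs) <- names
  attr(specs, "best") <- "RwGuIq"
  attr(specs, "runner_up") <- "RwGuIpIn"
  specs
}

#' Build the regression design matrix of a model
#'
#' @param regressors Output of [compute_regressors()] (or a design, which
#'   is converted first).
#' @param spec A [model_spec()] or model name.
#' @return Numeric matrix with an intercept column followed by the model's
#'   regressor columns, in component order.
#' @export
regressor_matrix <- function(regressors, spec) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (!all(unname(model_component_map) %in% names(regressors))) {
    regressors <- compute_regressors(regressors, validate = FALSE)
  }
  cols <- model_component_map[spec$components]
  X <- cbind(1, as.matrix(regressors[unname(cols)]))
  colnames(X) <- c("(Intercept)", names(cols))
  X
}

#' Linear predictor (logit) of a model
#'
#' \eqn{\beta_0 + \sum_k \beta_k \cdot \mathrm{component}_k} restricted to
#' the model's components. With \eqn{\beta_0 = 0, \beta_1 = 1,
#' \beta_2 = \gamma, \beta_3 = \alpha} under \code{RwGuIq} this equals the
#' cooperate-minus-defect utility difference on every trial.
#'
#' @inheritParams regressor_matrix
#' @param betas Coefficient vector of length \code{spec$n_params}
#'   (intercept first).
#' @return Numeric vector of logits.
#' @export
linear_index <- function(regressors, betas, spec) {
  if (is.character(spec)) spec <- model_spec(spec)
  if (length(betas) != spec$n_params) {
    stop_fmt("model %s expects %d coefficients, got %d", spec$name,
             spec$n_params, length(betas))
  }
  drop(regressor_matrix(regressors, spec) %*% betas)
}
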