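#' Canonical belief-frequency table for a 45-trial design
#'
#' The canonical task presents the trustee with 45 trials whose revealed
#' belief \eqn{\tau} (the truster's stated probability that the trustee
#' cooperates) takes five values with fixed frequencies: 0.60 on 7 trials,
#' 0.70 on 5, 0.80 on 13, 0.90 on 11 and 1.00 on 9. Beliefs below 0.60 are
#' excluded because a truster holding them would be expected to opt out.
#'
#' @return Named numeric vector mapping \eqn{\tau} values (as character
#'   names) to trial counts; the counts sum to 45.
#' @export
canonical_tau_table <- function() {
  c("0.6" = 7, "0.7" = 5, "0.8" = 13, "0.9" = 11, "1" = 9)
}

design_columns <- c("trial_id", "x_A", "x_B", "y_A", "y_B", "z_A", "z_B", "tau")

#' Construct a trust-game design from per-trial payoffs and beliefs
#'
#' A design is a data frame with one row per trial and columns
#' \code{trial_id}, \code{x_A}, \code{x_B} (payoffs to truster A and trustee
#' B when B cooperates), \code{y_A}, \code{y_B} (payoffs when B defects),
#' \code{z_A}, \code{z_B} (payoffs when A opts out) and \code{tau} (A's
#' revealed belief, a probability). Two payoff orderings define the game:
#' \eqn{y_A < z_A < x_A} (entering signals trust) and
#' \eqn{z_B < x_B < y_B} (defection tempts the trustee, creating scope for
#' guilt).
#'
#' @param trials Data frame containing the payoff and belief columns
#'   (\code{trial_id} is added when missing).
#' @param seed Optional integer recorded as the generating seed.
#' @param provenance Free-text note on where the design came from.
#' @param validate Check the design invariants and fail on violation.
#' @return A \code{trust_design} data frame.
#' @seealso [generate_design()], [validate_design()], [compute_regressors()]
#' @export
trust_design <- function(trials, seed = NULL, provenance = "user-supplied",
                         validate = TRUE) {
  trials <- as.data.frame(trials)
  if (!"trial_id" %in% names(trials)) {
    trials$trial_id <- seq_len(nrow(trials))
  }
  missing <- setdiff(design_columns, names(trials))
  if (length(missing) > 0) {
    stop_fmt("design is missing column(s): %s", paste(missing, collapse = ", "))
  }
  trials <- trials[design_columns]
  rownames(trials) <- NULL
  structure(trials,
            seed = seed,
            provenance = provenance,
            class = c("trust_design", "data.frame")) -> d
  if (validate) {
    report <- validate_design(d)
    if (nrow(report) > 0) {
      stop_fmt("invalid design:\n%s",
               paste(utils::head(report$message, 5L), collapse = "\n"))
    }
  }
  d
}

#' @export
print.trust_design <- function(x, ...) {
  cat(sprintf("Trust-game design: %d trials", nrow(x)))
  if (!is.null(attr(x, "seed"))) cat(sprintf(" (seed %s)", attr(x, "seed")))
  cat("\n")
  tab <- table(x$tau)
  cat("tau frequencies:",
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  reg <- compute_regressors(x, validate = FALSE)
  r <- max_abs_regressor_cor(reg)
  cat(sprintf("max |r| among Reward/Guilt/Inequity: %.3f\n", r))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("... %d more trials\n", nrow(x) - 4L))
  invisible(x)
}

# Per-trial ordering checks; returns character messages, one per violation.
check_trial_orderings <- function(trials) {
  msgs <- character(0)
  bad <- function(cond, fmt) {
    idx <- which(cond)
    if (length(idx) > 0) {
      sprintf(fmt, trials$trial_id[idx])
    } else character(0)
  }
  msgs <- c(
    msgs,
    bad(!(trials$y_A < trials$z_A), "trial %d violates y_A < z_A"),
    bad(!(trials$z_A < trials$x_A), "trial %d violates z_A < x_A"),
    bad(!(trials$z_B < trials$x_B), "trial %d violates z_B < x_B"),
    bad(!(trials$x_B < trials$y_B), "trial %d violates x_B < y_B")
  )
  pay <- as.matrix(trials[c("x_A", "x_B", "y_A", "y_B", "z_A", "z_B")])
  if (any(pay <= 0) || any(pay != round(pay))) {
    idx <- unique(trials$trial_id[rowSums(pay <= 0 | pay != round(pay)) > 0])
    msgs <- c(msgs, sprintf("trial %d has a non-positive or non-integer payoff",
                            idx))
  }
  if (any(trials$tau < 0 | trials$tau > 1)) {
    idx <- trials$trial_id[trials$tau < 0 | trials$tau > 1]
    msgs <- c(msgs, sprintf("trial %d has tau outside [0, 1]", idx))
  }
  msgs
}

#' Compute the choice-model regressors of a design
#'
#' Derives, for each trial, the covariates entering the logistic choice
#' model: \code{reward} \eqn{= x_B - y_B} (the trustee's monetary gain from
#' cooperating), \code{guilt} \eqn{= \tau (x_A - y_A)} (the shortfall the
#' trustee believes defection inflicts relative to the truster's
#' expectation), and \code{inequity} \eqn{= |y_A - y_B| - |x_A - x_B|} (how
#' much more unequal the defect allocation is than the cooperate
#' allocation). The Fehr-Schmidt split decomposes inequity into a
#' disadvantageous part \code{inequity_neg} \eqn{= \max(y_A - y_B, 0) -
#' \max(x_A - x_B, 0)} and an advantageous part \code{inequity_pos}
#' \eqn{= \max(y_B - y_A, 0) - \max(x_B - x_A, 0)}; both are oriented so
#' that positive values mean defection produces more of that inequity type
#' than cooperation, and they sum to \code{inequity} exactly.
#'
#' @param trials A \code{trust_design} or data frame with the payoff and
#'   belief columns; a single trial may be given as a named list.
#' @param validate Check payoff orderings first (an informative error names
#'   the violated inequality).
#' @return Data frame with columns \code{trial_id}, \code{reward},
#'   \code{guilt}, \code{inequity}, \code{inequity_pos},
#'   \code{inequity_neg}. \code{guilt} is always non-negative.
#' @examples
#' compute_regressors(list(x_A = 780, x_B = 650, y_A = 220, y_B = 910,
#'                         z_A = 400, z_B = 300, tau = 0.8))
#' @export
compute_regressors <- function(trials, validate = TRUE) {
  if (!is.data.frame(trials)) trials <- as.data.frame(trials)
  if (!"trial_id" %in% names(trials)) trials$trial_id <- seq_len(nrow(trials))
  if (validate) {
    msgs <- check_trial_orderings(trials)
    if (length(msgs) > 0) {
      stop_fmt("invalid trial(s):\n%s",
               paste(utils::head(msgs, 5L), collapse = "\n"))
    }
  }
  pos <- function(d) pmax(d, 0)
  data.frame(
    trial_id = trials$trial_id,
    reward = trials$x_B - trials$y_B,
    guilt = trials$tau * (trials$x_A - trials$y_A),
    inequity = abs(trials$y_A - trials$y_B) - abs(trials$x_A - trials$x_B),
    inequity_pos = pos(trials$y_B - trials$y_A) - pos(trials$x_B - trials$x_A),
    inequity_neg = pos(trials$y_A - trials$y_B) - pos(trials$x_A - trials$x_B)
  )
}

max_abs_regressor_cor <- function(regressors) {
  cols <- regressors[c("reward", "guilt", "inequity")]
  if (any(vapply(cols, stats::sd, numeric(1)) == 0)) return(NA_real_)
  r <- stats::cor(cols)
  max(abs(r[upper.tri(r)]))
}

#' Generate a trust-game design with near-orthogonal regressors
#'
#' Draws integer payoffs by rejection sampling until the three choice-model
#' regressors (Reward, Guilt, Inequity) are mutually close to orthogonal:
#' the maximum absolute pairwise Pearson correlation must fall below
#' \code{max_abs_corr} (default 0.30, the design constraint of the canonical
#' task). Each trial's truster payoffs are three distinct values ordered
#' \eqn{y_A < z_A < x_A} and trustee payoffs three distinct values ordered
#' \eqn{z_B < x_B < y_B}; beliefs follow \code{tau_table} in shuffled order.
#'
#' @param n_trials Number of trials; must equal \code{sum(tau_table)}.
#' @param tau_table Named vector of belief frequencies
#'   (default [canonical_tau_table()]).
#' @param payoff_min,payoff_max,payoff_step Payoff grid in yen (defaults
#'   100-1000 in steps of 10, matching the magnitudes of the task).
#' @param max_abs_corr Orthogonality threshold on \eqn{|r|}.
#' @param seed Integer seed; equal seeds yield identical designs.
#' @param max_tries Rejection-sampling budget; exhausting it raises an error
#'   reporting the best correlation achieved.
#' @return A \code{trust_design}.
#' @examples
#' d <- generate_design(seed = 1)
#' table(d$tau)
#' @export
generate_design <- function(n_trials = 45L,
                            tau_table = canonical_tau_table(),
                            payoff_min = 100L, payoff_max = 1000L,
                            payoff_step = 10L,
                            max_abs_corr = 0.30,
                            seed = NULL,
                            max_tries = 1000L) {
  stopifnot(is_count(n_trials), is_count(max_tries))
  if (sum(tau_table) != n_trials) {
    stop_fmt("tau_table frequencies sum to %d, not n_trials = %d",
             sum(tau_table), n_trials)
  }
  grid <- seq(payoff_min, payoff_max, by = payoff_step)
  if (length(grid) < 3L) stop_fmt("payoff range admits fewer than 3 values")
  taus <- rep(as.numeric(names(tau_table)), times = tau_table)
  with_seed(seed, {
    best_r <- Inf
    for (try in seq_len(max_tries)) {
      a <- t(replicate(n_trials, sort(sample(grid, 3L))))  # y_A < z_A < x_A
      b <- t(replicate(n_trials, sort(sample(grid, 3L))))  # z_B < x_B < y_B
      trials <- data.frame(
        trial_id = seq_len(n_trials),
        x_A = a[, 3L], x_B = b[, 2L],
        y_A = a[, 1L], y_B = b[, 3L],
        z_A = a[, 2L], z_B = b[, 1L],
        tau = sample(taus)
      )
      r <- max_abs_regressor_cor(compute_regressors(trials, validate = FALSE))
      if (r < best_r) best_r <- r
      if (r < max_abs_corr) {
        return(trust_design(trials, seed = seed,
                            provenance = sprintf(
                              "generate_design (attempt %d, max |r| = %.3f)",
                              try, r)))
      }
    }
    stop_fmt(paste0("rejection sampling budget exhausted after %d tries; ",
                    "best max |r| achieved = %.3f (threshold %.3f)"),
             max_tries, best_r, max_abs_corr)
  })
}

#' Validate a design against the task invariants
#'
#' Checks every per-trial payoff ordering, payoff positivity, belief range,
#' and optionally the belief frequency table and the regressor orthogonality
#' constraint. Violations are returned, not raised.
#'
#' @param design A design data frame.
#' @param tau_table Expected belief frequencies, or \code{NULL} to skip the
#'   frequency check (the default checks only when the design has 45
#'   trials).
#' @param max_abs_corr Orthogonality threshold; \code{NA} skips the check.
#' @return Data frame with columns \code{check} and \code{message}; zero
#'   rows when all invariants hold.
#' @export
validate_design <- function(design,
                            tau_table = if (nrow(design) == 45L)
                              canonical_tau_table() else NULL,
                            max_abs_corr = 0.30) {
  msgs <- check_trial_orderings(design)
  report <- data.frame(check = rep("trial", length(msgs)), message = msgs,
                       stringsAsFactors = FALSE)
  if (!is.null(tau_table)) {
    have <- table(factor(design$tau, levels = as.numeric(names(tau_table))))
    if (any(have != tau_table) || !all(design$tau %in% as.numeric(names(tau_table)))) {
      report <- rbind(report, data.frame(
        check = "tau_table",
        message = sprintf("tau frequencies %s do not match expected %s",
                          paste(sprintf("%s:%d", names(table(design$tau)),
                                        as.integer(table(design$tau))),
                                collapse = " "),
                          paste(sprintf("%s:%d", names(tau_table),
                                        as.integer(tau_table)),
                                collapse = " "))))
    }
  }
  if (!is.na(max_abs_corr) && length(msgs) == 0) {
    r <- max_abs_regressor_cor(compute_regressors(design, validate = FALSE))
    if (is.na(r)) {
      report <- rbind(report, data.frame(
        check = "orthogonality",
        message = "a regressor column has zero variance; correlations undefined"))
    } else if (r >= max_abs_corr) {
      report <- rbind(report, data.frame(
        check = "orthogonality",
        message = sprintf(
          "max |r| among Reward/Guilt/Inequity is %.3f (>= %.2f)",
          r, max_abs_corr)))
    }
  }
  rownames(report) <- NULL
  report
}

#' Read and write designs as CSV
#'
#' The on-disk format is a UTF-8 CSV with header columns \code{trial_id,
#' x_A, x_B, y_A, y_B, z_A, z_B, tau} ('.' decimal separator). The round
#' trip \code{read_design(write_design(d))} is the identity on all fields.
#'
#' @param design A \code{trust_design}.
#' @param path File path.
#' @param validate Validate trials on read.
#' @return \code{read_design} returns a \code{trust_design};
#'   \code{write_design} returns \code{path} invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design)[design_columns], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, validate = TRUE) {
  raw <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing <- setdiff(design_columns, names(raw))
  if (length(missing) > 0) {
    stop_fmt("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  }
  num_ok <- vapply(raw[design_columns], is.numeric, logical(1))
  if (!all(num_ok)) {
    stop_fmt("%s: non-numeric values in column(s) %s", path,
             paste(design_columns[!num_ok], collapse = ", "))
  }
  bad <- which(!stats::complete.cases(raw[design_columns]))
  if (length(bad) > 0) {
    stop_fmt("%s: malformed row(s) at line(s) %s", path,
             paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  trust_design(raw, provenance = sprintf("read from %s", path),
               validate = validate)
}
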