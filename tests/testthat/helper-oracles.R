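# Shared fixtures and independent oracles.

# The worked-example trial: belief 0.8, cooperate pays (780, 650),
# defect pays (220, 910), opt-out (400, 300).
fig1_trial <- function() {
  list(x_A = 780, x_B = 650, y_A = 220, y_B = 910,
       z_A = 400, z_B = 300, tau = 0.8)
}

# Independent Jeffreys-penalized log-likelihood (used by the grid oracle;
# written against the definition, not the package internals).
oracle_penalized_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log(1 + exp(eta)))
  p <- 1 / (1 + exp(-eta))
  info <- t(X) %*% (X * (p * (1 - p)))
  ll + 0.5 * log(det(info))
}

# Coarse-to-fine grid maximization of a 2-parameter objective. Final grid
# step 1e-4 per coordinate.
oracle_grid_max <- function(obj, center = c(0, 0), span = 4, step = 0.1,
                            refinements = 3) {
  for (level in seq_len(refinements + 1)) {
    g1 <- seq(center[1] - span, center[1] + span, by = step)
    g2 <- seq(center[2] - span, center[2] + span, by = step)
    vals <- outer(g1, g2, Vectorize(function(b0, b1) obj(c(b0, b1))))
    ij <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    center <- c(g1[ij[1]], g2[ij[2]])
    span <- 2 * step
    step <- step / 10
  }
  center
}

# A small deliberately non-orthogonal design: payoff gaps sorted with tau
# so the guilt and inequity columns co-vary strongly.
adversarial_design <- function(n = 45) {
  taus <- rep(c(0.6, 0.7, 0.8, 0.9, 1.0), times = c(7, 5, 13, 11, 9))
  taus <- sort(taus)
  gap <- round(seq(10, 60, length.out = n)) * 10  # x_A - y_A grows with tau
  y_A <- rep(150, n)
  # guilt = tau * gap and inequity = gap + 50 both increase along the
  # sorted trials
  data.frame(
    trial_id = seq_len(n),
    x_A = y_A + gap, x_B = y_A + gap - 50 - 10 * (seq_len(n) %% 7),
    y_A = y_A, y_B = y_A + gap + 100,
    z_A = y_A + pmax(gap %/% 2, 10), z_B = 50,
    tau = taus
  )
}

# Column values of a design without its generation metadata.
plain_design <- function(d) {
  d <- as.data.frame(d)
  attr(d, "seed") <- NULL
  attr(d, "provenance") <- NULL
  class(d) <- "data.frame"
  d
}

# Random valid trials for property tests.
random_trials <- function(n, seed) {
  trustgame:::with_seed(seed, {
    grid <- seq(100, 1000, by = 10)
    a <- t(replicate(n, sort(sample(grid, 3))))
    b <- t(replicate(n, sort(sample(grid, 3))))
    data.frame(trial_id = seq_len(n),
               x_A = a[, 3], x_B = b[, 2], y_A = a[, 1], y_B = b[, 3],
               z_A = a[, 2], z_B = b[, 1],
               tau = sample(seq(0.6, 1, by = 0.1), n, replace = TRUE))
  })
}

# Replicate a design k-fold with fresh trial ids (longer sessions for
# recovery studies).
replicate_design <- function(design, k) {
  out <- do.call(rbind, replicate(k, as.data.frame(design),
                                  simplify = FALSE))
  out$trial_id <- seq_len(nrow(out))
  trust_design(out, provenance = sprintf("replicated x%d", k))
}
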