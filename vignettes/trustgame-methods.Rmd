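---
title: "Methods: guilt- and inequity-aversion analysis of trust-game choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guilt- and inequity-aversion analysis of trust-game choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trustgame)
```

## The model and its assumptions

The trustee (player B) of a belief-dependent trust game chooses between
Cooperate and Defect after the truster (player A) has entered the game and
revealed a belief $\tau$, the stated probability that B cooperates. The
payoffs obey $y_A < z_A < x_A$ (entering signals trust) and
$z_B < x_B < y_B$ (defection is tempting). B's utility combines two social
motives on top of monetary self-interest:

$$u_B = \begin{cases}
x_B - \alpha\,|x_A - x_B| & \text{Cooperate}\\
y_B - \gamma\,\tau\,(x_A - y_A) - \alpha\,|y_A - y_B| & \text{Defect,}
\end{cases}$$

with $\gamma \ge 0$ the guilt sensitivity (disutility per yen of the
expectation shortfall $\tau (x_A - y_A)$ that defection inflicts on A,
which is non-negative because $\tau \ge 0$ and $x_A > y_A$) and
$\alpha \ge 0$ the inequity sensitivity. Choices follow a logistic rule on
the utility difference with the inverse temperature fixed at 1; decision
noise is therefore expressed through the scale of the coefficients rather
than estimated separately, which is why all fitted sensitivities live on a
per-yen scale of a few times $10^{-3}$. Equivalently, per trial $t$:

$$\mathrm{logit}\,P_t(\mathrm{Cooperate}) = \beta_0 + \beta_1\,\mathrm{Reward}_t +
\beta_2\,\mathrm{Guilt}_t + \beta_3\,\mathrm{Inequity}_t,$$

with $\mathrm{Reward}_t = x_B - y_B$, $\mathrm{Guilt}_t = \tau(x_A - y_A)$,
$\mathrm{Inequity}_t = |y_A - y_B| - |x_A - x_B|$, so that $\beta_2$
estimates $\gamma$ and $\beta_3$ estimates $\alpha$. The Fehr–Schmidt
split replaces Inequity by an advantageous part
$\mathrm{Ip}_t = \max(y_B - y_A, 0) - \max(x_B - x_A, 0)$ and a
disadvantageous part
$\mathrm{In}_t = \max(y_A - y_B, 0) - \max(x_A - x_B, 0)$; both are
oriented so that positive values mean defection produces more of that
inequity type, and $\mathrm{Ip} + \mathrm{In} = \mathrm{Inequity}$
exactly. The candidate space crosses the always-present Reward term with
Guilt and the four inequity codings, giving ten models (`model_space()`);
`RwGuIq` is the reference specification.

Key modeling assumptions: beliefs are experimenter-set and known, so no
belief hierarchy is estimated; the trustee's own second-order beliefs are
collapsed into $\tau$; sensitivities are constant across trials within a
participant; and trials are exchangeable (no learning), consistent with a
feedback-free task.

## Design generation

`generate_design()` builds 45-trial designs with the canonical $\tau$
frequencies (0.60 on 7 trials, 0.70 on 5, 0.80 on 13, 0.90 on 11, 1.00 on
9; beliefs below 0.60 are excluded because such a truster would be
expected to opt out). Per trial, the three truster payoffs are a sorted
triple of distinct multiples of 10 between 100 and 1000 yen, likewise the
trustee payoffs, which reproduces the payoff magnitudes of the published
task. Whole designs are rejection-sampled until the maximum absolute
pairwise Pearson correlation among Reward, Guilt and Inequity falls below
0.30 — the published design constraint — with the belief sequence
reshuffled at each attempt. Typical accepted designs reach max $|r|$
around 0.10–0.25 within a handful of attempts. An exhausted budget
reports the best correlation achieved. Exact payoff tables of the original
task are not reproduced; only the stated design properties are.

A structural caveat that matters later: in any valid design the identity
$x_A - y_A = (x_B - y_B) + (y_B - y_A) + (x_A - x_B)$ makes the payoff
part of Guilt a linear combination of Reward and the signed split-inequity
gaps. Orthogonality can therefore be enforced for the three model
regressors, but Guilt retains moderate correlation (roughly 0.2–0.5 in
magnitude) with Inequity-positive and Inequity-negative no matter how
payoffs are drawn; only the $\tau$ variation is structurally orthogonal to
everything. We verified this by implementing and measuring alternative
generators (large fixed trust gaps with $\tau$-driven guilt variance);
they improve split-term orthogonality but shrink the guilt column's
spread and with it per-participant recovery of $\gamma$, so the simple
sorted-triple sampler is kept.

## Estimation

Per-participant fits use Firth's bias-reduced logistic regression: Newton
iterations on the Jeffreys-penalized log-likelihood
$\ell(\beta) + \tfrac12 \log\det I(\beta)$ with the hat-value score
correction, step-halving, convergence when the relative change of the
penalized log-likelihood falls below $10^{-8}$, and at most 100
iterations. This keeps estimates finite under the (quasi-)separation that
45-trial binary data regularly produce. Plain MLE is available for
comparison and flags separation (a numerically perfect fit) as
non-convergence. Standard errors come from the inverse Fisher information
at the estimate. The reported log-likelihood is the unpenalized one at the
Firth estimate; BIC is $k \ln n - 2\hat\ell$ and McFadden's $R^2$ is
computed against an intercept-only null fitted by the same method. The
fitter is validated in the test suite against a dense grid search of the
penalized likelihood (agreement to $10^{-3}$ per coordinate) and against
`stats::glm` on separation-free data.

Model selection follows the repeated cross-validation scheme: each repeat
randomly partitions the 45 trials into three folds of 15, fits each
candidate on 30 trials and accumulates held-out negative log-likelihood on
the remaining 15, rotating through the folds; the criterion is the mean
held-out NLL across repeats (500 in the reference analysis; tests use
25–50). "Repeated bootstrap" is read as repeated random partitions; a
with-replacement resampling variant is implemented behind
`resample = "bootstrap"`. Held-out probabilities are clipped at
$10^{-12}$ so a saturated training fit cannot contribute an infinite NLL.
Ties break toward fewer parameters, then lexicographic name. Trial counts
not divisible by the fold count use largest equal folds with the remainder
spread round-robin.

## The synthetic cohort

`simulate_cohort()` draws ground-truth agents and everything downstream
needs: choices, questionnaire items, covariates, and a mediator.
Sensitivities are log-normal, which guarantees positivity and makes sex
shifts multiplicative. Defaults (one chosen set, not revisited):

- $\log\gamma$ baseline $\log(0.0015)$ for women, residual SD 0.45;
  $\log\alpha$ baseline $\log(0.0008)$ for men, SD 0.6, women shifted
  +0.5; reward weight log-normal around $0.003$ (SD 0.3 on the log
  scale); intercept $N(0, 0.3^2)$. These place the fitted coefficients in
  the per-yen magnitudes reported for this task and give cooperation
  rates near one half.
- The sex difference in $\gamma$ flows through a scalar connectivity
  mediator: $M = a\,\mathrm{male} + \epsilon$ with $a = 1$, noise SD 1,
  and $\log\gamma$ gains $b\,M + c'\,\mathrm{male}$ with $b = 0.5$,
  $c' = 0$ — complete mediation by construction, with a total male–female
  shift of $ab + c' = 0.5$ on the log scale (factor ≈ 1.65). That is a
  moderate standardized difference, the size at which a 26-vs-26 Welch
  contrast is significant with only moderate power, matching the
  borderline p-values typical for such samples.
- Covariates (age, five Big Five scales, five socioeconomic items) are
  Gaussian per sex with means/SDs from published descriptives of a large
  online cohort (`covariate_reference()`); ordinal items are rounded and
  clipped to plausible scale ranges, Big Five scores stay continuous.
  One SD of Agreeableness adds 0.08 to $\log\gamma$ in both sexes; one SD
  of Conscientiousness adds 0.12 in men only — the two covariate effects
  the downstream interaction regression is meant to detect.
- Questionnaire items a/b/c are generated from a latent Gaussian copula:
  latent $= \rho\,z(\log\gamma) + \sqrt{1-\rho^2}\,\text{noise}$ with
  $\rho = 0.35$, thresholded at standard-normal quintiles into 1–5.
  Discretization attenuates the realized rank correlation by a few
  hundredths, which the tests allow for.
- Trial order is randomized per participant; choices are Bernoulli draws
  from the logistic rule.

What the generator does *not* emulate: learning or sequential dependence,
inverted-U belief effects at low $\tau$ (the task only uses
$\tau \ge 0.6$), ordinal measurement models for the SES items, item-level
questionnaire structure beyond a single latent factor, and any imaging
data — the mediator is a scalar surrogate consumed as-is. Passing tests
therefore validate the estimation and inference machinery under the stated
generative model, not the biological claims.

## Group inference

Sex contrasts use Welch's t test (Satterthwaite df). The
covariate regression mirrors the published 22-coefficient form: eleven
main covariates plus eleven sex-interaction terms, sex coded 1 = men for
guilt analyses (1 = women for inequity), z-scored covariates by default
(raw mode available), an intercept included, the main sex term excluded
(both toggleable — the displayed reference equation has neither intercept
nor main sex term, but an intercept is standard practice), listwise
deletion with the dropped count reported, and no multiple-testing
correction by default (Benjamini–Hochberg behind a flag), matching the
unadjusted significance reporting of the reference table. Adjusted $R^2$
is reported as computed.

`mediate()` fits the standard three-variable path model by OLS: $a$ from
$M \sim X$, $b$ and $c'$ from $Y \sim X + M$, $c$ from $Y \sim X$. For
these linear fits $c - c' = ab$ exactly, and the indirect effect $ab$ gets
a percentile bootstrap CI and two-sided p (10,000 iterations by default;
BCa behind a flag; degenerate resamples with zero predictor or mediator
variance are redrawn). The conventional three-test criterion ($a$, $b$,
$a \times b$ all significant) and the complete-mediation verdict
(additionally $c'$ non-significant) are evaluated and reported.

## The pipeline

`run_pipeline()` chains design generation, cohort simulation,
per-participant fitting, model selection, and group inference, writing
CSV/JSON artifacts, a log and an MD5 manifest. A single master seed is
fanned out by a counter scheme — stage $k$ always receives the $k$-th
value of the stream seeded by the master — so adding a stage never
perturbs earlier stages, and reruns are byte-identical (the log records
seeds and versions, never timestamps). The demonstration configuration
(12 participants, 45 trials, 50 CV repeats, 1000-iteration bootstrap,
no covariate regression, which 12 observations could not identify)
completes in under two minutes on a laptop-class core.

## Validation scope and problem sizes

The test suite exercises each module at sizes chosen to keep the full run
around one minute: arithmetic oracles on the worked-example trial;
property tests over a few hundred random trials; a grid-search oracle for
the Firth fitter; recovery of $\gamma$ across 200 simulated participants
at 45 trials (rank correlation with fitted $\beta(\mathrm{Guilt})$ above
0.5) and 450 trials (above 0.9); selection-accuracy simulation with 20
strongly deterministic guilt-dominant agents; Welch type-I calibration
over 2000 null replicates; and byte-identity of pipeline reruns.

## Known limitations

- **Per-participant specification evidence is capped.** Because the
  payoff part of Guilt is a linear combination of Reward and the signed
  split-inequity gaps (see Design generation), the four-parameter
  siblings of `RwGuIq` (`RwGuIp`, `RwGuIn`) and — whenever
  $\gamma \bar\tau \approx \alpha$ — even the three-parameter `RwIp`
  capture most of the generative signal. At 45 Bernoulli trials the
  expected evidence for the exact specification over its nearest sibling
  is only a few deviance units, and pushing effect sizes higher saturates
  choice probabilities and destroys information rather than adding it.
  Consequently, group-level selection (mean predictive NLL and mean BIC)
  recovers the generating model reliably and it is the modal individual
  winner, but a strict per-participant majority of smallest-BIC wins is
  not attainable under this generative model; the corresponding strict
  assertion in the acceptance tests documents this and fails by design.
  The validation cohort for selection is guilt-dominant
  ($\gamma = 0.014$, $\alpha = 0.006$, centered logit) precisely to stay
  off the $\gamma\bar\tau = \alpha$ cancellation manifold.
- Firth shrinkage biases per-participant coefficients toward zero at 45
  trials; recovery is assessed by rank correlation, and the bias shrinks
  with trial count (tested at 45 vs 450).
- The mediator is linear-Gaussian; logistic or ordinal mediation variants
  are out of scope.
- The questionnaire copula assumes a single latent factor; realized
  item-level correlations inherit quintile-discretization attenuation.
- Adjusted $R^2$ of the 22-coefficient regression is reported as
  computed; no attempt is made to reproduce any particular published
  value of it.
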