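#' Scenario for a two-treatment, two-endpoint adaptive trial
#'
#' Describes the three-arm trial emulated by the simulator: two treatments
#' compared against a common control on a primary and a secondary endpoint
#' (hypotheses H1, H2 primary and H3, H4 secondary for treatments 1 and 2),
#' plus a toxicity marker per treatment. The six standardized test statistics
#' `(z1, z2, z3, z4, t1, t2)` are multivariate normal with mean
#' `sqrt(n_s / 2) * (d1/s1, d2/s2, d1/s1, d2/s2, 0, kappa/st)` at per-group
#' stage sample size `n_s` and correlation matrix built from: 1/2 between
#' arms on the same endpoint (balanced groups sharing the control), `rho`
#' between endpoints within an arm, `zeta` between a treatment's toxicity
#' marker and its primary endpoint, and the induced products (`zeta * rho`,
#' `rho / 2`, `zeta / 2`, `zeta * rho / 2`) elsewhere.
#'
#' @param delta1,delta2 Mean efficacy effect sizes of treatments 1 and 2
#'   (outcome units; equal across endpoints within a treatment).
#' @param sigma1,sigma2 Endpoint standard deviations (default 1).
#' @param sigma_t Toxicity-marker standard deviation (default 1).
#' @param rho Within-arm between-endpoint correlation.
#' @param zeta Toxicity-primary-endpoint correlation.
#' @param kappa Toxicity effect of treatment 2 (treatment 1 has none).
#' @param s Toxicity drop threshold on the z scale (default
#'   `qnorm(0.95) = 1.645`).
#' @param n,n1 Preplanned total and first-stage per-group sample sizes.
#' @param rule Interim adaptation rule: `"PP"` (no adaptation), `"SB"`
#'   (keep the arm with the larger interim primary z-score), `"FF"` (drop
#'   one arm at random with probability 1/2, independent of the data), or
#'   `"SF"` (drop any arm whose toxicity score exceeds `s`).
#' @param reallocate If `TRUE`, patients planned for a dropped arm are
#'   reallocated and the continued groups' second-stage per-group size is
#'   `n2_reallocated`; otherwise it stays `n - n1`.
#' @param n2_reallocated Second-stage per-group size after reallocation
#'   (default 82 for `n = 116`).
#' @param alpha One-sided familywise error level.
#' @param graph Preplanned [hyp_graph()] over H1..H4; defaults to the
#'   symmetric primary-before-secondary strategy of
#'   [graph_two_arm_hierarchy()].
#' @return An object of class `trial_scenario`.
#' @examples
#' trial_scenario(delta1 = 0.4, delta2 = 0.4, rule = "SB")
#' @export
trial_scenario <- function(delta1 = 0, delta2 = 0,
                           sigma1 = 1, sigma2 = 1, sigma_t = 1,
                           rho = 0.3, zeta = 0.5, kappa = 0,
                           s = stats::qnorm(0.95),
                           n = 116, n1 = 58,
                           rule = c("PP", "SB", "FF", "SF"),
                           reallocate = FALSE, n2_reallocated = 82,
                           alpha = 0.025,
                           graph = graph_two_arm_hierarchy()) {
  rule <- match.arg(rule)
  .check_alpha(alpha)
  if (!(n1 > 0 && n1 < n)) stop("need 0 < n1 < n", call. = FALSE)
  Sigma <- .trial_sigma(rho, zeta)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9) {
    stop("correlations rho, zeta do not give a positive semi-definite matrix",
      call. = FALSE
    )
  }
  structure(
    list(
      delta1 = delta1, delta2 = delta2,
      sigma1 = sigma1, sigma2 = sigma2, sigma_t = sigma_t,
      rho = rho, zeta = zeta, kappa = kappa, s = s,
      n = n, n1 = n1, rule = rule,
      reallocate = reallocate, n2_reallocated = n2_reallocated,
      alpha = alpha, graph = graph,
      Sigma = Sigma,
      theta_unit = c(
        delta1 / sigma1, delta2 / sigma2, delta1 / sigma1, delta2 / sigma2,
        0, kappa / sigma_t
      )
    ),
    class = "trial_scenario"
  )
}

# correlation of (z1, z2, z3, z4, t1, t2)
.trial_sigma <- function(rho, zeta) {
  S <- matrix(c(
    1, 1 / 2, rho, rho / 2, zeta, zeta / 2,
    1 / 2, 1, rho / 2, rho, zeta / 2, zeta,
    rho, rho / 2, 1, 1 / 2, zeta * rho, zeta * rho / 2,
    rho / 2, rho, 1 / 2, 1, zeta * rho / 2, zeta * rho,
    zeta, zeta / 2, zeta * rho, zeta * rho / 2, 1, 1 / 2,
    zeta / 2, zeta, zeta * rho / 2, zeta * rho, 1 / 2, 1
  ), 6, 6, byrow = TRUE)
  dimnames(S) <- list(.score_names, .score_names)
  S
}

.score_names <- c("z1", "z2", "z3", "z4", "t1", "t2")

#' @export
print.trial_scenario <- function(x, ...) {
  cat(sprintf(
    "<trial_scenario> delta = (%g, %g), rho = %g, zeta = %g, kappa = %g\n",
    x$delta1, x$delta2, x$rho, x$zeta, x$kappa
  ))
  cat(sprintf(
    "n = %g, n1 = %g, rule = %s, reallocate = %s (n2 = %g)\n",
    x$n, x$n1, x$rule, x$reallocate,
    if (x$reallocate) x$n2_reallocated else x$n - x$n1
  ))
  invisible(x)
}

#' Draw stagewise standardized test statistics
#'
#' One stage's score vector(s) `(z1, z2, z3, z4, t1, t2)` (or the requested
#' subset of components) from the scenario's multivariate normal model at
#' per-group stage sample size `n_s`. Stages are simulated as independent
#' draws; the full-data statistic is recovered as
#' `sqrt(t) * z(1) + sqrt(1 - t) * z(2)`.
#'
#' @param scenario A [trial_scenario()].
#' @param n_s Per-group sample size of the stage.
#' @param reps Number of draws.
#' @param active Components to draw (indices into
#'   `c("z1","z2","z3","z4","t1","t2")`).
#' @param seed Optional integer seed (`set.seed` is called when supplied;
#'   otherwise the current RNG stream is used).
#' @return A `reps` x `length(active)` matrix of scores.
#' @examples
#' scen <- trial_scenario(delta1 = 0.4, delta2 = 0.4)
#' simulate_stage_scores(scen, n_s = 58, reps = 3, seed = 1)
#' @export
simulate_stage_scores <- function(scenario, n_s, reps = 1,
                                  active = 1:6, seed = NULL) {
  stopifnot(inherits(scenario, "trial_scenario"))
  if (n_s <= 0) stop("`n_s` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  S <- scenario$Sigma[active, active, drop = FALSE]
  mu <- sqrt(n_s / 2) * scenario$theta_unit[active]
  k <- length(active)
  Z <- matrix(stats::rnorm(reps * k), reps, k) %*% chol(S)
  Z <- sweep(Z, 2, mu, `+`)
  colnames(Z) <- .score_names[active]
  Z
}

#' Apply the interim adaptation rule
#'
#' Given first-stage scores, decides which treatment arms are dropped and
#' the continued groups' second-stage per-group sample size. Dropping an arm
#' drops both of its hypotheses. `"SB"` keeps the arm with the larger
#' interim primary z-score (a tie, a probability-zero event, drops arm 2);
#' `"FF"` drops one arm with probability 1/2 independent of the data (one
#' uniform draw per trial); `"SF"` drops each arm whose toxicity score
#' exceeds the threshold `s` (possibly both, possibly neither); `"PP"` drops
#' nothing.
#'
#' @param interim First-stage scores: a vector of length 6 or a `reps` x 6
#'   matrix as returned by [simulate_stage_scores()].
#' @param scenario A [trial_scenario()].
#' @return A tibble with one row per trial: logical `drop1`, `drop2`, and
#'   `n2` (second-stage per-group size for continued treatment groups).
#' @export
apply_rule <- function(interim, scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  if (is.null(dim(interim))) interim <- matrix(interim, nrow = 1)
  if (ncol(interim) != 6) {
    stop("`interim` must have the 6 score components", call. = FALSE)
  }
  reps <- nrow(interim)
  drop1 <- drop2 <- rep(FALSE, reps)
  if (scenario$rule == "SB") {
    drop2 <- interim[, 1] >= interim[, 2]
    drop1 <- !drop2
  } else if (scenario$rule == "FF") {
    drop1 <- stats::runif(reps) < 0.5
    drop2 <- !drop1
  } else if (scenario$rule == "SF") {
    drop1 <- interim[, 5] > scenario$s
    drop2 <- interim[, 6] > scenario$s
  }
  one_dropped <- xor(drop1, drop2)
  n2 <- rep(scenario$n - scenario$n1, reps)
  if (scenario$reallocate) n2[one_dropped] <- scenario$n2_reallocated
  tibble::tibble(drop1 = drop1, drop2 = drop2, n2 = n2)
}

# second-stage graph used in the simulation when one arm is dropped: the
# continued arm's primary hypothesis gets weight 1, passed to its secondary
# hypothesis on rejection; the dropped arm's nodes and edges are zeroed
.continued_arm_graph <- function(scenario, arm) {
  m <- 4
  w <- numeric(m)
  G <- matrix(0, m, m)
  w[arm] <- 1
  G[arm, arm + 2] <- 1
  hyp_graph(w, G, names = scenario$graph$names)
}

# --- vectorised Monte Carlo engine -----------------------------------------
#
# draws stage-1 scores, applies the rule and draws stage-2 scores for all
# replicates at once; decision logic is specialised to the simulation's
# second-stage graphs, in which every intersection hypothesis carries at most
# one positive second-stage weight so that the eq8 allocation fractions
# reduce to v = w2 (a single 1). run_trial() recomputes single replicates
# through the generic object pipeline; the two paths are required to agree.
.engine_draws <- function(scenario, procedure, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  E1 <- simulate_stage_scores(scenario, scenario$n1, reps)
  sc <- scenario
  if (procedure == "gMCP") {
    # the preplanned fixed-sample procedure ignores the adaptation rule
    sc$rule <- "PP"
    sc$reallocate <- FALSE
  }
  rule_out <- apply_rule(E1, sc)
  # standardised stage-2 efficacy scores (mean added per replicate later,
  # since the stage-2 sample size may differ between replicates)
  E2 <- matrix(stats::rnorm(reps * 4), reps, 4) %*%
    chol(scenario$Sigma[1:4, 1:4])
  list(z1 = E1, rule = rule_out, e2 = E2, scenario = scenario)
}

.engine_decide <- function(draws, procedure) {
  scenario <- draws$scenario
  z1 <- draws$z1
  reps <- nrow(z1)
  drop1 <- draws$rule$drop1
  drop2 <- draws$rule$drop2
  n2 <- draws$rule$n2
  t <- scenario$n1 / scenario$n
  alpha <- scenario$alpha
  W <- .weight_matrix(derive_weights(scenario$graph))
  theta4 <- scenario$theta_unit[1:4]

  rej <- matrix(FALSE, reps, 4)

  # -- no arm dropped: preplanned fixed-sample graph test on pooled z
  none <- !drop1 & !drop2
  if (any(none)) {
    n2s <- scenario$n - scenario$n1
    z2 <- draws$e2[none, , drop = FALSE] +
      matrix(sqrt(n2s / 2) * theta4, sum(none), 4, byrow = TRUE)
    zf <- sqrt(t) * z1[none, 1:4, drop = FALSE] + sqrt(1 - t) * z2
    P <- 1 - stats::pnorm(zf)
    dec <- .closure_decisions(P, W, alpha)
    rej[none, ] <- .closure_elementary(dec, 4)
  }

  # -- exactly one arm dropped
  for (arm in 1:2) {
    sel <- if (arm == 1) drop2 & !drop1 else drop1 & !drop2
    if (!any(sel)) next
    c1 <- arm
    c2 <- arm + 2
    z2c <- draws$e2[sel, c(c1, c2), drop = FALSE] +
      cbind(
        sqrt(n2[sel] / 2) * theta4[c1],
        sqrt(n2[sel] / 2) * theta4[c2]
      )
    q <- matrix(1, sum(sel), 4)
    q[, c1] <- 1 - stats::pnorm(z2c[, 1])
    q[, c2] <- 1 - stats::pnorm(z2c[, 2])
    if (procedure == "agMTP") {
      rej[sel, ] <- .agmtp_one_arm(
        z1[sel, 1:4, drop = FALSE], q, W, alpha, t, c1, c2
      )
    } else { # gPA (and saMTP when nothing else changes)
      p <- matrix(1, sum(sel), 4)
      p[, c1] <- 1 - stats::pnorm(sqrt(t) * z1[sel, c1] + sqrt(1 - t) * z2c[, 1])
      p[, c2] <- 1 - stats::pnorm(sqrt(t) * z1[sel, c2] + sqrt(1 - t) * z2c[, 2])
      dec <- .closure_decisions(p, W, alpha)
      rej[sel, ] <- .closure_elementary(dec, 4)
    }
  }

  # -- both arms dropped (possible under SF): no elementary rejections
  rej
}

# vectorised adaptive closed test when the continued arm's hierarchy is the
# whole second-stage graph: every subset has one positive second-stage weight
# (the continued primary if present, else the continued secondary), whose
# allocation fraction is 1
.agmtp_one_arm <- function(z1, q, W, alpha, t, c1, c2) {
  reps <- nrow(z1)
  n_sub <- nrow(W)
  psi <- matrix(TRUE, reps, 4)
  for (J in seq_len(n_sub)) {
    wJ <- W[J, ]
    pos <- which(wJ > 0)
    B <- rep(0, reps)
    for (j in pos) {
      B <- B + ztest_pce(z1[, j], wJ[j] * alpha, t)
    }
    memb <- .bit_members(J, 4)
    jstar <- if (memb[c1]) c1 else if (memb[c2]) c2 else 0L
    decJ <- B >= 1
    if (jstar > 0L) decJ <- decJ | (q[, jstar] < B)
    for (i in which(memb)) psi[, i] <- psi[, i] & decJ
  }
  psi
}

#' Simulate a single adaptive trial
#'
#' Draws one trial from the scenario, applies the interim rule and evaluates
#' the requested procedure through the package's generic testing pipeline:
#' if nothing is dropped, the preplanned fixed-sample graph test on the
#' pooled z-scores; if one arm is dropped, either the adaptive closed test
#' (`"agMTP"`, second-stage graph = the continued arm's hierarchy at weight
#' 1, z-test partial conditional errors, eq8 fractions) or the inverse-normal
#' comparator (`"gPA"`); if both arms are dropped, no rejections.
#' `"gMCP"` ignores the rule and always performs the preplanned test.
#'
#' @param scenario A [trial_scenario()].
#' @param procedure `"gMCP"`, `"agMTP"` or `"gPA"`.
#' @param seed Optional integer seed.
#' @return A list with `decisions` (tibble: hypothesis, rejected), `dropped`
#'   (integer arms dropped at interim) and `n2` (second-stage per-group
#'   size).
#' @examples
#' scen <- trial_scenario(delta1 = 0.4, delta2 = 0.4, rule = "SB")
#' run_trial(scen, "agMTP", seed = 7)
#' @export
run_trial <- function(scenario, procedure = c("gMCP", "agMTP", "gPA"),
                      seed = NULL) {
  stopifnot(inherits(scenario, "trial_scenario"))
  procedure <- match.arg(procedure)
  draws <- .engine_draws(scenario, procedure, reps = 1, seed = seed)
  z1 <- drop(draws$z1)
  drop1 <- draws$rule$drop1[1]
  drop2 <- draws$rule$drop2[1]
  n2 <- draws$rule$n2[1]
  t <- scenario$n1 / scenario$n
  plan <- stage_plan(scenario$alpha, scenario$n, scenario$n1)
  theta4 <- scenario$theta_unit[1:4]
  graph <- scenario$graph
  hyp <- graph$names

  if (!drop1 && !drop2) {
    n2s <- scenario$n - scenario$n1
    z2 <- drop(draws$e2) + sqrt(n2s / 2) * theta4
    p <- 1 - stats::pnorm(sqrt(t) * z1[1:4] + sqrt(1 - t) * z2)
    res <- sequentially_rejective(p, graph, scenario$alpha)
    decisions <- tibble::tibble(hypothesis = hyp, rejected = res$rejected)
    dropped_arms <- integer(0)
  } else if (drop1 && drop2) {
    decisions <- tibble::tibble(hypothesis = hyp, rejected = FALSE)
    dropped_arms <- 1:2
  } else {
    arm <- if (drop1) 2L else 1L # continued arm
    dropped_arms <- if (drop1) 1L else 2L
    c1 <- arm
    c2 <- arm + 2L
    z2 <- drop(draws$e2)[c(c1, c2)] + sqrt(n2 / 2) * theta4[c(c1, c2)]
    q <- rep(1, 4)
    q[c(c1, c2)] <- 1 - stats::pnorm(z2)
    if (procedure == "agMTP") {
      fit <- agmtp(
        z1 = z1[1:4], q = q, graph = graph,
        graph2 = .continued_arm_graph(scenario, arm), plan = plan,
        continued = c(c1, c2), strategy = "eq8"
      )
      decisions <- tibble::tibble(
        hypothesis = hyp, rejected = fit$decisions$rejected
      )
    } else {
      q1 <- 1 - stats::pnorm(z1[1:4])
      res <- samtp_gpa(
        graph = graph, dropped = c(dropped_arms, dropped_arms + 2L),
        plan = plan, q1 = q1, q = q
      )
      decisions <- tibble::tibble(hypothesis = hyp, rejected = res$rejected)
    }
  }
  list(decisions = decisions, dropped = dropped_arms, n2 = n2)
}

#' Monte Carlo operating characteristics
#'
#' Estimates, in percent, the probability of at least one rejection (`pi`),
#' the per-hypothesis rejection probabilities (`pi_1` ... `pi_4`) and the
#' per-arm interim drop probabilities (`eta_1`, `eta_2`) for a scenario and
#' procedure, using the vectorised simulation engine. Reproducible given
#' `seed`.
#'
#' @inheritParams run_trial
#' @param reps Number of simulated trials.
#' @param seed Integer seed.
#' @return A one-row tibble of class `agmtp_oc` with columns `procedure`,
#'   `rule`, `reallocate`, `reps`, `pi`, `pi_1` .. `pi_4`, `eta_1`, `eta_2`
#'   and `se` (binomial Monte Carlo standard error of `pi`, in percent).
#' @examples
#' scen <- trial_scenario(delta1 = 0.4, delta2 = 0.4, rule = "SB")
#' operating_characteristics(scen, "agMTP", reps = 2000, seed = 1)
#' @export
operating_characteristics <- function(scenario,
                                      procedure = c("gMCP", "agMTP", "gPA"),
                                      reps, seed = NULL) {
  stopifnot(inherits(scenario, "trial_scenario"), reps >= 1)
  procedure <- match.arg(procedure)
  draws <- .engine_draws(scenario, procedure, reps = reps, seed = seed)
  rej <- .engine_decide(draws, procedure)
  pi_any <- 100 * mean(rowSums(rej) > 0)
  out <- tibble::tibble(
    procedure = procedure,
    rule = if (procedure == "gMCP") "PP" else scenario$rule,
    reallocate = scenario$reallocate,
    reps = as.integer(reps),
    pi = pi_any,
    pi_1 = 100 * mean(rej[, 1]),
    pi_2 = 100 * mean(rej[, 2]),
    pi_3 = 100 * mean(rej[, 3]),
    pi_4 = 100 * mean(rej[, 4]),
    eta_1 = 100 * mean(draws$rule$drop1),
    eta_2 = 100 * mean(draws$rule$drop2),
    se = 100 * sqrt(pi_any / 100 * (1 - pi_any / 100) / reps)
  )
  class(out) <- c("agmtp_oc", class(out))
  out
}

#' Sample-size determination for the preplanned graph test
#'
#' Searches for the smallest per-group sample size, subject to a
#' divisibility constraint, at which the fixed-sample graph-based test
#' rejects at least one primary hypothesis (H1 or H2) with the target
#' probability. Power per candidate is estimated by Monte Carlo with common
#' random numbers across candidates, which makes the estimated power curve
#' monotone in `n` replicate by replicate, so a bracketed bisection over the
#' divisible candidates applies.
#'
#' @param target Target power in (0, 1), e.g. 0.9.
#' @param delta Common standardized effect size of both treatments on both
#'   endpoints.
#' @param sigma Common endpoint standard deviation.
#' @param rho Within-arm between-endpoint correlation.
#' @param zeta Toxicity correlation (carried in the scenario; it does not
#'   influence the efficacy test).
#' @param alpha One-sided familywise error level.
#' @param divisor Candidate sample sizes are multiples of this (default 4,
#'   so that half of a dropped arm's second stage can be reallocated).
#' @param reps Monte Carlo replicates per candidate.
#' @param seed Integer seed.
#' @param n_max Upper bound of the search.
#' @param graph Preplanned [hyp_graph()].
#' @return A list of class `sample_size_search` with `n` (the selected
#'   per-group size) and `power_curve` (tibble of candidate `n` and
#'   estimated `power`).
#' @examples
#' find_sample_size(
#'   target = 0.9, delta = 0.4, rho = 0.3,
#'   reps = 2000, seed = 1
#' )
#' @export
find_sample_size <- function(target = 0.9, delta = 0.4, sigma = 1,
                             rho = 0.3, zeta = 0.5, alpha = 0.025,
                             divisor = 4, reps = 1e5, seed = NULL,
                             n_max = 1000, graph = graph_two_arm_hierarchy()) {
  if (!(target > 0 && target < 1)) stop("`target` must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  S4 <- .trial_sigma(rho, zeta)[1:4, 1:4]
  E <- matrix(stats::rnorm(reps * 4), reps, 4) %*% chol(S4)
  W <- .weight_matrix(derive_weights(graph))
  theta4 <- rep(delta / sigma, 4)
  power_at <- function(n) {
    Z <- E + matrix(sqrt(n / 2) * theta4, reps, 4, byrow = TRUE)
    P <- 1 - stats::pnorm(Z)
    dec <- .closure_decisions(P, W, alpha)
    psi <- .closure_elementary(dec, 4)
    mean(psi[, 1] | psi[, 2])
  }
  evaluated <- list()
  pw <- function(n) {
    key <- as.character(n)
    if (is.null(evaluated[[key]])) evaluated[[key]] <<- power_at(n)
    evaluated[[key]]
  }
  lo <- divisor
  hi <- divisor
  while (pw(hi) < target) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_max) {
      stop("target power not reachable below n_max = ", n_max, call. = FALSE)
    }
  }
  # bisection over multiples of `divisor`; pw is monotone under common
  # random numbers
  lo_k <- lo %/% divisor
  hi_k <- hi %/% divisor
  while (hi_k - lo_k > 1) {
    mid_k <- (lo_k + hi_k) %/% 2
    if (pw(mid_k * divisor) >= target) hi_k <- mid_k else lo_k <- mid_k
  }
  n_sel <- as.integer(hi_k * divisor)
  curve <- tibble::tibble(
    n = as.integer(names(evaluated)),
    power = unlist(evaluated, use.names = FALSE)
  )
  curve <- dplyr::arrange(curve, .data$n)
  structure(
    list(n = n_sel, target = target, power_curve = curve),
    class = "sample_size_search"
  )
}

#' @export
print.sample_size_search <- function(x, ...) {
  cat(sprintf(
    "<sample_size_search> smallest n with power >= %g: %d per group\n",
    x$target, x$n
  ))
  print(x$power_curve)
  invisible(x)
}
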