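test_that("gamma equals alpha when the weighting strategy is unchanged", {
  set.seed(29)
  plan <- case_plan()
  for (rep in 1:10) {
    m <- sample(2:4, 1)
    z1 <- rnorm(m, 1)
    w <- runif(m)
    w <- w / sum(w)
    B <- sum(ztest_pce(z1, w * plan$alpha, plan$t))
    if (B >= 1) next
    expect_equal(solve_gamma(z1, w, B, plan), plan$alpha, tolerance = 1e-8)
  }
})

test_that("gamma solves the conditional-level equation for modified weights", {
  plan <- case_plan()
  z1 <- c(1.66, 1.42)
  # reversed fixed sequence: all second-stage weight on H2
  B <- ztest_pce(z1[1], plan$alpha, plan$t) # A1(alpha) + A2(0)
  g <- solve_gamma(z1, c(0, 1), B, plan)
  expect_equal(g, oracle_gamma(z1, c(0, 1), B, plan$alpha, plan$t),
    tolerance = 1e-8
  )
  expect_equal(ztest_pce(z1[2], g, plan$t), B, tolerance = 1e-9)
  # switch to a Holm-type split: each summand positive and below the total
  gh <- solve_gamma(z1, c(1 / 2, 1 / 2), B, plan)
  expect_equal(gh, oracle_gamma(z1, c(1 / 2, 1 / 2), B, plan$alpha, plan$t),
    tolerance = 1e-8
  )
  parts <- ztest_pce(z1, gh / 2, plan$t)
  expect_equal(sum(parts), B, tolerance = 1e-9)
  expect_true(all(parts > 0 & parts < B))

  expect_error(solve_gamma(z1, c(0, 0), B, plan), "zero")
  expect_error(solve_gamma(z1, c(0, 1), 1.2, plan), "interim")
})

test_that("eq8 allocation fractions sum to one and vanish with the weight", {
  set.seed(31)
  plan <- case_plan()
  for (rep in 1:10) {
    m <- 4
    z1 <- rnorm(m, 0.8)
    w <- runif(m)
    w <- w / sum(w)
    B <- sum(ztest_pce(z1, w * plan$alpha, plan$t))
    if (B >= 1) next
    w2 <- w
    w2[sample(m, 1)] <- 0
    w2 <- w2 / sum(w2)
    v <- allocation_fractions(z1, w2, B, plan)
    expect_equal(sum(v), 1, tolerance = 1e-7)
    expect_true(all(v[w2 == 0] == 0))
    expect_true(all(v >= 0))
  }
  # direct strategy passes the weights through
  expect_identical(
    allocation_fractions(c(1, 1), c(0.3, 0.7), 0.1, plan, strategy = "direct"),
    c(0.3, 0.7)
  )
})

test_that("equal recycling hands dropped errors to the continued hypotheses", {
  A <- c(0.06, 0.04, 0.02, NA)
  # nothing dropped: fractions are A / B
  v <- equal_recycling_fractions(A, continued = 1:3)
  expect_equal(v[1:3], c(0.06, 0.04, 0.02) / 0.12)
  # dropping H2 splits its error equally among the continued members
  v2 <- equal_recycling_fractions(A, continued = c(1, 3))
  B <- 0.12
  expect_equal(v2, c(0.06 + 0.02, 0, 0.02 + 0.02, 0) / B)
  expect_equal(sum(v2), 1)
  # recycled conditional levels dominate the preplanned ones
  expect_true(all(v2[c(1, 3)] * B >= A[c(1, 3)]))
  expect_error(equal_recycling_fractions(A, continued = 4), "continued")
})

test_that("the adapted intersection test rejects at interim when B >= 1", {
  expect_identical(adapted_intersection_decision(rep(1, 3), rep(0, 3), 1.2), 1L)
  expect_identical(adapted_intersection_decision(rep(1, 3), c(1, 0, 0), 0.9), 0L)
  # strict comparison: a p-value exactly at the boundary does not reject
  expect_identical(adapted_intersection_decision(c(0.05, 1), c(1, 0), 0.05), 0L)
  expect_identical(adapted_intersection_decision(c(0.049, 1), c(1, 0), 0.05), 1L)
})

test_that("the worked two-treatment example rejects exactly H1 and H3", {
  fit <- agmtp(
    z1 = case_z1(), q = c(0.059, 1, 0.031, 1),
    graph = case_graph(), graph2 = graph_two_arm_hierarchy(dropped = 2),
    plan = case_plan()
  )
  expect_identical(fit$decisions$rejected, c(TRUE, FALSE, TRUE, FALSE))
  # with exactly one positive second-stage weight per subset, the eq8
  # fractions coincide with the second-stage weights
  W2 <- attr(fit$design$weights2, "weight_matrix")
  expect_equal(unname(fit$design$v), unname(W2), tolerance = 1e-7)
  # the binding conditional levels: min B over subsets containing H1, and
  # over subsets containing H3 but not H1
  inter <- fit$intersections
  in_J <- function(i) bitwAnd(bitwShiftR(inter$bitmask, i - 1L), 1L) == 1L
  expect_equal(round(min(inter$B[in_J(1)]), 3), 0.074)
  expect_equal(round(min(inter$B[in_J(3) & !in_J(1)]), 3), 0.111)
})

test_that("adaptive closure matches the exhaustive oracle on random designs", {
  set.seed(37)
  plan <- case_plan()
  for (rep in 1:40) {
    m <- sample(2:4, 1)
    g <- random_graph(m)
    z1 <- rnorm(m, 0.5)
    q <- runif(m)
    dropped <- if (m > 2 && runif(1) < 0.5) sample(m, 1) else integer(0)
    continued <- setdiff(seq_len(m), dropped)
    w2 <- unname(g$w)
    G2 <- unname(g$G)
    w2[dropped] <- 0
    G2[dropped, ] <- 0
    G2[, dropped] <- 0
    g2 <- hyp_graph(w2, G2, names = g$names)
    q_full <- q
    q_full[dropped] <- 1
    fit <- agmtp(z1, q_full, g, g2, plan, continued = continued)
    expect_identical(
      fit$decisions$rejected,
      oracle_agmtp(z1, q_full, g, g2, plan$alpha, plan$t),
      label = paste("design", rep)
    )
  }
})

test_that("no adaptation reduces to the preplanned test, modulo early rejections", {
  set.seed(43)
  plan <- case_plan()
  g <- case_graph()
  w <- derive_weights(g)
  for (rep in 1:50) {
    z1 <- rnorm(4, runif(1, -0.5, 2))
    z2 <- rnorm(4, runif(1, -0.5, 2))
    q <- 1 - pnorm(z2)
    p_full <- 1 - pnorm(sqrt(plan$t) * z1 + sqrt(1 - plan$t) * z2)
    fixed <- closed_test(p_full, w, plan$alpha)$rejected
    fit <- agmtp(z1, q, g, g, plan)
    adaptive <- fit$decisions$rejected
    # the interim B >= 1 branch can only add rejections
    expect_true(all(fixed <= adaptive))
    if (max(fit$design$B) < 1) expect_identical(adaptive, fixed)
  }
})

test_that("gamma never falls below alpha after dropping positively weighted hypotheses", {
  set.seed(47)
  plan <- case_plan()
  for (rep in 1:20) {
    m <- 4
    g <- random_graph(m)
    z1 <- rnorm(m, 0.5)
    dropped <- sample(m, 1)
    W <- attr(derive_weights(g), "weight_matrix")
    for (J in seq_len(2^m - 1)) {
      memb <- bitwAnd(bitwShiftR(J, 0:(m - 1)), 1L) == 1L
      if (!memb[dropped]) next
      wJ <- W[J, ]
      if (wJ[dropped] <= 0) next # nothing recycled
      B <- sum(ztest_pce(z1, wJ * plan$alpha, plan$t)[wJ > 0])
      if (B >= 1) next
      w2 <- wJ
      w2[dropped] <- 0
      if (all(w2 <= 0)) next
      expect_gte(solve_gamma(z1, w2, B, plan), plan$alpha - 1e-9)
    }
  }
})

test_that("the adaptive closed test dominates the inverse-normal comparator", {
  set.seed(53)
  plan <- case_plan()
  n_strict <- 0
  for (rep in 1:1000) {
    m <- 4
    g <- random_graph(m)
    z1 <- rnorm(m, runif(1, 0, 1.5))
    z2 <- rnorm(m, runif(1, 0, 1.5))
    q <- 1 - pnorm(z2)
    dropped <- sample(m, sample(1:2, 1))
    continued <- setdiff(seq_len(m), dropped)
    # second-stage weights: the preplanned per-subset weights with the
    # dropped hypotheses' columns zeroed (the theorem's construction)
    w2tbl <- derive_weights(g)
    W2 <- attr(w2tbl, "weight_matrix")
    W2[, dropped] <- 0
    attr(w2tbl, "weight_matrix") <- W2
    q_full <- q
    q_full[dropped] <- 1
    fit <- agmtp(z1, q_full, g, w2tbl, plan,
      continued = continued, pce = inverse_normal_pce
    )
    ag <- fit$decisions$rejected
    q1 <- 1 - pnorm(z1)
    gpa <- samtp_gpa(
      graph = g, dropped = dropped, plan = plan,
      q1 = q1, q = q_full
    )$rejected
    expect_true(all(gpa <= ag), label = paste("instance", rep))
    if (any(ag & !gpa)) n_strict <- n_strict + 1
  }
  # the gain is real: strictly more rejections in some instances
  expect_gt(n_strict, 0)
})

test_that("the comparator reduces to the preplanned test when nothing is dropped", {
  set.seed(59)
  plan <- stage_plan(0.025, 116, 58) # equal stages
  g <- case_graph()
  for (rep in 1:20) {
    z1 <- rnorm(4, 1)
    z2 <- rnorm(4, 1)
    res <- samtp_gpa(
      graph = g, dropped = integer(0), plan = plan,
      q1 = 1 - pnorm(z1), q = 1 - pnorm(z2)
    )
    fixed <- sequentially_rejective(
      1 - pnorm(sqrt(0.5) * z1 + sqrt(0.5) * z2), g, plan$alpha
    )
    expect_identical(res$rejected, fixed$rejected)
  }
  expect_false(any(samtp_gpa(
    graph = g, dropped = 1:4, plan = plan,
    q1 = rep(0.01, 4), q = rep(0.01, 4)
  )$rejected))
})
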