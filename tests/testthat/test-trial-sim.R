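test_that("scenario construction validates its correlation structure", {
  scen <- trial_scenario(delta1 = 0.4, delta2 = 0.4, rho = 0.3, zeta = 0.5)
  S <- scen$Sigma
  expect_equal(S["z1", "z2"], 1 / 2)
  expect_equal(S["z1", "z3"], 0.3)
  expect_equal(S["z1", "t1"], 0.5)
  expect_equal(S["z3", "t1"], 0.5 * 0.3)
  expect_equal(S["z4", "t1"], 0.5 * 0.3 / 2)
  expect_true(isSymmetric(S))
  expect_error(
    trial_scenario(rho = 1.2, zeta = 0.5),
    "positive semi-definite"
  )
  expect_error(trial_scenario(n = 58, n1 = 58), "n1")
})

test_that("stagewise scores have the prescribed means and correlations", {
  scen0 <- trial_scenario(delta1 = 0, delta2 = 0, kappa = 0)
  Z <- simulate_stage_scores(scen0, n_s = 58, reps = 20000, seed = 61)
  expect_true(all(abs(colMeans(Z)) < 3 / sqrt(20000) * 1.1))

  scen <- trial_scenario(delta1 = 0, delta2 = 0.4, rho = 0.3, zeta = 0.5)
  Z <- simulate_stage_scores(scen, n_s = 58, reps = 20000, seed = 62)
  # mean of z2 is sqrt(n_s / 2) * delta2 / sigma2
  expect_lt(abs(mean(Z[, "z2"]) - sqrt(29) * 0.4), 3 / sqrt(20000))
  # same-endpoint cross-arm correlation 1/2; within-arm endpoint rho
  expect_lt(abs(cor(Z[, "z1"], Z[, "z2"]) - 0.5), 3 / sqrt(20000) * 1.5)
  expect_lt(abs(cor(Z[, "z1"], Z[, "z3"]) - 0.3), 3 / sqrt(20000) * 1.5)
  expect_error(simulate_stage_scores(scen, n_s = 0), "n_s")
})

test_that("interim rules drop the intended arms", {
  z <- c(1.66, 1.42, 1.90, 0.79, 0, 0)
  sb <- trial_scenario(rule = "SB")
  out <- apply_rule(z, sb)
  expect_false(out$drop1)
  expect_true(out$drop2) # arm 1 has the larger interim primary z
  expect_equal(out$n2, 58)

  pp <- apply_rule(z, trial_scenario(rule = "PP"))
  expect_false(pp$drop1 || pp$drop2)

  sf <- trial_scenario(rule = "SF", reallocate = TRUE, n2_reallocated = 82)
  both <- apply_rule(c(0, 0, 0, 0, 2, 2), sf)
  expect_true(both$drop1 && both$drop2)
  expect_equal(both$n2, 58) # reallocation only applies when one arm is dropped
  one <- apply_rule(c(0, 0, 0, 0, 0, 2), sf)
  expect_true(!one$drop1 && one$drop2)
  expect_equal(one$n2, 82)
  none <- apply_rule(c(0, 0, 0, 0, 0, 0), sf)
  expect_false(none$drop1 || none$drop2)

  set.seed(63)
  ff <- apply_rule(
    matrix(0, 10000, 6), trial_scenario(rule = "FF")
  )
  expect_true(all(xor(ff$drop1, ff$drop2)))
  expect_lt(abs(mean(ff$drop1) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("drop probability under select-better matches the closed form", {
  scen <- trial_scenario(delta1 = 0, delta2 = 0.4, rule = "SB")
  oc <- operating_characteristics(scen, "agMTP", reps = 5e4, seed = 64)
  # interim z1 - z2 is normal with unit variance (cross-arm correlation 1/2)
  eta_true <- 100 * pnorm(sqrt(58 / 2) * 0.4)
  mcse <- 100 * sqrt(eta_true / 100 * (1 - eta_true / 100) / 5e4)
  expect_lt(abs(oc$eta_1 - eta_true), 3 * mcse)
  expect_equal(oc$eta_1 + oc$eta_2, 100)
})

test_that("single-trial runs agree with the vectorised engine", {
  scens <- list(
    trial_scenario(delta1 = 0.3, delta2 = 0.4, rule = "SB"),
    trial_scenario(delta1 = 0.4, delta2 = 0.4, rule = "SF", kappa = 0.4,
      reallocate = TRUE),
    trial_scenario(delta1 = 0, delta2 = 0.4, rule = "FF")
  )
  for (scen in scens) {
    for (proc in c("gMCP", "agMTP", "gPA")) {
      for (seed in 101:130) {
        single <- run_trial(scen, proc, seed = seed)
        oc <- operating_characteristics(scen, proc, reps = 1, seed = seed)
        expect_equal(
          unname(unlist(oc[, c("pi_1", "pi_2", "pi_3", "pi_4")])),
          100 * as.numeric(single$decisions$rejected),
          label = paste(scen$rule, proc, seed)
        )
        expect_equal(
          unname(unlist(oc[, c("eta_1", "eta_2")])),
          100 * as.numeric(1:2 %in% single$dropped)
        )
      }
    }
  }
})

test_that("every comparator rejection is also an adaptive rejection, per trial", {
  scen <- trial_scenario(
    delta1 = 0.3, delta2 = 0.4, rule = "FF", reallocate = FALSE
  )
  n_strict <- 0
  for (seed in 201:500) {
    ag <- run_trial(scen, "agMTP", seed = seed)$decisions$rejected
    gpa <- run_trial(scen, "gPA", seed = seed)$decisions$rejected
    expect_true(all(gpa <= ag), label = paste("seed", seed))
    if (any(ag & !gpa)) n_strict <- n_strict + 1
  }
  expect_gt(n_strict, 0)
})

test_that("operating characteristics are reproducible and internally consistent", {
  scen <- trial_scenario(delta1 = 0.4, delta2 = 0.4, rule = "SB")
  oc1 <- operating_characteristics(scen, "agMTP", reps = 2000, seed = 65)
  oc2 <- operating_characteristics(scen, "agMTP", reps = 2000, seed = 65)
  expect_identical(oc1, oc2)
  expect_gte(oc1$pi, max(oc1$pi_1, oc1$pi_2, oc1$pi_3, oc1$pi_4))
  expect_true(all(unlist(oc1[, c("pi", "pi_1", "eta_1", "eta_2")]) >= 0))
  oc_single <- operating_characteristics(scen, "gPA", reps = 1, seed = 66)
  expect_true(all(unlist(oc_single[, c("pi", "pi_1", "pi_2")]) %in% c(0, 100)))
})

test_that("a secondary hypothesis is never rejected without its primary", {
  # the hierarchy holds for the preplanned test; check it survives adaptation
  scen <- trial_scenario(delta1 = 0.4, delta2 = 0.4, rule = "SF", kappa = 0.4)
  for (seed in 301:400) {
    for (proc in c("gMCP", "gPA")) {
      d <- run_trial(scen, proc, seed = seed)$decisions$rejected
      expect_true(d[1] >= d[3] && d[2] >= d[4])
    }
  }
})

test_that("simulated power is nondecreasing in the sample size", {
  fs <- find_sample_size(
    target = 0.9, delta = 0.4, rho = 0.3, reps = 20000, seed = 67
  )
  expect_true(all(diff(fs$power_curve$power) >= 0))
  expect_equal(fs$n %% 4, 0)
  expect_error(find_sample_size(target = 1.5), "target")
})
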