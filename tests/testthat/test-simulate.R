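test_that("degenerate success probabilities give deterministic outcomes", {
  tr <- simulate_trial(fixed_design(), theta_a = 1, theta_b = 1, n = 10, seed = 1)
  expect_true(all(tr$success))
  tr0 <- simulate_trial(fixed_design(), theta_a = 0, theta_b = 0, n = 10, seed = 1)
  expect_false(any(tr0$success))
})

test_that("batch records are consistent with the per-patient sequences", {
  designs <- list(
    fixed_design(),
    rpw_design(u = 1, alpha = 0, beta = 1),
    crdp_design(n = 9, p = 0.9, ell = 1.35)
  )
  for (d in designs) {
    b <- simulate_trials(d, 0.4, 0.6, n = 9, reps = 40, seed = 11)
    expect_equal(b$records$n_a + b$records$n_b, rep(9L, 40))
    expect_equal(b$records$n_a, as.integer(rowSums(b$arm_a)))
    expect_equal(b$records$s_a, as.integer(rowSums(b$arm_a & b$success)))
    expect_equal(b$records$s_b, as.integer(rowSums(!b$arm_a & b$success)))
    expect_true(all(b$records$s_a <= b$records$n_a))
    expect_true(all(b$records$s_b <= b$records$n_b))
  }
})

test_that("a replicate batch is reproducible and decomposable", {
  d <- rpw_design()
  b1 <- simulate_trials(d, 0.3, 0.6, n = 12, reps = 30, seed = 99)
  b2 <- simulate_trials(d, 0.3, 0.6, n = 12, reps = 30, seed = 99)
  expect_identical(b1$records, b2$records)
  expect_identical(b1$arm_a, b2$arm_a)

  # replicate i alone equals the sequential simulator run from its sub-seed
  for (i in c(1L, 17L, 30L)) {
    tr <- simulate_trial(d, 0.3, 0.6, n = 12, seed = b1$rep_seeds[i])
    expect_identical(unname(b1$arm_a[i, ]), tr$arm == "A")
    expect_identical(unname(b1$success[i, ]), tr$success)
  }
})

test_that("fixed randomisation gives a binomial arm-A sample size", {
  b <- simulate_trials(fixed_design(), 0.5, 0.5, n = 20, reps = 10000, seed = 4)
  obs <- table(factor(b$records$n_a, levels = 0:20))
  expected <- dbinom(0:20, 20, 0.5) * 10000
  keep <- expected >= 5  # pool nothing, just drop far tails for validity
  stat <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  pval <- pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("the deterministic constrained policy always meets the constraint", {
  d <- crdp_design(n = 12, p = 1, ell = 3)
  b <- simulate_trials(d, 0.2, 0.8, reps = 1000, seed = 5)
  expect_true(all(pmin(b$records$n_a, b$records$n_b) >= 3))
})

test_that("the terminal penalty curbs constraint violations relative to RDP", {
  crdp <- crdp_design(n = 12, p = 0.9, ell = 3)
  rdp <- rdp_design(n = 12, p = 0.9)
  bc <- simulate_trials(crdp, 0.2, 0.8, reps = 2000, seed = 6)
  br <- simulate_trials(rdp, 0.2, 0.8, reps = 2000, seed = 6)
  viol <- function(b) mean(pmin(b$records$n_a, b$records$n_b) < 3)
  expect_lt(viol(bc), viol(br))
})

test_that("allocation trajectories average the superior-arm indicator", {
  # a prior overwhelmingly favouring A makes the DP allocate A throughout
  d <- policy_design(solve_policy(6, p = 1, prior = beta_prior(200, 1, 1, 200)))
  b <- simulate_trials(d, 0.6, 0.4, reps = 50, seed = 8)
  expect_equal(allocation_trajectory(b)$prop_superior, rep(1, 6))

  bf <- simulate_trials(fixed_design(), 0.5, 0.5, n = 10, reps = 10000, seed = 9)
  expect_true(all(abs(allocation_trajectory(bf)$prop_superior - 0.5) < 0.02))
})

test_that("mismatched trial size is rejected", {
  d <- crdp_design(n = 8, p = 0.9, ell = 1.2)
  expect_error(simulate_trials(d, 0.5, 0.5, n = 10, reps = 2), "solved for")
  expect_error(simulate_trial(fixed_design(), 0.5, 0.5), "`n` must be supplied")
  expect_error(simulate_trials(fixed_design(), 1.2, 0.5, n = 5, reps = 2), "\\[0, 1\\]")
})
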