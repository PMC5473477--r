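test_that("one-period reward is the randomisation-weighted posterior mean", {
  # equipoise: both actions worth 0.5 whatever p
  expect_equal(one_period_reward(state_row(0, 0, 0, 0), action = 1, p = 0.9), 0.5)
  # after one success on A the posterior mean of A is Beta(2, 1) -> 2/3
  st <- state_row(1, 0, 0, 0)
  expect_equal(one_period_reward(st, action = 1, p = 1), 2 / 3)
  expect_equal(one_period_reward(st, action = 2, p = 0.9),
               0.1 * (2 / 3) + 0.9 * 0.5)
  # asymmetric prior enters through the posterior, not the raw counts
  expect_equal(
    one_period_reward(st, action = 1, p = 1, prior = beta_prior(2, 3, 1, 1)),
    3 / 6
  )
  expect_error(one_period_reward(st, action = 3, p = 1))
})

test_that("terminal reward penalises an under-sampled arm by -n", {
  # n = 75, threshold 0.15 * 75 = 11.25: (40, 35) fine, (64, 11) penalised
  ok <- state_row(20, 20, 18, 17)
  bad <- state_row(30, 34, 6, 5)
  expect_equal(terminal_reward(ok, n = 75, ell = 11.25), 0)
  expect_equal(terminal_reward(bad, n = 75, ell = 11.25), -75)
  expect_equal(terminal_reward(bad, n = 75, ell = 0), 0)
  expect_error(terminal_reward(ok, n = 74, ell = 0), "stage")
})

test_that("tiny-horizon values match hand enumeration", {
  p1 <- solve_policy(1)
  expect_equal(p1$value0, 0.5)
  expect_equal(p1$actions[[1]], 0L) # symmetric arms: tie at the empty history

  expect_equal(solve_policy(2)$value0, 13 / 12)

  # p = 0.5 makes both actions identical: martingale of posterior means
  expect_equal(solve_policy(4, p = 0.5)$value0, 2)
})

test_that("backward induction agrees with the brute-force tree oracle", {
  cases <- tidyr::expand_grid(
    n = c(3L, 6L),
    p = c(0.5, 0.9, 1),
    ell = c(0, 1),
    prior_id = 1:2
  )
  priors <- list(c(1, 1, 1, 1), c(2, 1, 1, 3))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    prior <- priors[[cs$prior_id]]
    expect_equal(
      solve_policy(cs$n, p = cs$p, ell = cs$ell, prior = prior)$value0,
      oracle_value(cs$n, p = cs$p, ell = cs$ell, prior = prior),
      tolerance = 1e-10,
      info = sprintf("n=%d p=%g ell=%g prior=%d", cs$n, cs$p, cs$ell, cs$prior_id)
    )
  }
})

test_that("p = 0.5 closed form holds for asymmetric priors", {
  prior <- beta_prior(3, 1, 1, 2)
  mu <- c(3 / 4, 1 / 3)
  expect_equal(solve_policy(10, p = 0.5, prior = prior)$value0,
               10 * mean(mu), tolerance = 1e-12)
})

test_that("value bounds hold across all stages", {
  pol <- solve_policy(10, p = 0.9, ell = 0)
  for (t in 0:10) {
    v <- pol$values[[t + 1]]
    expect_true(all(v >= 0 - 1e-12 & v <= 10 - t + 1e-12))
  }
  polc <- solve_policy(10, p = 0.9, ell = 3)
  expect_true(all(unlist(polc$values) >= -10 - 1e-12))
  # the penalty can only lower the achievable value
  expect_lte(polc$value0, pol$value0 + 1e-12)
})

test_that("F0 is nondecreasing in the degree of randomisation", {
  f0 <- vapply(seq(0.5, 1, by = 0.1),
               function(p) solve_policy(8, p = p)$value0, numeric(1))
  expect_true(all(diff(f0) >= -1e-12))
})

test_that("arm-swap symmetry holds under a symmetric prior", {
  n <- 6
  pol <- solve_policy(n, p = 0.9, ell = 1)
  for (t in 0:(n - 1)) {
    st <- stage_states(t)
    swapped <- state_index(st$s_b, st$f_b, st$s_a, st$f_a)
    v <- pol$values[[t + 1]]
    a <- pol$actions[[t + 1]]
    expect_equal(v, v[swapped])
    # action 1 <-> action 2, ties map to ties
    expect_equal(a, c(0L, 2L, 1L)[a[swapped] + 1L])
  }
})

test_that("allocation probabilities follow the recorded actions", {
  pol <- solve_policy(5, p = 0.9)
  expect_equal(allocation_prob(pol, state_row(0, 0, 0, 0)), 0.5) # tie at t = 0
  # after a success on A the DP favours A; RDP shares the argmax
  dp <- solve_policy(5, p = 1)
  expect_equal(allocation_prob(dp, state_row(1, 0, 0, 0)), 1)
  expect_equal(allocation_prob(pol, state_row(1, 0, 0, 0)), 0.9)
  expect_equal(allocation_prob(pol, state_row(0, 1, 0, 0)), 0.1)
  expect_error(allocation_prob(pol, state_row(3, 2, 0, 0)), "stage")
})

test_that("parameter validation rejects infeasible designs", {
  expect_error(solve_policy(5, ell = 3), "infeasible")
  expect_error(solve_policy(5, p = 0.3), "randomisation")
  expect_error(solve_policy(300), "max_n")
  expect_error(beta_prior(0, 1, 1, 1), "positive")
})

test_that("policy CSV export round-trips actions exactly", {
  pol <- solve_policy(4, p = 0.9, ell = 1, prior = beta_prior(2, 1, 1, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_policy(pol, path)
  back <- read_policy(path)
  expect_identical(back$actions, pol$actions)
  expect_equal(back$values, pol$values)
  expect_equal(back$value0, pol$value0)
  expect_equal(back$p, pol$p)
  expect_equal(back$ell, pol$ell)
  expect_equal(as.numeric(back$prior), as.numeric(pol$prior))

  # action column survives byte-identically in the file itself
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  expect_identical(sort(unique(tab$action[tab$stage < 4])),
                   sort(unique(tidy(pol)$action[tidy(pol)$stage < 4])))
})
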