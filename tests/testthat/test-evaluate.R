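test_that("Fisher p-values agree with stats::fisher.test on small tables", {
  # every 2x2 table with total count <= 11
  tabs <- enumerate_states(11)
  tabs <- tabs[tabs$stage == 11, ]
  mine <- fisher_exact_2x2(tabs$s_a, tabs$f_a, tabs$s_b, tabs$f_b)
  ref <- vapply(seq_len(nrow(tabs)), function(i) {
    stats::fisher.test(matrix(
      c(tabs$s_a[i], tabs$f_a[i], tabs$s_b[i], tabs$f_b[i]),
      nrow = 2, byrow = TRUE
    ))$p.value
  }, numeric(1))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("Fisher test handles modal and degenerate tables", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(0, 0, 3, 7), 1)  # empty arm: no evidence
  expect_equal(fisher_exact_2x2(8, 2, 2, 8), 0.02301414, tolerance = 1e-6)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("sample proportions are per-arm and undefined for empty arms", {
  rec <- tibble::tibble(n_a = c(26L, 0L, 10L), n_b = c(29L, 10L, 0L),
                        s_a = c(8L, 0L, 10L), s_b = c(13L, 4L, 0L))
  est <- estimate_proportions(rec)
  expect_equal(est$theta_a_hat, c(8 / 26, NA, 1))
  expect_equal(est$theta_b_hat, c(13 / 29, 0.4, NA))
})

test_that("summary metrics reduce a batch to its operating characteristics", {
  # identical replicates whose estimate equals the truth: zero bias and MSE
  rec <- tibble::tibble(n_a = rep(10L, 5), n_b = rep(10L, 5),
                        s_a = rep(5L, 5), s_b = rep(2L, 5))
  m <- summarize_trials(rec, theta_a = 0.5, theta_b = 0.2, n = 20)
  expect_equal(m$bias, 0)
  expect_equal(m$mse, 0)
  expect_equal(m$pct_superior, 50)
  expect_equal(m$n_estimable, 5L)
  expect_equal(m$mean_theta_a_hat, 0.5)

  # empty-arm replicates are excluded from estimation and never reject
  rec2 <- tibble::tibble(n_a = c(10L, 0L), n_b = c(0L, 10L),
                         s_a = c(9L, 0L), s_b = c(0L, 1L))
  m2 <- summarize_trials(rec2, theta_a = 0.9, theta_b = 0.1, n = 10)
  expect_equal(m2$n_estimable, 0L)
  expect_equal(m2$reject_rate, 0)
  expect_true(is.nan(m2$bias))
  expect_error(summarize_trials(rec2[0, ], theta_a = 0.5, theta_b = 0.5, n = 10),
               "empty")
  expect_error(summarize_trials(rec2, alpha = 1.5, theta_a = 0.9,
                                theta_b = 0.1, n = 10), "alpha")
})

test_that("MSE dominates squared bias in every summary", {
  set.seed(21)
  for (i in 1:5) {
    th <- runif(2)
    b <- simulate_trials(rpw_design(), th[1], th[2], n = 15, reps = 300,
                         seed = sample.int(1e6, 1))
    m <- summarize_trials(b)
    expect_gte(m$mse, m$bias^2 - 1e-12)
  }
})

test_that("fixed randomisation is unbiased within Monte-Carlo error", {
  b <- simulate_trials(fixed_design(), 0.5, 0.2, n = 30, reps = 10000, seed = 31)
  m <- summarize_trials(b)
  rec <- estimate_proportions(b)
  err <- with(rec[rec$n_a > 0 & rec$n_b > 0, ],
              theta_a_hat - theta_b_hat - 0.3)
  expect_lt(abs(m$bias), 3 * sd(err) / sqrt(length(err)))
})

test_that("the conditional test is conservative under the null", {
  for (d in list(fixed_design(), rpw_design(),
                 crdp_design(n = 20, p = 0.9, ell = 3))) {
    b <- simulate_trials(d, 0.5, 0.5, n = 20, reps = 4000, seed = 41)
    expect_lt(summarize_trials(b, alpha = 0.1)$reject_rate, 0.1)
  }
})
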