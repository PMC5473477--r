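#' Expected one-period reward of an action
#'
#' The Bayes-expected reward from treating the next patient, given the
#' trial history and the degree of randomisation `p`. Under action 1 the
#' next patient receives arm A with probability `p` (arm B with `1 - p`),
#' so the expected reward is `p * mu_A + (1 - p) * mu_B` where `mu_j` is
#' the posterior mean success probability of arm `j`; action 2 mirrors the
#' expression. With `p = 1` this reduces to the posterior mean of the
#' chosen arm.
#'
#' @param states Data frame with columns `s_a`, `f_a`, `s_b`, `f_b`
#'   (observed counts, prior excluded); vectorised over rows.
#' @param action `1` (favour arm A) or `2` (favour arm B).
#' @param p Degree of randomisation in `[0.5, 1]`.
#' @param prior A [beta_prior()].
#' @return Numeric vector of expected rewards, each in `[0, 1]`.
#' @examples
#' one_period_reward(stage_states(0), action = 1, p = 0.9) # 0.5 at equipoise
#' @export
one_period_reward <- function(states, action = 1, p = 1, prior = beta_prior()) {
  states <- check_states(states)
  prior <- as_beta_prior(prior)
  check_p(p)
  if (!action %in% c(1, 2)) rlang::abort("`action` must be 1 or 2.")
  mu_a <- (states$s_a + prior[["s_a"]]) /
    (states$s_a + prior[["s_a"]] + states$f_a + prior[["f_a"]])
  mu_b <- (states$s_b + prior[["s_b"]]) /
    (states$s_b + prior[["s_b"]] + states$f_b + prior[["f_b"]])
  if (action == 1) p * mu_a + (1 - p) * mu_b else (1 - p) * mu_a + p * mu_b
}

#' Terminal reward with a minimum per-arm sample-size penalty
#'
#' At the end of the trial a state is penalised by `-n` when either arm
#' has recruited fewer than `ell` patients (observed counts only, prior
#' pseudo-counts excluded); otherwise the terminal reward is 0. The large
#' negative value steers the backward induction away from histories that
#' end with an under-sampled arm. `ell = 0` recovers the unconstrained
#' designs.
#'
#' @param states Data frame of terminal states (each row must sum to `n`).
#' @param n Trial size.
#' @param ell Degree of constraining: the minimum per-arm observed sample
#'   size. Real-valued; the penalty triggers when a count is strictly
#'   below `ell`.
#' @return Numeric vector of 0 / `-n` values.
#' @export
terminal_reward <- function(states, n, ell = 0) {
  states <- check_states(states)
  stopifnot(length(n) == 1L, n >= 1, n == round(n), length(ell) == 1L, ell >= 0)
  t <- states$s_a + states$f_a + states$s_b + states$f_b
  if (any(t != n)) {
    rlang::abort("terminal reward is defined only for states at stage n.")
  }
  n_a <- states$s_a + states$f_a
  n_b <- states$s_b + states$f_b
  ifelse(n_a < ell | n_b < ell, -as.double(n), 0)
}

#' Solve an adaptive allocation policy by backward induction
#'
#' Computes, for every reachable history of a two-armed Bernoulli trial of
#' size `n`, the optimal randomised action and the value function `F_t`
#' (the maximum Bayes-expected number of successes in the remainder of the
#' trial, minus any terminal penalty). The recursion runs from the
#' terminal stage, where the value is [terminal_reward()], back to the
#' empty history, taking at each state the better of the two randomised
#' actions:
#' action 1 treats the next patient with arm A with probability `p`,
#' action 2 with probability `1 - p`. Special cases: `p = 1, ell = 0` is
#' the deterministic optimal DP design; `0.5 < p < 1, ell = 0` the
#' randomised DP (RDP) design; `p < 1, ell > 0` the constrained
#' randomised DP (CRDP) design; `p = 0.5` is fixed equal randomisation
#' (both actions coincide).
#'
#' When the two action values agree to within `tie_tol` the action is
#' recorded as a tie and resolved 0.5/0.5 at allocation time, which
#' preserves the exact arm-exchange symmetry of symmetric priors.
#'
#' @param n Trial size (number of patients), a positive integer.
#' @param p Degree of randomisation, in `[0.5, 1]`.
#' @param ell Degree of constraining (minimum per-arm observed sample
#'   size); requires `2 * ell <= n`.
#' @param prior A [beta_prior()] (or numeric vector of length 4).
#' @param keep_values Keep the full value table for all stages (`TRUE`,
#'   the default) or only the stage-0 value (`FALSE`, lighter in memory
#'   when only the policy is needed).
#' @param tie_tol Absolute tolerance for declaring the two action values
#'   tied.
#' @param max_n Resource guard: refuse `n` above this cap. Backward
#'   induction over the four-dimensional lattice grows as `n^4` and is
#'   practical up to about `n = 200`.
#' @return An object of class `crdp_policy` with elements `n`, `p`,
#'   `ell`, `prior`, `value0` (the stage-0 value `F_0`), `actions` (a list
#'   over stages `0..n-1` of integer vectors in canonical state order:
#'   1 = favour A, 2 = favour B, 0 = tie) and, if `keep_values`, `values`
#'   (a list over stages `0..n`). Query it with [allocation_prob()],
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' pol <- solve_policy(n = 10, p = 0.9, ell = 1.5)
#' glance(pol)
#' @export
solve_policy <- function(n, p = 1, ell = 0, prior = beta_prior(),
                         keep_values = TRUE, tie_tol = 1e-12, max_n = 200L) {
  stopifnot(length(n) == 1L, is.finite(n), n >= 1, n == round(n))
  n <- as.integer(n)
  check_p(p)
  stopifnot(length(ell) == 1L, is.finite(ell), ell >= 0)
  if (2 * ell > n) {
    rlang::abort(sprintf(
      "infeasible constraint: 2 * ell = %g exceeds n = %d.", 2 * ell, n
    ))
  }
  if (n > max_n) {
    rlang::abort(sprintf(
      "n = %d exceeds max_n = %d; raise `max_n` deliberately if you have the memory and patience.",
      n, max_n
    ))
  }
  prior <- as_beta_prior(prior)
  sa0 <- prior[["s_a"]]; fa0 <- prior[["f_a"]]
  sb0 <- prior[["s_b"]]; fb0 <- prior[["f_b"]]

  # terminal stage: penalty only
  S <- stage_states_matrix(n)
  n_a <- S[, 1L] + S[, 2L]
  v_next <- ifelse(n_a < ell | (n - n_a) < ell, -as.double(n), 0)

  actions <- vector("list", n)
  values <- if (keep_values) vector("list", n + 1L) else NULL
  if (keep_values) values[[n + 1L]] <- v_next

  for (t in seq.int(n - 1L, 0L)) {
    S <- stage_states_matrix(t)
    s_a <- S[, 1L]; f_a <- S[, 2L]; s_b <- S[, 3L]
    f_b <- t - s_a - f_a - s_b
    mu_a <- (s_a + sa0) / (s_a + sa0 + f_a + fa0)
    mu_b <- (s_b + sb0) / (s_b + sb0 + f_b + fb0)
    # continuation values under the four possible next observations
    f_arm_a <- mu_a * (1 + v_next[state_index_at(s_a + 1L, f_a, s_b, t + 1L)]) +
      (1 - mu_a) * v_next[state_index_at(s_a, f_a + 1L, s_b, t + 1L)]
    f_arm_b <- mu_b * (1 + v_next[state_index_at(s_a, f_a, s_b + 1L, t + 1L)]) +
      (1 - mu_b) * v_next[state_index_at(s_a, f_a, s_b, t + 1L)]
    f1 <- p * f_arm_a + (1 - p) * f_arm_b
    f2 <- (1 - p) * f_arm_a + p * f_arm_b
    v_next <- pmax(f1, f2)
    act <- integer(length(f1))        # 0 = tie
    act[f1 - f2 > tie_tol] <- 1L
    act[f2 - f1 > tie_tol] <- 2L
    actions[[t + 1L]] <- act
    if (keep_values) values[[t + 1L]] <- v_next
  }

  structure(
    list(n = n, p = p, ell = ell, prior = prior, value0 = v_next[[1L]],
         actions = actions, values = values, tie_tol = tie_tol),
    class = "crdp_policy"
  )
}

#' Probability of allocating arm A under a solved policy
#'
#' Looks up the recorded action for each state and maps it to the arm-A
#' allocation probability: `p` for action 1, `1 - p` for action 2, and
#' 0.5 for a tie.
#'
#' @param policy A [solve_policy()] result.
#' @param states Data frame with columns `s_a`, `f_a`, `s_b`, `f_b`; every
#'   row must be at a stage `< n`.
#' @return Numeric vector of arm-A allocation probabilities.
#' @export
allocation_prob <- function(policy, states) {
  stopifnot(inherits(policy, "crdp_policy"))
  states <- check_states(states)
  t <- states$s_a + states$f_a + states$s_b + states$f_b
  if (any(t >= policy$n)) {
    rlang::abort("states at stage >= n have no allocation to make.")
  }
  act <- integer(nrow(states))
  for (tt in unique(t)) {
    i <- which(t == tt)
    idx <- state_index_at(states$s_a[i], states$f_a[i], states$s_b[i], tt)
    act[i] <- policy$actions[[tt + 1L]][idx]
  }
  action_to_prob(act, policy$p)
}

action_to_prob <- function(action, p) {
  ifelse(action == 1L, p, ifelse(action == 2L, 1 - p, 0.5))
}

check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0.5 || p > 1) {
    rlang::abort("degree of randomisation `p` must be a single value in [0.5, 1].")
  }
  invisible(p)
}

#' @export
print.crdp_policy <- function(x, ...) {
  kind <- policy_kind(x$p, x$ell)
  cat(sprintf(
    "%s policy: n = %d, p = %g, ell = %g\n", kind, x$n, x$p, x$ell
  ))
  cat(sprintf("  F0 (Bayes-expected successes at the empty history): %.6f\n",
              x$value0))
  cat(sprintf("  states: %s across %d stages; values %s\n",
              format(sum(choose((0:x$n) + 3, 3)), big.mark = ","), x$n + 1L,
              if (is.null(x$values)) "discarded" else "retained"))
  invisible(x)
}

policy_kind <- function(p, ell) {
  if (p == 0.5) "Fixed-equivalent (p = 0.5)"
  else if (p == 1 && ell == 0) "DP"
  else if (ell == 0) "RDP"
  else "CRDP"
}

#' Export / import a solved policy as CSV
#'
#' Writes one row per (stage, state) with the value (`NA` when the policy
#' was solved with `keep_values = FALSE`) and the action encoded as `"A"`
#' (favour arm A), `"B"` (favour arm B) or `"tie"`. Design parameters
#' travel in a `# crdp-policy:` comment header so that [read_policy()]
#' can rebuild a queryable `crdp_policy` object; the action column
#' round-trips exactly.
#'
#' @param policy A `crdp_policy`.
#' @param path File path.
#' @return `write_policy()` returns `path` invisibly; `read_policy()`
#'   returns a `crdp_policy`.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "crdp_policy"))
  tab <- tidy(policy)
  header <- sprintf(
    "# crdp-policy: n=%d p=%.17g ell=%.17g prior=%.17g,%.17g,%.17g,%.17g tie_tol=%.17g f0=%.17g",
    policy$n, policy$p, policy$ell,
    policy$prior[["s_a"]], policy$prior[["f_a"]],
    policy$prior[["s_b"]], policy$prior[["f_b"]], policy$tie_tol, policy$value0
  )
  writeLines(header, path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# crdp-policy:")) {
    rlang::abort("not a crdp policy file: missing `# crdp-policy:` header.")
  }
  kv <- strsplit(sub("^# crdp-policy: ", "", header), " ")[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(x) as.numeric(strsplit(x[[2]], ",")[[1]])),
    vapply(kv, `[[`, "", 1L)
  )
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  n <- as.integer(meta$n)
  actions <- vector("list", n)
  values <- vector("list", n + 1L)
  code <- c(A = 1L, B = 2L, tie = 0L)
  for (t in 0:n) {
    rows <- tab[tab$stage == t, ]
    ord <- order(state_index_at(rows$s_a, rows$f_a, rows$s_b, t))
    rows <- rows[ord, ]
    if (t < n) actions[[t + 1L]] <- unname(code[rows$action])
    values[[t + 1L]] <- rows$value
  }
  if (anyNA(values[[1L]])) values <- NULL
  structure(
    list(n = n, p = meta$p, ell = meta$ell,
         prior = beta_prior(meta$prior[1], meta$prior[2], meta$prior[3], meta$prior[4]),
         value0 = meta$f0,
         actions = actions, values = values, tie_tol = meta$tie_tol),
    class = "crdp_policy"
  )
}
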