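#' Trial design constructors
#'
#' A design specifies how each successive patient is randomised between
#' the two arms:
#'
#' * `fixed_design()` — fixed equal randomisation, probability 0.5 for
#'   arm A at every stage regardless of history.
#' * `rpw_design()` — the randomised play-the-winner urn. The urn starts
#'   with `u` balls of each type and a patient's arm is drawn in
#'   proportion to the ball counts (with replacement). A success on A or
#'   a failure on B adds `beta` type-A balls and `alpha` type-B balls;
#'   symmetrically for the other outcomes, with `0 <= alpha <= beta`.
#'   The defaults `u = 1, alpha = 0, beta = 1` are the classic
#'   play-the-winner rule used in the ECMO trial.
#' * `dp_design()`, `rdp_design()`, `crdp_design()` — policy-driven
#'   designs backed by the backward-induction solution of
#'   [solve_policy()]: the deterministic optimal DP design (`p = 1`, no
#'   constraint), the randomised DP design (degree of randomisation `p`,
#'   no constraint), and the constrained randomised DP design (`p` plus a
#'   minimum per-arm sample size `ell`, default `0.15 n`). A pre-solved
#'   policy can be passed to avoid recomputation; otherwise the policy is
#'   solved at construction.
#' * `policy_design()` — wrap an arbitrary solved policy.
#'
#' @param u Initial balls of each type in the urn (positive integer).
#' @param alpha,beta Balls of the other / reinforced type added per
#'   observed outcome; integers with `0 <= alpha <= beta`.
#' @param n Trial size the policy is solved for.
#' @param p Degree of randomisation in `[0.5, 1]`.
#' @param ell Degree of constraining (minimum per-arm sample size).
#' @param prior A [beta_prior()].
#' @param policy Optional pre-solved [solve_policy()] result matching the
#'   other arguments.
#' @param label Short label used in metrics tables.
#' @param ... Arguments passed on to [solve_policy()].
#' @return An object of class `ra_design`.
#' @examples
#' fixed_design()
#' rpw_design(u = 1, alpha = 0, beta = 1)
#' crdp_design(n = 12, p = 0.9, ell = 1.8)
#' @name designs
NULL

#' @rdname designs
#' @export
fixed_design <- function() {
  new_design("fixed", list())
}

#' @rdname designs
#' @export
rpw_design <- function(u = 1, alpha = 0, beta = 1) {
  stopifnot(
    length(u) == 1L, u >= 1, u == round(u),
    length(alpha) == 1L, alpha == round(alpha),
    length(beta) == 1L, beta == round(beta)
  )
  if (alpha < 0 || alpha > beta) {
    rlang::abort("randomised play-the-winner requires 0 <= alpha <= beta.")
  }
  new_design("rpw", list(u = as.integer(u), alpha = as.integer(alpha),
                         beta = as.integer(beta)))
}

#' @rdname designs
#' @export
dp_design <- function(n, prior = beta_prior(), policy = NULL, ...) {
  policy_backed("dp", n, p = 1, ell = 0, prior = prior, policy = policy, ...)
}

#' @rdname designs
#' @export
rdp_design <- function(n, p = 0.9, prior = beta_prior(), policy = NULL, ...) {
  policy_backed("rdp", n, p = p, ell = 0, prior = prior, policy = policy, ...)
}

#' @rdname designs
#' @export
crdp_design <- function(n, p = 0.9, ell = 0.15 * n, prior = beta_prior(),
                        policy = NULL, ...) {
  policy_backed("crdp", n, p = p, ell = ell, prior = prior, policy = policy, ...)
}

#' @rdname designs
#' @export
policy_design <- function(policy, label = "policy") {
  stopifnot(inherits(policy, "crdp_policy"))
  new_design(label, list(n = policy$n, p = policy$p, ell = policy$ell,
                         policy = policy))
}

policy_backed <- function(label, n, p, ell, prior, policy, ...) {
  if (is.null(policy)) {
    policy <- solve_policy(n = n, p = p, ell = ell, prior = prior, ...)
  } else {
    stopifnot(inherits(policy, "crdp_policy"))
    if (policy$n != n || policy$p != p || policy$ell != ell) {
      rlang::abort("supplied `policy` was solved for different (n, p, ell).")
    }
  }
  new_design(label, list(n = policy$n, p = policy$p, ell = policy$ell,
                         policy = policy))
}

new_design <- function(type, params) {
  structure(c(list(design = type), params), class = "ra_design")
}

#' @export
print.ra_design <- function(x, ...) {
  cat("<ra_design>", x$design)
  par <- x[setdiff(names(x), c("design", "policy"))]
  if (length(par)) {
    cat(":", paste(names(par), unlist(par), sep = " = ", collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Sequential allocation-rule interface to a design
#'
#' Instantiates the pull-based rule a simulator interacts with: ask
#' `$prob()` for the current arm-A allocation probability, then report the
#' observed `(arm, outcome)` with `$observe()`. The rule only ever sees
#' outcomes of already-treated patients, so the sequential
#' allocate-then-observe protocol is enforced by construction. `$reset()`
#' restores the initial internal state.
#'
#' @param design An [fixed_design()], [rpw_design()] or policy-backed
#'   design.
#' @return An object of class `alloc_rule`: a list of closures `prob()`,
#'   `observe(arm_a, success)`, `reset()` and `state()` (a snapshot of the
#'   rule's internal state, for inspection) sharing a common environment.
#' @examples
#' rule <- as_rule(rpw_design())
#' rule$prob()              # 0.5 from the symmetric urn
#' rule$observe(TRUE, TRUE) # success on arm A
#' rule$prob()              # now 2/3
#' @export
as_rule <- function(design) {
  stopifnot(inherits(design, "ra_design"))
  rule <- switch(
    design$design,
    fixed = fixed_rule_impl(),
    rpw = rpw_rule_impl(design$u, design$alpha, design$beta),
    policy_rule_impl(design$policy)
  )
  structure(rule, class = "alloc_rule", design = design$design)
}

fixed_rule_impl <- function() {
  list(
    prob = function() 0.5,
    observe = function(arm_a, success) invisible(NULL),
    reset = function() invisible(NULL),
    state = function() list()
  )
}

rpw_rule_impl <- function(u, alpha, beta) {
  balls_a <- balls_b <- u
  list(
    prob = function() balls_a / (balls_a + balls_b),
    observe = function(arm_a, success) {
      reinforce_a <- (arm_a & success) | (!arm_a & !success)
      if (reinforce_a) {
        balls_a <<- balls_a + beta
        balls_b <<- balls_b + alpha
      } else {
        balls_a <<- balls_a + alpha
        balls_b <<- balls_b + beta
      }
      invisible(NULL)
    },
    reset = function() {
      balls_a <<- u
      balls_b <<- u
      invisible(NULL)
    },
    state = function() list(balls_a = balls_a, balls_b = balls_b)
  )
}

policy_rule_impl <- function(policy) {
  s_a <- f_a <- s_b <- f_b <- 0L
  list(
    prob = function() {
      t <- s_a + f_a + s_b + f_b
      if (t >= policy$n) {
        rlang::abort("trial complete: no allocation beyond stage n - 1.")
      }
      act <- policy$actions[[t + 1L]][state_index_at(s_a, f_a, s_b, t)]
      action_to_prob(act, policy$p)
    },
    observe = function(arm_a, success) {
      if (arm_a) {
        if (success) s_a <<- s_a + 1L else f_a <<- f_a + 1L
      } else {
        if (success) s_b <<- s_b + 1L else f_b <<- f_b + 1L
      }
      invisible(NULL)
    },
    reset = function() {
      s_a <<- 0L; f_a <<- 0L; s_b <<- 0L; f_b <<- 0L
      invisible(NULL)
    },
    state = function() list(s_a = s_a, f_a = f_a, s_b = s_b, f_b = f_b)
  )
}
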