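#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solved policy into a state-by-state table
#'
#' One row per reachable state, with the value-to-go (`NA` when the
#' policy was solved with `keep_values = FALSE`) and the recorded action
#' (`"A"`, `"B"` or `"tie"`). Terminal states (stage `n`) carry the
#' terminal reward and no action. Beware the row count: a policy for
#' `n = 75` has about 1.5 million states.
#'
#' @param x A `crdp_policy`.
#' @param stages Optional subset of stages `0..n` to return.
#' @param ... Unused.
#' @return A tibble with columns `stage`, `s_a`, `f_a`, `s_b`, `f_b`,
#'   `value`, `action`.
#' @method tidy crdp_policy
#' @export
tidy.crdp_policy <- function(x, stages = NULL, ...) {
  stages <- if (is.null(stages)) 0:x$n else intersect(stages, 0:x$n)
  act_chr <- c("tie", "A", "B")
  purrr::map_dfr(stages, function(t) {
    st <- stage_states(t)
    st$value <- if (!is.null(x$values)) {
      x$values[[t + 1L]]
    } else if (t == x$n) {
      terminal_reward(st, x$n, x$ell)
    } else {
      NA_real_
    }
    st$action <- if (t < x$n) act_chr[x$actions[[t + 1L]] + 1L] else NA_character_
    dplyr::mutate(st, stage = t, .before = 1L)
  })
}

#' @rdname tidy.crdp_policy
#' @method glance crdp_policy
#' @export
glance.crdp_policy <- function(x, ...) {
  n_states <- sum(choose((0:x$n) + 3, 3))
  tibble::tibble(
    n = x$n, p = x$p, ell = x$ell,
    prior_mean_a = prior_means(x$prior)[["a"]],
    prior_mean_b = prior_means(x$prior)[["b"]],
    expected_successes = x$value0,
    n_states = n_states
  )
}

#' Tidiers for simulated trial batches
#'
#' `tidy()` returns the per-replicate records with sample-proportion
#' estimates appended; `glance()` a one-row summary of the batch
#' scenario.
#'
#' @param x A `trial_batch`.
#' @param ... Unused.
#' @method tidy trial_batch
#' @export
tidy.trial_batch <- function(x, ...) {
  estimate_proportions(x)
}

#' @rdname tidy.trial_batch
#' @method glance trial_batch
#' @export
glance.trial_batch <- function(x, ...) {
  tibble::tibble(
    design = x$design, theta_a = x$theta_a, theta_b = x$theta_b,
    n = x$n, reps = x$reps,
    mean_n_a = mean(x$records$n_a), mean_n_b = mean(x$records$n_b)
  )
}
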