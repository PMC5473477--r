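#' Enumerate the trial-state lattice
#'
#' After `t` patients have been treated, the observable history of a
#' two-armed trial with binary endpoints is the count vector
#' `(s_a, f_a, s_b, f_b)` of per-arm successes and failures, with
#' `s_a + f_a + s_b + f_b = t`. `stage_states()` enumerates all states at a
#' single stage; `enumerate_states()` stacks stages `0..n`. The number of
#' states at stage `t` is `choose(t + 3, 3)` (compositions of `t` into four
#' nonnegative parts).
#'
#' States are produced in a fixed canonical order (`s_a` slowest, then
#' `f_a`, then `s_b`); [state_index()] ranks a state within its stage in
#' that same order, which is what lets the backward-induction solver and
#' the simulator address value and action tables by arithmetic alone.
#'
#' @param t Stage (number of patients already treated), a nonnegative
#'   integer.
#' @param n Trial size, a positive integer.
#' @return A tibble with integer columns `s_a`, `f_a`, `s_b`, `f_b` (and,
#'   for `enumerate_states()`, a leading `stage` column).
#' @examples
#' stage_states(2) # 10 states
#' nrow(enumerate_states(3))
#' @export
stage_states <- function(t) {
  stopifnot(length(t) == 1L, is.finite(t), t >= 0, t == round(t))
  m <- stage_states_matrix(as.integer(t))
  tibble::tibble(
    s_a = m[, 1L], f_a = m[, 2L], s_b = m[, 3L],
    f_b = as.integer(t) - m[, 1L] - m[, 2L] - m[, 3L]
  )
}

#' @rdname stage_states
#' @export
enumerate_states <- function(n) {
  stopifnot(length(n) == 1L, is.finite(n), n >= 1, n == round(n))
  purrr::map_dfr(0:n, function(t) {
    dplyr::mutate(stage_states(t), stage = t, .before = 1L)
  })
}

# Integer matrix (s_a, f_a, s_b) of all states at stage t, canonical order.
stage_states_matrix <- function(t) {
  blocks <- lapply(0:t, function(a) {
    m <- t - a
    f_a <- rep.int(0:m, (m:0) + 1L)
    s_b <- sequence((m:0) + 1L) - 1L
    cbind(rep.int(a, length(f_a)), f_a, s_b, deparse.level = 0L)
  })
  do.call(rbind, blocks)
}

#' Rank of a state within its stage
#'
#' One-based position of the state `(s_a, f_a, s_b, f_b)` in the canonical
#' order of [stage_states()] at stage `t = s_a + f_a + s_b + f_b`.
#' Vectorised over all four count arguments.
#'
#' @param s_a,f_a,s_b,f_b Nonnegative integer counts of per-arm successes
#'   and failures.
#' @return Integer-valued rank in `1..choose(t + 3, 3)`.
#' @export
state_index <- function(s_a, f_a, s_b, f_b) {
  t <- s_a + f_a + s_b + f_b
  choose(t + 3, 3) - choose(t - s_a + 3, 3) +
    choose(t - s_a + 2, 2) - choose(t - s_a - f_a + 2, 2) + s_b + 1
}

# Rank used internally during induction/simulation, where the target stage
# is known and f_b is implicit.
state_index_at <- function(s_a, f_a, s_b, t) {
  choose(t + 3, 3) - choose(t - s_a + 3, 3) +
    choose(t - s_a + 2, 2) - choose(t - s_a - f_a + 2, 2) + s_b + 1
}

# Validate a states data frame; returns it with integer-ish columns checked.
check_states <- function(states) {
  cols <- c("s_a", "f_a", "s_b", "f_b")
  if (!is.data.frame(states) || !all(cols %in% names(states))) {
    rlang::abort("`states` must be a data frame with columns s_a, f_a, s_b, f_b.")
  }
  for (cl in cols) {
    v <- states[[cl]]
    if (any(v < 0) || any(v != round(v))) {
      rlang::abort(sprintf("column `%s` must hold nonnegative integers.", cl))
    }
  }
  states
}
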