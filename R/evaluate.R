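#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' Conditional test of equal success probabilities given the observed
#' per-arm counts. Conditioning on both margins makes the number of arm-A
#' successes hypergeometric under the null; the two-sided p-value follows
#' the point-probability rule — the sum of the probabilities of all
#' tables with the observed margins that are no more probable than the
#' observed one (a relative tolerance of 1e-7 guards the comparison
#' against floating-point noise, as in [stats::fisher.test()]). A table
#' with a zero row or column margin carries no evidence and returns 1.
#' Vectorised over tables.
#'
#' @param s_a,f_a,s_b,f_b Nonnegative integer counts: successes and
#'   failures on arms A and B.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)  # the modal table: p = 1
#' fisher_exact_2x2(8, 2, 2, 8)
#' @export
fisher_exact_2x2 <- function(s_a, f_a, s_b, f_b) {
  k <- length(s_a)
  stopifnot(length(f_a) == k, length(s_b) == k, length(f_b) == k)
  counts <- cbind(s_a, f_a, s_b, f_b)
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("all four cell counts must be nonnegative integers.")
  }
  vapply(seq_len(k), function(i) {
    fisher_p_one(s_a[i], f_a[i], s_b[i], f_b[i])
  }, numeric(1))
}

fisher_p_one <- function(s_a, f_a, s_b, f_b) {
  row_a <- s_a + f_a
  row_b <- s_b + f_b
  col_s <- s_a + s_b
  if (row_a == 0 || row_b == 0 || col_s == 0 || (f_a + f_b) == 0) return(1)
  support <- max(0, col_s - row_b):min(col_s, row_a)
  d <- stats::dhyper(support, row_a, row_b, col_s)
  d_obs <- d[support == s_a]
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Sample-proportion estimates from trial records
#'
#' Appends the end-of-trial point estimates `theta_a_hat = s_a / n_a` and
#' `theta_b_hat = s_b / n_b` to a records table. An arm that recruited no
#' patients has no defined estimate and yields `NA`.
#'
#' @param records A data frame with columns `n_a`, `n_b`, `s_a`, `s_b`
#'   (one row per replicate), or a `trial_batch`.
#' @return The records tibble with `theta_a_hat` and `theta_b_hat` added.
#' @export
estimate_proportions <- function(records) {
  records <- as_records(records)
  dplyr::mutate(
    records,
    theta_a_hat = ifelse(.data$n_a > 0, .data$s_a / .data$n_a, NA_real_),
    theta_b_hat = ifelse(.data$n_b > 0, .data$s_b / .data$n_b, NA_real_)
  )
}

#' Operating characteristics of a replicate batch
#'
#' Aggregates a batch of simulated trials into the standard performance
#' measures for a response-adaptive design:
#'
#' * `reject_rate` — fraction of replicates with a two-sided Fisher exact
#'   p-value below `alpha`. This is the empirical power when
#'   `theta_a != theta_b` and the type I error rate when they are equal.
#'   A replicate in which an arm recruited nobody cannot reject.
#' * `pct_superior` — mean percentage of patients allocated to the truly
#'   superior arm (arm A by convention when the arms are equal): the
#'   patient-benefit measure.
#' * `bias`, `mse` — mean error and mean squared error of the
#'   treatment-effect estimator `delta_hat = theta_a_hat - theta_b_hat`
#'   about the true difference, averaged over replicates where both arms
#'   are estimable (`n_estimable` reports how many).
#' * `mean_/sd_theta_*_hat` — across-replicate mean and standard
#'   deviation of each arm's sample-proportion estimate.
#'
#' @param batch A [simulate_trials()] result, or a records data frame
#'   (then `theta_a`, `theta_b` and `n` must be given).
#' @param alpha Nominal significance level of the Fisher test.
#' @param theta_a,theta_b,n Scenario parameters; taken from the batch
#'   when available.
#' @return A one-row tibble with columns `reps`, `reject_rate`,
#'   `pct_superior`, `bias`, `mse`, `mean_theta_a_hat`, `sd_theta_a_hat`,
#'   `mean_theta_b_hat`, `sd_theta_b_hat`, `n_estimable`.
#' @examples
#' b <- simulate_trials(fixed_design(), 0.5, 0.7, n = 25, reps = 200, seed = 1)
#' summarize_trials(b)
#' @export
summarize_trials <- function(batch, alpha = 0.1, theta_a = NULL,
                             theta_b = NULL, n = NULL) {
  if (inherits(batch, "trial_batch")) {
    theta_a <- batch$theta_a
    theta_b <- batch$theta_b
    n <- batch$n
  }
  if (is.null(theta_a) || is.null(theta_b) || is.null(n)) {
    rlang::abort("`theta_a`, `theta_b` and `n` are required with a plain records table.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    rlang::abort("`alpha` must be a single value in (0, 1).")
  }
  rec <- estimate_proportions(batch)
  if (nrow(rec) == 0L) rlang::abort("empty replicate collection.")

  # Fisher p-values: many replicates share a table, so test unique tables
  tab <- dplyr::distinct(
    dplyr::transmute(rec, s_a = .data$s_a, f_a = .data$n_a - .data$s_a,
                     s_b = .data$s_b, f_b = .data$n_b - .data$s_b)
  )
  tab$p <- fisher_exact_2x2(tab$s_a, tab$f_a, tab$s_b, tab$f_b)
  rec <- dplyr::left_join(
    dplyr::mutate(rec, f_a = .data$n_a - .data$s_a, f_b = .data$n_b - .data$s_b),
    tab, by = c("s_a", "f_a", "s_b", "f_b")
  )
  estimable <- rec$n_a > 0 & rec$n_b > 0
  reject <- rec$p < alpha & estimable

  superior_a <- theta_a >= theta_b
  n_sup <- if (superior_a) rec$n_a else rec$n_b
  delta_hat <- rec$theta_a_hat - rec$theta_b_hat
  err <- delta_hat[estimable] - (theta_a - theta_b)

  tibble::tibble(
    reps = nrow(rec),
    reject_rate = mean(reject),
    pct_superior = mean(100 * n_sup / n),
    bias = mean(err),
    mse = mean(err^2),
    mean_theta_a_hat = mean(rec$theta_a_hat[estimable]),
    sd_theta_a_hat = stats::sd(rec$theta_a_hat[estimable]),
    mean_theta_b_hat = mean(rec$theta_b_hat[estimable]),
    sd_theta_b_hat = stats::sd(rec$theta_b_hat[estimable]),
    n_estimable = sum(estimable)
  )
}

as_records <- function(x) {
  if (inherits(x, "trial_batch")) return(x$records)
  cols <- c("n_a", "n_b", "s_a", "s_b")
  if (!is.data.frame(x) || !all(cols %in% names(x))) {
    rlang::abort("records must have columns n_a, n_b, s_a, s_b.")
  }
  tibble::as_tibble(x)
}
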