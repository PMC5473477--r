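#' Independent Beta priors on the two success probabilities
#'
#' The arm success probabilities are given independent conjugate priors
#' `theta_A ~ Beta(s_a, f_a)` and `theta_B ~ Beta(s_b, f_b)`, parameterised
#' as pseudo-successes and pseudo-failures. Conjugacy with the Bernoulli
#' likelihood means the posterior after observing the trial history is
#' again Beta with the observed counts added to these pseudo-counts.
#' The default `beta_prior()` is the uniform (equipoise) prior
#' `Beta(1, 1)` on both arms.
#'
#' @param s_a,f_a Prior pseudo-successes / pseudo-failures for arm A
#'   (strictly positive reals; integers not required).
#' @param s_b,f_b Likewise for arm B.
#' @return An object of class `beta_prior`: a named numeric vector with
#'   elements `s_a`, `f_a`, `s_b`, `f_b`.
#' @examples
#' beta_prior()             # uniform on both arms
#' beta_prior(2, 1, 1, 1)   # optimism about arm A
#' @export
beta_prior <- function(s_a = 1, f_a = 1, s_b = 1, f_b = 1) {
  x <- c(s_a = s_a, f_a = f_a, s_b = s_b, f_b = f_b)
  if (!is.numeric(x) || length(x) != 4L || any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort("all four Beta pseudo-counts must be finite and strictly positive.")
  }
  structure(as.double(x), names = names(x), class = "beta_prior")
}

as_beta_prior <- function(prior) {
  if (inherits(prior, "beta_prior")) return(prior)
  if (is.numeric(prior) && length(prior) == 4L) {
    return(beta_prior(prior[[1]], prior[[2]], prior[[3]], prior[[4]]))
  }
  rlang::abort("`prior` must be a beta_prior or a numeric vector of length 4.")
}

# Prior means of the two arms.
prior_means <- function(prior) {
  c(a = prior[["s_a"]] / (prior[["s_a"]] + prior[["f_a"]]),
    b = prior[["s_b"]] / (prior[["s_b"]] + prior[["f_b"]]))
}

#' @export
print.beta_prior <- function(x, ...) {
  mu <- prior_means(x)
  cat(sprintf(
    "Beta priors: arm A ~ Beta(%g, %g) (mean %.3f), arm B ~ Beta(%g, %g) (mean %.3f)\n",
    x[["s_a"]], x[["f_a"]], mu[["a"]], x[["s_b"]], x[["f_b"]], mu[["b"]]
  ))
  invisible(x)
}
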