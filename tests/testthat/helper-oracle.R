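# Independent brute-force oracle for the optimal adaptive value F_0:
# plain top-down recursion over the full allocation/outcome tree from the
# definition of the value function, no memoisation, no state lattice.
oracle_value <- function(n, p = 1, ell = 0, prior = c(1, 1, 1, 1)) {
  rec <- function(s_a, f_a, s_b, f_b) {
    t <- s_a + f_a + s_b + f_b
    if (t == n) {
      return(if (s_a + f_a < ell || s_b + f_b < ell) -n else 0)
    }
    mu_a <- (s_a + prior[1]) / (s_a + prior[1] + f_a + prior[2])
    mu_b <- (s_b + prior[3]) / (s_b + prior[3] + f_b + prior[4])
    v_a <- mu_a * (1 + rec(s_a + 1, f_a, s_b, f_b)) +
      (1 - mu_a) * rec(s_a, f_a + 1, s_b, f_b)
    v_b <- mu_b * (1 + rec(s_a, f_a, s_b + 1, f_b)) +
      (1 - mu_b) * rec(s_a, f_a, s_b, f_b + 1)
    max(p * v_a + (1 - p) * v_b, (1 - p) * v_a + p * v_b)
  }
  rec(0, 0, 0, 0)
}

# One state row as a data frame, for the vectorised state-based ops.
state_row <- function(s_a, f_a, s_b, f_b) {
  tibble::tibble(s_a = s_a, f_a = f_a, s_b = s_b, f_b = f_b)
}
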