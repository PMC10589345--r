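# Independent oracles used across the suite.

# Fixation probability of the Moran birth-death chain, computed by solving
# the absorbing-chain linear system numerically (states 0..n; from state k a
# mutant is chosen to reproduce with probability weight (1+s)k against the
# n-k wild-types, and the individual that dies is uniform).  This route never
# touches the closed-form formula under test.
chain_fixation <- function(s, i, n) {
  if (n == 1) return(as.numeric(i >= 1))
  k <- 1:(n - 1)
  w <- (1 + s) * k
  p_up <- (w / (w + (n - k))) * ((n - k) / n)
  p_dn <- ((n - k) / (w + (n - k))) * (k / n)
  # h(k) = p_up h(k+1) + p_dn h(k-1) + (1 - p_up - p_dn) h(k), h(0)=0, h(n)=1
  A <- diag(p_up + p_dn, n - 1)
  for (j in seq_len(n - 2)) {
    A[j, j + 1] <- -p_up[j]
    A[j + 1, j] <- -p_dn[j + 1]
  }
  b <- numeric(n - 1)
  b[n - 1] <- p_up[n - 1]
  h <- solve(A, b)
  c(0, h, 1)[i + 1]
}

# Infection-free equilibrium density of the within-patch logistic model.
logistic_equilibrium <- function(r, d, K) K * (1 - d / r)

abm_base <- function(...) {
  defaults <- list(R = 0.5, D = 0.05, A = 0.1, B = 0, s = 0, n1 = 20, n2 = 20)
  do.call(abm_params, modifyList(defaults, list(...)))
}

deme_base <- function(...) {
  defaults <- list(r = 0.7, d = 0.1, beta = 0, a = 0.5, K = 100, mu = 0.02,
                   s = 0, n1 = 4, n2 = 3)
  do.call(deme_params, modifyList(defaults, list(...)))
}
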