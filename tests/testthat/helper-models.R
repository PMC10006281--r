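# Worked models used throughout the suite (two-state chains with known
# closed forms, and their canonical/Coxian counterparts).

# upper-triangular two-state chain with a free second rate `a` and free
# initial mass `p` on state 1; redundant for a = 1 (standard exponential)
chain2 <- function(p = 1, a = 5) {
  ph_rep(c(p, 1 - p), matrix(c(-3, 0, 2, -a), 2, 2))
}

# two equivalent Coxian competing-risks triples (m = K = 2) with
# subdensities f1 = 5e^{-4t} - 3e^{-5t}, f2 = 3e^{-4t} - 2e^{-5t}
cr_a <- function() {
  cr_rep(c(1, 0), matrix(c(-4, 0, 1, -5), 2, 2), matrix(c(2, 3, 1, 2), 2, 2))
}
cr_b <- function() {
  cr_rep(c(1, 0), matrix(c(-5, 0, 2, -4), 2, 2),
         matrix(c(2, 5/2, 1, 3/2), 2, 2))
}

# their shared canonical mixture
can_ab <- function() {
  canonical_cr(c(5, 4), matrix(c(0.40, 0.25, 0.20, 0.15), 2, 2))
}

# similarity matrix linking chain2(3/5) to its transformed twin
twin_pair <- function() {
  B <- matrix(c(2, -1, -1, 2), 2, 2)
  a <- chain2(p = 3/5)
  b <- ph_rep(as.numeric(a$p %*% B), solve(B) %*% a$Q %*% B)
  list(a = a, b = b, B = B)
}

# random valid canonical competing-risks model with well-separated rates
random_canonical <- function(m, K) {
  lambda <- sort(exp(stats::runif(m, -0.5, 2)), decreasing = TRUE)
  for (i in seq_len(m - 1)) {
    if (lambda[i] - lambda[i + 1] < 0.1 * lambda[1]) {
      lambda[i + 1] <- lambda[i] * 0.7
    }
  }
  lambda <- sort(lambda, decreasing = TRUE)
  P <- matrix(stats::rexp(m * K), m, K)
  canonical_cr(lambda, P / sum(P))
}
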