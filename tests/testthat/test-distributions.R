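test_that("transition probabilities are stochastic and solve the forward equations", {
  rep <- cr_a()
  expect_equal(unname(transition_probabilities(rep, 0)), diag(4))
  P1 <- transition_probabilities(rep, 1)
  expect_equal(unname(rowSums(P1)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(P1 >= -1e-14))
  # oracle: integrate dP/dt = P A with a fine RK4 grid
  A <- full_generator(rep)
  P <- diag(4); h <- 1e-3
  for (i in seq_len(1000)) {
    k1 <- P %*% A
    k2 <- (P + h / 2 * k1) %*% A
    k3 <- (P + h / 2 * k2) %*% A
    k4 <- (P + h * k3) %*% A
    P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(unname(P1), unname(P), tolerance = 1e-9)
  # long-run: transient block vanishes, absorption probabilities remain
  Pinf <- transition_probabilities(rep, 60)
  expect_lt(max(abs(Pinf[1:2, 1:2])), 1e-12)
  expect_equal(Pinf[1, 3], sub_cdf(rep, 1, Inf), tolerance = 1e-10)
})

test_that("exponential special case: chain with unit exit from every state", {
  ph <- chain2(p = 0.3, a = 1)  # both states exit at rate 1
  tt <- c(0, 0.2, 1, 3)
  expect_equal(ph_cdf(ph, tt), 1 - exp(-tt), tolerance = 1e-12)
  expect_equal(ph_pdf(ph, tt), exp(-tt), tolerance = 1e-12)
  expect_equal(ph_survival(ph, tt), exp(-tt), tolerance = 1e-12)
  expect_equal(ph_hazard(ph, tt), rep(1, 4), tolerance = 1e-12)
})

test_that("cdf/pdf/survival/hazard are mutually consistent", {
  ph <- chain2(p = 1, a = 5)
  tt <- seq(0, 3, by = 0.25)
  expect_equal(ph_cdf(ph, tt) + ph_survival(ph, tt), rep(1, length(tt)),
               tolerance = 1e-12)
  expect_equal(ph_pdf(ph, 0), sum(ph$p * exit_vector(ph$Q)))
  # -dS/dt = f by central differences
  h <- 1e-6
  num <- -(ph_survival(ph, tt[-1] + h) - ph_survival(ph, tt[-1] - h)) / (2 * h)
  expect_equal(num, ph_pdf(ph, tt[-1]), tolerance = 1e-7)
  expect_equal(ph_hazard(ph, 1), ph_pdf(ph, 1) / ph_survival(ph, 1))
  expect_true(all(diff(ph_cdf(ph, tt)) >= 0))
  expect_true(all(diff(ph_survival(ph, tt)) <= 0))
})

test_that("pdf matches the partial-fraction inversion of its transform", {
  # f*(s) = (s+15)/((s+3)(s+5)) inverts to 6 e^{-3t} - 5 e^{-5t}
  ph <- chain2(p = 1, a = 5)
  tt <- seq(0.1, 2, length.out = 10)
  expect_equal(ph_pdf(ph, tt), 6 * exp(-3 * tt) - 5 * exp(-5 * tt),
               tolerance = 1e-12)
})

test_that("subdensities and sub-CDFs reproduce closed forms and lump correctly", {
  rep <- cr_a()
  tt <- seq(0.05, 2.5, length.out = 10)
  expect_equal(sub_pdf(rep, 1, tt), 5 * exp(-4 * tt) - 3 * exp(-5 * tt),
               tolerance = 1e-10)
  expect_equal(sub_pdf(rep, 2, tt), 3 * exp(-4 * tt) - 2 * exp(-5 * tt),
               tolerance = 1e-10)
  expect_equal(sub_cdf(rep, 1, 0), 0)
  expect_equal(sub_cdf(rep, 1, Inf), 0.65, tolerance = 1e-12)
  expect_equal(sub_cdf(rep, 1, Inf) + sub_cdf(rep, 2, Inf), 1,
               tolerance = 1e-12)
  # lumping identities, cause sums equal the lumped model functions
  expect_equal(sub_pdf(rep, 1, tt) + sub_pdf(rep, 2, tt), ph_pdf(rep, tt),
               tolerance = 1e-10)
  expect_equal(sub_cdf(rep, 1, tt) + sub_cdf(rep, 2, tt), ph_cdf(rep, tt),
               tolerance = 1e-10)
  expect_true(all(diff(sub_cdf(rep, 2, tt)) >= 0))
  expect_error(sub_cdf(rep, 3, 1), "cause")
})

test_that("cause-specific hazards sum to the overall hazard", {
  rep <- cr_a()
  tt <- c(0.1, 0.5, 1, 2)
  expect_equal(cause_specific_hazard(rep, 1, tt) +
                 cause_specific_hazard(rep, 2, tt),
               ph_hazard(rep, tt), tolerance = 1e-10)
  # at t = 0 with p = (1,0) the hazards are the first-state exit rates
  expect_equal(cause_specific_hazard(rep, 1, 0), 2)
  expect_equal(cause_specific_hazard(rep, 2, 0), 1)
  # single transient state: constant hazards equal to the exit rates
  one <- cr_rep(1, matrix(-3, 1, 1), matrix(c(2, 1), 1, 2))
  expect_equal(cause_specific_hazard(one, 1, tt), rep(2, 4))
  expect_equal(cause_specific_hazard(one, 2, tt), rep(1, 4))
})

test_that("subdensity eigen-decomposition recovers the exponential terms", {
  terms <- sub_pdf_terms(cr_a(), 1)
  expect_equal(terms$rate, c(5, 4))
  expect_equal(terms$coef, c(-3, 5), tolerance = 1e-12)
  terms2 <- sub_pdf_terms(cr_a(), 2)
  expect_equal(terms2$coef, c(-2, 3), tolerance = 1e-12)
})

test_that("hypoexponential closed forms match convolution and matrix exponential", {
  # two stages: convolution of exp(5) and exp(4) is 20(e^{-4t} - e^{-5t})
  tt <- seq(0.05, 2, length.out = 9)
  expect_equal(hypoexp_pdf(c(5, 4), tt), 20 * (exp(-4 * tt) - exp(-5 * tt)),
               tolerance = 1e-12)
  expect_equal(hypoexp_survival(c(5, 4), tt),
               5 * exp(-4 * tt) - 4 * exp(-5 * tt), tolerance = 1e-12)
  expect_equal(hypoexp_pdf(3, tt), 3 * exp(-3 * tt))
  expect_equal(hypoexp_survival(3, 0), 1)
  # series-chain matrix exponential oracle up to six stages
  set.seed(42)
  for (m in c(2, 4, 6)) {
    lam <- sort(exp(runif(m, 0, 2)), decreasing = TRUE)
    lam <- lam * (1 + 0.2 * rev(seq_len(m)))  # enforce separation
    lam <- sort(lam, decreasing = TRUE)
    Q <- diag(-lam, m, m)
    for (i in seq_len(m - 1)) Q[i, i + 1] <- lam[i]
    chain <- ph_rep(c(1, numeric(m - 1)), Q)
    for (t0 in c(0.1, 0.7, 1.5)) {
      expect_equal(hypoexp_pdf(lam, t0), ph_pdf(chain, t0),
                   tolerance = 1e-10)
      expect_equal(hypoexp_survival(lam, t0), ph_survival(chain, t0),
                   tolerance = 1e-10)
    }
  }
  # finite-difference consistency of survival and density
  h <- 1e-6
  num <- -(hypoexp_survival(c(5, 4, 2), tt + h) -
             hypoexp_survival(c(5, 4, 2), tt - h)) / (2 * h)
  expect_equal(num, hypoexp_pdf(c(5, 4, 2), tt), tolerance = 1e-7)
  # coalescing rates are refused with a pointer to the fallback
  expect_error(hypoexp_pdf(c(3, 3 + 1e-9), 1), "matrix-exponential")
})

test_that("pdf of a valid representation integrates to one", {
  for (rep in list(cr_a(), chain2(p = 0.4, a = 5))) {
    up <- 1
    while (ph_survival(rep, up) > 1e-9) up <- up * 2
    val <- stats::integrate(function(t) ph_pdf(rep, t), 0, up,
                            rel.tol = 1e-9)$value
    expect_equal(val, 1, tolerance = 1e-6)
  }
})

test_that("canonical mixture densities match the converted representation", {
  can <- can_ab()
  tt <- seq(0.05, 2, length.out = 8)
  expect_equal(canonical_sub_pdf(can, 1, tt),
               5 * exp(-4 * tt) - 3 * exp(-5 * tt), tolerance = 1e-10)
  rep <- coxian_from_canonical(can)
  for (j in 1:2) {
    expect_equal(canonical_sub_pdf(can, j, tt), sub_pdf(rep, j, tt),
                 tolerance = 1e-9)
    expect_equal(canonical_sub_cdf(can, j, tt), sub_cdf(rep, j, tt),
                 tolerance = 1e-9)
  }
  # a single active cell reduces to the full hypoexponential
  solo <- canonical_cr(c(5, 4), matrix(c(0, 1), 2, 1))
  expect_equal(canonical_sub_pdf(solo, 1, tt), hypoexp_pdf(c(5, 4), tt))
})

test_that("grid evaluation tabulates consistent columns", {
  grid <- evaluate_grid(cr_a(), seq(0, 2, by = 0.5))
  expect_named(grid, c("t", "S", "f", "F_1", "F_2", "f_1", "f_2",
                       "lambda_1", "lambda_2"))
  expect_equal(grid$f_1 + grid$f_2, grid$f, tolerance = 1e-10)
  expect_equal(grid$S[1], 1)
  expect_equal(grid$lambda_1, grid$f_1 / grid$S)
})
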