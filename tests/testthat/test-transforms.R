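test_that("Laplace transforms of the worked chains have the known coefficients", {
  # (p=1, a=5): (s + 15) / ((s+3)(s+5))
  rt <- laplace_transform(chain2(p = 1, a = 5))
  expect_equal(rt$den, c(15, 8, 1), tolerance = 1e-12)
  expect_equal(rt$nums[[1]], c(15, 1), tolerance = 1e-12)
  # single state: lambda / (s + lambda)
  rt1 <- laplace_transform(ph_rep(1, matrix(-7, 1, 1)))
  expect_equal(rt1$den, c(7, 1))
  expect_equal(rt1$nums[[1]], 7)
  # evaluation matches p'(sI - Q)^{-1} l at positive s
  ph <- chain2(p = 0.3, a = 5)
  rt3 <- laplace_transform(ph)
  for (s in c(0.5, 1, 2, 10)) {
    direct <- as.numeric(ph$p %*% solve(s * diag(2) - ph$Q,
                                        exit_vector(ph$Q)))
    expect_equal(rt_eval(rt3, s), direct, tolerance = 1e-10)
  }
  # total mass: f*(0) = 1
  expect_equal(rt_eval(rt3, 0), 1, tolerance = 1e-12)
})

test_that("per-cause transforms share the denominator and sum to the lumped one", {
  rt <- sub_laplace(cr_a())
  expect_equal(rt$den, c(20, 9, 1), tolerance = 1e-12)
  expect_equal(rt$nums[[1]], c(13, 2), tolerance = 1e-12)
  expect_equal(rt$nums[[2]], c(7, 1), tolerance = 1e-12)
  lump <- laplace_transform(lump_to_single_risk(cr_a()))
  expect_equal(rt$nums[[1]] + rt$nums[[2]], lump$nums[[1]],
               tolerance = 1e-10)
})

test_that("reduction cancels only factors shared by all cause numerators", {
  # a = 1 chain is the standard exponential at any p: degree drops to 1
  red <- reduce_transform(laplace_transform(chain2(p = 0.37, a = 1)))
  expect_equal(red$degree, 1L)
  expect_equal(red$den, c(1, 1), tolerance = 1e-7)
  expect_equal(red$nums[[1]], 1, tolerance = 1e-7)
  # already reduced: idempotent
  rt <- reduce_transform(sub_laplace(cr_a()))
  expect_equal(rt$degree, 2L)
  expect_equal(reduce_transform(rt)$den, rt$den)
  # competing risks: a factor common to D and one numerator only must stay
  stay <- rational_transform(c(20, 9, 1), list(c(8, 2), c(12, 7) - c(0, 6)))
  # numerator 1 has root -4 (shared with D), numerator 2 does not
  expect_equal(reduce_transform(stay)$degree, 2L)
})

test_that("degree and redundancy follow the reduced transform", {
  expect_equal(ph_degree(chain2(p = 0.5, a = 1)), 1L)
  expect_true(is_redundant(chain2(p = 0.2, a = 1)))
  # a = 5: redundant exactly at p = 1/2 (factor s+5) and p = 0 (factor s+3)
  expect_true(is_redundant(chain2(p = 1/2, a = 5)))
  expect_equal(reduce_transform(laplace_transform(chain2(p = 1/2, a = 5)))$den,
               c(3, 1), tolerance = 1e-7)
  expect_true(is_redundant(chain2(p = 0, a = 5)))
  expect_false(is_redundant(chain2(p = 1, a = 5)))
  expect_equal(ph_degree(chain2(p = 1, a = 5)), 2L)
  expect_false(is_redundant(cr_a()))
})

test_that("canonical weights of the two-state chain solve to (1/5, 4/5)", {
  can <- canonical_from_triangular(chain2(p = 1, a = 5))
  expect_equal(can$lambda, c(5, 3))
  expect_equal(as.numeric(can$P), c(1/5, 4/5), tolerance = 1e-12)
  # already canonical input is a fixed point
  cox <- coxian_from_canonical(can)
  again <- canonical_cr_from_rep(cox)
  expect_equal(again$lambda, can$lambda, tolerance = 1e-10)
  expect_equal(again$P, can$P, tolerance = 1e-10)
})

test_that("the degree-3 mixture admits no three-state canonical form", {
  # depth weights (1/2, 0, 0, 1/2) on rates 4 > 3 > 2 > 1: the transform
  # has a common factor (s+4), but re-solving at the reduced dimension
  # yields a negative weight, so no order-3 chain exists
  can4 <- canonical_cr(c(4, 3, 2, 1), matrix(c(0.5, 0, 0, 0.5), 4, 1))
  cox4 <- coxian_from_canonical(can4)
  expect_equal(ph_degree(cox4), 3L)
  red <- reduce_transform(sub_laplace(cox4))
  expect_equal(red$den, c(6, 11, 6, 1), tolerance = 1e-6)
  expect_error(canonical_from_transform(red),
               "negative weight.*index 2")
})

test_that("canonical competing-risks weights reproduce the known mixture", {
  can <- canonical_cr_from_rep(cr_a())
  expect_equal(can$lambda, c(5, 4))
  expect_equal(as.numeric(can$P), c(0.40, 0.25, 0.20, 0.15),
               tolerance = 1e-12)
  # the equivalent triple gives the identical canonical output
  can_b <- canonical_cr_from_rep(cr_b())
  expect_equal(can_b$lambda, can$lambda)
  expect_equal(can_b$P, can$P, tolerance = 1e-12)
  # single-risk column agrees with the plain solver
  ph <- chain2(p = 1, a = 5)
  as_cr <- cr_rep(ph$p, ph$Q, matrix(exit_vector(ph$Q), ncol = 1))
  expect_equal(as.numeric(canonical_cr_from_rep(as_cr)$P),
               as.numeric(canonical_from_triangular(ph)$P),
               tolerance = 1e-12)
})

test_that("Coxian form of a canonical mixture has the known matrices", {
  # single risk: weights (1/5, 4/5) on rates (5, 3) -> Q = [[-5,4],[0,-3]]
  cox <- coxian_from_canonical(canonical_cr(c(5, 3), c(1/5, 4/5)))
  expect_equal(cox$Q, matrix(c(-5, 0, 4, -3), 2, 2), tolerance = 1e-12)
  expect_equal(cox$p, c(1, 0))
  # competing risks: recovers the second worked triple exactly
  cox2 <- coxian_from_canonical(can_ab())
  expect_equal(cox2$Q, cr_b()$Q, tolerance = 1e-12)
  expect_equal(cox2$L, cr_b()$L, tolerance = 1e-12)
  # all mass at depth 1: no link, first-row exits lambda1 * p_1j
  shallow <- canonical_cr(c(6, 2), matrix(c(0.7, 0, 0.3, 0), 2, 2))
  coxs <- coxian_from_canonical(shallow)
  expect_equal(coxs$Q[1, 2], 0)
  expect_equal(coxs$L[1, ], 6 * c(0.7, 0.3))
  # row conservation: link + exits = rate
  expect_equal(cox2$Q[1, 2] + sum(cox2$L[1, ]), -cox2$Q[1, 1])
})

test_that("canonical round trip preserves transforms and densities", {
  set.seed(7)
  for (trial in 1:8) {
    m <- sample(2:5, 1)
    K <- sample(1:3, 1)
    can <- random_canonical(m, K)
    cox <- coxian_from_canonical(can)
    expect_length(validate_rep(cox), 0)
    back <- canonical_cr_from_rep(cox)
    expect_equal(back$lambda, can$lambda, tolerance = 1e-9)
    expect_equal(back$P, can$P, tolerance = 1e-9)
    expect_equal(sum(back$P), 1, tolerance = 1e-9)
    tt <- seq(0.1, 2, length.out = 5)
    for (j in seq_len(K)) {
      expect_equal(canonical_sub_pdf(can, j, tt), sub_pdf(cox, j, tt),
                   tolerance = 1e-9)
    }
  }
})

test_that("ordering enumeration keeps decreasing order and drops invalid ones", {
  # m = 1: the single trivial permutation
  one <- cr_rep(1, matrix(-3, 1, 1), matrix(c(2, 1), 1, 2))
  expect_length(valid_orderings(one), 1)
  # worked pair: both orders of (5, 4) are valid, as the two triples show
  ords <- valid_orderings(cr_a())
  expect_equal(length(ords), 2)
  # degree-3 mixture at dimension 4: reversed (increasing) order invalid
  can4 <- canonical_cr(c(4, 3, 2, 1), matrix(c(0.5, 0, 0, 0.5), 4, 1))
  cox4 <- coxian_from_canonical(can4)
  expect_error(valid_orderings(cox4), "redundant")
  ords4 <- valid_orderings(cox4, allow_redundant = TRUE)
  dec <- c(4, 3, 2, 1)
  expect_true(any(vapply(ords4, function(o) all(o == dec), logical(1))))
  expect_false(any(vapply(ords4, function(o) all(o == rev(dec)), logical(1))))
})
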