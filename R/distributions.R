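#' Canonical Coxian competing-risks mixture
#'
#' The identifiable canonical form of a Coxian (upper-triangular) phase-type
#' competing-risks model: a single series chain with strictly decreasing
#' rates `lambda[1] > ... > lambda[m]`, entered `i` steps from absorption
#' with probability `P[i, j]` and then absorbed into state m+j. The failure
#' time of a path of depth `i` is the hypoexponential sum of independent
#' exponentials with rates `lambda[1..i]`, so the subdensities are plain
#' mixtures of hypoexponential densities and no matrix exponentials are
#' needed in the likelihood.
#'
#' @param lambda numeric vector of positive rates, nonincreasing.
#' @param P m x K matrix of nonnegative mixing probabilities summing to 1;
#'   a vector is taken as a single-cause column (K = 1).
#' @param validate stop on violated invariants (default `TRUE`).
#' @return object of class `canonical_cr` with fields `lambda`, `P`, `m`, `K`.
#' @examples
#' can5 <- canonical_cr(c(5, 4), matrix(c(0.40, 0.25, 0.20, 0.15), 2, 2))
#' canonical_sub_pdf(can5, 1, 0.5)
#' @export
canonical_cr <- function(lambda, P, validate = TRUE) {
  lambda <- as.numeric(lambda)
  if (is.null(dim(P))) P <- matrix(as.numeric(P), ncol = 1)
  P <- as.matrix(P)
  storage.mode(P) <- "double"
  if (nrow(P) != length(lambda)) {
    stop("structural error: nrow(P) = ", nrow(P),
         " does not match length(lambda) = ", length(lambda))
  }
  obj <- structure(list(lambda = lambda, P = P,
                        m = length(lambda), K = ncol(P)),
                   class = "canonical_cr")
  if (validate) {
    if (any(lambda <= 0)) stop("rates must be strictly positive")
    if (any(diff(lambda) > .ph_tol)) stop("rates must be nonincreasing")
    if (any(P < -.ph_tol)) stop("mixing probabilities must be nonnegative")
    if (abs(sum(P) - 1) > .ph_tol) {
      stop("mixing probabilities must sum to 1, got ", format(sum(P)))
    }
  }
  obj
}

#' @export
print.canonical_cr <- function(x, ...) {
  cat("Canonical Coxian competing-risks mixture: m =", x$m,
      "stages, K =", x$K, "risks\n")
  cat("lambda:", format(x$lambda), "\n")
  cat("P (rows = steps from absorption, cols = cause):\n")
  print(x$P)
  invisible(x)
}

expm_mat <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

#' Transition probability matrix of the absorbing chain
#'
#' `P(t) = e^{At}` for the full generator `A`, evaluated in block form:
#' `[[e^{Qt}, Q^{-1}(e^{Qt} - I) L], [0, I]]`. Rows sum to one.
#'
#' @param rep a `ph_rep` or `cr_rep`.
#' @param t a single nonnegative time.
#' @return `(m+K) x (m+K)` stochastic matrix.
#' @export
transition_probabilities <- function(rep, t) {
  stopifnot(inherits(rep, "ph_rep"), length(t) == 1, t >= 0)
  Q <- rep$Q
  L <- if (inherits(rep, "cr_rep")) rep$L else matrix(exit_vector(Q), ncol = 1)
  m <- nrow(Q); K <- ncol(L)
  E <- expm_mat(Q * t)
  abs_block <- solve(Q, (E - diag(m)) %*% L)
  P <- rbind(cbind(E, abs_block),
             cbind(matrix(0, K, m), diag(K)))
  dimnames(P) <- dimnames(full_generator(rep))
  P
}

#' Distribution functions of the absorption time
#'
#' Survival `S(t) = p' e^{Qt} 1`, density `f(t) = p' e^{Qt} l`, cumulative
#' distribution `F(t) = 1 - S(t)` and hazard `f(t)/S(t)` of the time to
#' absorption. All are vectorized over `t`. For a competing-risks
#' representation these describe the lumped absorption time, irrespective
#' of cause.
#'
#' When `S(t)` underflows to zero at very large `t`, `ph_hazard()` returns
#' `NA` with a warning rather than an indeterminate 0/0.
#'
#' @param ph a `ph_rep` (or `cr_rep`).
#' @param t nonnegative time(s).
#' @return numeric vector the length of `t`.
#' @examples
#' ph <- ph_rep(c(1, 0), matrix(c(-3, 0, 2, -5), 2, 2))
#' ph_cdf(ph, c(0, 1, 10))
#' @export
ph_survival <- function(ph, t) {
  stopifnot(inherits(ph, "ph_rep"), all(t >= 0))
  vapply(t, function(tt) {
    as.numeric(ph$p %*% expm_mat(ph$Q * tt) %*% rep(1, ph$m))
  }, numeric(1))
}

#' @rdname ph_survival
#' @export
ph_cdf <- function(ph, t) 1 - ph_survival(ph, t)

#' @rdname ph_survival
#' @export
ph_pdf <- function(ph, t) {
  stopifnot(inherits(ph, "ph_rep"), all(t >= 0))
  ell <- exit_vector(ph$Q)
  vapply(t, function(tt) {
    as.numeric(ph$p %*% expm_mat(ph$Q * tt) %*% ell)
  }, numeric(1))
}

#' @rdname ph_survival
#' @export
ph_hazard <- function(ph, t) {
  S <- ph_survival(ph, t)
  f <- ph_pdf(ph, t)
  out <- f / S
  if (any(S <= 0)) {
    warning("survival underflow at large t; hazard returned as NA")
    out[S <= 0] <- NA_real_
  }
  out
}

check_cause <- function(rep, j) {
  if (length(j) != 1 || j != round(j) || j < 1 || j > rep$K) {
    stop("cause j must be an integer in 1..", rep$K)
  }
}

#' Cumulative incidence, subdensity and cause-specific hazard
#'
#' For a competing-risks representation with exit columns `l_j`:
#' the cumulative incidence function `F_j(t) = p' Q^{-1}(e^{Qt} - I) l_j`
#' (probability of failing from cause j by time t), its derivative, the
#' subdensity `f_j(t) = p' e^{Qt} l_j`, and the cause-specific hazard
#' `f_j(t)/S(t)`. `sub_cdf()` accepts `t = Inf`, returning the exact limit
#' `-p' Q^{-1} l_j` (the lifetime probability of cause j). Vectorized in `t`.
#'
#' @param rep a `cr_rep`.
#' @param j cause index in 1..K.
#' @param t nonnegative time(s); `Inf` allowed in `sub_cdf()`.
#' @return numeric vector the length of `t`.
#' @examples
#' rep20 <- cr_rep(c(1, 0), matrix(c(-4, 0, 1, -5), 2, 2),
#'                 matrix(c(2, 3, 1, 2), 2, 2))
#' sub_cdf(rep20, 1, Inf)  # 0.65
#' @export
sub_cdf <- function(rep, j, t) {
  stopifnot(inherits(rep, "cr_rep"), all(t >= 0))
  check_cause(rep, j)
  ellj <- rep$L[, j]
  lim <- as.numeric(-rep$p %*% solve(rep$Q, ellj))
  vapply(t, function(tt) {
    if (is.infinite(tt)) return(lim)
    as.numeric(rep$p %*% solve(rep$Q, (expm_mat(rep$Q * tt) - diag(rep$m)) %*% ellj))
  }, numeric(1))
}

#' @rdname sub_cdf
#' @export
sub_pdf <- function(rep, j, t) {
  stopifnot(inherits(rep, "cr_rep"), all(t >= 0))
  check_cause(rep, j)
  ellj <- rep$L[, j]
  vapply(t, function(tt) {
    as.numeric(rep$p %*% expm_mat(rep$Q * tt) %*% ellj)
  }, numeric(1))
}

#' @rdname sub_cdf
#' @export
cause_specific_hazard <- function(rep, j, t) {
  S <- ph_survival(rep, t)
  f <- sub_pdf(rep, j, t)
  out <- f / S
  if (any(S <= 0)) {
    warning("survival underflow at large t; hazard returned as NA")
    out[S <= 0] <- NA_real_
  }
  out
}

#' Decompose a subdensity into exponential terms
#'
#' Writes `f_j(t) = p' e^{Qt} l_j` as a sum of `c_k e^{mu_k t}` terms via the
#' eigendecomposition of `Q` (requires distinct eigenvalues). Useful for
#' reading off closed-form subdensities.
#'
#' @param rep a `cr_rep`.
#' @param j cause index.
#' @return data frame with columns `rate` (the positive decay rate, i.e.
#'   minus the eigenvalue) and `coef`, sorted by decreasing rate.
#' @examples
#' rep20 <- cr_rep(c(1, 0), matrix(c(-4, 0, 1, -5), 2, 2),
#'                 matrix(c(2, 3, 1, 2), 2, 2))
#' sub_pdf_terms(rep20, 1)  # 5 e^{-4t} - 3 e^{-5t}
#' @export
sub_pdf_terms <- function(rep, j) {
  stopifnot(inherits(rep, "cr_rep"))
  check_cause(rep, j)
  eg <- eigen(rep$Q)
  if (any(abs(Im(eg$values)) > 1e-10)) {
    stop("Q has complex eigenvalues; no real exponential-term decomposition")
  }
  if (min(dist(Re(eg$values))) < 1e-10 * max(abs(eg$values))) {
    stop("Q has (near-)repeated eigenvalues; decomposition is not diagonal")
  }
  V <- Re(eg$vectors)
  coefs <- as.numeric((rep$p %*% V) * t(solve(V, rep$L[, j])))
  out <- data.frame(rate = -Re(eg$values), coef = coefs)
  out[order(-out$rate), , drop = FALSE]
}

# ---- hypoexponential closed forms -----------------------------------------

# relative gap below which the partial-fraction coefficients are unreliable
.hypoexp_gap <- 1e-6

check_hypoexp_rates <- function(lambdas) {
  if (any(lambdas <= 0)) stop("hypoexponential rates must be strictly positive")
  if (length(lambdas) > 1) {
    gap <- min(dist(lambdas))
    if (gap < .hypoexp_gap * max(lambdas)) {
      stop("rates too close for the closed-form hypoexponential ",
           "(min gap ", format(gap), "); use the matrix-exponential path ",
           "(ph_pdf/ph_survival on the series chain) instead")
    }
  }
  invisible(lambdas)
}

# partial-fraction coefficients: pdf = sum_l cf[l] exp(-lambda[l] t)
hypoexp_pdf_coefs <- function(lambdas) {
  i <- length(lambdas)
  vapply(seq_len(i), function(l) {
    prod(lambdas) / prod(lambdas[-l] - lambdas[l])
  }, numeric(1))
}

# survival = sum_l (cf[l]/lambda[l]) exp(-lambda[l] t)
hypoexp_surv_coefs <- function(lambdas) hypoexp_pdf_coefs(lambdas) / lambdas

#' Hypoexponential density and survival
#'
#' Closed-form density and survival function of the sum of independent
#' exponentials with distinct rates `lambdas` (the sojourn through the first
#' `i = length(lambdas)` stages of a series chain), via partial fractions:
#' `g(t) = sum_l [prod_u lambda_u / prod_{u != l}(lambda_u - lambda_l)]
#' e^{-lambda_l t}`. Vectorized over `t`.
#'
#' The partial-fraction coefficients blow up as rates coalesce, so rates
#' closer than `1e-6 * max(lambdas)` are rejected with an error pointing to
#' the matrix-exponential route (build the series chain and use
#' [ph_pdf()]/[ph_survival()]).
#'
#' @param lambdas strictly positive, pairwise-distinct rates.
#' @param t nonnegative time(s).
#' @return numeric vector the length of `t`.
#' @examples
#' hypoexp_pdf(c(5, 4), 0.3)      # 20 (e^{-1.2} - e^{-1.5})
#' hypoexp_survival(c(5, 4), 0.3) # 5 e^{-1.2} - 4 e^{-1.5}
#' @export
hypoexp_pdf <- function(lambdas, t) {
  check_hypoexp_rates(lambdas)
  cf <- hypoexp_pdf_coefs(lambdas)
  as.numeric(exp(-outer(t, lambdas)) %*% cf)
}

#' @rdname hypoexp_pdf
#' @export
hypoexp_survival <- function(lambdas, t) {
  check_hypoexp_rates(lambdas)
  cf <- hypoexp_surv_coefs(lambdas)
  as.numeric(exp(-outer(t, lambdas)) %*% cf)
}

#' Subdensity and cumulative incidence of the canonical mixture
#'
#' For a canonical Coxian competing-risks model, the cause-j subdensity is
#' the mixture `f_j(t) = sum_i P[i, j] g_(i)(t)` of hypoexponential
#' densities over entry depth `i`, and the cumulative incidence is the
#' corresponding mixture of hypoexponential CDFs. Vectorized over `t`.
#'
#' @param can a `canonical_cr`.
#' @param j cause index in 1..K.
#' @param t nonnegative time(s).
#' @return numeric vector the length of `t`.
#' @export
canonical_sub_pdf <- function(can, j, t) {
  stopifnot(inherits(can, "canonical_cr"))
  check_cause(can, j)
  out <- numeric(length(t))
  for (i in seq_len(can$m)) {
    if (can$P[i, j] == 0) next
    out <- out + can$P[i, j] * hypoexp_pdf(can$lambda[seq_len(i)], t)
  }
  out
}

#' @rdname canonical_sub_pdf
#' @export
canonical_sub_cdf <- function(can, j, t) {
  stopifnot(inherits(can, "canonical_cr"))
  check_cause(can, j)
  out <- numeric(length(t))
  for (i in seq_len(can$m)) {
    if (can$P[i, j] == 0) next
    out <- out + can$P[i, j] * (1 - hypoexp_survival(can$lambda[seq_len(i)], t))
  }
  out
}

#' Evaluate all distribution functions on a time grid
#'
#' Tabulates survival, density, per-cause cumulative incidence, subdensity
#' and cause-specific hazard on a grid, for export or plotting.
#'
#' @param rep a `cr_rep`.
#' @param times nonnegative time grid.
#' @return data frame with columns `t`, `S`, `f`, then `F_j`, `f_j`,
#'   `lambda_j` for each cause j.
#' @export
evaluate_grid <- function(rep, times) {
  stopifnot(inherits(rep, "cr_rep"))
  out <- data.frame(t = times,
                    S = ph_survival(rep, times),
                    f = ph_pdf(rep, times))
  for (j in seq_len(rep$K)) {
    out[[paste0("F_", j)]] <- sub_cdf(rep, j, times)
  }
  for (j in seq_len(rep$K)) {
    out[[paste0("f_", j)]] <- sub_pdf(rep, j, times)
  }
  for (j in seq_len(rep$K)) {
    out[[paste0("lambda_", j)]] <- out[[paste0("f_", j)]] / out$S
  }
  out
}
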