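# Polynomials are stored as numeric coefficient vectors in ascending power
# order: c(a0, a1, ..., an) is a0 + a1 s + ... + an s^n. This matches
# base::polyroot and the JSON serialization.

poly_mul <- function(a, b) {
  r <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    r[idx] <- r[idx] + a[i] * b
  }
  r
}

poly_from_roots <- function(rts) {
  p <- 1
  for (r in rts) p <- poly_mul(p, c(-r, 1))
  p
}

poly_eval <- function(p, s) {
  out <- 0 * s
  for (i in rev(seq_along(p))) out <- out * s + p[i]
  out
}

poly_trim <- function(p, tol = 0) {
  n <- length(p)
  while (n > 1 && abs(p[n]) <= tol) n <- n - 1L
  p[seq_len(n)]
}

# synthetic division of p by (s - r); assumes r is (near) a root
poly_deflate <- function(p, r) {
  n <- length(p) - 1L
  out <- numeric(n)
  out[n] <- p[n + 1L]
  if (n > 1) for (i in (n - 1L):1L) out[i] <- p[i + 1L] + r * out[i + 1L]
  out
}

# coefficients of det(sI - Q) by the Faddeev-LeVerrier recursion
charpoly_coefs <- function(Q) {
  m <- nrow(Q)
  cs <- numeric(m + 1L)
  cs[m + 1L] <- 1
  Mk <- diag(m)
  for (k in seq_len(m)) {
    AM <- Q %*% Mk
    ck <- -sum(diag(AM)) / k
    cs[m + 1L - k] <- ck
    Mk <- AM + ck * diag(m)
  }
  cs
}

#' Rational Laplace transform of a (competing-risks) phase-type model
#'
#' Container for the per-cause Laplace transforms `f*_j(s) = N_j(s)/D(s)`
#' with a shared monic denominator `D(s) = det(sI - Q)`. Coefficients are
#' stored in ascending power order. Total probability one means the cause
#' numerators evaluated at `s = 0` sum to `D(0)`.
#'
#' @param denominator ascending coefficients of the denominator; normalized
#'   to monic.
#' @param numerators list of ascending coefficient vectors, one per cause,
#'   each of degree < degree(D).
#' @return object of class `rational_transform` with fields `den`, `nums`,
#'   `K`, `degree`.
#' @export
rational_transform <- function(denominator, numerators) {
  den <- poly_trim(as.numeric(denominator))
  lead <- den[length(den)]
  if (lead == 0) stop("denominator is identically zero")
  den <- den / lead
  nums <- lapply(numerators, function(n) poly_trim(as.numeric(n) / lead))
  if (any(vapply(nums, length, 1L) > length(den) - 1L)) {
    stop("numerator degree must be below denominator degree")
  }
  structure(list(den = den, nums = nums, K = length(nums),
                 degree = length(den) - 1L),
            class = "rational_transform")
}

#' @export
print.rational_transform <- function(x, ...) {
  fmt <- function(p) paste(format(p), collapse = ", ")
  cat("Rational Laplace transform, degree", x$degree, "with", x$K,
      "cause(s)\n")
  cat("D (ascending):", fmt(x$den), "\n")
  for (j in seq_len(x$K)) cat("N_", j, " (ascending): ", fmt(x$nums[[j]]),
                              "\n", sep = "")
  invisible(x)
}

#' Evaluate a rational transform at real points
#'
#' @param rt a `rational_transform`.
#' @param s numeric evaluation points (must avoid the poles).
#' @param j cause index (default 1).
#' @return numeric vector of `N_j(s)/D(s)`.
#' @export
rt_eval <- function(rt, s, j = 1) {
  poly_eval(rt$nums[[j]], s) / poly_eval(rt$den, s)
}

# numerator of p'(sI-Q)^{-1} v over D(s)=det(sI-Q), by interpolation at
# integer sample points (safe: all poles have negative real part)
transform_numerator <- function(p, Q, v, den) {
  m <- nrow(Q)
  ssamp <- seq_len(m)
  vals <- vapply(ssamp, function(s) {
    as.numeric(p %*% solve(s * diag(m) - Q, v)) * poly_eval(den, s)
  }, numeric(1))
  V <- outer(ssamp, 0:(m - 1L), "^")
  as.numeric(solve(V, vals))
}

#' Laplace transform of a phase-type distribution
#'
#' The rational function `f*(s) = p'(sI - Q)^{-1} l` with
#' `D(s) = det(sI - Q)` as denominator, returned unreduced (dimension m
#' gives degree m; use [reduce_transform()] to cancel common factors).
#'
#' @param ph a `ph_rep`.
#' @return a `rational_transform` with one cause.
#' @examples
#' ph <- ph_rep(c(1, 0), matrix(c(-3, 0, 2, -5), 2, 2))
#' laplace_transform(ph)  # (s + 15) / ((s+3)(s+5))
#' @export
laplace_transform <- function(ph) {
  stopifnot(inherits(ph, "ph_rep"))
  den <- charpoly_coefs(ph$Q)
  num <- transform_numerator(ph$p, ph$Q, exit_vector(ph$Q), den)
  rational_transform(den, list(num))
}

#' Per-cause Laplace transforms of the subdensities
#'
#' `f*_j(s) = p'(sI - Q)^{-1} l_j` for each cause, sharing the denominator
#' `det(sI - Q)`.
#'
#' @param rep a `cr_rep`.
#' @return a `rational_transform` with K causes.
#' @export
sub_laplace <- function(rep) {
  stopifnot(inherits(rep, "cr_rep"))
  den <- charpoly_coefs(rep$Q)
  nums <- lapply(seq_len(rep$K), function(j) {
    transform_numerator(rep$p, rep$Q, rep$L[, j], den)
  })
  rational_transform(den, nums)
}

# roots of an ascending-coefficient polynomial (complex)
poly_roots <- function(p) {
  p <- poly_trim(p)
  if (length(p) == 1L) return(complex(0))
  polyroot(p)
}

#' Cancel common factors of a rational transform
#'
#' A root of the denominator is canceled only when *every* cause numerator
#' shares it (within a relative pairing tolerance on root distance): the
#' joint distribution is unchanged exactly when the factor divides all
#' numerators simultaneously. The degree of the result is the degree of
#' the phase-type distribution. Idempotent.
#'
#' @param rt a `rational_transform`.
#' @param tol relative tolerance for root pairing.
#' @return a reduced `rational_transform`.
#' @export
reduce_transform <- function(rt, tol = 1e-7) {
  stopifnot(inherits(rt, "rational_transform"))
  den <- rt$den
  nums <- rt$nums
  num_scale <- vapply(nums, function(n) max(abs(n)), numeric(1))
  zero_num <- num_scale <= tol * max(num_scale, 1)
  repeat {
    drts <- poly_roots(den)
    if (!length(drts)) break
    canceled <- FALSE
    for (r in drts) {
      shares <- vapply(seq_along(nums), function(j) {
        if (zero_num[j]) return(TRUE)
        nrts <- poly_roots(nums[[j]])
        length(nrts) > 0 && min(Mod(nrts - r)) <= tol * max(1, Mod(r))
      }, logical(1))
      if (all(shares)) {
        den <- Re(poly_deflate(den, r))
        nums <- lapply(seq_along(nums), function(j) {
          if (zero_num[j]) return(nums[[j]])
          nrts <- poly_roots(nums[[j]])
          rj <- nrts[which.min(Mod(nrts - r))]
          lead <- nums[[j]][length(nums[[j]])]
          Re(poly_deflate(nums[[j]] / lead, rj)) * lead
        })
        canceled <- TRUE
        break
      }
    }
    if (!canceled) break
  }
  # zero numerators must not exceed the new degree bound
  nums <- lapply(nums, function(n) {
    n <- poly_trim(n, tol = 0)
    if (length(n) > length(den) - 1L) n[seq_len(length(den) - 1L)] else n
  })
  rational_transform(den, nums)
}

#' Degree and redundancy of a representation
#'
#' The degree of a phase-type (competing-risks) distribution is the degree
#' of the denominator of its reduced Laplace transform. A dimension-m
#' representation is redundant when its degree is below m, i.e. the same
#' distribution admits a transform of lower order.
#'
#' @param rep a `ph_rep` or `cr_rep`.
#' @return `ph_degree()`: integer degree; `is_redundant()`: logical.
#' @examples
#' ph <- ph_rep(c(0.5, 0.5), matrix(c(-3, 0, 2, -1), 2, 2))
#' ph_degree(ph)     # 1: the standard exponential
#' is_redundant(ph)  # TRUE
#' @export
ph_degree <- function(rep) {
  rt <- if (inherits(rep, "cr_rep")) sub_laplace(rep) else laplace_transform(rep)
  reduce_transform(rt)$degree
}

#' @rdname ph_degree
#' @export
is_redundant <- function(rep) {
  ph_degree(rep) < rep$m
}

# ---- canonical forms -------------------------------------------------------

check_triangular <- function(Q) {
  scale <- max(abs(Q))
  if (any(abs(Q[lower.tri(Q)]) > 1e-12 * scale)) {
    stop("Q must be upper triangular; general representations are handled ",
         "by the equivalence tools, not the canonical solver")
  }
  lam <- -diag(Q)
  if (any(abs(Im(lam)) > 0)) stop("complex rates are not supported")
  if (length(lam) > 1 && min(dist(lam)) < .hypoexp_gap * max(lam)) {
    stop("canonical solve requires pairwise distinct rates on the diagonal")
  }
  lam
}

# Solve sum_i w_i * prod(lambda[1:i]) * prod_{u>i}(s + lambda[u]) = N(s)
# for the depth weights w, given rates in the chosen diagonal order.
# The system is triangular in the coefficient basis; a dense solve is fine
# at these dimensions.
solve_canonical_weights <- function(lambda, num) {
  m <- length(lambda)
  M <- vapply(seq_len(m), function(i) {
    pol <- prod(lambda[seq_len(i)]) *
      (if (i < m) poly_from_roots(-lambda[(i + 1):m]) else 1)
    c(pol, numeric(m - length(pol)))
  }, numeric(m))
  M <- matrix(M, nrow = m)
  rhs <- c(num, numeric(m - length(num)))
  as.numeric(solve(M, rhs))
}

#' Canonical mixture form of an upper-triangular phase-type model
#'
#' Any phase-type distribution with upper-triangular `Q` (real, distinct
#' rates) has a unique canonical representation: a series chain with
#' decreasing rates entered `i` steps from absorption with probability
#' `p_i >= 0`. The weights are found by matching numerator coefficients of
#' `sum_i p_i g*_(i)(s)` against the target transform; the system is
#' triangular and solved by back-substitution. A negative solved weight
#' means no canonical representation exists at this dimension, and an error
#' carrying the offending index is raised.
#'
#' `canonical_from_transform()` performs the same solve directly on a
#' (typically reduced) rational transform, taking the rates from the
#' denominator roots; `canonical_cr_from_rep()` solves each cause column of
#' a competing-risks representation against one shared decreasing rate
#' vector.
#'
#' @param ph a `ph_rep` with upper-triangular `Q`.
#' @return a `canonical_cr` (with K = 1 for the single-risk solvers).
#' @examples
#' ph <- ph_rep(c(1, 0), matrix(c(-3, 0, 2, -5), 2, 2))
#' canonical_from_triangular(ph)  # weights 1/5, 4/5 on rates 5, 3
#' @export
canonical_from_triangular <- function(ph) {
  stopifnot(inherits(ph, "ph_rep"))
  lam <- sort(check_triangular(ph$Q), decreasing = TRUE)
  rt <- laplace_transform(ph)
  w <- solve_canonical_weights(lam, rt$nums[[1]])
  check_weights(w, cause = NULL)
  canonical_cr(lam, matrix(w, ncol = 1))
}

check_weights <- function(w, cause, tol = 1e-9) {
  neg <- which(w < -tol)
  if (length(neg)) {
    stop("no canonical representation at this dimension: negative weight ",
         format(w[neg[1]]), " at index ", neg[1],
         if (!is.null(cause)) paste0(" (cause ", cause, ")") else "")
  }
  invisible(pmax(w, 0))
}

#' @rdname canonical_from_triangular
#' @param rt a `rational_transform` whose denominator has real, distinct,
#'   negative roots.
#' @export
canonical_from_transform <- function(rt) {
  stopifnot(inherits(rt, "rational_transform"))
  rts <- poly_roots(rt$den)
  if (any(abs(Im(rts)) > 1e-9 * max(1, Mod(rts)))) {
    stop("complex poles: no canonical mixture form")
  }
  lam <- sort(-Re(rts), decreasing = TRUE)
  if (any(lam <= 0)) stop("denominator roots must be negative reals")
  if (length(lam) > 1 && min(dist(lam)) < .hypoexp_gap * max(lam)) {
    stop("canonical solve requires pairwise distinct rates")
  }
  W <- vapply(seq_len(rt$K), function(j) {
    w <- solve_canonical_weights(lam, rt$nums[[j]])
    check_weights(w, cause = if (rt$K > 1) j else NULL)
  }, numeric(length(lam)))
  canonical_cr(lam, matrix(W, ncol = rt$K))
}

#' @rdname canonical_from_triangular
#' @param rep a `cr_rep` with upper-triangular `Q`.
#' @export
canonical_cr_from_rep <- function(rep) {
  stopifnot(inherits(rep, "cr_rep"))
  lam <- sort(check_triangular(rep$Q), decreasing = TRUE)
  rt <- sub_laplace(rep)
  W <- vapply(seq_len(rep$K), function(j) {
    w <- solve_canonical_weights(lam, rt$nums[[j]])
    check_weights(w, cause = j)
  }, numeric(rep$m))
  canonical_cr(lam, matrix(W, ncol = rep$K))
}

#' Coxian competing-risks representation of a canonical mixture
#'
#' Converts the canonical mixture (decreasing rates, entry-depth weights)
#' into the equivalent Coxian triple: `p = (1, 0, ..., 0)`, bidiagonal `Q`
#' with diagonal `-lambda` in decreasing-rate order, and exit matrix `L`.
#' With `R_i` the probability of reaching chain position i (the tail weight
#' sum), the link rate is `alpha_{i,i+1} = lambda_i R_{i+1}/R_i` and the
#' exits are `L_{ij} = lambda_i P[i, j]/R_i`, so each row satisfies
#' `alpha_{i,i+1} + sum_j L_{ij} = lambda_i` and existence is guaranteed by
#' the decreasing order. Positions with zero reaching probability are
#' unreachable; their rows are filled with a pass-through link (and a
#' cause-1 exit in the last row), which leaves the distribution unchanged.
#'
#' @param can a `canonical_cr`.
#' @return a `cr_rep` in Coxian form.
#' @examples
#' can5 <- canonical_cr(c(5, 4), matrix(c(0.40, 0.25, 0.20, 0.15), 2, 2))
#' coxian_from_canonical(can5)
#' @export
coxian_from_canonical <- function(can) {
  stopifnot(inherits(can, "canonical_cr"))
  m <- can$m; K <- can$K
  lam <- can$lambda
  exit_prob <- rowSums(can$P)
  reach <- rev(cumsum(rev(exit_prob)))       # R_i = P(reach position i)
  Q <- diag(-lam, m, m)
  L <- matrix(0, m, K)
  for (i in seq_len(m)) {
    if (reach[i] > 0) {
      L[i, ] <- lam[i] * can$P[i, ] / reach[i]
      if (i < m) Q[i, i + 1] <- lam[i] * reach[i + 1] / reach[i]
    } else {
      # unreachable position: any conserving row works
      if (i < m) Q[i, i + 1] <- lam[i] else L[i, 1] <- lam[i]
    }
  }
  cr_rep(c(1, numeric(m - 1)), Q, L)
}

#' Diagonal orderings admitting a valid Coxian representation
#'
#' A Coxian competing-risks model with distinct diagonal rates can always be
#' written with the rates in decreasing order; other orderings may or may
#' not admit a valid (nonnegative) representation of the same distribution.
#' For each permutation of the rates this solves, per cause, the triangular
#' coefficient-matching system equating the target sub-Laplace transforms to
#' a Coxian chain with that diagonal order, and keeps the permutation iff
#' all solved depth weights are nonnegative (which makes all link and exit
#' rates nonnegative).
#'
#' @param rep a `cr_rep` or `ph_rep` with upper-triangular `Q`.
#' @param tol nonnegativity tolerance on solved weights.
#' @param allow_redundant redundant representations are rejected by default
#'   (reduce first); set `TRUE` to screen orderings of the full-dimension
#'   chain anyway.
#' @return list of valid orderings, each a numeric vector of rates in
#'   diagonal order; the decreasing ordering is always present.
#' @export
valid_orderings <- function(rep, tol = 1e-9, allow_redundant = FALSE) {
  stopifnot(inherits(rep, "ph_rep"))
  lam <- check_triangular(rep$Q)
  if (!allow_redundant && is_redundant(rep)) {
    stop("representation is redundant; reduce it (reduce_transform / ",
         "canonical_from_transform) before enumerating orderings, or set ",
         "allow_redundant = TRUE")
  }
  rt <- if (inherits(rep, "cr_rep")) sub_laplace(rep) else laplace_transform(rep)
  m <- length(lam)
  if (m > 8) stop("ordering enumeration is factorial in m; m <= 8 required")
  perms <- permutations_of(m)
  keep <- list()
  for (pi in perms) {
    ord <- lam[pi]
    ok <- TRUE
    for (j in seq_len(rt$K)) {
      w <- solve_canonical_weights(ord, rt$nums[[j]])
      if (any(w < -tol)) { ok <- FALSE; break }
    }
    if (ok) keep[[length(keep) + 1L]] <- ord
  }
  dec <- sort(lam, decreasing = TRUE)
  if (!any(vapply(keep, function(o) isTRUE(all.equal(o, dec)), logical(1)))) {
    stop("internal error: decreasing ordering not found valid")
  }
  keep
}

permutations_of <- function(m) {
  if (m == 1) return(list(1L))
  sub <- permutations_of(m - 1L)
  out <- vector("list", m * length(sub))
  k <- 0L
  for (i in seq_len(m)) {
    for (s in sub) {
      k <- k + 1L
      rest <- seq_len(m)[-i]
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}
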