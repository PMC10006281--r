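#' Phase-type representation (p, Q)
#'
#' Constructs the Markov-chain representation of a phase-type distribution:
#' an initial probability vector `p` over the `m` transient states and an
#' `m x m` sub-generator `Q` holding the transition rates between transient
#' states. The exit rate to the single absorbing state is implied by
#' conservation, `l = -Q 1`. States are numbered 1..m in all printed output,
#' matching the usual textbook convention.
#'
#' @param p numeric vector of initial probabilities (length m, sums to 1).
#' @param Q numeric m x m matrix; nonnegative off-diagonal rates, strictly
#'   negative diagonal, row sums <= 0, all eigenvalues with negative real
#'   part (absorption certain).
#' @param validate if `TRUE` (default), stop on any violated invariant.
#'   Set `FALSE` to build an intentionally invalid object for inspection
#'   with [validate_rep()].
#' @return an object of class `ph_rep` with fields `p`, `Q`, `m`.
#' @seealso [cr_rep()] for several absorbing states, [validate_rep()].
#' @examples
#' ph <- ph_rep(c(1, 0), matrix(c(-3, 0, 2, -5), 2, 2))
#' exit_vector(ph)
#' @export
ph_rep <- function(p, Q, validate = TRUE) {
  p <- as.numeric(p)
  Q <- as.matrix(Q)
  storage.mode(Q) <- "double"
  if (nrow(Q) != ncol(Q)) {
    stop("structural error: Q must be square, got ", nrow(Q), " x ", ncol(Q))
  }
  if (length(p) != nrow(Q)) {
    stop("structural error: length(p) = ", length(p),
         " does not match dim(Q) = ", nrow(Q))
  }
  obj <- structure(list(p = p, Q = Q, m = length(p)), class = "ph_rep")
  if (validate) stop_if_invalid(obj)
  obj
}

#' Competing-risks phase-type representation (p, Q, L)
#'
#' The triple determining a phase-type competing-risks model: as [ph_rep()]
#' but with `K >= 1` absorbing states m+1, ..., m+K and an `m x K` matrix `L`
#' of exit rates into them. Conservation requires `L 1 = -Q 1` (each row of
#' the full generator sums to zero), so `L` carries `(K-1) m` free parameters
#' and the triple `(K+1) m - 1` in total (see [parameter_count()]).
#'
#' The class inherits from `ph_rep`: functions of the absorption time alone
#' (survival, density, hazard) apply unchanged, since they only involve the
#' lumped exit vector `L 1`.
#'
#' @param p,Q as in [ph_rep()].
#' @param L numeric m x K matrix of nonnegative exit rates.
#' @param validate stop on violated invariants (default `TRUE`).
#' @return an object of class `c("cr_rep", "ph_rep")` with fields `p`, `Q`,
#'   `L`, `m`, `K`.
#' @examples
#' rep20 <- cr_rep(c(1, 0),
#'                 matrix(c(-4, 0, 1, -5), 2, 2),
#'                 matrix(c(2, 3, 1, 2), 2, 2))
#' full_generator(rep20)
#' @export
cr_rep <- function(p, Q, L, validate = TRUE) {
  base <- ph_rep(p, Q, validate = FALSE)
  L <- as.matrix(L)
  storage.mode(L) <- "double"
  if (nrow(L) != base$m) {
    stop("structural error: L has ", nrow(L), " rows but Q is ",
         base$m, " x ", base$m)
  }
  obj <- structure(list(p = base$p, Q = base$Q, L = L,
                        m = base$m, K = ncol(L)),
                   class = c("cr_rep", "ph_rep"))
  if (validate) stop_if_invalid(obj)
  obj
}

#' @export
print.ph_rep <- function(x, ...) {
  cat("Phase-type representation: m =", x$m, "transient states\n")
  cat("p:", format(x$p), "\n")
  cat("Q:\n"); print(x$Q)
  invisible(x)
}

#' @export
print.cr_rep <- function(x, ...) {
  cat("Competing-risks phase-type representation: m =", x$m,
      "transient states, K =", x$K, "risks\n")
  cat("p:", format(x$p), "\n")
  cat("Q:\n"); print(x$Q)
  cat("L:\n"); print(x$L)
  invisible(x)
}

# absolute tolerance for probability sums / rate balance; inputs typically
# come from JSON round trips at double precision
.ph_tol <- 1e-8

#' Validate a representation against its model invariants
#'
#' Checks every invariant of a phase-type or competing-risks representation
#' and returns a character vector naming each violated rule (empty when the
#' representation is valid). Structural problems (inconsistent shapes) are
#' raised as errors by the constructors, not reported here.
#'
#' Rules checked: nonnegative `p` summing to 1; nonnegative off-diagonal and
#' strictly negative diagonal of `Q`; nonpositive row sums of `Q`; all
#' eigenvalues of `Q` with strictly negative real part (certain absorption,
#' `Q` invertible); and for competing risks additionally nonnegative `L`
#' with `L 1 = -Q 1`.
#'
#' @param rep a `ph_rep` or `cr_rep`.
#' @param tol absolute tolerance for sum and sign checks.
#' @return character vector of violation messages; `character(0)` if valid.
#' @examples
#' validate_rep(ph_rep(c(1, 0), matrix(c(-3, 0, 2, -5), 2, 2)))
#' bad <- ph_rep(c(1), matrix(0, 1, 1), validate = FALSE)
#' validate_rep(bad)
#' @export
validate_rep <- function(rep, tol = .ph_tol) {
  stopifnot(inherits(rep, "ph_rep"))
  p <- rep$p; Q <- rep$Q; m <- rep$m
  bad <- character(0)
  if (any(p < -tol)) {
    bad <- c(bad, paste0("p: negative entry at index ",
                         which(p < -tol)[1]))
  }
  if (abs(sum(p) - 1) > tol) {
    bad <- c(bad, paste0("p: entries sum to ", format(sum(p)), ", not 1"))
  }
  off <- Q; diag(off) <- 0
  if (any(off < -tol)) {
    idx <- which(off < -tol, arr.ind = TRUE)[1, ]
    bad <- c(bad, paste0("Q: negative off-diagonal entry at (",
                         idx[1], ",", idx[2], ")"))
  }
  if (any(diag(Q) >= 0)) {
    bad <- c(bad, paste0("Q: nonnegative diagonal entry at state ",
                         which(diag(Q) >= 0)[1]))
  }
  rs <- rowSums(Q)
  if (any(rs > tol)) {
    bad <- c(bad, paste0("Q: positive row sum at state ",
                         which(rs > tol)[1]))
  }
  ev <- eigen(Q, only.values = TRUE)$values
  if (any(Re(ev) >= -.Machine$double.eps * max(1, max(abs(Q))))) {
    bad <- c(bad, "Q: eigenvalue with nonnegative real part (absorption not certain)")
  }
  if (inherits(rep, "cr_rep")) {
    L <- rep$L
    if (any(L < -tol)) {
      idx <- which(L < -tol, arr.ind = TRUE)[1, ]
      bad <- c(bad, paste0("L: negative entry at (", idx[1], ",", idx[2], ")"))
    }
    resid <- rowSums(L) + rowSums(Q)
    if (any(abs(resid) > tol)) {
      bad <- c(bad, paste0("L: row ", which(abs(resid) > tol)[1],
                           " violates L 1 = -Q 1 (residual ",
                           format(max(abs(resid))), ")"))
    }
  }
  bad
}

stop_if_invalid <- function(rep) {
  bad <- validate_rep(rep)
  if (length(bad)) {
    stop("invalid representation:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(rep)
}

#' Exit-rate vector of a sub-generator
#'
#' Rates from each transient state into the (lumped) absorbing set,
#' `l = -Q 1`, forced by the zero row sums of the full generator.
#'
#' @param Q an m x m sub-generator matrix, or a `ph_rep`/`cr_rep` whose `Q`
#'   is used.
#' @param tol entries below `-tol` indicate an invalid sub-generator.
#' @return nonnegative numeric vector of length m (tiny negative round-off
#'   is clamped to zero).
#' @examples
#' exit_vector(matrix(c(-3, 0, 2, -5), 2, 2))  # (1, 5)
#' @export
exit_vector <- function(Q, tol = .ph_tol) {
  if (inherits(Q, "ph_rep")) Q <- Q$Q
  ell <- -as.numeric(Q %*% rep(1, nrow(Q)))
  if (any(ell < -tol)) {
    stop("invalid sub-generator: row ", which(ell < -tol)[1],
         " has positive sum ", format(-ell[ell < -tol][1]))
  }
  pmax(ell, 0)
}

#' Full generator of the absorbing chain
#'
#' Assembles the `(m+K) x (m+K)` infinitesimal generator in block form
#' `[[Q, L], [0, 0]]` (for a plain phase-type representation, `K = 1` and
#' `L` is the exit vector `-Q 1`). Every row sums to zero.
#'
#' @param rep a `ph_rep` or `cr_rep`.
#' @return square numeric matrix with state names `s1..sm, a1..aK`.
#' @export
full_generator <- function(rep) {
  stopifnot(inherits(rep, "ph_rep"))
  Q <- rep$Q
  L <- if (inherits(rep, "cr_rep")) rep$L else matrix(exit_vector(Q), ncol = 1)
  m <- nrow(Q); K <- ncol(L)
  A <- rbind(cbind(Q, L), matrix(0, K, m + K))
  dimnames(A) <- rep(list(c(paste0("s", seq_len(m)), paste0("a", seq_len(K)))), 2)
  A
}

#' Number of free parameters of a competing-risks representation
#'
#' A triple (p, Q, L) with m transient states and K risks has
#' `(K+1) m - 1` free parameters: `2m - 1` for the lumped phase-type part
#' and `(K-1) m` for the split of each exit rate across causes. With
#' `K = 1` this reduces to the classical `2m - 1`.
#'
#' @param m number of transient states (>= 1).
#' @param K number of absorbing states / risks (>= 1).
#' @return integer parameter count.
#' @examples
#' parameter_count(2, 2)  # 5
#' @export
parameter_count <- function(m, K) {
  if (m < 1 || K < 1 || m != round(m) || K != round(K)) {
    stop("m and K must be positive integers")
  }
  as.integer((K + 1) * m - 1)
}

#' Lump all risks into a single absorbing state
#'
#' Drops the cause labels: the absorption time of a competing-risks model
#' has the plain phase-type distribution with the same (p, Q), whose exit
#' vector is the row sum `L 1 = -Q 1`.
#'
#' @param rep a `cr_rep` (a `ph_rep` is returned unchanged).
#' @return a `ph_rep`.
#' @export
lump_to_single_risk <- function(rep) {
  stopifnot(inherits(rep, "ph_rep"))
  ph_rep(rep$p, rep$Q)
}
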