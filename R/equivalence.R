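#' Do two representations define the same distribution?
#'
#' Two (competing-risks) phase-type representations define the same joint
#' law of (time, cause) exactly when their reduced rational Laplace
#' transforms agree, cause by cause. Both transforms are reduced (common
#' factors of the denominator and all cause numerators canceled) and then
#' compared coefficientwise with monic denominators.
#'
#' @param repA,repB both `ph_rep` or both `cr_rep` with equal K.
#' @param tol absolute coefficientwise tolerance.
#' @return logical.
#' @examples
#' a <- cr_rep(c(1, 0), matrix(c(-4, 0, 1, -5), 2, 2),
#'             matrix(c(2, 3, 1, 2), 2, 2))
#' b <- cr_rep(c(1, 0), matrix(c(-5, 0, 2, -4), 2, 2),
#'             matrix(c(2, 5/2, 1, 3/2), 2, 2))
#' same_distribution(a, b)  # TRUE
#' @export
same_distribution <- function(repA, repB, tol = 1e-8) {
  rtA <- rep_transform(repA)
  rtB <- rep_transform(repB)
  if (rtA$K != rtB$K) stop("representations have different numbers of risks")
  rA <- reduce_transform(rtA)
  rB <- reduce_transform(rtB)
  if (rA$degree != rB$degree) return(FALSE)
  if (max(abs(rA$den - rB$den)) > tol) return(FALSE)
  for (j in seq_len(rA$K)) {
    nA <- c(rA$nums[[j]], numeric(rA$degree - length(rA$nums[[j]])))
    nB <- c(rB$nums[[j]], numeric(rB$degree - length(rB$nums[[j]])))
    if (max(abs(nA - nB)) > tol) return(FALSE)
  }
  TRUE
}

rep_transform <- function(rep) {
  stopifnot(inherits(rep, "ph_rep"))
  if (inherits(rep, "cr_rep")) sub_laplace(rep) else laplace_transform(rep)
}

# Krylov-style moment matrix with rows p' Q^k, k = 0..m-1; nonsingular
# exactly when the representation behaves nonredundantly for this purpose
moment_matrix <- function(rep) {
  m <- rep$m
  M <- matrix(0, m, m)
  v <- rep$p
  for (k in seq_len(m)) {
    M[k, ] <- v
    v <- as.numeric(v %*% rep$Q)
  }
  M
}

#' Construct the similarity matrix linking two equivalent representations
#'
#' For two nonredundant same-dimension representations of the same
#' distribution there is a nonsingular matrix `B` with unit row sums such
#' that `p_b' = p_a' B`, `Q_b = B^{-1} Q_a B` and (for competing risks)
#' `L_b = B^{-1} L_a`. The construction builds the moment matrices `M_x`
#' with rows `p' Q^k` (k = 0..m-1) and sets `B = M_a^{-1} M_b`; since the
#' similarity relations force `M_b = M_a B`, this recovers a valid `B`
#' whenever one exists. All relations are then verified explicitly and
#' `NULL` is returned (invisibly, with a message) if any fails, so a
#' spurious solve cannot masquerade as equivalence.
#'
#' @param repA,repB nonredundant representations of equal dimension and K.
#' @param tol residual tolerance for the verification.
#' @return the m x m matrix `B`, or `NULL` if the representations are not
#'   equivalent.
#' @examples
#' a <- cr_rep(c(1, 0), matrix(c(-4, 0, 1, -5), 2, 2),
#'             matrix(c(2, 3, 1, 2), 2, 2))
#' b <- cr_rep(c(1, 0), matrix(c(-5, 0, 2, -4), 2, 2),
#'             matrix(c(2, 5/2, 1, 3/2), 2, 2))
#' find_similarity(a, b)  # [[1, 0], [-1, 2]]
#' @export
find_similarity <- function(repA, repB, tol = 1e-8) {
  stopifnot(inherits(repA, "ph_rep"), inherits(repB, "ph_rep"))
  if (repA$m != repB$m) stop("representations must have the same dimension")
  crA <- inherits(repA, "cr_rep"); crB <- inherits(repB, "cr_rep")
  if (crA != crB || (crA && repA$K != repB$K)) {
    stop("representations must have the same number of risks")
  }
  if (is_redundant(repA) || is_redundant(repB)) {
    stop("similarity construction requires nonredundant representations; ",
         "reduce to minimal order first")
  }
  Ma <- moment_matrix(repA)
  if (kappa(Ma, exact = TRUE) > 1e10) {
    stop("moment matrix numerically singular: representation behaves as ",
         "redundant at working precision")
  }
  B <- solve(Ma, moment_matrix(repB))
  rep_v <- verify_similarity(repA, repB, B, tol = tol)
  if (!rep_v$pass) {
    message("representations are not equivalent (max residual ",
            format(max(unlist(rep_v[startsWith(names(rep_v), "residual")]))),
            ")")
    return(invisible(NULL))
  }
  B
}

#' Verify the similarity relations for a candidate matrix
#'
#' Reports the max-norm residuals of `p_b' - p_a' B`,
#' `Q_b - B^{-1} Q_a B`, `L_b - B^{-1} L_a` (competing risks only) and of
#' the unit-row-sum condition `B 1 = 1`, together with a pass flag
#' (all residuals below `tol` and `B` nonsingular).
#'
#' @param repA,repB representations of equal dimension.
#' @param B candidate m x m matrix.
#' @param tol pass threshold on every residual.
#' @return list with `residual_p`, `residual_Q`, `residual_L` (for
#'   competing-risks pairs), `residual_rowsum`, `nonsingular`, `pass`.
#' @export
verify_similarity <- function(repA, repB, B, tol = 1e-8) {
  stopifnot(nrow(B) == repA$m, ncol(B) == repA$m, repA$m == repB$m)
  d <- det(B)
  nonsing <- is.finite(d) && abs(d) > 1e-12
  out <- list(
    residual_p = max(abs(repB$p - as.numeric(repA$p %*% B))),
    residual_Q = if (nonsing)
      max(abs(repB$Q - solve(B, repA$Q %*% B))) else Inf,
    residual_rowsum = max(abs(rowSums(B) - 1))
  )
  if (inherits(repA, "cr_rep") && inherits(repB, "cr_rep")) {
    out$residual_L <- if (nonsing)
      max(abs(repB$L - solve(B, repA$L))) else Inf
  }
  out$nonsingular <- nonsing
  out$pass <- nonsing &&
    all(unlist(out[startsWith(names(out), "residual")]) < tol)
  out
}

is_coxian_form <- function(rep) {
  m <- rep$m
  if (max(abs(rep$p - c(1, numeric(m - 1)))) > .ph_tol) return(FALSE)
  mask <- upper.tri(rep$Q) & !(col(rep$Q) == row(rep$Q) + 1L)
  all(abs(rep$Q[lower.tri(rep$Q)]) <= 1e-12 * max(abs(rep$Q))) &&
    all(abs(rep$Q[mask]) <= 1e-12 * max(abs(rep$Q)))
}

#' Identifiability certificate for equally ordered Coxian models
#'
#' For two nonredundant Coxian competing-risks models with initial vector
#' `(1, 0, ..., 0)` and identically ordered diagonals, equality of all
#' cumulative incidence functions forces `Q` and `L` to be identical
#' entrywise — the parameterization is identifiable. This checks the
#' preconditions (Coxian form, nonredundancy, equal diagonal ordering),
#' reporting any violation rather than silently proceeding, then compares
#' distributions and asserts entrywise equality of the matrices.
#'
#' @param repA,repB Coxian `cr_rep` objects.
#' @param tol entrywise tolerance for the matrix comparison.
#' @return list with `preconditions_ok`, `violations` (character),
#'   `same_distribution`, `matrices_equal` (NA when preconditions fail or
#'   the distributions differ).
#' @export
coxian_uniqueness_check <- function(repA, repB, tol = 1e-9) {
  stopifnot(inherits(repA, "cr_rep"), inherits(repB, "cr_rep"))
  viol <- character(0)
  if (!is_coxian_form(repA)) viol <- c(viol, "repA is not in Coxian form with p = (1,0,...,0)")
  if (!is_coxian_form(repB)) viol <- c(viol, "repB is not in Coxian form with p = (1,0,...,0)")
  if (repA$m != repB$m || repA$K != repB$K) {
    viol <- c(viol, "dimensions or number of risks differ")
  } else {
    ordA <- order(-diag(repA$Q)); ordB <- order(-diag(repB$Q))
    if (!identical(ordA, ordB)) {
      viol <- c(viol, "diagonals of Q are not ordered in the same way")
    }
  }
  if (!length(viol)) {
    if (is_redundant(repA)) viol <- c(viol, "repA is redundant")
    if (is_redundant(repB)) viol <- c(viol, "repB is redundant")
  }
  if (length(viol)) {
    return(list(preconditions_ok = FALSE, violations = viol,
                same_distribution = NA, matrices_equal = NA))
  }
  same <- same_distribution(repA, repB)
  eq <- if (same) {
    max(abs(repA$Q - repB$Q)) < tol && max(abs(repA$L - repB$L)) < tol
  } else NA
  list(preconditions_ok = TRUE, violations = character(0),
       same_distribution = same, matrices_equal = eq)
}
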