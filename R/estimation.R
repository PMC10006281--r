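# ---- log-domain hypoexponential machinery ---------------------------------
#
# The E-step and likelihood work entirely in the log domain so that large
# observation times (where every exp(-lambda t) term underflows) still give
# finite log-densities. Hypoexponential densities are signed mixtures of
# exponentials, so a signed log-sum-exp is used.

row_max <- function(M) {
  out <- M[, 1L]
  for (c in seq_len(ncol(M))[-1L]) out <- pmax(out, M[, c])
  out
}

# rowwise log |sum_l sign_l exp(logmat[k,l])|; returns -Inf where the signed
# sum is <= 0 (numerical cancellation near t = 0 for deep stages)
signed_lse_rows <- function(logmat, signs) {
  M <- row_max(logmat)
  s <- rowSums(exp(logmat - M) * rep(signs, each = nrow(logmat)))
  out <- rep(-Inf, length(M))
  ok <- is.finite(M) & !is.na(s) & s > 0
  out[ok] <- M[ok] + log(s[ok])
  out
}

# n x m matrices of log g_(i)(t_k) and log S_(i)(t_k) for stage depths i;
# the exponential terms e^{-lambda_l t} are shared across depths
log_hypoexp_matrices <- function(lambda, t) {
  m <- length(lambda)
  n <- length(t)
  E <- -outer(t, lambda)
  logG <- matrix(-Inf, n, m)
  logS <- matrix(-Inf, n, m)
  for (i in seq_len(m)) {
    li <- lambda[seq_len(i)]
    cf <- hypoexp_pdf_coefs(li)
    Ei <- E[, seq_len(i), drop = FALSE]
    logG[, i] <- signed_lse_rows(Ei + rep(log(abs(cf)), each = n), sign(cf))
    sf <- cf / li
    logS[, i] <- signed_lse_rows(Ei + rep(log(abs(sf)), each = n), sign(sf))
  }
  list(logG = logG, logS = logS)
}

min_gap_ok <- function(lambda) {
  length(lambda) == 1 ||
    min(-diff(lambda)) > .hypoexp_gap * max(lambda)
}

#' Observed-data log-likelihood of the canonical model
#'
#' For an event record (t, j) the contribution is
#' `log sum_i P[i, j] g_(i)(t)`; for a right-censored record (t, 0) it is
#' `log sum_{i,j} P[i, j] S_(i)(t)`, marginalizing the latent entry depth.
#' Records with zero density under the model contribute `-Inf`, which is
#' reported via a warning rather than silently dropped.
#'
#' @param can a `canonical_cr` with strictly decreasing rates.
#' @param data competing-risks data frame (`time`, `status`), statuses in
#'   0..K with 0 = censored.
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(can, data) {
  stopifnot(inherits(can, "canonical_cr"))
  data <- validate_dataset(data, K = can$K)
  mats <- log_hypoexp_matrices(can$lambda, data$time)
  logP <- log(can$P)                      # -Inf where P is 0, handled by LSE
  ll <- numeric(nrow(data))
  for (j in seq_len(can$K)) {
    idx <- data$status == j
    if (!any(idx)) next
    ll[idx] <- lse_rows(mats$logG[idx, , drop = FALSE] +
                          rep(logP[, j], each = sum(idx)))
  }
  cens <- data$status == 0
  if (any(cens)) {
    terms <- do.call(cbind, lapply(seq_len(can$K), function(j) {
      mats$logS[cens, , drop = FALSE] + rep(logP[, j], each = sum(cens))
    }))
    ll[cens] <- lse_rows(terms)
  }
  if (any(!is.finite(ll))) {
    warning(sum(!is.finite(ll)),
            " record(s) have zero density under the model (-Inf loglik)")
  }
  sum(ll)
}

lse_rows <- function(logmat) {
  M <- row_max(logmat)
  out <- M + log(rowSums(exp(logmat - M)))
  out[!is.finite(M)] <- -Inf
  out
}

#' E-step: posterior responsibilities of the latent entry depth
#'
#' Returns the array `r[k, i, j] = E(X_{k,ij} | T_k, D_k)` of posterior
#' probabilities that individual k entered the chain i steps from absorption
#' in the cause-j subchain. For an event of cause j, `r[k, i, j]` is
#' proportional to `g_(i)(t_k) P[i, j]` over i (zero for other causes); for
#' a censored record it is proportional to `S_(i)(t_k) P[i, j]` over all
#' (i, j). Computed in the log domain.
#'
#' @inheritParams observed_loglik
#' @return n x m x K array; event rows sum to 1 within their cause slice,
#'   censored rows sum to 1 over all (i, j).
#' @export
e_step <- function(can, data) {
  stopifnot(inherits(can, "canonical_cr"))
  data <- validate_dataset(data, K = can$K)
  n <- nrow(data); m <- can$m; K <- can$K
  mats <- log_hypoexp_matrices(can$lambda, data$time)
  logP <- log(can$P)
  r <- array(0, dim = c(n, m, K))
  for (j in seq_len(K)) {
    idx <- data$status == j
    if (!any(idx)) next
    lw <- mats$logG[idx, , drop = FALSE] + rep(logP[, j], each = sum(idx))
    r[idx, , j] <- softmax_rows(lw)
  }
  cens <- data$status == 0
  if (any(cens)) {
    lw <- do.call(cbind, lapply(seq_len(K), function(j) {
      mats$logS[cens, , drop = FALSE] + rep(logP[, j], each = sum(cens))
    }))
    r[cens, , ] <- softmax_rows(lw)
  }
  r
}

softmax_rows <- function(logw) {
  M <- row_max(logw)
  w <- exp(logw - M)
  w / rowSums(w)
}

# expected complete-data log-likelihood terms that depend on lambda
expected_rate_objective <- function(lambda, t, wE, wC) {
  if (!min_gap_ok(lambda)) return(-Inf)
  mats <- log_hypoexp_matrices(lambda, t)
  gE <- mats$logG * wE
  gC <- mats$logS * wC
  gE[wE == 0] <- 0
  gC[wC == 0] <- 0
  val <- sum(gE) + sum(gC)
  if (!is.finite(val)) -Inf else val
}

#' M-step: update the mixing probabilities and rates
#'
#' The mixing probabilities have the closed-form multinomial update
#' `P[i, j] = mean_k r[k, i, j]`. The rates maximize the expected
#' complete-data log-likelihood numerically under the strict ordering
#' constraint, via the reparameterization `lambda_m = exp(theta_m)`,
#' `lambda_i = lambda_{i+1} + exp(theta_i)` and BFGS. Any uphill step is
#' accepted (generalized EM); if the optimizer fails to improve the
#' objective, the previous rates are kept and the result flagged.
#'
#' @param resp responsibility array from [e_step()].
#' @param data the data the responsibilities were computed on.
#' @param can current model (supplies the starting rates).
#' @return updated `canonical_cr`, with attribute `gem_fallback = TRUE`
#'   when the rate update was rejected.
#' @export
m_step <- function(resp, data, can) {
  stopifnot(inherits(can, "canonical_cr"))
  n <- dim(resp)[1]
  P_new <- apply(resp, c(2, 3), mean)
  event <- data$status > 0
  w_all <- apply(resp, c(1, 2), sum)       # n x m, summed over causes
  wE <- w_all * event
  wC <- w_all * !event
  m <- can$m
  obj0 <- expected_rate_objective(can$lambda, data$time, wE, wC)
  theta0 <- log(pmax(-diff(c(can$lambda, 0)), 1e-12))
  lam_of <- function(theta) rev(cumsum(rev(exp(theta))))
  negQ <- function(theta) {
    v <- expected_rate_objective(lam_of(theta), data$time, wE, wC)
    if (!is.finite(v)) 1e12 else -v
  }
  fallback <- FALSE
  # a partial maximization suffices (generalized EM): a short BFGS run per
  # M-step is far cheaper overall than driving the inner problem to optimum
  opt <- tryCatch(
    stats::optim(theta0, negQ, method = "BFGS",
                 control = list(maxit = 8, reltol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value) && -opt$value > obj0) {
    lambda_new <- lam_of(opt$par)
  } else {
    lambda_new <- can$lambda
    fallback <- TRUE
  }
  out <- canonical_cr(lambda_new, P_new, validate = FALSE)
  attr(out, "gem_fallback") <- fallback
  out
}

default_init <- function(data, m, K) {
  rate0 <- m / mean(data$time)
  lambda <- rate0 * 2 ^ ((m + 1) / 2 - seq_len(m))
  canonical_cr(lambda, matrix(1 / (m * K), m, K))
}

jitter_init <- function(base) {
  lambda <- sort(base$lambda * exp(stats::runif(base$m, -0.7, 0.7)),
                 decreasing = TRUE)
  # enforce a workable gap
  for (i in seq_len(base$m - 1)) {
    if (lambda[i] - lambda[i + 1] < 0.05 * lambda[1]) {
      lambda[i + 1] <- lambda[i] * 0.8
    }
  }
  lambda <- sort(lambda, decreasing = TRUE)
  P <- matrix(stats::rexp(base$m * base$K), base$m, base$K)
  canonical_cr(lambda, P / sum(P), validate = FALSE)
}

#' Fit the canonical Coxian competing-risks model by EM
#'
#' Alternates [e_step()] and [m_step()] from one or several starting points
#' until the relative change in the observed-data log-likelihood falls
#' below `tol` or `max_iter` is reached; the best restart by final
#' log-likelihood is returned. The default start spaces the rates
#' geometrically around `m / mean(T)` with uniform mixing probabilities;
#' additional restarts jitter it from a seeded stream. Within every run the
#' log-likelihood trace is nondecreasing (up to arithmetic noise), the EM
#' guarantee.
#'
#' @param data data frame with columns `time`, `status`.
#' @param m number of chain stages.
#' @param K number of risks; default: largest observed status.
#' @param init optional explicit `canonical_cr` start (used for the first
#'   run).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param restarts number of EM runs.
#' @param seed root seed for the restart jitter.
#' @param polish after the EM loop, run a quasi-Newton ascent of the
#'   observed-data log-likelihood from the best EM solution (default
#'   `TRUE`). The likelihood surface has a flat ridge trading rate against
#'   mixing-probability changes, along which plain EM creeps; the polish
#'   finishes the climb. The step is accepted only if it improves the
#'   log-likelihood, so the trace stays nondecreasing.
#' @return object of class `em_fit`: `model` (fitted `canonical_cr`),
#'   `loglik` (final value), `trace` (per-iteration log-likelihood of the
#'   winning run, including the polish step when accepted), `iterations`,
#'   `converged`, `settings`.
#' @examples
#' can5 <- canonical_cr(c(5, 4), matrix(c(0.40, 0.25, 0.20, 0.15), 2, 2))
#' d <- sample_dataset(can5, 300, seed = 7)
#' fit <- fit_em(d, m = 2, restarts = 1, max_iter = 100)
#' fit$model
#' @export
fit_em <- function(data, m, K = NULL, init = NULL, tol = 1e-8,
                   max_iter = 2000, restarts = 3, seed = 1, polish = TRUE) {
  data <- validate_dataset(data, K = K)
  K <- attr(data, "K")
  stopifnot(m >= 1)
  base <- default_init(data, m, K)
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    start <- if (r == 1 && !is.null(init)) init
             else if (r == 1) base
             else { set.seed(substream_seed(seed * 7919, r)); jitter_init(base) }
    runs[[r]] <- tryCatch(em_single_run(start, data, tol, max_iter),
                          error = function(e) list(loglik = -Inf, error = conditionMessage(e)))
  }
  lls <- vapply(runs, function(x) x$loglik %||% -Inf, numeric(1))
  if (all(!is.finite(lls))) {
    stop("all EM restarts failed or degenerated; messages: ",
         paste(unlist(lapply(runs, `[[`, "error")), collapse = "; "))
  }
  best <- runs[[which.max(lls)]]
  if (polish) {
    pol <- polish_fit(best$model, data, best$loglik)
    if (pol$loglik > best$loglik) {
      best$model <- pol$model
      best$loglik <- pol$loglik
      best$trace <- c(best$trace, pol$loglik)
    }
  }
  structure(list(model = best$model, loglik = best$loglik,
                 trace = best$trace, iterations = best$iterations,
                 converged = best$converged,
                 settings = list(m = m, K = K, tol = tol,
                                 max_iter = max_iter, restarts = restarts,
                                 seed = seed, polish = polish)),
            class = "em_fit")
}

# direct quasi-Newton ascent of the observed log-likelihood, started at the
# EM solution; rates via ordered log-increments, mixing matrix via softmax
polish_fit <- function(can, data, ll0) {
  m <- can$m; K <- can$K
  par0 <- c(log(pmax(-diff(c(can$lambda, 0)), 1e-12)),
            log(pmax(as.numeric(can$P), 1e-12)))
  unpack <- function(par) {
    lambda <- rev(cumsum(rev(exp(par[seq_len(m)]))))
    w <- exp(par[-seq_len(m)] - max(par[-seq_len(m)]))
    canonical_cr(lambda, matrix(w / sum(w), m, K), validate = FALSE)
  }
  negll <- function(par) {
    mod <- unpack(par)
    if (!min_gap_ok(mod$lambda)) return(1e12)
    v <- tryCatch(suppressWarnings(observed_loglik(mod, data)),
                  error = function(e) -Inf)
    if (!is.finite(v)) 1e12 else -v
  }
  opt <- tryCatch(
    stats::optim(par0, negll, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || -opt$value <= ll0) {
    return(list(model = can, loglik = ll0))
  }
  list(model = unpack(opt$par), loglik = -opt$value)
}

em_single_run <- function(can, data, tol, max_iter) {
  # starting P entries of exactly 0 would pin responsibilities at 0 forever;
  # mix with a whisper of uniform mass
  if (any(can$P <= 0)) {
    P <- can$P + 1e-8
    can <- canonical_cr(can$lambda, P / sum(P), validate = FALSE)
  }
  trace <- numeric(0)
  ll_old <- suppressWarnings(observed_loglik(can, data))
  if (!is.finite(ll_old)) stop("starting point has zero-likelihood records")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    r <- e_step(can, data)
    can <- m_step(r, data, can)
    ll <- suppressWarnings(observed_loglik(can, data))
    trace <- c(trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(model = can, loglik = ll_old, trace = trace,
       iterations = it, converged = converged)
}

#' @export
print.em_fit <- function(x, ...) {
  cat("Canonical Coxian competing-risks EM fit\n")
  cat("  m =", x$settings$m, ", K =", x$settings$K,
      ", iterations =", x$iterations,
      ", converged =", x$converged, "\n")
  cat("  log-likelihood:", format(x$loglik), "\n")
  cat("  lambda:", format(x$model$lambda), "\n")
  cat("  P:\n")
  print(x$model$P)
  invisible(x)
}

#' Aalen-Johansen estimates of the cumulative incidence functions
#'
#' Nonparametric cumulative incidence estimates for right-censored
#' competing-risks data, computed by the multistate product-limit estimator
#' (via [survival::survfit()] with a factor status). Beyond the last event
#' time, the cause-specific estimates and the overall Kaplan-Meier survival
#' sum to 1.
#'
#' @param data data frame with columns `time`, `status` (0 = censored).
#' @param K number of risks; default: largest observed status.
#' @return object of class `aj_estimate`: `time` (event/censoring grid),
#'   `cif` (matrix, one column per cause), `surv` (overall survival), `K`.
#' @export
aalen_johansen <- function(data, K = NULL) {
  data <- validate_dataset(data, K = K)
  K <- attr(data, "K")
  if (nrow(data) == 0) stop("empty dataset")
  ev <- factor(data$status, levels = 0:K)
  fit <- survival::survfit(survival::Surv(data$time, ev) ~ 1)
  states <- fit$states
  cols <- match(as.character(seq_len(K)), states)
  if (anyNA(cols)) stop("internal error: missing state in survfit output")
  cif <- fit$pstate[, cols, drop = FALSE]
  colnames(cif) <- paste0("cause", seq_len(K))
  structure(list(time = fit$time, cif = cif,
                 surv = fit$pstate[, match("(s0)", states)], K = K),
            class = "aj_estimate")
}

#' Evaluate an Aalen-Johansen estimate at arbitrary times
#'
#' Right-continuous step-function evaluation of the cause-j cumulative
#' incidence estimate.
#'
#' @param aj an `aj_estimate`.
#' @param j cause index.
#' @param t evaluation time(s).
#' @return numeric vector the length of `t`.
#' @export
aj_cif_at <- function(aj, j, t) {
  stopifnot(inherits(aj, "aj_estimate"), j >= 1, j <= aj$K)
  stats::stepfun(aj$time, c(0, aj$cif[, j]))(t)
}

#' Model vs nonparametric cumulative incidence comparison
#'
#' Tabulates the fitted model's cumulative incidence functions alongside
#' the Aalen-Johansen estimates from the data, per cause, on a common time
#' grid — the standard goodness-of-fit display for a parametric
#' competing-risks fit.
#'
#' @param fit an `em_fit` (must have converged) or a `canonical_cr`.
#' @param data the dataset to compare against.
#' @param times evaluation grid; default: 200 points spanning the data.
#' @return data frame with columns `time`, `cause`, `cif_model`, `cif_aj`.
#' @export
fitted_cif_report <- function(fit, data, times = NULL) {
  can <- if (inherits(fit, "em_fit")) {
    if (!isTRUE(fit$converged)) {
      warning("EM fit did not converge; comparison may be unreliable")
    }
    fit$model
  } else fit
  stopifnot(inherits(can, "canonical_cr"))
  data <- validate_dataset(data, K = can$K)
  if (is.null(times)) {
    times <- seq(0, max(data$time), length.out = 200)
  }
  aj <- aalen_johansen(data, K = can$K)
  do.call(rbind, lapply(seq_len(can$K), function(j) {
    data.frame(time = times, cause = j,
               cif_model = canonical_sub_cdf(can, j, times),
               cif_aj = aj_cif_at(aj, j, times))
  }))
}
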