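# Per-individual substreams: individual k of a run with root seed s always
# sees the same draws, so the first k rows of an n-run equal a k-run and
# scaled-down reruns of a large experiment stay comparable.
substream_seed <- function(root, k) {
  as.integer((as.double(root) * 48271 + k * 16807) %% 2147483647)
}

#' Simulate one path of the absorbing Markov chain
#'
#' Standard competing-exponential-clocks simulation: the sojourn in state i
#' is exponential with the total outflow rate `-Q[i,i]`, and the next state
#' is drawn proportionally to the outgoing rates (transient via `Q`,
#' absorbing via `L`). Uses the current RNG state; seed the session (or use
#' [sample_dataset()]) for reproducibility.
#'
#' @param rep a `cr_rep` (or `ph_rep`, treated as one risk).
#' @return list with `time` (absorption time), `cause` (1..K) and `states`
#'   (transient states visited, in order).
#' @export
sample_path <- function(rep) {
  stopifnot(inherits(rep, "ph_rep"))
  Q <- rep$Q
  L <- if (inherits(rep, "cr_rep")) rep$L else matrix(exit_vector(Q), ncol = 1)
  m <- nrow(Q); K <- ncol(L)
  state <- sample.int(m, 1L, prob = rep$p)
  states <- state
  time <- 0
  repeat {
    total <- -Q[state, state]
    time <- time + stats::rexp(1L, total)
    rates <- c(Q[state, ], L[state, ])
    rates[state] <- 0
    nxt <- sample.int(m + K, 1L, prob = rates)
    if (nxt > m) {
      return(list(time = time, cause = nxt - m, states = states))
    }
    state <- nxt
    states <- c(states, state)
  }
}

#' Simulate one observation from the canonical mixture
#'
#' Draws the entry depth and cause `(i, j)` with probability `P[i, j]`, then
#' the failure time as the sum of `i` independent exponentials with rates
#' `lambda[1..i]`. Distributionally identical to [sample_path()] on
#' [coxian_from_canonical()] of the same model.
#'
#' @param can a `canonical_cr`.
#' @return list with `time` and `cause`.
#' @export
sample_canonical <- function(can) {
  stopifnot(inherits(can, "canonical_cr"))
  cell <- sample.int(can$m * can$K, 1L, prob = as.numeric(can$P))
  i <- (cell - 1L) %% can$m + 1L
  j <- (cell - 1L) %/% can$m + 1L
  list(time = sum(stats::rexp(i, can$lambda[seq_len(i)])), cause = j)
}

#' Simulate a right-censored competing-risks dataset
#'
#' Draws `n` independent (time, cause) pairs from a representation or a
#' canonical mixture and applies independent right censoring. The observed
#' time is the minimum of the event and censoring times; `status` is 0 for
#' a censored record and the cause index otherwise (ties, a probability-zero
#' event, are resolved in favour of the event). Each individual gets its own
#' RNG substream derived from `seed`, so identical seeds give identical
#' datasets and the first k rows do not depend on `n`.
#'
#' @param model a `cr_rep`, `ph_rep` or `canonical_cr`.
#' @param n number of individuals.
#' @param censoring one of `censor_none()`, `censor_exponential(rate)`,
#'   `censor_fixed(time)`, `censor_quantile(prob)` (administrative
#'   censoring at the model's prob-quantile of the failure time).
#' @param seed integer root seed.
#' @return data frame with columns `time`, `status` and attributes `K` and
#'   `seed`.
#' @examples
#' can5 <- canonical_cr(c(5, 4), matrix(c(0.40, 0.25, 0.20, 0.15), 2, 2))
#' d <- sample_dataset(can5, 100, censor_exponential(0.5), seed = 1)
#' table(d$status)
#' @export
sample_dataset <- function(model, n, censoring = censor_none(), seed = 1) {
  stopifnot(n >= 1)
  if (!inherits(censoring, "censor_spec")) {
    stop("invalid censoring spec: use censor_none(), censor_exponential(), ",
         "censor_fixed() or censor_quantile()")
  }
  draw <- if (inherits(model, "canonical_cr")) {
    K <- model$K
    function() sample_canonical(model)
  } else if (inherits(model, "ph_rep")) {
    K <- if (inherits(model, "cr_rep")) model$K else 1L
    function() sample_path(model)
  } else stop("model must be a cr_rep, ph_rep or canonical_cr")
  t0 <- censor_time_fun(censoring, model)
  times <- numeric(n); status <- integer(n)
  for (k in seq_len(n)) {
    set.seed(substream_seed(seed, k))
    ev <- draw()
    cens <- t0()
    if (cens < ev$time) {
      times[k] <- cens; status[k] <- 0L
    } else {
      times[k] <- ev$time; status[k] <- as.integer(ev$cause)
    }
  }
  structure(data.frame(time = times, status = status),
            K = K, seed = seed)
}

#' Censoring specifications for [sample_dataset()]
#'
#' `censor_none()` applies no censoring; `censor_exponential(rate)` draws an
#' independent exponential censoring time; `censor_fixed(time)` censors
#' administratively at a fixed time; `censor_quantile(prob)` censors at the
#' model's `prob`-quantile of the failure-time distribution (found by root
#' search on the survival function).
#'
#' @param rate positive censoring hazard.
#' @param time positive fixed censoring time.
#' @param prob quantile level in (0, 1).
#' @return an object of class `censor_spec`.
#' @export
censor_none <- function() structure(list(type = "none"), class = "censor_spec")

#' @rdname censor_none
#' @export
censor_exponential <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1, rate > 0)
  structure(list(type = "exponential", rate = rate), class = "censor_spec")
}

#' @rdname censor_none
#' @export
censor_fixed <- function(time) {
  stopifnot(is.numeric(time), length(time) == 1, time > 0)
  structure(list(type = "fixed", time = time), class = "censor_spec")
}

#' @rdname censor_none
#' @export
censor_quantile <- function(prob) {
  stopifnot(is.numeric(prob), length(prob) == 1, prob > 0, prob < 1)
  structure(list(type = "quantile", prob = prob), class = "censor_spec")
}

censor_time_fun <- function(spec, model) {
  switch(spec$type,
    none = function() Inf,
    exponential = function() stats::rexp(1L, spec$rate),
    fixed = function() spec$time,
    quantile = {
      surv <- if (inherits(model, "canonical_cr")) {
        function(t) sum(vapply(seq_len(model$K), function(j)
          canonical_sub_cdf(model, j, t), numeric(1))) # F(t)
      } else {
        function(t) ph_cdf(model, t)
      }
      t0 <- stats::uniroot(function(t) surv(t) - spec$prob,
                           lower = 1e-12, upper = 1,
                           extendInt = "upX", tol = 1e-10)$root
      function() t0
    })
}

#' Validate a competing-risks dataset
#'
#' Checks a data frame of observed `(time, status)` pairs: equal-length
#' numeric columns, strictly positive times, integer statuses in 0..K
#' (0 = right-censored), no missing values. Violations are reported with
#' the offending row index.
#'
#' @param data data frame with columns `time` and `status`.
#' @param K number of risks; defaults to the maximum observed status.
#' @return the validated data frame, invisibly, with attribute `K`.
#' @export
validate_dataset <- function(data, K = NULL) {
  if (!all(c("time", "status") %in% names(data))) {
    stop("dataset must have columns 'time' and 'status'")
  }
  if (anyNA(data$time) || anyNA(data$status)) {
    stop("missing value at row ",
         which(is.na(data$time) | is.na(data$status))[1])
  }
  if (any(data$time <= 0)) {
    stop("nonpositive time at row ", which(data$time <= 0)[1])
  }
  if (any(data$status != round(data$status)) || any(data$status < 0)) {
    stop("status must be a nonnegative integer; offending row ",
         which(data$status != round(data$status) | data$status < 0)[1])
  }
  if (is.null(K)) K <- max(data$status, attr(data, "K") %||% 0L, 1L)
  if (any(data$status > K)) {
    stop("status above K = ", K, " at row ", which(data$status > K)[1])
  }
  attr(data, "K") <- as.integer(K)
  invisible(data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
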