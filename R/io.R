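#' Read and write model specifications as JSON
#'
#' Models are serialized as a JSON object with a `type` discriminator:
#' `"cr_rep"` carries `m`, `K`, `p`, `Q`, `L` (matrices row-major as arrays
#' of arrays); `"ph_rep"` carries `m`, `p`, `Q`; `"canonical_cr"` carries
#' `m`, `K`, `lambda`, `P`. Numbers are written at full double precision so
#' a write/read round trip is loss-free.
#'
#' @param path file path.
#' @param model a `ph_rep`, `cr_rep` or `canonical_cr`.
#' @return `read_model()` returns the model object; `write_model()` the
#'   path, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- if (inherits(model, "cr_rep")) {
    list(type = "cr_rep", m = model$m, K = model$K, p = model$p,
         Q = model$Q, L = model$L)
  } else if (inherits(model, "ph_rep")) {
    list(type = "ph_rep", m = model$m, p = model$p, Q = model$Q)
  } else if (inherits(model, "canonical_cr")) {
    list(type = "canonical_cr", m = model$m, K = model$K,
         lambda = model$lambda, P = model$P)
  } else stop("model must be a ph_rep, cr_rep or canonical_cr")
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type)) stop("model JSON is missing the 'type' field")
  switch(obj$type,
    cr_rep = cr_rep(obj$p, as_matrix(obj$Q, "Q"), as_matrix(obj$L, "L")),
    ph_rep = ph_rep(obj$p, as_matrix(obj$Q, "Q")),
    canonical_cr = canonical_cr(obj$lambda, as_matrix(obj$P, "P")),
    stop("unknown model type: ", obj$type))
}

as_matrix <- function(x, field) {
  if (is.null(x)) stop("model JSON is missing the '", field, "' field")
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Read and write competing-risks datasets as CSV
#'
#' The on-disk format is comma-separated text with a required header
#' `time,status`; `status` is 0 for right-censored records and j for
#' absorption in state m+j. Period decimal separator regardless of locale.
#' Reading validates every row (positive time, integer status in 0..K) and
#' reports the offending row on failure.
#'
#' @param data data frame with columns `time`, `status`.
#' @param path file path.
#' @param K number of risks; default: inferred as the maximum status.
#' @return `read_dataset()` returns the validated data frame with
#'   attribute `K`; `write_dataset()` the path, invisibly.
#' @export
write_dataset <- function(data, path) {
  validate_dataset(data)
  utils::write.csv(data[, c("time", "status")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, K = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- utils::read.csv(path)
  if (!all(c("time", "status") %in% names(data))) {
    stop("dataset must have a 'time,status' header; found: ",
         paste(names(data), collapse = ","))
  }
  out <- validate_dataset(data, K = K)
  attr(data, "K") <- attr(out, "K")
  data
}
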