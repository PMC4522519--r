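#' JSON serialization of states and instruments
#'
#' Complex matrices are stored as nested arrays of `[real, imag]` pairs
#' (row-major: `matrix[[i]][[j]] = [re, im]`), with full double precision so
#' the round-trip is exact.  States carry a `factor_dims` key recording their
#' tensor structure.
#'
#' @name serialization
NULL

.cmat_to_list <- function(m) {
  lapply(seq_len(nrow(m)), function(i)
    lapply(seq_len(ncol(m)), function(j) c(Re(m[i, j]), Im(m[i, j]))))
}

.cmat_from_list <- function(l) {
  d1 <- length(l); d2 <- length(l[[1]])
  m <- matrix(0 + 0i, d1, d2)
  for (i in seq_len(d1)) for (j in seq_len(d2)) {
    p <- as.numeric(l[[i]][[j]])
    m[i, j] <- complex(real = p[1], imaginary = p[2])
  }
  m
}

#' @rdname serialization
#' @param x a [qstate()].
#' @param path optional file path; when given the JSON is written there.
#' @return `qstate_to_json()`: a JSON string (invisibly, when writing to a
#'   file); `qstate_from_json()`: the reconstructed `qstate`.
#' @examples
#' s <- rand_qstate(2)
#' identical_to_s <- qstate_from_json(qstate_to_json(s))
#' @export
qstate_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "qstate"))
  obj <- list(matrix = .cmat_to_list(x$matrix),
              factor_dims = as.integer(x$dims))
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname serialization
#' @param json a JSON string, or a path to a JSON file.
#' @export
qstate_from_json <- function(json) {
  if (length(json) == 1 && !grepl("[{]", json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  qstate(.cmat_from_list(obj$matrix), dims = unlist(obj$factor_dims))
}

#' @rdname serialization
#' @param inst a `projective_observable`, `atomic_instrument`, `povm` or
#'   `dl_instrument`.
#' @export
instrument_to_json <- function(inst, path = NULL) {
  type <- class(inst)[1]
  ops <- switch(type,
    projective_observable = lapply(inst$projectors, .cmat_to_list),
    atomic_instrument = lapply(inst$kraus, .cmat_to_list),
    povm = lapply(inst$effects, .cmat_to_list),
    dl_instrument = lapply(inst$kraus,
                           function(ks) lapply(ks, .cmat_to_list)),
    stop("not a serializable instrument: ", type, call. = FALSE))
  obj <- list(type = type, labels = inst$labels, operators = ops)
  if (type == "projective_observable" && !is.null(inst$values))
    obj$values <- inst$values
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname serialization
#' @export
instrument_from_json <- function(json) {
  if (length(json) == 1 && !grepl("[{]", json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  labels <- unlist(obj$labels)
  type <- unlist(obj$type)
  switch(type,
    projective_observable = projective_observable(
      lapply(obj$operators, .cmat_from_list), labels = labels,
      values = if (!is.null(obj$values)) unlist(obj$values)),
    atomic_instrument = atomic_instrument(
      lapply(obj$operators, .cmat_from_list), labels = labels),
    povm = povm(lapply(obj$operators, .cmat_from_list), labels = labels),
    dl_instrument = dl_instrument(
      lapply(obj$operators, function(ks) lapply(ks, .cmat_from_list)),
      labels = labels),
    stop("unknown instrument type in JSON: ", type, call. = FALSE))
}

#' Write an outcome distribution as CSV
#'
#' @param dist an `outcome_distribution` (or anything coercible with
#'   [as.data.frame()] to label/probability rows).
#' @param path output file.
#' @return The data.frame written, invisibly.
#' @export
write_distribution_csv <- function(dist, path) {
  df <- as.data.frame(dist)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
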