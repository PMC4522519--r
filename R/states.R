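#' Pure states, density operators and unitaries
#'
#' The state algebra underlying the whole package: a mental state (of
#' sensation, of perception, or of the composite mind) is a density operator
#' -- a Hermitian, positive, trace-one complex matrix.  Pure states are the
#' rank-1 projectors; every density operator is a convex mixture of pure
#' states.  Composite sensation--perception states live on the tensor
#' product of the two factors and are reduced back to one factor with the
#' partial trace.
#'
#' @name states
NULL

## tolerances used throughout: 1e-12 for trace/Hermiticity checks,
## 1e-10 for positivity (double-precision accumulation over <= 11 steps)
.tol_herm <- 1e-12
.tol_pos <- 1e-10

#' Construct a pure state
#'
#' A pure state is a normalized complex coefficient vector.  Two colinear
#' vectors represent the same state; no canonical phase is enforced.
#'
#' @param coefficients complex (or numeric) vector of length d.
#' @param validate check normalization (default TRUE).
#' @return An object of class `pure_state`.
#' @examples
#' pure_state(c(1, 1) / sqrt(2))
#' @export
pure_state <- function(coefficients, validate = TRUE) {
  coefficients <- as.complex(coefficients)
  if (validate) {
    nrm2 <- sum(Mod(coefficients)^2)
    if (abs(nrm2 - 1) > 1e-12)
      stop("pure state coefficients must be normalized: |psi|^2 = ",
           format(nrm2), call. = FALSE)
  }
  structure(coefficients, class = "pure_state")
}

#' @export
print.pure_state <- function(x, ...) {
  cat("<pure_state> dim", length(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' Construct a density operator
#'
#' @param matrix d x d complex matrix: Hermitian, positive, trace one.
#' @param dims integer vector of tensor-factor dimensions whose product is d.
#'   Records the tensor structure H (x) K when present; factor 1 is always the
#'   sensation space H, factor 2 the perception space K.
#' @param validate verify the density-operator invariants (default TRUE).
#'   Skipping validation is for internal measurement chains only.
#' @return An object of class `qstate`.
#' @examples
#' qstate(diag(2) / 2)                      # maximally mixed qubit
#' qstate(diag(4) / 4, dims = c(2, 2))      # product structure recorded
#' @export
qstate <- function(matrix, dims = nrow(matrix), validate = TRUE) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "complex"
  dims <- as.integer(dims)
  if (any(dims < 1L)) stop("factor dims must be positive integers", call. = FALSE)
  if (prod(dims) != nrow(matrix) || nrow(matrix) != ncol(matrix))
    stop("dims must be a factorization of the (square) matrix dimension",
         call. = FALSE)
  x <- structure(list(matrix = matrix, dims = dims), class = "qstate")
  if (validate) validate_qstate(x)
  x
}

#' Validate the density-operator invariants
#'
#' Checks Hermiticity (1e-12), positivity (smallest eigenvalue >= -1e-10) and
#' unit trace (1e-12).  Called by [qstate()] unless `validate = FALSE`.
#'
#' @param x a `qstate`.
#' @return `x`, invisibly; errors otherwise.
#' @export
validate_qstate <- function(x) {
  m <- x$matrix
  if (max(Mod(m - Conj(t(m)))) > .tol_herm)
    stop("density operator is not Hermitian within 1e-12", call. = FALSE)
  tr <- Re(sum(diag(m)))
  if (abs(tr - 1) > .tol_herm)
    stop("density operator must have trace 1, got ", format(tr), call. = FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -.tol_pos)
    stop("density operator is not positive: min eigenvalue ",
         format(min(ev)), call. = FALSE)
  invisible(x)
}

#' @export
print.qstate <- function(x, digits = 4, ...) {
  cat("<qstate> dim", nrow(x$matrix))
  if (length(x$dims) > 1) cat(" = ", paste(x$dims, collapse = " x "), sep = "")
  pd <- purity_defect(x)
  cat(if (pd > -1e-12) "  (pure)" else sprintf("  purity defect %.4g", pd), "\n")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Represent a pure state as its density operator
#'
#' Returns the rank-1 projector |psi><psi|, which is idempotent and has
#' purity defect zero.
#'
#' @param psi a [pure_state()] or coefficient vector.
#' @param dims optional factor dimensions (see [qstate()]).
#' @return A `qstate`.
#' @examples
#' pure_to_density(pure_state(c(1, 0)))
#' @export
pure_to_density <- function(psi, dims = NULL) {
  if (!inherits(psi, "pure_state")) psi <- pure_state(psi)
  v <- as.complex(unclass(psi))
  m <- outer(v, Conj(v))
  qstate(m, dims = if (is.null(dims)) length(v) else dims, validate = FALSE)
}

#' Degree of purity of a state
#'
#' The purity defect Tr\[rho^2 - rho\] is 0 exactly for pure states (rank-1
#' projectors, which are idempotent) and strictly negative for mixed states;
#' it is bounded below by 1/d - 1.
#'
#' @param rho a `qstate`.
#' @return A real number in \[1/d - 1, 0\].
#' @examples
#' purity_defect(qstate(diag(2) / 2))   # -0.5
#' @export
purity_defect <- function(rho) {
  stopifnot(inherits(rho, "qstate"))
  m <- rho$matrix
  Re(sum(diag(m %*% m)) - sum(diag(m)))
}

#' Is a state pure?
#'
#' @param rho a `qstate`.
#' @param tol tolerance on the purity defect.
#' @return TRUE if Tr\[rho^2 - rho\] is 0 within `tol`.
#' @export
is_pure <- function(rho, tol = 1e-12) purity_defect(rho) > -tol

#' Mix states
#'
#' The convex combination sum_i p_i rho_i.  Any density operator arises this
#' way from pure states, though the decomposition is not unique.
#'
#' @param states list of `qstate`s of equal dimension.
#' @param weights nonnegative weights summing to 1 (within 1e-12).
#' @return The mixture as a `qstate`.
#' @examples
#' mix_states(list(pure_to_density(c(1, 0)), pure_to_density(c(0, 1))),
#'            c(0.5, 0.5))
#' @export
mix_states <- function(states, weights) {
  stopifnot(is.list(states), length(states) == length(weights))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  d <- nrow(states[[1]]$matrix)
  m <- matrix(0 + 0i, d, d)
  for (i in seq_along(states)) {
    if (nrow(states[[i]]$matrix) != d)
      stop("all states must have the same dimension", call. = FALSE)
    m <- m + weights[i] * states[[i]]$matrix
  }
  qstate(m, dims = states[[1]]$dims, validate = FALSE)
}

#' Tensor product of states
#'
#' Kronecker product of the matrices; the factor dimensions are concatenated
#' so the composite remembers its tensor structure.  By package convention
#' the sensation space H is always the first factor and the perception space
#' K the second.
#'
#' @param a,b `qstate`s.
#' @return A `qstate` on the composite space.
#' @examples
#' qtensor(qstate(diag(2) / 2), pure_to_density(c(1, 0)))
#' @export
qtensor <- function(a, b) {
  stopifnot(inherits(a, "qstate"), inherits(b, "qstate"))
  qstate(kronecker(a$matrix, b$matrix), dims = c(a$dims, b$dims),
         validate = FALSE)
}

#' Partial trace
#'
#' Reduces a composite state to the state of one tensor factor:
#' `partial_trace(R, keep = 2)` on a sensation--perception state R gives the
#' perception state Tr_H R.
#'
#' @param rho a `qstate` whose `dims` record at least two factors.
#' @param keep index of the factor to keep.
#' @return The reduced `qstate` on the kept factor.
#' @examples
#' R <- qtensor(qstate(diag(2) / 2), pure_to_density(c(1, 0)))
#' partial_trace(R, keep = 1)
#' @export
partial_trace <- function(rho, keep) {
  stopifnot(inherits(rho, "qstate"))
  dims <- rho$dims
  if (length(dims) < 2)
    stop("partial_trace requires recorded tensor structure: ",
         "construct the state with dims = c(d_H, d_K, ...)", call. = FALSE)
  keep <- as.integer(keep)
  if (length(keep) != 1 || keep < 1 || keep > length(dims))
    stop("keep must be a single factor index in 1..", length(dims),
         call. = FALSE)
  out <- .ptrace(rho$matrix, dims, keep)
  qstate(out, dims = dims[keep], validate = FALSE)
}

## reshape-based partial trace over all factors except `keep`
.ptrace <- function(m, dims, keep) {
  n <- length(dims)
  ## index order in the matrix is row = (i_1 ... i_n) with i_1 slowest
  ## (kronecker convention); as an array, dim = rev(dims) twice, fastest first
  a <- array(m, dim = c(rev(dims), rev(dims)))
  ## array slot of factor k (row side) is n - k + 1; column side adds n
  slot <- n - keep + 1L
  d <- dims[keep]
  perm <- c(slot, slot + n, setdiff(seq_len(2L * n), c(slot, slot + n)))
  a <- aperm(a, perm)
  dim(a) <- c(d, d, prod(dims)^2 / d^2)
  rest <- prod(dims) / d
  ## keep only diagonal blocks of the traced part: entries where the traced
  ## multi-indices agree on row and column side
  sel <- seq(1L, rest * rest, by = rest + 1L)
  out <- apply(a[, , sel, drop = FALSE], c(1, 2), sum)
  out
}

#' Construct a unitary operator
#'
#' @param matrix d x d complex matrix with U U* = I within 1e-10.
#' @param validate check unitarity (default TRUE).
#' @return An object of class `unitary`.
#' @examples
#' unitary(diag(2))
#' @export
unitary <- function(matrix, validate = TRUE) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "complex"
  if (validate) {
    d <- nrow(matrix)
    if (d != ncol(matrix) ||
        max(Mod(matrix %*% Conj(t(matrix)) - diag(d))) > 1e-10)
      stop("matrix is not unitary within 1e-10", call. = FALSE)
  }
  structure(list(matrix = matrix), class = "unitary")
}

#' @export
print.unitary <- function(x, digits = 4, ...) {
  cat("<unitary> dim", nrow(x$matrix), "\n")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Unitary conjugation of a state
#'
#' The evolution rho -> U rho U*: spectrum, trace and purity are preserved.
#'
#' @param rho a `qstate`.
#' @param U a [unitary()] of matching dimension.
#' @return The evolved `qstate`.
#' @examples
#' H <- unitary(matrix(c(1, 1, 1, -1), 2) / sqrt(2))
#' evolve(pure_to_density(c(1, 0)), H)
#' @export
evolve <- function(rho, U) {
  stopifnot(inherits(rho, "qstate"), inherits(U, "unitary"))
  if (nrow(U$matrix) != nrow(rho$matrix))
    stop("dimension mismatch: state is ", nrow(rho$matrix),
         ", unitary is ", nrow(U$matrix), call. = FALSE)
  qstate(U$matrix %*% rho$matrix %*% Conj(t(U$matrix)),
         dims = rho$dims, validate = FALSE)
}

#' Random states and unitaries
#'
#' Seeded generators used by the property-style tests and the multistart
#' fitter: Haar-random unitaries via QR of a complex Ginibre matrix; random
#' density operators as normalized G G* with G Ginibre (full rank almost
#' surely), or Haar-random pure states.
#'
#' @param d dimension.
#' @param pure draw a pure state instead of a full-rank mixed state?
#' @param dims optional factor dimensions for the returned state.
#' @return `rand_qstate()` a `qstate`; `rand_unitary()` a `unitary`.
#' @examples
#' set.seed(1)
#' rand_qstate(2)
#' rand_unitary(4)
#' @export
rand_qstate <- function(d, pure = FALSE, dims = d) {
  if (pure) {
    v <- stats::rnorm(d) + 1i * stats::rnorm(d)
    v <- v / sqrt(sum(Mod(v)^2))
    return(pure_to_density(pure_state(v, validate = FALSE), dims = dims))
  }
  g <- matrix(stats::rnorm(d * d) + 1i * stats::rnorm(d * d), d, d)
  m <- g %*% Conj(t(g))
  qstate(m / Re(sum(diag(m))), dims = dims, validate = FALSE)
}

#' @rdname rand_qstate
#' @export
rand_unitary <- function(d) {
  g <- matrix(stats::rnorm(d * d) + 1i * stats::rnorm(d * d), d, d)
  qr_ <- qr(g)
  q <- qr.Q(qr_)
  r <- qr.R(qr_)
  ## fix the phase ambiguity so the distribution is Haar
  q <- q %*% diag(diag(r) / Mod(diag(r)), d)
  unitary(q, validate = FALSE)
}
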