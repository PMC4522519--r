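#' Indirect measurement of a sensation state through a perception state
#'
#' Sensation states are not open to conscious introspection, so they cannot
#' be measured directly.  Instead the sensation state rho (on H) and the
#' perception state sigma (on K) interact unitarily,
#' `R_out = U (rho (x) sigma) U*`, and the conscious perception is a
#' projective measurement `(P_i)` on the perception factor alone.  On the
#' sensation factor this induces an unsharp POVM
#' `M_i = Tr_K[(I (x) sigma) U* (I (x) P_i) U]` whose effects are in general
#' not projectors: sensation subspaces leading to different perceptions may
#' overlap, which is the signature of bistable perception.
#'
#' @name indirect
NULL

#' Define an indirect-measurement scheme
#'
#' @param interaction a [unitary()] on the composite space H (x) K (dimension
#'   `d_H * d_K`); the sensation space H is always the first tensor factor.
#' @param perception_obs a [projective_observable()] on K.
#' @param d_H,d_K factor dimensions (default: `d_K` from the observable,
#'   `d_H` inferred from the interaction).
#' @return An object of class `indirect_scheme`.
#' @examples
#' sch <- indirect_scheme(controlled_rotation(c(-pi / 4, pi / 4)),
#'                        basis_observable(2, labels = c("L", "R")))
#' @export
indirect_scheme <- function(interaction, perception_obs,
                            d_K = perception_obs$dim,
                            d_H = nrow(interaction$matrix) / d_K) {
  stopifnot(inherits(interaction, "unitary"),
            inherits(perception_obs, "projective_observable"))
  d_H <- as.integer(d_H); d_K <- as.integer(d_K)
  if (d_H * d_K != nrow(interaction$matrix))
    stop("interaction must act on a space of dimension d_H * d_K",
         call. = FALSE)
  if (perception_obs$dim != d_K)
    stop("perception observable must act on the d_K-dimensional factor",
         call. = FALSE)
  structure(list(d_H = d_H, d_K = d_K, interaction = interaction,
                 perception_obs = perception_obs),
            class = "indirect_scheme")
}

#' @export
print.indirect_scheme <- function(x, ...) {
  cat("<indirect_scheme> d_H =", x$d_H, ", d_K =", x$d_K, ", outcomes:",
      paste(x$perception_obs$labels, collapse = ", "), "\n")
  invisible(x)
}

## lifted projectors I (x) P_i on the composite space
.lifted_projectors <- function(scheme) {
  lapply(scheme$perception_obs$projectors,
         function(p) kronecker(diag(scheme$d_H), p))
}

#' Run one indirect measurement
#'
#' Evolves the product state `rho (x) sigma` by the interaction unitary and
#' projectively measures the perception factor.  For each outcome `i` it
#' returns the probability `Tr[R_out (I (x) P_i)]`, the post-measurement
#' perception state `sigma_i = Tr_H[R_out (I (x) P_i)] / p_i` and the
#' post-measurement sensation state (the feedback of the conscious
#' perception) `rho_i = Tr_K[R_out (I (x) P_i)] / p_i`.
#'
#' @param scheme an [indirect_scheme()].
#' @param rho sensation `qstate` on H.
#' @param sigma perception `qstate` on K.
#' @return A list of class `indirect_result`: one element per outcome with
#'   fields `label`, `probability`, `post_sensation`, `post_perception`
#'   (post-states are NULL when the probability is below 1e-14).
#' @export
run_indirect <- function(scheme, rho, sigma) {
  stopifnot(inherits(scheme, "indirect_scheme"),
            inherits(rho, "qstate"), inherits(sigma, "qstate"))
  if (nrow(rho$matrix) != scheme$d_H || nrow(sigma$matrix) != scheme$d_K)
    stop("state dimensions must match the scheme (d_H = ", scheme$d_H,
         ", d_K = ", scheme$d_K, ")", call. = FALSE)
  U <- scheme$interaction$matrix
  R_out <- U %*% kronecker(rho$matrix, sigma$matrix) %*% Conj(t(U))
  dims <- c(scheme$d_H, scheme$d_K)
  out <- lapply(seq_along(scheme$perception_obs$labels), function(i) {
    lab <- scheme$perception_obs$labels[i]
    P <- kronecker(diag(scheme$d_H), scheme$perception_obs$projectors[[i]])
    X <- R_out %*% P
    p <- Re(sum(diag(X)))
    if (p > 1e-14) {
      ## sandwich P X P keeps the reduced blocks Hermitian
      Xs <- P %*% X
      list(label = lab, probability = p,
           post_sensation = qstate(.ptrace(Xs, dims, 1L) / p, dims = dims[1],
                                   validate = FALSE),
           post_perception = qstate(.ptrace(Xs, dims, 2L) / p, dims = dims[2],
                                    validate = FALSE))
    } else {
      list(label = lab, probability = max(p, 0),
           post_sensation = NULL, post_perception = NULL)
    }
  })
  structure(out, class = "indirect_result",
            labels = scheme$perception_obs$labels)
}

#' @export
print.indirect_result <- function(x, digits = 4, ...) {
  cat("<indirect_result>\n")
  p <- vapply(x, `[[`, numeric(1), "probability")
  names(p) <- vapply(x, `[[`, character(1), "label")
  print(round(p, digits))
  invisible(x)
}

#' Probabilities of an indirect result
#'
#' @param x an `indirect_result`.
#' @return Named numeric vector of outcome probabilities.
#' @export
outcome_probabilities <- function(x) {
  stopifnot(inherits(x, "indirect_result"))
  stats::setNames(vapply(x, `[[`, numeric(1), "probability"),
                  vapply(x, `[[`, character(1), "label"))
}

#' Reduced perception state after the interaction
#'
#' `sigma_out = Tr_H[U (rho (x) sigma) U*]`: the perception factor of the
#' evolved composite, before any outcome is registered.  Born probabilities
#' on `sigma_out` coincide with the composite-trace probabilities of
#' [run_indirect()].
#'
#' @inheritParams run_indirect
#' @return A `qstate` on K.
#' @export
reduced_perception_state <- function(scheme, rho, sigma) {
  stopifnot(inherits(scheme, "indirect_scheme"))
  U <- scheme$interaction$matrix
  R_out <- U %*% kronecker(rho$matrix, sigma$matrix) %*% Conj(t(U))
  qstate(.ptrace(R_out, c(scheme$d_H, scheme$d_K), 2L),
         dims = scheme$d_K, validate = FALSE)
}

#' POVM induced on the sensation space
#'
#' The unsharp observable through which the perception measurement acts on
#' the sensation state:
#' `M_i = Tr_K[(I (x) sigma) U* (I (x) P_i) U]`, equivalently (by the cyclic
#' property of the trace over K)
#' `M_i = Tr_K[U* (I (x) P_i) U (I (x) sigma)]`.  The effects are positive
#' Hermitian and sum to the identity, and `Tr(rho M_i)` reproduces the
#' [run_indirect()] probabilities for every sensation state `rho`.
#'
#' @param scheme an [indirect_scheme()].
#' @param sigma perception `qstate` on K.
#' @param form which of the two equivalent trace orderings to evaluate
#'   (they agree entry-wise; both are exposed for cross-checking).
#' @return A [povm()] on H.
#' @export
induced_povm <- function(scheme, sigma, form = c("sigma_first", "sigma_last")) {
  stopifnot(inherits(scheme, "indirect_scheme"), inherits(sigma, "qstate"))
  form <- match.arg(form)
  U <- scheme$interaction$matrix
  Ud <- Conj(t(U))
  Isig <- kronecker(diag(scheme$d_H), sigma$matrix)
  dims <- c(scheme$d_H, scheme$d_K)
  effects <- lapply(scheme$perception_obs$projectors, function(p) {
    IP <- kronecker(diag(scheme$d_H), p)
    m <- if (form == "sigma_first") Isig %*% Ud %*% IP %*% U
         else Ud %*% IP %*% U %*% Isig
    e <- .ptrace(m, dims, 1L)
    (e + Conj(t(e))) / 2   # symmetrize away rounding in the trace
  })
  povm(effects, labels = scheme$perception_obs$labels, validate = FALSE)
}

## ---- interaction unitaries -------------------------------------------------

#' Controlled-rotation sensation--perception interaction
#'
#' The default interaction family: the sensation basis state `|k>` steers a
#' real rotation of the (two-dimensional) perception plane by angle `mu_k`,
#' `U = sum_k |k><k| (x) R(mu_k)`.  The difference of the angles sets how
#' much information about the sensation leaks into the perception factor:
#' `mu_0 = mu_1` carries none (the induced POVM is trivial), while
#' `mu = c(-pi/4, pi/4)` acting on the neutral perception state
#' `(|L> + |R>)/sqrt(2)` is a sharp measurement of the sensation basis.
#'
#' @param mu numeric vector of rotation angles (radians), one per sensation
#'   basis state; its length is d_H.
#' @return A [unitary()] on the composite space of dimension `2 * length(mu)`.
#' @export
controlled_rotation <- function(mu) {
  d_H <- length(mu)
  blocks <- lapply(mu, rotation2)
  U <- matrix(0 + 0i, 2 * d_H, 2 * d_H)
  for (k in seq_len(d_H)) {
    idx <- (2 * k - 1):(2 * k)
    U[idx, idx] <- blocks[[k]]
  }
  unitary(U, validate = FALSE)
}

#' Real rotation of a two-dimensional plane
#'
#' @param angle rotation angle in radians.
#' @return A 2 x 2 [unitary()] matrix (returned as a plain complex matrix).
#' @export
rotation2 <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2) + 0i
}

#' Generic unitary from a Hermitian generator
#'
#' `U = exp(i H)` with H the Hermitian matrix parameterized by a real vector
#' of length d^2: first the d diagonal entries, then, column-major over the
#' upper triangle, the real and imaginary parts of the off-diagonal entries.
#' Computed by spectral decomposition of H.
#'
#' @param params real vector of length d^2.
#' @param d dimension.
#' @return A [unitary()] on a d-dimensional space.
#' @export
hermitian_unitary <- function(params, d) {
  if (length(params) != d * d)
    stop("params must have length d^2 = ", d * d, call. = FALSE)
  H <- matrix(0 + 0i, d, d)
  diag(H) <- params[seq_len(d)]
  k <- d
  for (j in seq_len(d)) for (i in seq_len(d)) if (i < j) {
    H[i, j] <- params[k + 1] + 1i * params[k + 2]
    H[j, i] <- Conj(H[i, j])
    k <- k + 2
  }
  e <- eigen(H, symmetric = TRUE)
  U <- e$vectors %*% diag(exp(1i * e$values), d) %*% Conj(t(e$vectors))
  unitary(U, validate = FALSE)
}
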