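#' Quantum instruments, apparatuses and POVMs
#'
#' A mental apparatus is a set of outcome probabilities together with the
#' back-action each conscious outcome exerts on the state.  Three
#' representations are provided, in increasing generality:
#'
#' * [projective_observable()] -- von Neumann--Lueders measurements: mutually
#'   orthogonal projectors `P_a` summing to the identity; probability
#'   `Tr(P_a rho)`, post-state `P_a rho P_a / Tr(P_a rho P_a)`.
#' * [atomic_instrument()] -- one contraction operator `Q_a` per outcome with
#'   `sum Q_a* Q_a = I`; probability `Tr(Q_a* Q_a rho)`, post-state
#'   `Q_a rho Q_a* / p`.  Pure states stay pure.
#' * [dl_instrument()] -- Davies--Lewis instruments: one positive
#'   superoperator `E(a)` per outcome, trace-preserving in total, stored as a
#'   list of Kraus components per outcome.  Post-states of pure states are in
#'   general mixed.
#'
#' All three induce a [povm()] via [as_povm()], and all are measured with the
#' common generic [measure()].
#'
#' @name instruments
NULL

.chk_labels <- function(labels, n) {
  if (is.null(labels)) labels <- as.character(seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels) || n == 0)
    stop("outcome labels must be distinct and match the operator count",
         call. = FALSE)
  labels
}

.as_cmat <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "complex"
  m
}

#' Projective (von Neumann--Lueders) observable
#'
#' @param projectors list of d x d orthogonal projectors, pairwise orthogonal
#'   and summing to the identity (checked to 1e-10).
#' @param labels character outcome labels (default "1", "2", ...).
#' @param values optional numeric eigenvalues attached to the labels; the
#'   labels themselves carry the meaning of the measurement results.
#' @param validate check the projector family (default TRUE).
#' @return An object of class `projective_observable`.
#' @examples
#' basis_observable(2, labels = c("L", "R"))
#' @export
projective_observable <- function(projectors, labels = NULL, values = NULL,
                                  validate = TRUE) {
  projectors <- lapply(projectors, .as_cmat)
  labels <- .chk_labels(labels, length(projectors))
  d <- nrow(projectors[[1]])
  if (validate) {
    tot <- matrix(0 + 0i, d, d)
    for (i in seq_along(projectors)) {
      p <- projectors[[i]]
      if (max(Mod(p %*% p - p)) > 1e-10 || max(Mod(p - Conj(t(p)))) > 1e-10)
        stop("projector ", labels[i], " is not a Hermitian idempotent",
             call. = FALSE)
      for (j in seq_along(projectors)) if (j > i &&
        max(Mod(p %*% projectors[[j]])) > 1e-10)
        stop("projectors ", labels[i], " and ", labels[j],
             " are not orthogonal", call. = FALSE)
      tot <- tot + p
    }
    if (max(Mod(tot - diag(d))) > 1e-10)
      stop("projectors must sum to the identity", call. = FALSE)
  }
  if (!is.null(values) && length(values) != length(labels))
    stop("values must match labels", call. = FALSE)
  structure(list(projectors = stats::setNames(projectors, labels),
                 labels = labels, values = values, dim = d),
            class = "projective_observable")
}

#' Basis observable on a d-dimensional space
#'
#' Convenience constructor: the rank-1 projectors onto the computational
#' basis.  With `labels = c("L", "R")` on d = 2 this is the perception
#' observable used throughout the rotation protocol.
#'
#' @param d dimension.
#' @param labels outcome labels (default "1".."d").
#' @param values optional numeric values.
#' @return A `projective_observable`.
#' @export
basis_observable <- function(d, labels = NULL, values = NULL) {
  projs <- lapply(seq_len(d), function(i) {
    p <- matrix(0 + 0i, d, d); p[i, i] <- 1 + 0i; p
  })
  projective_observable(projs, labels = labels, values = values,
                        validate = FALSE)
}

#' Atomic instrument
#'
#' @param kraus list of d x d contraction operators Q_a, one per outcome,
#'   with `sum Q_a* Q_a = I` within 1e-10.
#' @param labels character outcome labels.
#' @param validate check the normalization condition (default TRUE).
#' @return An object of class `atomic_instrument`.
#' @examples
#' ## a projective observable is the special case Q_a = P_a
#' P <- basis_observable(2)
#' atomic_instrument(P$projectors, labels = P$labels)
#' @export
atomic_instrument <- function(kraus, labels = NULL, validate = TRUE) {
  kraus <- lapply(kraus, .as_cmat)
  labels <- .chk_labels(labels, length(kraus))
  d <- nrow(kraus[[1]])
  if (validate) {
    tot <- matrix(0 + 0i, d, d)
    for (q in kraus) tot <- tot + Conj(t(q)) %*% q
    if (max(Mod(tot - diag(d))) > 1e-10)
      stop("Kraus operators must satisfy sum Q*Q = I within 1e-10",
           call. = FALSE)
  }
  structure(list(kraus = stats::setNames(kraus, labels), labels = labels,
                 dim = d),
            class = "atomic_instrument")
}

#' Positive operator valued measure
#'
#' @param effects list of positive Hermitian d x d operators summing to the
#'   identity within 1e-10.
#' @param labels character outcome labels.
#' @param validate check positivity and completeness (default TRUE).
#' @return An object of class `povm`.
#' @export
povm <- function(effects, labels = NULL, validate = TRUE) {
  effects <- lapply(effects, .as_cmat)
  labels <- .chk_labels(labels, length(effects))
  d <- nrow(effects[[1]])
  if (validate) {
    tot <- matrix(0 + 0i, d, d)
    for (i in seq_along(effects)) {
      e <- effects[[i]]
      if (max(Mod(e - Conj(t(e)))) > 1e-10)
        stop("effect ", labels[i], " is not Hermitian", call. = FALSE)
      ev <- eigen(e, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-10)
        stop("effect ", labels[i], " is not positive", call. = FALSE)
      tot <- tot + e
    }
    if (max(Mod(tot - diag(d))) > 1e-10)
      stop("effects must sum to the identity within 1e-10", call. = FALSE)
  }
  structure(list(effects = stats::setNames(effects, labels), labels = labels,
                 dim = d),
            class = "povm")
}

#' Davies--Lewis instrument
#'
#' Each outcome's state transformer E(a) is stored as a finite list of Kraus
#' components, `E(a) rho = sum_k Q_ak rho Q_ak*`: positivity holds by
#' construction and the atomic case is the one-component special case.  The
#' total map E(O) must preserve the trace, i.e.
#' `sum_{a,k} Q_ak* Q_ak = I` within 1e-10.
#'
#' @param kraus list (one entry per outcome) of lists of d x d matrices.
#' @param labels character outcome labels.
#' @param validate check total trace preservation (default TRUE).
#' @return An object of class `dl_instrument`.
#' @examples
#' ## a depolarizing-style outcome with two Kraus components
#' dl_instrument(list(L = list(diag(2) / sqrt(2)),
#'                    R = list(matrix(c(0, 1, 0, 0), 2) / sqrt(2),
#'                             matrix(c(0, 0, 1, 0), 2) / sqrt(2))))
#' @export
dl_instrument <- function(kraus, labels = NULL, validate = TRUE) {
  if (is.null(labels)) labels <- names(kraus)
  kraus <- lapply(kraus, function(ks) lapply(ks, .as_cmat))
  labels <- .chk_labels(labels, length(kraus))
  d <- nrow(kraus[[1]][[1]])
  if (validate) {
    tot <- matrix(0 + 0i, d, d)
    for (ks in kraus) for (q in ks) tot <- tot + Conj(t(q)) %*% q
    if (max(Mod(tot - diag(d))) > 1e-10)
      stop("total map must be trace preserving: sum Q*Q = I within 1e-10",
           call. = FALSE)
  }
  structure(list(kraus = stats::setNames(kraus, labels), labels = labels,
                 dim = d),
            class = "dl_instrument")
}

#' Promote an atomic instrument to a Davies--Lewis instrument
#'
#' @param inst an `atomic_instrument`.
#' @return A `dl_instrument` with one Kraus component per outcome,
#'   reproducing the atomic measurement exactly.
#' @export
as_dl_instrument <- function(inst) {
  stopifnot(inherits(inst, "atomic_instrument"))
  dl_instrument(lapply(inst$kraus, list), labels = inst$labels,
                validate = FALSE)
}

#' @export
print.projective_observable <- function(x, ...) {
  cat("<projective_observable> dim", x$dim, " outcomes:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}
#' @export
print.atomic_instrument <- function(x, ...) {
  cat("<atomic_instrument> dim", x$dim, " outcomes:",
      paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}
#' @export
print.povm <- function(x, ...) {
  cat("<povm> dim", x$dim, " outcomes:", paste(x$labels, collapse = ", "),
      "\n")
  invisible(x)
}
#' @export
print.dl_instrument <- function(x, ...) {
  cat("<dl_instrument> dim", x$dim, " outcomes:",
      paste(x$labels, collapse = ", "),
      " components:", paste(vapply(x$kraus, length, 1L), collapse = ","),
      "\n")
  invisible(x)
}

## ---- measurement ----------------------------------------------------------

.outcome_distribution <- function(labels, probabilities, post_states) {
  probabilities <- pmax(Re(probabilities), 0)
  structure(list(labels = labels,
                 probabilities = stats::setNames(probabilities, labels),
                 post_states = stats::setNames(post_states, labels)),
            class = "outcome_distribution")
}

#' @export
print.outcome_distribution <- function(x, digits = 4, ...) {
  cat("<outcome_distribution>\n")
  print(round(x$probabilities, digits))
  invisible(x)
}

#' @export
as.data.frame.outcome_distribution <- function(x, ...) {
  data.frame(label = x$labels, probability = unname(x$probabilities),
             stringsAsFactors = FALSE)
}

#' Measure a state with an apparatus
#'
#' Applies a measurement to a density operator and returns the outcome
#' probabilities together with the conditional post-measurement states.
#' Outcomes with probability below 1e-14 carry no post-state (the
#' conditional state is undefined; see [post_state()]).
#'
#' @param rho a [qstate()].
#' @param apparatus a `projective_observable`, `atomic_instrument`,
#'   `dl_instrument` or (probabilities only) a `povm`.
#' @param ... unused.
#' @return An `outcome_distribution`: labels, probabilities (summing to 1)
#'   and post-states.
#' @examples
#' measure(pure_to_density(c(1, 1) / sqrt(2)), basis_observable(2))
#' @export
measure <- function(rho, apparatus, ...) UseMethod("measure", apparatus)

#' @export
measure.projective_observable <- function(rho, apparatus, ...) {
  measure(rho, atomic_instrument(apparatus$projectors,
                                 labels = apparatus$labels,
                                 validate = FALSE))
}

#' @export
measure.atomic_instrument <- function(rho, apparatus, ...) {
  stopifnot(inherits(rho, "qstate"))
  if (nrow(rho$matrix) != apparatus$dim)
    stop("dimension mismatch between state and instrument", call. = FALSE)
  out <- lapply(apparatus$kraus, function(q) {
    m <- q %*% rho$matrix %*% Conj(t(q))
    p <- Re(sum(diag(m)))
    list(p = p,
         post = if (p > 1e-14) qstate(m / p, dims = rho$dims,
                                      validate = FALSE))
  })
  .outcome_distribution(apparatus$labels,
                        vapply(out, `[[`, numeric(1), "p"),
                        lapply(out, `[[`, "post"))
}

#' @export
measure.dl_instrument <- function(rho, apparatus, ...) {
  stopifnot(inherits(rho, "qstate"))
  if (nrow(rho$matrix) != apparatus$dim)
    stop("dimension mismatch between state and instrument", call. = FALSE)
  out <- lapply(apparatus$labels, function(a) {
    m <- dl_apply(apparatus, rho, labels = a)
    p <- Re(sum(diag(m)))
    list(p = p,
         post = if (p > 1e-14) qstate(m / p, dims = rho$dims,
                                      validate = FALSE))
  })
  .outcome_distribution(apparatus$labels,
                        vapply(out, `[[`, numeric(1), "p"),
                        lapply(out, `[[`, "post"))
}

#' @export
measure.povm <- function(rho, apparatus, ...) {
  stopifnot(inherits(rho, "qstate"))
  p <- vapply(apparatus$effects,
              function(e) Re(sum(diag(e %*% rho$matrix))), numeric(1))
  .outcome_distribution(apparatus$labels, p,
                        vector("list", length(apparatus$labels)))
}

#' Conditional post-measurement state
#'
#' @param dist an `outcome_distribution`.
#' @param label the realized outcome.
#' @return The post-state `qstate`.  Requesting the post-state of a
#'   zero-probability outcome is an error: conditioning on an event of
#'   probability zero is undefined.
#' @export
post_state <- function(dist, label) {
  stopifnot(inherits(dist, "outcome_distribution"))
  if (!label %in% dist$labels) stop("unknown outcome label: ", label,
                                    call. = FALSE)
  st <- dist$post_states[[label]]
  if (is.null(st))
    stop("post-state of outcome '", label,
         "' is undefined: outcome probability is (numerically) zero",
         call. = FALSE)
  st
}

#' Induced POVM of an apparatus
#'
#' Every instrument induces a POVM reproducing its outcome probabilities:
#' `M_a = Q_a* Q_a` for atomic instruments, and for a Davies--Lewis
#' instrument the adjoint superoperator applied to the identity,
#' `M_a = E*(a) I`, so that `Tr(M_a rho) = Tr(E(a) rho)` for every state.
#'
#' @param x an apparatus.
#' @param ... unused.
#' @return A [povm()].
#' @export
as_povm <- function(x, ...) UseMethod("as_povm")

#' @export
as_povm.projective_observable <- function(x, ...) {
  povm(x$projectors, labels = x$labels, validate = FALSE)
}

#' @export
as_povm.atomic_instrument <- function(x, ...) {
  povm(lapply(x$kraus, function(q) Conj(t(q)) %*% q),
       labels = x$labels, validate = FALSE)
}

#' @export
as_povm.dl_instrument <- function(x, ...) {
  ## adjoint of rho -> sum Q rho Q* applied to I is sum Q* Q
  povm(lapply(x$kraus, function(ks) {
    Reduce(`+`, lapply(ks, function(q) Conj(t(q)) %*% q))
  }), labels = x$labels, validate = FALSE)
}

#' @export
as_povm.povm <- function(x, ...) x

#' Apply a Davies--Lewis map over a subset of outcomes
#'
#' Computes the unnormalized operator `E(Gamma) rho = sum_{a in Gamma}
#' E(a) rho`.  For `Gamma` the full outcome set the result has trace
#' `Tr rho` (trace preservation); the empty subset gives the zero operator.
#' The map is additive over disjoint subsets by construction.
#'
#' @param inst a `dl_instrument`.
#' @param rho a `qstate`.
#' @param labels subset of outcome labels (default: all).
#' @return An unnormalized d x d complex matrix (not a `qstate`).
#' @export
dl_apply <- function(inst, rho, labels = inst$labels) {
  stopifnot(inherits(inst, "dl_instrument"), inherits(rho, "qstate"))
  labels <- as.character(labels)
  if (!all(labels %in% inst$labels))
    stop("unknown outcome label(s): ",
         paste(setdiff(labels, inst$labels), collapse = ", "), call. = FALSE)
  d <- inst$dim
  out <- matrix(0 + 0i, d, d)
  for (a in labels) for (q in inst$kraus[[a]])
    out <- out + q %*% rho$matrix %*% Conj(t(q))
  out
}

#' Sequential composition of two apparatuses
#'
#' Measuring first with `first` and then with `second` defines a composite
#' apparatus whose outcomes are ordered pairs, with the chain rule
#' `p((a, b) | rho) = p(b | rho_a) p(a | rho)` -- the quantum generalization
#' of the Bayes rule -- and pair post-states `(rho_a)_b`.
#'
#' @param rho initial `qstate`.
#' @param first,second apparatuses accepted by [measure()] (not bare POVMs:
#'   post-states are needed for the chain).
#' @return An `outcome_distribution` over pair labels `"a.b"`, with a
#'   `pairs` attribute holding the label matrix.
#' @export
compose_sequential <- function(rho, first, second) {
  d1 <- measure(rho, first)
  labs <- character(0); probs <- numeric(0); posts <- list()
  pairs <- NULL
  for (a in d1$labels) {
    pa <- d1$probabilities[[a]]
    if (pa <= 1e-14) {
      ## zero-probability branch contributes zero to every pair
      for (b in .app_labels(second)) {
        labs <- c(labs, paste(a, b, sep = "."))
        probs <- c(probs, 0)
        posts <- c(posts, list(NULL))
        pairs <- rbind(pairs, c(a, b))
      }
      next
    }
    d2 <- measure(d1$post_states[[a]], second)
    for (b in d2$labels) {
      labs <- c(labs, paste(a, b, sep = "."))
      probs <- c(probs, pa * d2$probabilities[[b]])
      posts <- c(posts, list(d2$post_states[[b]]))
      pairs <- rbind(pairs, c(a, b))
    }
  }
  out <- .outcome_distribution(labs, probs, posts)
  attr(out, "pairs") <- pairs
  out
}

.app_labels <- function(x) x$labels

#' Mixing-law residual of an apparatus
#'
#' Outcome probabilities must be affine in the state: a probabilistic
#' mixture of sensations produces the mixture of probabilities for the
#' perception outputs,
#' `p(a | q1 rho1 + q2 rho2) = q1 p(a | rho1) + q2 p(a | rho2)`.
#' This returns the maximal absolute violation over outcomes; for every
#' measurement kind implemented here it is zero up to rounding, because all
#' probabilities are traces against fixed effect operators.
#'
#' @param apparatus any apparatus accepted by [measure()].
#' @param rho1,rho2 `qstate`s.
#' @param q1 weight of `rho1` (weight of `rho2` is `1 - q1`).
#' @return Maximal absolute residual (a nonnegative number).
#' @export
mixing_law_residual <- function(apparatus, rho1, rho2, q1) {
  stopifnot(q1 >= 0, q1 <= 1)
  q2 <- 1 - q1
  mix <- mix_states(list(rho1, rho2), c(q1, q2))
  p_mix <- measure(mix, apparatus)$probabilities
  p1 <- measure(rho1, apparatus)$probabilities
  p2 <- measure(rho2, apparatus)$probabilities
  max(abs(p_mix - (q1 * p1 + q2 * p2)))
}

#' Random instruments
#'
#' Seeded generators for property-style testing: `rand_atomic_instrument()`
#' draws Ginibre matrices G_a and normalizes them through the inverse square
#' root of sum G_a* G_a, so the normalization condition holds exactly;
#' `rand_dl_instrument()` does the same across all Kraus components of all
#' outcomes.
#'
#' @param d dimension.
#' @param n_outcomes number of outcomes.
#' @param labels optional labels.
#' @param n_components Kraus components per outcome (DL case).
#' @return An `atomic_instrument` / `dl_instrument`.
#' @examples
#' set.seed(1)
#' rand_atomic_instrument(2, 2)
#' @export
rand_atomic_instrument <- function(d, n_outcomes = 2L, labels = NULL) {
  g <- lapply(seq_len(n_outcomes), function(i)
    matrix(stats::rnorm(d * d) + 1i * stats::rnorm(d * d), d, d))
  s <- Reduce(`+`, lapply(g, function(m) Conj(t(m)) %*% m))
  e <- eigen(s, symmetric = TRUE)
  s_inv_sqrt <- e$vectors %*% diag(1 / sqrt(e$values), d) %*% Conj(t(e$vectors))
  atomic_instrument(lapply(g, function(m) m %*% s_inv_sqrt),
                    labels = labels, validate = FALSE)
}

#' @rdname rand_atomic_instrument
#' @export
rand_dl_instrument <- function(d, n_outcomes = 2L, n_components = 2L,
                               labels = NULL) {
  g <- lapply(seq_len(n_outcomes), function(i)
    lapply(seq_len(n_components), function(k)
      matrix(stats::rnorm(d * d) + 1i * stats::rnorm(d * d), d, d)))
  s <- Reduce(`+`, lapply(unlist(g, recursive = FALSE),
                          function(m) Conj(t(m)) %*% m))
  e <- eigen(s, symmetric = TRUE)
  s_inv_sqrt <- e$vectors %*% diag(1 / sqrt(e$values), d) %*% Conj(t(e$vectors))
  dl_instrument(lapply(g, function(ks)
    lapply(ks, function(m) m %*% s_inv_sqrt)),
    labels = labels, validate = FALSE)
}
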