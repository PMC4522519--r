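#' Temporal contextuality of sequential perception statistics
#'
#' Statistics collected under different contexts (different angle sequences)
#' need not be marginals of one classical (Kolmogorov) joint distribution
#' over all the variables.  [joint_feasibility()] decides embeddability by
#' solving the corresponding nonnegative linear system over the 2^n global
#' assignments, and [lg_statistic()] computes the standard three-time
#' Leggett--Garg combination K = C12 + C23 - C13 of two-time correlators,
#' whose classical (macrorealist) bound is 1: K > 1 certifies that no single
#' joint distribution reproduces the pairwise statistics.
#'
#' @name contextuality
NULL

#' Context-indexed perception statistics
#'
#' @param variables character vector of variable names (e.g. time slots or
#'   angle labels).
#' @param contexts list of contexts; each is a list with `vars` (an ordered
#'   subset of `variables`) and `probs`, a named probability vector over all
#'   level combinations of those variables, named `"L.R"` style with the
#'   levels of `vars[1]` first.
#' @param levels outcome levels of every variable (default `c("L", "R")`).
#' @return An object of class `context_statistics`.
#' @examples
#' context_statistics(c("t1", "t2"),
#'   list(list(vars = c("t1", "t2"),
#'             probs = c(L.L = .4, L.R = .1, R.L = .1, R.R = .4))))
#' @export
context_statistics <- function(variables, contexts, levels = c("L", "R")) {
  variables <- as.character(variables)
  stopifnot(length(variables) >= 1, !anyDuplicated(variables))
  contexts <- lapply(contexts, function(ctx) {
    stopifnot(all(ctx$vars %in% variables))
    want <- .assignment_names(length(ctx$vars), levels)
    if (!setequal(names(ctx$probs), want))
      stop("context over (", paste(ctx$vars, collapse = ", "),
           ") must name all ", length(want), " assignments", call. = FALSE)
    p <- ctx$probs[want]
    if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9)
      stop("context distribution must be a probability vector (sum 1 ",
           "within 1e-9)", call. = FALSE)
    list(vars = as.character(ctx$vars), probs = p)
  })
  structure(list(variables = variables, contexts = contexts, levels = levels),
            class = "context_statistics")
}

## assignment names "l1.l2..." with the first variable varying slowest
.assignment_names <- function(k, levels) {
  L <- length(levels)
  a <- seq_len(L^k) - 1L
  cols <- vapply(seq_len(k),
                 function(j) levels[(a %/% L^(k - j)) %% L + 1L],
                 character(L^k))
  apply(matrix(cols, ncol = k), 1, paste, collapse = ".")
}

#' @export
print.context_statistics <- function(x, ...) {
  cat("<context_statistics>", length(x$variables), "variables,",
      length(x$contexts), "contexts\n")
  for (ctx in x$contexts)
    cat("  (", paste(ctx$vars, collapse = ", "), "): ",
        paste(sprintf("%s=%.3f", names(ctx$probs), ctx$probs),
              collapse = " "), "\n", sep = "")
  invisible(x)
}

## ---- nonnegative least squares (Lawson--Hanson active set) ------------------
## Exact active-set solve of min ||A x - b||, x >= 0.  The passive set never
## exceeds the row count, so even with 2^12 columns each iteration only
## factorizes a tiny matrix.  Used because no LP solver is available: the
## feasibility residual is read off at the NNLS optimum, whose zero set
## coincides with that of the minimax program.
.nnls <- function(A, b, tol = 1e-11, max_iter = 10L * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    cand <- which(!passive & w > tol * max(1, max(abs(w))))
    if (!length(cand)) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P[x[P] <= tol]] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Can context statistics be embedded in one classical joint?
#'
#' Decides whether a probability vector over all global outcome assignments
#' exists whose marginals reproduce every context's joint distribution.  The
#' constraint system (one row per context probability plus normalization) is
#' solved as a nonnegative least-squares problem with an exact active-set
#' method; the reported residual is the maximal absolute marginal violation
#' at the optimum, which is zero (to rounding) exactly when the statistics
#' are embeddable.
#'
#' @param stats a [context_statistics()].
#' @param tol feasibility tolerance on the residual (default 1e-8).
#' @param max_vars guard on the 2^n enumeration (default 12).
#' @return An object of class `contextuality_report`: `feasible`, `residual`,
#'   `lg_value` (NA here; see [lg_statistic()]), `classical_bound`,
#'   `joint` (a best-fitting global distribution) and
#'   `marginal_mismatch`, the largest single-variable marginal disagreement
#'   between contexts sharing a variable, with the offending pair named.
#' @export
joint_feasibility <- function(stats, tol = 1e-8, max_vars = 12L) {
  stopifnot(inherits(stats, "context_statistics"))
  vars <- stats$variables
  n <- length(vars)
  if (n > max_vars)
    stop("joint feasibility enumerates 2^n assignments; n = ", n,
         " exceeds max_vars = ", max_vars, call. = FALSE)
  levels <- stats$levels
  L <- length(levels)
  ## global assignments: column j of G = level index of variable j
  G <- as.matrix(expand.grid(rep(list(seq_len(L)), n),
                             KEEP.OUT.ATTRS = FALSE))
  colnames(G) <- vars
  N <- nrow(G)
  rows <- list(); rhs <- numeric(0)
  for (ctx in stats$contexts) {
    k <- length(ctx$vars)
    sub <- G[, ctx$vars, drop = FALSE]
    ## assignment index with vars[1] slowest, matching .assignment_names
    idx <- rep(1L, N)
    for (j in seq_len(k)) idx <- (idx - 1L) * L + sub[, j]
    for (a in seq_len(L^k)) {
      rows[[length(rows) + 1L]] <- as.numeric(idx == a)
      rhs <- c(rhs, unname(ctx$probs[a]))
    }
  }
  A_marg <- do.call(rbind, rows)
  A <- rbind(A_marg, rep(1, N))
  b <- c(rhs, 1)
  x <- .nnls(A, b)
  s <- sum(x)
  if (s > 0) x <- x / s
  residual <- max(abs(A_marg %*% x - rhs))
  ## single-variable marginal consistency across contexts
  mm <- list(value = 0, pair = NULL)
  for (v in vars) {
    holders <- which(vapply(stats$contexts,
                            function(c) v %in% c$vars, logical(1)))
    if (length(holders) < 2) next
    margs <- lapply(holders, function(ci) {
      ctx <- stats$contexts[[ci]]
      k <- length(ctx$vars); pos <- match(v, ctx$vars)
      ## level of v in assignment a (vars[1] slowest)
      a_idx <- seq_len(L^k)
      lev <- ((a_idx - 1L) %/% L^(k - pos)) %% L + 1L
      vapply(seq_len(L), function(l) sum(ctx$probs[lev == l]), numeric(1))
    })
    for (i in seq_along(holders)) for (j in seq_along(holders)) if (i < j) {
      d <- max(abs(margs[[i]] - margs[[j]]))
      if (d > mm$value) mm <- list(value = d, pair = c(holders[i],
                                                      holders[j]),
                                   variable = v)
    }
  }
  structure(list(feasible = residual < tol, residual = residual,
                 lg_value = NA_real_, classical_bound = 1,
                 joint = stats::setNames(as.numeric(x), NULL),
                 marginal_mismatch = mm, tol = tol),
            class = "contextuality_report")
}

#' @export
print.contextuality_report <- function(x, ...) {
  cat("<contextuality_report>\n",
      " feasible: ", x$feasible,
      "  residual: ", format(x$residual, digits = 4), "\n", sep = "")
  if (!is.na(x$lg_value))
    cat("  Leggett-Garg K = ", format(x$lg_value, digits = 6),
        "  (classical bound ", x$classical_bound, ")\n", sep = "")
  if (x$marginal_mismatch$value > x$tol)
    cat("  inconsistent marginals of ", x$marginal_mismatch$variable,
        " between contexts ", paste(x$marginal_mismatch$pair,
                                    collapse = " and "),
        " (max diff ", format(x$marginal_mismatch$value, digits = 3),
        ")\n", sep = "")
  invisible(x)
}

## ---- Leggett--Garg statistic ------------------------------------------------

## joint distribution over the measured steps of a context run
.joint_from_run <- function(run) {
  meas <- which(!is.na(run$outcome_index[1, ]))
  o <- run$outcome_index[, meas, drop = FALSE]
  L <- length(run$labels)
  idx <- rep(1L, nrow(o))
  for (j in seq_len(ncol(o))) idx <- (idx - 1L) * L + o[, j]
  p <- vapply(seq_len(L^ncol(o)), function(a) sum(run$paths$probability[idx == a]),
              numeric(1))
  names(p) <- .assignment_names(ncol(o), run$labels)
  p
}

#' Pairwise two-time contexts of a model
#'
#' Builds the [context_statistics()] of the three pair-measurement protocols
#' over an angle triple: in protocol `"two_time"` all three images are
#' presented in order (the sensation dynamics always acts) but responses are
#' collected only at the two chosen slots; `"marginalize"` measures at all
#' three slots and marginalizes the full joint.
#'
#' @param model a [schroeder_model()].
#' @param angles numeric vector of three presentation angles (degrees).
#' @param protocol `"two_time"` (default) or `"marginalize"`.
#' @return A `context_statistics` over variables `t1, t2, t3` with the three
#'   pairwise contexts.
#' @export
pairwise_contexts <- function(model, angles,
                              protocol = c("two_time", "marginalize")) {
  protocol <- match.arg(protocol)
  stopifnot(length(angles) == 3)
  vars <- paste0("t", 1:3)
  pairs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  full <- if (protocol == "marginalize")
    run_context(model, rotation_context(angles = angles)) else NULL
  contexts <- lapply(pairs, function(pr) {
    if (protocol == "two_time") {
      msk <- seq_len(3) %in% pr
      run <- run_context(model, rotation_context(angles = angles),
                         measured = msk)
      list(vars = vars[pr], probs = .joint_from_run(run))
    } else {
      p3 <- .joint_from_run(full)
      ## marginalize the third variable out of the full triple joint
      o <- as.matrix(expand.grid(rep(list(seq_len(2)), 3)))[, 3:1]
      idx <- (o[, pr[1]] - 1L) * 2L + o[, pr[2]]
      p <- vapply(seq_len(4), function(a) sum(p3[idx == a]), numeric(1))
      names(p) <- .assignment_names(2, full$labels)
      list(vars = vars[pr], probs = p)
    }
  })
  context_statistics(vars, contexts, levels = model$perception_obs$labels)
}

#' Leggett--Garg statistic of a model at three times
#'
#' Encodes the first outcome label as +1 and the second as -1, computes the
#' two-time correlators C_jk = E\[s_j s_k\] from the exact sequential path
#' probabilities of the pair protocols, and returns
#' `K = C12 + C23 - C13`.  Any classical joint distribution obeys `K <= 1`;
#' `K > 1` certifies temporal contextuality.
#'
#' @inheritParams pairwise_contexts
#' @return The value K, with the three correlators in attribute
#'   `"correlators"`.
#' @examples
#' lg_statistic(fixture_model("contextual"), c(0, 45, 90))
#' @export
lg_statistic <- function(model, angles,
                         protocol = c("two_time", "marginalize")) {
  stats <- pairwise_contexts(model, angles, protocol)
  ## signs for L.L, L.R, R.L, R.R (first variable slowest)
  corr <- vapply(stats$contexts,
                 function(ctx) sum(ctx$probs * c(1, -1, -1, 1)),
                 numeric(1))
  names(corr) <- c("C12", "C23", "C13")
  K <- corr[["C12"]] + corr[["C23"]] - corr[["C13"]]
  attr(K, "correlators") <- corr
  K
}

#' Full contextuality report for a model at three times
#'
#' Combines [joint_feasibility()] over the three pairwise contexts with the
#' Leggett--Garg statistic.
#'
#' @inheritParams pairwise_contexts
#' @param tol feasibility tolerance.
#' @return A `contextuality_report` with `lg_value` filled in.
#' @export
contextuality_report <- function(model, angles,
                                 protocol = c("two_time", "marginalize"),
                                 tol = 1e-8) {
  stats <- pairwise_contexts(model, angles, protocol)
  rep_ <- joint_feasibility(stats, tol = tol)
  rep_$lg_value <- as.numeric(lg_statistic(model, angles, protocol))
  rep_
}
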