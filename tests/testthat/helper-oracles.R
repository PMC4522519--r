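## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: the partial trace is the element-wise summation
## definition, path probabilities are chained one state at a time through
## run_indirect, and classical embeddability is decided by vertex
## enumeration.

## partial trace by explicit basis summation: Tr_2 keeps factor 1, etc.
ptrace_oracle <- function(m, dims, keep) {
  dH <- dims[1]; dK <- dims[2]
  if (keep == 1) {
    out <- matrix(0 + 0i, dH, dH)
    for (i in 1:dH) for (j in 1:dH) for (k in 1:dK)
      out[i, j] <- out[i, j] + m[(i - 1) * dK + k, (j - 1) * dK + k]
  } else {
    out <- matrix(0 + 0i, dK, dK)
    for (k in 1:dK) for (l in 1:dK) for (i in 1:dH)
      out[k, l] <- out[k, l] + m[(i - 1) * dK + k, (i - 1) * dK + l]
  }
  out
}

## exact path probabilities by chaining single steps (slow reference route)
brute_paths <- function(model, angles) {
  recur <- function(rho, sig, k) {
    if (k > length(angles)) return(stats::setNames(1, ""))
    br <- perception_step(model, rho, sig, angles[k])
    out <- numeric(0)
    for (o in br) {
      if (o$probability < 1e-14) next
      sub <- recur(o$rho, o$sigma, k + 1)
      names(sub) <- ifelse(names(sub) == "", o$label,
                           paste(o$label, names(sub), sep = "."))
      out <- c(out, o$probability * sub)
    }
    out
  }
  recur(model$rho0, model$sigma0, 1)
}

## classical embeddability by brute-force vertex enumeration: a vertex of
## {x >= 0 : A x = b} is supported on a linearly independent column set, so
## enumerating exact solves on all such subsets decides feasibility.
feasible_oracle <- function(stats, tol = 1e-8) {
  vars <- stats$variables
  n <- length(vars); L <- length(stats$levels); N <- L^n
  G <- as.matrix(expand.grid(rep(list(seq_len(L)), n),
                             KEEP.OUT.ATTRS = FALSE))
  colnames(G) <- vars
  rows <- list(); rhs <- numeric(0)
  for (ctx in stats$contexts) {
    k <- length(ctx$vars)
    idx <- rep(1L, N)
    for (j in seq_len(k)) idx <- (idx - 1L) * L + G[, ctx$vars[j]]
    for (a in seq_len(L^k)) {
      rows[[length(rows) + 1L]] <- as.numeric(idx == a)
      rhs <- c(rhs, unname(ctx$probs[a]))
    }
  }
  A <- rbind(do.call(rbind, rows), rep(1, N))
  b <- c(rhs, 1)
  r <- qr(A)$rank
  for (k in 0:r) {
    for (S in utils::combn(N, k, simplify = FALSE)) {
      As <- A[, S, drop = FALSE]
      if (k > 0 && qr(As)$rank < k) next
      xs <- if (k > 0) qr.coef(qr(As), b) else numeric(0)
      if (anyNA(xs)) next
      res <- b - if (k > 0) As %*% xs else 0
      if (max(abs(res)) < tol && all(xs > -1e-9)) return(TRUE)
    }
  }
  FALSE
}

## random context statistics over n binary variables: either the marginals of
## one global joint (feasible by construction) or independently drawn
## pairwise tables (typically inconsistent)
rand_context_stats <- function(n, n_ctx, from_joint = TRUE) {
  vars <- paste0("t", seq_len(n))
  pairs <- utils::combn(n, 2, simplify = FALSE)
  use <- sample(pairs, min(n_ctx, length(pairs)))
  joint <- runif(2^n); joint <- joint / sum(joint)
  G <- as.matrix(expand.grid(rep(list(1:2), n), KEEP.OUT.ATTRS = FALSE))
  contexts <- lapply(use, function(pr) {
    if (from_joint) {
      idx <- (G[, pr[1]] - 1L) * 2L + G[, pr[2]]
      p <- vapply(1:4, function(a) sum(joint[idx == a]), numeric(1))
    } else {
      p <- runif(4); p <- p / sum(p)
    }
    names(p) <- c("L.L", "L.R", "R.L", "R.R")
    list(vars = vars[pr], probs = p)
  })
  context_statistics(vars, contexts)
}
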