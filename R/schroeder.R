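#' Sequential rotation protocol for bistable perception
#'
#' An ambiguous figure (the Schroeder stair) is presented at a sequence of
#' rotation angles C = (theta_1, ..., theta_m); this ordered sequence is the
#' *context* of the experiment.  At each presentation the image drives a
#' unitary dynamics of the sensation state, `rho -> U_theta rho U_theta*`,
#' the evolved sensation interacts with the current perception state through
#' a fixed unitary (the same at every angle), and the conscious binary answer
#' L/R is a projective measurement on the perception factor.  Registering the
#' answer disentangles the mental state into the product of the two
#' conditional reduced states, which seed the next presentation.
#'
#' [run_context()] enumerates all 2^m outcome paths exactly;
#' [sample_trajectory()] and [sample_outcomes()] draw Monte-Carlo
#' realizations.
#'
#' @name schroeder
NULL

## ---- sensation dynamics families -------------------------------------------

#' Sensation dynamics induced by the rotated image
#'
#' The default family maps the presentation angle theta (degrees) to a real
#' rotation of the two-dimensional sensation plane by
#' `g(theta) = a + b * theta_rad` (radians): a monotone angle-to-rotation map,
#' the minimal family able to produce the clockwise/counterclockwise
#' crossover.  `b = 0` gives angle-independent dynamics, under which
#' clockwise and counterclockwise marginal curves coincide.
#'
#' @param a intercept of the rotation angle, radians.
#' @param b slope, radians of sensation rotation per radian of image
#'   rotation.
#' @return An object of class `sensation_family` with fields `fn(theta_deg)`
#'   (a [unitary()] matrix) and a vectorized `bfn`.
#' @examples
#' fam <- sensation_family(0, 1)
#' fam$fn(45)
#' @export
sensation_family <- function(a = 0, b = 1) {
  force(a); force(b)
  fn <- function(theta_deg) rotation2(a + b * theta_deg * pi / 180)
  bfn <- function(theta_deg) {
    g <- a + b * theta_deg * pi / 180
    out <- array(0 + 0i, c(2, 2, length(g)))
    out[1, 1, ] <- cos(g); out[2, 2, ] <- cos(g)
    out[2, 1, ] <- sin(g); out[1, 2, ] <- -sin(g)
    out
  }
  structure(list(type = "rotation", par = c(a = a, b = b), fn = fn,
                 bfn = bfn, d_H = 2L),
            class = "sensation_family")
}

#' @rdname sensation_family
#' @param alpha phase slope (radians per radian of image rotation) of the
#'   diagonal family `diag(exp(i alpha theta_rad), exp(-i alpha theta_rad))`,
#'   which commutes with basis-controlled interactions and therefore yields
#'   classically embeddable statistics.
#' @export
diagonal_phase_family <- function(alpha = 1) {
  force(alpha)
  fn <- function(theta_deg) {
    g <- alpha * theta_deg * pi / 180
    diag(c(exp(1i * g), exp(-1i * g)))
  }
  bfn <- function(theta_deg) {
    g <- alpha * theta_deg * pi / 180
    out <- array(0 + 0i, c(2, 2, length(g)))
    out[1, 1, ] <- exp(1i * g); out[2, 2, ] <- exp(-1i * g)
    out
  }
  structure(list(type = "diagonal", par = c(alpha = alpha), fn = fn,
                 bfn = bfn, d_H = 2L),
            class = "sensation_family")
}

#' @rdname sensation_family
#' @param fn function mapping an angle in degrees to a d_H x d_H unitary
#'   matrix (plain complex matrix).
#' @param d_H sensation dimension.
#' @param par optional parameter vector stored for bookkeeping.
#' @export
custom_sensation_family <- function(fn, d_H = 2L, par = NULL) {
  force(fn); d_H <- as.integer(d_H)
  bfn <- function(theta_deg) {
    out <- array(0 + 0i, c(d_H, d_H, length(theta_deg)))
    for (b in seq_along(theta_deg)) out[, , b] <- fn(theta_deg[b])
    out
  }
  structure(list(type = "custom", par = par, fn = fn, bfn = bfn, d_H = d_H),
            class = "sensation_family")
}

#' @export
print.sensation_family <- function(x, ...) {
  cat("<sensation_family>", x$type)
  if (length(x$par)) cat(" (", paste(names(x$par), signif(unlist(x$par), 4),
                                     sep = " = ", collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

## ---- rotation contexts ------------------------------------------------------

#' Rotation context: an ordered sequence of presentation angles
#'
#' The three experimental presets span 11 evenly spaced angles between 0 and
#' 90 degrees: `"clockwise"` ascends 0 -> 90, `"counterclockwise"` descends
#' 90 -> 0, `"random"` is a seeded permutation of the same angles.
#'
#' @param angles explicit numeric angle sequence in degrees (overrides
#'   `preset`).
#' @param preset one of `"clockwise"`, `"counterclockwise"`, `"random"`.
#' @param seed seed for the `"random"` preset permutation.
#' @param n_angles number of evenly spaced angles in the presets.
#' @return An object of class `rotation_context`.
#' @examples
#' rotation_context(preset = "clockwise")
#' rotation_context(preset = "random", seed = 7)
#' @export
rotation_context <- function(angles = NULL,
                             preset = c("clockwise", "counterclockwise",
                                        "random"),
                             seed = NULL, n_angles = 11L) {
  if (is.null(angles)) {
    preset <- match.arg(preset)
    base <- seq(0, 90, length.out = n_angles)
    angles <- switch(preset,
      clockwise = base,
      counterclockwise = rev(base),
      random = {
        if (is.null(seed))
          stop("the 'random' preset needs a seed", call. = FALSE)
        with_seed(seed, sample(base))
      })
    name <- preset
  } else {
    angles <- as.numeric(angles)
    if (!length(angles)) stop("angles must be nonempty", call. = FALSE)
    name <- "custom"
  }
  structure(list(angles = angles, name = name, seed = seed),
            class = "rotation_context")
}

#' @export
print.rotation_context <- function(x, ...) {
  cat("<rotation_context>", x$name, ":",
      paste(round(x$angles, 2), collapse = ", "), "\n")
  invisible(x)
}

## ---- the model --------------------------------------------------------------

#' Sequential-perception model
#'
#' Bundles everything the rotation protocol needs: the sensation dynamics
#' family, the (angle-independent) sensation--perception interaction, the
#' perception observable, and the initial states.  Defaults: the neutral
#' perception state `(|L> + |R>)/sqrt(2)` (the deepest state of uncertainty),
#' a maximally mixed pre-recognition sensation state, and a
#' [controlled_rotation()] interaction.
#'
#' @param family a [sensation_family()].
#' @param interaction a [unitary()] on the d_H * d_K composite space.
#' @param perception_obs a [projective_observable()] on K (default: the L/R
#'   basis observable on a two-dimensional perception space).
#' @param rho0 initial sensation `qstate` (default maximally mixed).
#' @param sigma0 initial perception `qstate` (default the neutral
#'   superposition projector).
#' @param reset_sigma logical: reset the perception state to `sigma0` before
#'   each presentation instead of carrying the conditional perception state
#'   forward (default FALSE: carry forward).
#' @return An object of class `schroeder_model`.
#' @examples
#' m <- schroeder_model(sensation_family(0, 1),
#'                      controlled_rotation(c(-pi / 4, pi / 4)))
#' @export
schroeder_model <- function(family = sensation_family(0, 1),
                            interaction = controlled_rotation(c(-pi / 4,
                                                                pi / 4)),
                            perception_obs = basis_observable(
                              2, labels = c("L", "R")),
                            rho0 = NULL, sigma0 = NULL,
                            reset_sigma = FALSE) {
  stopifnot(inherits(family, "sensation_family"),
            inherits(interaction, "unitary"),
            inherits(perception_obs, "projective_observable"))
  d_K <- perception_obs$dim
  d_H <- nrow(interaction$matrix) / d_K
  if (d_H != round(d_H) || d_H != family$d_H)
    stop("interaction dimension must equal family d_H times perception d_K",
         call. = FALSE)
  d_H <- as.integer(d_H)
  if (is.null(rho0)) rho0 <- qstate(diag(d_H) / d_H, validate = FALSE)
  if (is.null(sigma0))
    sigma0 <- pure_to_density(pure_state(rep(1, d_K) / sqrt(d_K)))
  stopifnot(inherits(rho0, "qstate"), inherits(sigma0, "qstate"))
  if (nrow(rho0$matrix) != d_H || nrow(sigma0$matrix) != d_K)
    stop("rho0 / sigma0 dimensions must match d_H / d_K", call. = FALSE)
  structure(list(family = family, interaction = interaction,
                 perception_obs = perception_obs, rho0 = rho0,
                 sigma0 = sigma0, reset_sigma = isTRUE(reset_sigma),
                 d_H = d_H, d_K = d_K,
                 scheme = indirect_scheme(interaction, perception_obs,
                                          d_K = d_K, d_H = d_H)),
            class = "schroeder_model")
}

#' @export
print.schroeder_model <- function(x, ...) {
  cat("<schroeder_model> d_H =", x$d_H, ", d_K =", x$d_K,
      ", outcomes:", paste(x$perception_obs$labels, collapse = "/"),
      if (x$reset_sigma) ", sigma reset each step" else
        ", sigma carried forward", "\n")
  print(x$family)
  invisible(x)
}

#' One step of the rotation protocol
#'
#' Applies the angle-theta sensation dynamics, couples the evolved sensation
#' to the perception state, and measures: for each outcome it returns the
#' probability and the disentangled product pair (rho', sigma') that seeds
#' the next presentation.  This is the slow, single-state reference route
#' (through [run_indirect()]); [run_context()] uses a vectorized engine that
#' is cross-checked against it.
#'
#' @param model a [schroeder_model()].
#' @param rho,sigma current sensation / perception `qstate`s.
#' @param theta presentation angle in degrees.
#' @return A list, one element per outcome: `label`, `probability`, `rho`,
#'   `sigma` (NULL states on zero-probability branches).
#' @export
perception_step <- function(model, rho, sigma, theta) {
  stopifnot(inherits(model, "schroeder_model"))
  rho_theta <- evolve(rho, unitary(model$family$fn(theta), validate = FALSE))
  res <- run_indirect(model$scheme, rho_theta, sigma)
  lapply(res, function(o) {
    list(label = o$label, probability = o$probability,
         rho = o$post_sensation,
         sigma = if (model$reset_sigma) model$sigma0 else o$post_perception)
  })
}

## ---- batched branch engine --------------------------------------------------
## All 2^k live branches (or all n sampled trajectories) advance together as
## d x d x B complex arrays; every operation is a handful of BLAS calls or
## vectorized index sums, so an 11-angle exact enumeration costs milliseconds.

## left-multiply every slab: M %*% A[,,b]
.bL <- function(M, A) {
  d1 <- nrow(M); d2 <- dim(A)[2]; B <- dim(A)[3]
  array(M %*% matrix(A, ncol(M), d2 * B), c(d1, d2, B))
}

## right-multiply every slab: A[,,b] %*% M
.bR <- function(A, M) {
  d1 <- dim(A)[1]; d2 <- dim(A)[2]; B <- dim(A)[3]; d3 <- ncol(M)
  Ap <- aperm(A, c(1, 3, 2)); dim(Ap) <- c(d1 * B, d2)
  Cp <- Ap %*% M; dim(Cp) <- c(d1, B, d3)
  aperm(Cp, c(1, 3, 2))
}

## slab-wise product of two batches: X[,,b] %*% Y[,,b]
.bmmb <- function(X, Y) {
  d1 <- dim(X)[1]; d2 <- dim(X)[2]; d3 <- dim(Y)[2]; B <- dim(X)[3]
  C <- array(0 + 0i, c(d1, d3, B))
  for (i in seq_len(d1)) for (j in seq_len(d3)) {
    acc <- X[i, 1, ] * Y[1, j, ]
    if (d2 > 1) for (k in 2:d2) acc <- acc + X[i, k, ] * Y[k, j, ]
    C[i, j, ] <- acc
  }
  C
}

.bconj_t <- function(A) Conj(aperm(A, c(2, 1, 3)))

## slab-wise Kronecker product (H slow, K fast -- matches base kronecker())
.bkron <- function(A, S) {
  dH <- dim(A)[1]; dK <- dim(S)[1]; B <- dim(A)[3]
  R <- array(0 + 0i, c(dH * dK, dH * dK, B))
  for (i in seq_len(dH)) for (j in seq_len(dH))
    for (k in seq_len(dK)) for (l in seq_len(dK))
      R[(i - 1) * dK + k, (j - 1) * dK + l, ] <- A[i, j, ] * S[k, l, ]
  R
}

## slab-wise traces and partial traces
.btr <- function(R) {
  d <- dim(R)[1]
  acc <- R[1, 1, ]
  if (d > 1) for (m in 2:d) acc <- acc + R[m, m, ]
  acc
}

.bptrace_keepH <- function(R, dH, dK) {
  out <- array(0 + 0i, c(dH, dH, dim(R)[3]))
  for (i in seq_len(dH)) for (j in seq_len(dH)) {
    acc <- R[(i - 1) * dK + 1, (j - 1) * dK + 1, ]
    if (dK > 1) for (k in 2:dK)
      acc <- acc + R[(i - 1) * dK + k, (j - 1) * dK + k, ]
    out[i, j, ] <- acc
  }
  out
}

.bptrace_keepK <- function(R, dH, dK) {
  out <- array(0 + 0i, c(dK, dK, dim(R)[3]))
  for (k in seq_len(dK)) for (l in seq_len(dK)) {
    acc <- R[k, l, ]
    if (dH > 1) for (i in 2:dH)
      acc <- acc + R[(i - 1) * dK + k, (i - 1) * dK + l, ]
    out[k, l, ] <- acc
  }
  out
}

## replicate a single matrix into a batch
.brep <- function(M, B) array(rep(as.complex(M), B), c(nrow(M), ncol(M), B))

## core engine.
## mode "exact":    angles is a vector; branches double at each measured step.
## mode "sample":   angles is a vector (shared order) or an n x m matrix (one
##                  order per trajectory); n trajectories advance in parallel
##                  and outcomes are drawn from the per-branch conditionals.
## mode "evaluate": like "sample", but the realized outcomes are supplied
##                  (given_outcomes, n x m integer) and the engine returns the
##                  per-trajectory log path probability.
## measured: logical vector, length m; at unmeasured steps only the sensation
##           dynamics acts (the picture is shown, no response is collected).
.branch_engine <- function(model, angles, mode = c("exact", "sample",
                                                   "evaluate"),
                           n = 1L, measured = NULL, given_outcomes = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(angles)) {
    stopifnot(mode != "exact", nrow(angles) == n)
    m <- ncol(angles)
    per_branch_angles <- TRUE
  } else {
    m <- length(angles)
    per_branch_angles <- FALSE
  }
  if (is.null(measured)) measured <- rep(TRUE, m)
  stopifnot(length(measured) == m)
  labels <- model$perception_obs$labels
  n_out <- length(labels)
  dH <- model$d_H; dK <- model$d_K
  U <- model$interaction$matrix
  Ud <- Conj(t(U))
  IPs <- lapply(model$perception_obs$projectors,
                function(p) kronecker(diag(dH), p))

  B <- if (mode == "exact") 1L else as.integer(n)
  if (mode == "evaluate") {
    stopifnot(is.matrix(given_outcomes), nrow(given_outcomes) == B,
              ncol(given_outcomes) == m)
    logp <- numeric(B)
  }
  rho <- .brep(model$rho0$matrix, B)
  sig <- .brep(model$sigma0$matrix, B)
  w <- rep(1, B)
  outcomes <- matrix(NA_integer_, B, m)
  marg <- matrix(NA_real_, m, n_out, dimnames = list(NULL, labels))
  step_probs <- if (mode == "sample")
    array(NA_real_, c(B, m, n_out)) else NULL

  for (s in seq_len(m)) {
    th <- if (per_branch_angles) angles[, s] else angles[s]
    ## sensation dynamics
    if (per_branch_angles) {
      Us <- model$family$bfn(th)
      rho <- .bmmb(.bmmb(Us, rho), .bconj_t(Us))
    } else {
      Um <- model$family$fn(th)
      rho <- .bR(.bL(Um, rho), Conj(t(Um)))
    }
    if (!measured[s]) next
    ## interaction + perception measurement
    R <- .bkron(rho, sig)
    R <- .bR(.bL(U, R), Ud)
    p_list <- vector("list", n_out)
    rho_list <- vector("list", n_out)
    sig_list <- vector("list", n_out)
    for (i in seq_len(n_out)) {
      X <- .bR(.bL(IPs[[i]], R), IPs[[i]])
      p <- pmax(Re(.btr(X)), 0)
      psafe <- pmax(p, 1e-30)
      rho_i <- .bptrace_keepH(X, dH, dK)
      sig_i <- if (model$reset_sigma) .brep(model$sigma0$matrix, dim(X)[3])
               else .bptrace_keepK(X, dH, dK)
      rho_i <- rho_i / rep(psafe, each = dH * dH)
      if (!model$reset_sigma) sig_i <- sig_i / rep(psafe, each = dK * dK)
      p_list[[i]] <- p; rho_list[[i]] <- rho_i; sig_list[[i]] <- sig_i
    }
    pmat <- do.call(cbind, p_list)            # B x n_out
    marg[s, ] <- colSums(w * pmat)

    if (mode == "exact") {
      Bn <- dim(rho)[3]
      rho <- array(unlist(rho_list, use.names = FALSE),
                   c(dH, dH, Bn * n_out))
      sig <- array(unlist(sig_list, use.names = FALSE),
                   c(dK, dK, Bn * n_out))
      w <- as.numeric(w * pmat)               # column-major: outcome-major
      outcomes <- outcomes[rep(seq_len(Bn), times = n_out), , drop = FALSE]
      outcomes[, s] <- rep(seq_len(n_out), each = Bn)
    } else {
      if (mode == "sample") {
        step_probs[, s, ] <- pmat
        u <- stats::runif(B)
        cum <- t(apply(pmat, 1, cumsum))
        o <- rowSums(u > cum) + 1L
        o[o > n_out] <- n_out
      } else {
        o <- given_outcomes[, s]
        logp <- logp + log(pmax(pmat[cbind(seq_len(B), o)], 1e-300))
      }
      for (i in seq_len(n_out)) {
        sel <- o == i
        if (!any(sel)) next
        rho[, , sel] <- rho_list[[i]][, , sel]
        sig[, , sel] <- sig_list[[i]][, , sel]
      }
      outcomes[, s] <- o
    }
  }
  list(weights = w, outcomes = outcomes, marginals = marg,
       step_probs = step_probs, labels = labels, measured = measured,
       logp = if (mode == "evaluate") logp)
}

## ---- exact enumeration ------------------------------------------------------

#' Run a rotation context exactly
#'
#' Enumerates all outcome paths (i_1, ..., i_m) of a context, chaining the
#' per-step measurement with the quantum Bayes rule, and returns the exact
#' path probabilities together with the per-angle marginals
#' `p(X_theta_k = L)`.
#'
#' @param model a [schroeder_model()].
#' @param context a [rotation_context()] (or numeric vector of angles).
#' @param measured optional logical vector: at unmeasured steps the sensation
#'   dynamics acts but no response is collected (used by the
#'   two-time Leggett--Garg protocol).
#' @param max_steps guard for the 2^m enumeration (default 16); longer
#'   contexts must be sampled with [sample_outcomes()].
#' @return An object of class `context_run` with components `paths` (a
#'   data.frame of all outcome sequences and their probabilities, summing to
#'   1) and `marginals` (a data.frame with step, angle_deg and one
#'   probability column per outcome).
#' @examples
#' m <- fixture_model("hysteresis")
#' run_context(m, rotation_context(preset = "clockwise"))$marginals
#' @export
run_context <- function(model, context, measured = NULL, max_steps = 16L) {
  stopifnot(inherits(model, "schroeder_model"))
  if (!inherits(context, "rotation_context"))
    context <- rotation_context(angles = context)
  m <- length(context$angles)
  n_meas <- if (is.null(measured)) m else sum(measured)
  if (n_meas > max_steps)
    stop("exact enumeration of ", n_meas, " measured steps exceeds ",
         max_steps, "; use sample_outcomes() instead", call. = FALSE)
  eng <- .branch_engine(model, context$angles, mode = "exact",
                        measured = measured)
  lab <- eng$labels
  path <- apply(eng$outcomes, 1, function(o)
    paste(lab[o[!is.na(o)]], collapse = "."))
  paths <- data.frame(path = path, probability = eng$weights,
                      stringsAsFactors = FALSE)
  marg <- data.frame(step = seq_len(m), angle_deg = context$angles)
  for (j in seq_along(lab)) marg[[paste0("p_", lab[j])]] <- eng$marginals[, j]
  structure(list(context = context, paths = paths, marginals = marg,
                 outcome_index = eng$outcomes, labels = lab,
                 measured = eng$measured),
            class = "context_run")
}

#' @export
print.context_run <- function(x, digits = 4, ...) {
  cat("<context_run>", x$context$name, "-", nrow(x$paths), "paths\n")
  print(round(as.data.frame(lapply(x$marginals, round, digits)), digits))
  invisible(x)
}

## ---- sampling ---------------------------------------------------------------

#' Sample one perception trajectory
#'
#' Draws a single realized outcome sequence, step by step, from the
#' conditional per-step distributions.  Reproducible given the seed.
#'
#' @inheritParams run_context
#' @param seed integer seed.
#' @return A data.frame with columns step, angle_deg, one probability column
#'   per outcome, and the realized outcome label.
#' @export
sample_trajectory <- function(model, context, seed) {
  stopifnot(inherits(model, "schroeder_model"))
  if (!inherits(context, "rotation_context"))
    context <- rotation_context(angles = context)
  eng <- with_seed(seed, .branch_engine(model, context$angles,
                                        mode = "sample", n = 1L))
  out <- data.frame(step = seq_along(context$angles),
                    angle_deg = context$angles)
  for (j in seq_along(eng$labels))
    out[[paste0("p_", eng$labels[j])]] <- eng$step_probs[1, , j]
  out$outcome <- eng$labels[eng$outcomes[1, ]]
  out
}

#' Sample many outcome sequences at once
#'
#' Vectorized Monte-Carlo: `n` independent trajectories advance in parallel.
#' `angles` may be a matrix with one row per trajectory, allowing a different
#' presentation order per subject (the random-order group of the experiment).
#'
#' @param model a [schroeder_model()].
#' @param angles numeric vector of angles (degrees), or an `n x m` matrix of
#'   per-trajectory angle orders.
#' @param n number of trajectories.
#' @param seed integer seed.
#' @return A character matrix (`n x m`) of outcome labels.
#' @export
sample_outcomes <- function(model, angles, n, seed) {
  stopifnot(inherits(model, "schroeder_model"))
  eng <- with_seed(seed, .branch_engine(model, angles, mode = "sample",
                                        n = as.integer(n)))
  matrix(eng$labels[eng$outcomes], nrow = n)
}
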