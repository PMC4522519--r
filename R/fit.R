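#' Maximum-likelihood fitting of the rotation-protocol model
#'
#' Estimates the four model parameters -- the sensation-rotation intercept
#' and slope (a, b) and the two controlled-rotation interaction angles
#' (mu0, mu1) -- from binary response data.  Because unitary
#' parameterizations carry gauge freedom the raw parameters are identifiable
#' only up to symmetries; the contract of a fit is the predicted probability
#' curve, not the parameter vector.
#'
#' @name fitting
NULL

## rebuild a model from a parameter vector, inheriting everything else
## (initial states, observable, reset flag) from the template
model_from_par <- function(par, template) {
  par <- unlist(par)
  stopifnot(length(par) == 4)
  if (!all(is.finite(par)))
    stop("invalid parameters: all of (a, b, mu0, mu1) must be finite",
         call. = FALSE)
  names(par) <- c("a", "b", "mu0", "mu1")
  schroeder_model(family = sensation_family(par[["a"]], par[["b"]]),
                  interaction = controlled_rotation(c(par[["mu0"]],
                                                      par[["mu1"]])),
                  perception_obs = template$perception_obs,
                  rho0 = template$rho0, sigma0 = template$sigma0,
                  reset_sigma = template$reset_sigma)
}

## frequency curve from either a curve or a raw experiment table
.as_curve <- function(data) {
  if (all(c("n", "p_L") %in% names(data))) return(data)
  if ("response" %in% names(data)) return(empirical_frequencies(data))
  stop("data must be an experiment table or a frequency curve", call. = FALSE)
}

#' Negative log-likelihood of model parameters
#'
#' Two likelihoods are available. The curve likelihood (`data` a frequency
#' curve, or a table which is aggregated first) treats each (group, angle)
#' cell as binomial with the model's exact per-angle marginal under that
#' group's deterministic context; groups mapped to `"random"` are skipped,
#' since a curve loses the per-subject orders.  The sequential likelihood
#' (`data` a raw table, `sequential = TRUE`) uses each subject's exact path
#' probability -- the chained quantum Bayes rule along their realized outcome
#' sequence -- and handles random orders exactly.  Probabilities are clipped
#' to \[1e-12, 1 - 1e-12\] so degenerate parameters stay finite.
#'
#' @param par numeric vector `(a, b, mu0, mu1)`.
#' @param data frequency curve (columns group, angle_deg, n, p_L) or
#'   experiment table (columns subject, group, pres_index, angle_deg,
#'   response).
#' @param template a [schroeder_model()] supplying everything the parameters
#'   do not (initial states, observable, reset flag).
#' @param contexts named character vector mapping groups to context presets.
#' @param sequential use the per-subject exact path likelihood (requires a
#'   raw table).
#' @return The negative log-likelihood (finite for finite parameters).
#' @export
schroeder_nll <- function(par, data, template = schroeder_model(),
                          contexts = c(A = "random", B = "clockwise",
                                       C = "counterclockwise"),
                          sequential = FALSE) {
  model <- model_from_par(par, template)
  clip <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (sequential) {
    if (!"response" %in% names(data))
      stop("sequential likelihood needs a raw experiment table",
           call. = FALSE)
    nll <- 0
    for (g in intersect(unique(data$group), names(contexts))) {
      sub <- data[data$group == g, , drop = FALSE]
      sub <- sub[order(sub$subject, sub$pres_index), , drop = FALSE]
      m <- max(sub$pres_index)
      ids <- unique(sub$subject)
      ang <- matrix(sub$angle_deg, ncol = m, byrow = TRUE)
      oc <- matrix(match(sub$response, model$perception_obs$labels),
                   ncol = m, byrow = TRUE)
      eng <- .branch_engine(model, ang, mode = "evaluate", n = length(ids),
                            given_outcomes = oc)
      nll <- nll - sum(eng$logp)
    }
    return(nll)
  }
  curve <- .as_curve(data)
  nll <- 0
  for (g in intersect(unique(curve$group), names(contexts))) {
    if (contexts[[g]] == "random") next
    cc <- curve[curve$group == g & curve$n > 0, , drop = FALSE]
    run <- run_context(model, rotation_context(preset = contexts[[g]],
                                               n_angles = nrow(cc)))
    p <- clip(run$marginals$p_L[match(cc$angle_deg,
                                      run$marginals$angle_deg)])
    x <- cc$n * cc$p_L
    nll <- nll - sum(x * log(p) + (cc$n - x) * log(1 - p))
  }
  nll
}

#' Fit the rotation-protocol model
#'
#' Derivative-free (Nelder--Mead) maximum likelihood with seeded multistarts;
#' the best local optimum is returned.  The number of informative data cells
#' is compared against the parameter count, and under-determined problems
#' (e.g. a single angle in a single context) are flagged, not silently fit.
#'
#' Three likelihood strategies are available through `sequential`:
#' `FALSE` fits the binomial curve likelihood of the deterministic-order
#' groups (fast, but a random-order group is ignored and distinct parameter
#' basins can tie); `TRUE` fits the exact per-subject path likelihood
#' throughout (exact but slow at large n); `"refine"` -- the recommended
#' setting when a random-order group is present -- explores with the curve
#' likelihood, then uses the sequential likelihood of the full table to
#' select among the multistart optima and polishes the winner with the
#' sequential likelihood of the random-order group plus the curve likelihood
#' of the others.
#'
#' @param data frequency curve or experiment table (see [schroeder_nll()]);
#'   `sequential = TRUE` or `"refine"` require a raw table.
#' @param template model supplying non-fitted structure.
#' @param contexts named map from groups to context presets.
#' @param sequential `FALSE`, `TRUE`, or `"refine"` (see Details).
#' @param multistart number of seeded starting points (>= 1; default 8).
#' @param seed integer seed for the multistart draws.
#' @param maxit Nelder--Mead iteration cap per start.
#' @return An object of class `schroeder_fit` with components `par`, `nll`,
#'   `convergence` (0 = converged), `underdetermined`, `starts` (per-start
#'   record of starting point, optimum and likelihoods), `model` (the fitted
#'   [schroeder_model()]) and the data.
#' @seealso [predict.schroeder_fit()], [simulate.schroeder_fit()]
#' @export
fit_schroeder <- function(data, template = schroeder_model(),
                          contexts = c(A = "random", B = "clockwise",
                                       C = "counterclockwise"),
                          sequential = FALSE, multistart = 8L, seed = 1L,
                          maxit = 400L) {
  refine <- identical(sequential, "refine")
  seq_all <- isTRUE(sequential)
  if ((refine || seq_all) && !"response" %in% names(data))
    stop("sequential likelihoods need a raw experiment table", call. = FALSE)
  curve <- if (!seq_all) .as_curve(data) else NULL
  n_cells <- if (seq_all) {
    length(unique(data$angle_deg)) *
      length(intersect(unique(data$group), names(contexts)))
  } else {
    used <- curve$group %in% names(contexts)[contexts != "random"]
    sum(used & curve$n > 0)
  }
  underdetermined <- n_cells < 4
  if (underdetermined)
    warning("fit is under-determined: ", n_cells,
            " informative cells for 4 parameters", call. = FALSE)
  explore_obj <- if (seq_all)
    function(par) schroeder_nll(par, data, template, contexts,
                                sequential = TRUE)
  else
    function(par) schroeder_nll(par, curve, template, contexts)
  starts <- lapply(seq_len(multistart), function(r) {
    if (r == 1L) c(a = 0, b = 1, mu0 = -pi / 4, mu1 = pi / 4)
    else with_seed(derive_seed(seed, r),
                   c(a = stats::runif(1, -1, 1),
                     b = stats::runif(1, 0, 2),
                     mu0 = stats::runif(1, -pi / 2, pi / 2),
                     mu1 = stats::runif(1, -pi / 2, pi / 2)))
  })
  fits <- lapply(starts, function(s)
    stats::optim(s, explore_obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-9)))
  values <- vapply(fits, `[[`, numeric(1), "value")
  starts_df <- data.frame(start = seq_len(multistart),
                          t(vapply(starts, unlist, numeric(4))),
                          t(vapply(fits, function(f) unname(f$par),
                                   numeric(4))),
                          nll = values,
                          convergence = vapply(fits, `[[`, numeric(1),
                                               "convergence"))
  names(starts_df)[2:9] <- c("a0", "b0", "mu00", "mu10",
                             "a", "b", "mu0", "mu1")
  if (refine) {
    ## select the basin by the exact sequential likelihood of all groups,
    ## then polish with the sequential likelihood of the random-order
    ## group(s) plus the curve likelihood of the deterministic groups
    seq_values <- vapply(fits, function(f)
      schroeder_nll(f$par, data, template, contexts, sequential = TRUE),
      numeric(1))
    starts_df$seq_nll <- seq_values
    rnd_groups <- names(contexts)[contexts == "random"]
    data_rnd <- data[data$group %in% rnd_groups, , drop = FALSE]
    polish_obj <- function(par)
      schroeder_nll(par, curve, template, contexts) +
        if (nrow(data_rnd)) schroeder_nll(par, data_rnd, template,
                                          contexts, sequential = TRUE)
        else 0
    ## Nelder-Mead restarts rebuild the simplex; loop until converged
    best <- fits[[which.min(seq_values)]]
    for (round in 1:3) {
      best <- stats::optim(best$par, polish_obj, method = "Nelder-Mead",
                           control = list(maxit = 150L, reltol = 1e-8))
      if (best$convergence == 0) break
    }
    final_nll <- schroeder_nll(best$par, data, template, contexts,
                               sequential = TRUE)
  } else {
    best <- fits[[which.min(values)]]
    final_nll <- best$value
  }
  structure(list(
    par = best$par, nll = final_nll,
    convergence = best$convergence,
    underdetermined = underdetermined,
    starts = starts_df,
    model = model_from_par(best$par, template),
    template = template, contexts = contexts, data = data,
    sequential = sequential, seed = seed,
    n_obs = if (seq_all || refine) length(unique(data$subject))
            else sum(curve$n)),
    class = "schroeder_fit")
}

#' @export
print.schroeder_fit <- function(x, digits = 4, ...) {
  cat("Rotation-protocol model fit (maximum likelihood)\n")
  cat("  parameters:", paste(names(x$par),
                             signif(x$par, digits), sep = " = ",
                             collapse = ", "), "\n")
  cat("  negative log-likelihood:", format(x$nll, digits = 8), "\n")
  if (x$convergence != 0)
    cat("  WARNING: optimizer did not report convergence (code ",
        x$convergence, ")\n", sep = "")
  if (x$underdetermined) cat("  WARNING: under-determined fit\n")
  invisible(x)
}

#' @export
summary.schroeder_fit <- function(object, ...) {
  print(object)
  cat("\nMultistart record (best of", nrow(object$starts), "):\n")
  print(object$starts, digits = 4)
  invisible(object)
}

#' @export
coef.schroeder_fit <- function(object, ...) object$par

#' @export
logLik.schroeder_fit <- function(object, ...) {
  structure(-object$nll, df = length(object$par), nobs = object$n_obs,
            class = "logLik")
}

#' Predicted per-angle perception probabilities
#'
#' @param object a `schroeder_fit`.
#' @param context context preset name, [rotation_context()], or angle vector.
#' @param n_pictures angles in the preset grid.
#' @param n_random number of seeded random orders averaged for the
#'   `"random"` context.
#' @param seed seed for the random-order average.
#' @param ... unused.
#' @return data.frame with `angle_deg` and predicted `p_L`.
#' @export
predict.schroeder_fit <- function(object, context = "clockwise",
                                  n_pictures = 11L, n_random = 200L,
                                  seed = 1L, ...) {
  context_marginal_curve(object$model, context, n_pictures = n_pictures,
                         n_random = n_random, seed = seed)
}

#' Exact marginal probability curve of a model under a context
#'
#' For deterministic contexts this is the exact [run_context()] marginal,
#' reported per angle.  For the `"random"` context -- a fresh uniformly
#' random order per subject -- the per-angle marginal is the expectation over
#' orders, estimated by averaging the exact marginals of `n_random` seeded
#' permutations (no response sampling is involved, so the only error is the
#' finite number of orders).
#'
#' @param model a [schroeder_model()].
#' @param context preset name, [rotation_context()], or numeric angle vector.
#' @param n_pictures angles in the preset grid.
#' @param n_random orders averaged for `"random"`.
#' @param seed seed for the order draws.
#' @return data.frame with `angle_deg` and `p_L`, sorted by angle.
#' @export
context_marginal_curve <- function(model, context, n_pictures = 11L,
                                   n_random = 200L, seed = 1L) {
  if (inherits(context, "rotation_context") || is.numeric(context)) {
    run <- run_context(model, context)
    mg <- run$marginals[, c("angle_deg", "p_L")]
    return(mg[order(mg$angle_deg), , drop = FALSE])
  }
  stopifnot(is.character(context))
  if (context %in% c("clockwise", "counterclockwise")) {
    run <- run_context(model, rotation_context(preset = context,
                                               n_angles = n_pictures))
    mg <- run$marginals[, c("angle_deg", "p_L")]
    return(mg[order(mg$angle_deg), , drop = FALSE])
  }
  if (context != "random") stop("unknown context: ", context, call. = FALSE)
  base <- seq(0, 90, length.out = n_pictures)
  acc <- stats::setNames(numeric(n_pictures), format(base))
  for (r in seq_len(n_random)) {
    ctx <- rotation_context(preset = "random",
                            seed = derive_seed(seed, r),
                            n_angles = n_pictures)
    mg <- run_context(model, ctx)$marginals
    acc <- acc + mg$p_L[match(base, mg$angle_deg)]
  }
  data.frame(angle_deg = base, p_L = unname(acc / n_random))
}

#' Simulate response tables from a fitted model
#'
#' @param object a `schroeder_fit`.
#' @param nsim number of tables.
#' @param seed integer seed.
#' @param design an [experiment_design()] (default: the reference design).
#' @param ... unused.
#' @return A single experiment table if `nsim = 1`, else a list of tables.
#' @export
simulate.schroeder_fit <- function(object, nsim = 1, seed = 1L,
                                   design = experiment_design(), ...) {
  tabs <- lapply(seq_len(nsim), function(i)
    simulate_experiment(object$model, design, seed = derive_seed(seed, i)))
  if (nsim == 1) tabs[[1]] else tabs
}

#' @export
residuals.schroeder_fit <- function(object, ...) {
  curve <- .as_curve(object$data)
  res <- rep(NA_real_, nrow(curve))
  for (g in unique(curve$group)) {
    ctx <- object$contexts[[g]]
    if (is.null(ctx) || ctx == "random") next
    sel <- which(curve$group == g & curve$n > 0)
    pred <- context_marginal_curve(object$model, ctx,
                                   n_pictures = length(sel))
    res[sel] <- curve$p_L[sel] -
      pred$p_L[match(curve$angle_deg[sel], pred$angle_deg)]
  }
  res
}

#' Plot observed and fitted perception curves
#'
#' @param x a `schroeder_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.schroeder_fit <- function(x, ...) {
  curve <- .as_curve(x$data)
  dets <- names(x$contexts)[x$contexts != "random"]
  cols <- seq_along(dets) + 1
  graphics::plot(NULL, xlim = c(0, 90), ylim = c(0, 1),
                 xlab = "rotation angle (degrees)",
                 ylab = "p(X = L)", ...)
  for (i in seq_along(dets)) {
    g <- dets[i]
    cc <- curve[curve$group == g & curve$n > 0, ]
    graphics::points(cc$angle_deg, cc$p_L, col = cols[i], pch = 16)
    pred <- context_marginal_curve(x$model, x$contexts[[g]],
                                   n_pictures = nrow(cc))
    graphics::lines(pred$angle_deg, pred$p_L, col = cols[i])
  }
  graphics::legend("topright", legend = paste(dets, x$contexts[dets]),
                   col = cols, lty = 1, pch = 16, bty = "n")
  invisible(x)
}
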