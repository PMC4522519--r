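#' Synthetic three-group rotation experiment
#'
#' Emulates the reference experimental design: three groups of subjects
#' (defaults 55, 48 and 48) each see 11 pictures of the ambiguous figure at
#' angles between 0 and 90 degrees and answer L ("left side is front") or R.
#' Group A sees the pictures in a fresh random order per subject, group B in
#' clockwise order 0 -> 90, group C in counterclockwise order 90 -> 0.
#' Responses are generated by a [schroeder_model()]; all subjects share one
#' parameter set (the model describes a single idealized agent).
#'
#' @name experiment_sim
NULL

#' Experiment design
#'
#' @param groups named integer vector of group sizes.
#' @param contexts named character vector mapping each group to a context
#'   preset: `"random"`, `"clockwise"` or `"counterclockwise"`.
#' @param n_pictures number of presentation angles (evenly spaced 0--90).
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design()   # the reference 55/48/48 design
#' @export
experiment_design <- function(groups = c(A = 55L, B = 48L, C = 48L),
                              contexts = c(A = "random", B = "clockwise",
                                           C = "counterclockwise"),
                              n_pictures = 11L) {
  stopifnot(length(groups) >= 1, all(groups > 0),
            !is.null(names(groups)),
            setequal(names(groups), names(contexts)))
  valid <- c("random", "clockwise", "counterclockwise")
  if (!all(contexts %in% valid))
    stop("contexts must be one of: ", paste(valid, collapse = ", "),
         call. = FALSE)
  structure(list(groups = groups, contexts = contexts[names(groups)],
                 n_pictures = as.integer(n_pictures)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>", sum(x$groups), "subjects,",
      x$n_pictures, "pictures\n")
  for (g in names(x$groups))
    cat("  group", g, ":", x$groups[[g]], "subjects,",
        x$contexts[[g]], "order\n")
  invisible(x)
}

#' Simulate the experiment
#'
#' Each subject is an independent sampled trajectory under their group's
#' context; random-order subjects each draw a fresh presentation order.  All
#' randomness fans out from `seed` through [derive_seed()], so the same seed
#' reproduces the table exactly.
#'
#' @param model a [schroeder_model()].
#' @param design an [experiment_design()].
#' @param seed integer seed.
#' @return A data.frame (the experiment table) with one row per subject per
#'   picture: `subject`, `group`, `pres_index` (presentation position),
#'   `angle_deg`, `response`.
#' @examples
#' tab <- simulate_experiment(fixture_model("hysteresis"),
#'                            experiment_design(), seed = 1)
#' head(tab)
#' @export
simulate_experiment <- function(model, design, seed) {
  stopifnot(inherits(model, "schroeder_model"),
            inherits(design, "experiment_design"))
  base <- seq(0, 90, length.out = design$n_pictures)
  m <- design$n_pictures
  out <- vector("list", length(design$groups))
  for (gi in seq_along(design$groups)) {
    g <- names(design$groups)[gi]
    n <- design$groups[[gi]]
    ctx <- design$contexts[[g]]
    if (ctx == "random") {
      orders <- t(vapply(seq_len(n), function(s)
        with_seed(derive_seed(seed, gi * 1000000L + s), sample(base)),
        numeric(m)))
      angles <- orders
    } else {
      angles <- if (ctx == "clockwise") base else rev(base)
    }
    resp <- sample_outcomes(model, angles, n,
                            seed = derive_seed(seed, gi * 1000000L))
    ang_mat <- if (is.matrix(angles)) angles
               else matrix(angles, n, m, byrow = TRUE)
    out[[gi]] <- data.frame(
      subject = rep(sprintf("%s%04d", g, seq_len(n)), each = m),
      group = g,
      pres_index = rep(seq_len(m), n),
      angle_deg = as.vector(t(ang_mat)),
      response = as.vector(t(resp)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Empirical frequency curves
#'
#' Per group and angle, the fraction of L responses and the cell count.
#' Cells present in the angle grid but empty for a group are kept with
#' `n = 0` and `p_L = NA` rather than fabricated.
#'
#' @param table an experiment table from [simulate_experiment()] (columns
#'   `group`, `angle_deg`, `response`), or any data.frame with those columns.
#' @param label the outcome counted in the numerator (default `"L"`).
#' @return A data.frame with columns `group`, `angle_deg`, `n`, `p_L`.
#' @export
empirical_frequencies <- function(table, label = "L") {
  stopifnot(nrow(table) > 0,
            all(c("group", "angle_deg", "response") %in% names(table)))
  groups <- sort(unique(table$group))
  angles <- sort(unique(table$angle_deg))
  grid <- expand.grid(group = groups, angle_deg = angles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- integer(nrow(grid)); p <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sel <- table$group == grid$group[i] & table$angle_deg == grid$angle_deg[i]
    n[i] <- sum(sel)
    p[i] <- if (n[i] > 0) mean(table$response[sel] == label) else NA_real_
  }
  out <- data.frame(grid, n = n, p_L = p)
  out[order(out$group, out$angle_deg), , drop = FALSE]
}
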