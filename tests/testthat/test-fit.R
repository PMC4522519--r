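test_that("the balanced no-information model has the closed-form likelihood", {
  ## identity interaction + perception reset: p = 1/2 at every cell, so the
  ## NLL of balanced data is N log 2
  template <- schroeder_model(reset_sigma = TRUE)
  curve <- data.frame(group = rep(c("B", "C"), each = 11),
                      angle_deg = rep(seq(0, 90, length.out = 11), 2),
                      n = 50, p_L = 0.5)
  nll <- schroeder_nll(c(a = 0, b = 1, mu0 = 0, mu1 = 0), curve,
                       template = template)
  expect_equal(nll, sum(curve$n) * log(2), tolerance = 1e-9)
})

test_that("degenerate parameters stay finite through clipping", {
  curve <- data.frame(group = "B", angle_deg = seq(0, 90, length.out = 11),
                      n = 10, p_L = c(1, rep(0.5, 9), 0))
  ## a model that predicts p = 1 or 0 exactly would blow up without clipping
  det <- schroeder_model(sigma0 = pure_to_density(c(1, 0)),
                         reset_sigma = TRUE)
  nll <- schroeder_nll(c(0, 0, 0, 0), curve, template = det)
  expect_true(is.finite(nll))
  expect_error(schroeder_nll(c(NA, 1, 0, 0), curve), "finite")
})

test_that("sequential and curve likelihoods agree where both apply", {
  ## for a single-step context the path likelihood is the Bernoulli one
  m <- fixture_model("hysteresis")
  tab <- simulate_experiment(m, experiment_design(
    groups = c(B = 200L), contexts = c(B = "clockwise"), n_pictures = 1),
    seed = 31)
  par <- c(0, 0.75, -pi / 8, pi / 8)
  nll_seq <- schroeder_nll(par, tab, template = m, sequential = TRUE)
  nll_cur <- schroeder_nll(par, empirical_frequencies(tab), template = m)
  expect_equal(nll_seq, nll_cur, tolerance = 1e-6)
})

test_that("the true parameters sit at a likelihood optimum in expectation", {
  truth <- fixture_model("hysteresis")
  tab <- simulate_experiment(truth, experiment_design(
    groups = c(B = 2500L, C = 2500L),
    contexts = c(B = "clockwise", C = "counterclockwise")), seed = 41)
  freq <- empirical_frequencies(tab)
  par0 <- c(a = 0, b = 0.75, mu0 = -pi / 8, mu1 = pi / 8)
  nll0 <- schroeder_nll(par0, freq, template = truth)
  ## perturbations along identifiable directions (single-mu shifts move
  ## along a near-flat gauge ridge and are excluded)
  for (delta in list(c(0.15, 0, 0, 0), c(0, 0.2, 0, 0), c(0, 0, 0.2, 0.2),
                     c(0, 0, -0.2, 0.2)))
    expect_gt(schroeder_nll(par0 + delta, freq, template = truth), nll0)
})

test_that("a short multistart fit converges and its object methods work", {
  ## a 5-angle grid keeps every likelihood evaluation cheap
  truth <- fixture_model("hysteresis")
  tab <- simulate_experiment(truth, experiment_design(
    groups = c(B = 1500L, C = 1500L),
    contexts = c(B = "clockwise", C = "counterclockwise"),
    n_pictures = 5), seed = 43)
  freq <- empirical_frequencies(tab)
  fit <- fit_schroeder(freq, template = truth,
                       contexts = c(B = "clockwise",
                                    C = "counterclockwise"),
                       multistart = 2, seed = 6, maxit = 800)
  expect_s3_class(fit, "schroeder_fit")
  expect_equal(fit$convergence, 0)
  expect_false(fit$underdetermined)
  expect_named(coef(fit), c("a", "b", "mu0", "mu1"))
  expect_equal(nrow(fit$starts), 2)
  expect_true(is.finite(logLik(fit)))
  ## predicted curves near the truth (probability-level recovery)
  for (ctxn in c("clockwise", "counterclockwise")) {
    pt <- context_marginal_curve(truth, ctxn, n_pictures = 5)
    pf <- predict(fit, ctxn, n_pictures = 5)
    expect_lt(max(abs(pt$p_L - pf$p_L)), 0.05)
  }
  ## residuals are small at the optimum
  expect_lt(max(abs(residuals(fit)), na.rm = TRUE), 0.05)
  ## simulate() round-trips through the fitted model
  tab2 <- simulate(fit, seed = 2, design = experiment_design(
    groups = c(B = 5L), contexts = c(B = "clockwise")))
  expect_equal(nrow(tab2), 55)
})

test_that("refitting a fit's own simulations returns the same curves", {
  ## self-consistency at the probability level, on a cheap 5-angle grid
  truth <- fixture_model("hysteresis")
  des <- experiment_design(groups = c(B = 1500L, C = 1500L),
                           contexts = c(B = "clockwise",
                                        C = "counterclockwise"),
                           n_pictures = 5)
  ctxs <- c(B = "clockwise", C = "counterclockwise")
  fit1 <- fit_schroeder(empirical_frequencies(
    simulate_experiment(truth, des, seed = 47)), template = truth,
    contexts = ctxs, multistart = 2, seed = 8, maxit = 800)
  tab2 <- simulate_experiment(fit1$model, des, seed = 48)
  fit2 <- fit_schroeder(empirical_frequencies(tab2), template = truth,
                        contexts = ctxs, multistart = 2, seed = 9,
                        maxit = 800)
  for (ctxn in ctxs) {
    p1 <- context_marginal_curve(fit1$model, ctxn, n_pictures = 5)
    p2 <- context_marginal_curve(fit2$model, ctxn, n_pictures = 5)
    expect_lt(max(abs(p1$p_L - p2$p_L)), 0.05)
  }
})

test_that("under-determined fits are flagged loudly", {
  curve <- data.frame(group = "B", angle_deg = 0, n = 20, p_L = 0.4)
  expect_warning(
    fit <- fit_schroeder(curve, contexts = c(B = "clockwise"),
                         multistart = 1, maxit = 20),
    "under-determined")
  expect_true(fit$underdetermined)
})
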