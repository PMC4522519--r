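test_that("context presets span 0-90 in the declared orders", {
  cw <- rotation_context(preset = "clockwise")
  ccw <- rotation_context(preset = "counterclockwise")
  expect_equal(cw$angles, seq(0, 90, length.out = 11))
  expect_equal(ccw$angles, rev(cw$angles))
  rnd <- rotation_context(preset = "random", seed = 5)
  expect_setequal(rnd$angles, cw$angles)
  expect_identical(rnd$angles,
                   rotation_context(preset = "random", seed = 5)$angles)
  expect_error(rotation_context(preset = "random"), "seed")
  expect_error(rotation_context(angles = numeric(0)), "nonempty")
})

test_that("sensation families return unitaries across the angle range", {
  fams <- list(sensation_family(0.3, 0.8), diagonal_phase_family(1.2),
               custom_sensation_family(function(th) rotation2(th * pi / 180)))
  for (fam in fams) for (th in seq(0, 90, by = 15)) {
    U <- fam$fn(th)
    expect_lt(max(Mod(U %*% Conj(t(U)) - diag(2))), 1e-10)
    ## batched constructor agrees with the scalar one
    expect_lt(max(Mod(fam$bfn(c(th, th + 1))[, , 1] - U)), 1e-12)
  }
})

test_that("a static model answers 50/50 forever", {
  m <- schroeder_model(family = custom_sensation_family(function(th) diag(2)),
                       interaction = unitary(diag(4)))
  run <- run_context(m, rotation_context(preset = "clockwise"))
  expect_equal(run$marginals$p_L, rep(0.5, 11), tolerance = 1e-12)
  expect_equal(sum(run$paths$probability), 1, tolerance = 1e-9)
})

test_that("equal interaction angles carry no information about sensation", {
  ## mu0 = mu1 makes the induced effects proportional to the identity, so
  ## the outcome distribution cannot depend on the sensation state
  m1 <- schroeder_model(interaction = controlled_rotation(c(0.3, 0.3)),
                        rho0 = pure_to_density(c(1, 0)))
  m2 <- schroeder_model(interaction = controlled_rotation(c(0.3, 0.3)),
                        rho0 = rand_qstate(2))
  a <- c(0, 30, 60)
  expect_equal(run_context(m1, a)$marginals$p_L,
               run_context(m2, a)$marginals$p_L, tolerance = 1e-12)
})

test_that("the branch engine reproduces the single-step reference route", {
  set.seed(61)
  for (m in list(fixture_model("hysteresis"), fixture_model("classical"),
                 schroeder_model(sensation_family(0.2, 0.9),
                                 controlled_rotation(c(-0.5, 0.9)),
                                 rho0 = rand_qstate(2),
                                 sigma0 = rand_qstate(2)))) {
    angles <- c(0, 36, 81)
    run <- run_context(m, angles)
    bp <- brute_paths(m, angles)
    keep <- run$paths$probability > 1e-12
    expect_lt(max(abs(bp[run$paths$path[keep]] -
                      run$paths$probability[keep])), 1e-10)
    expect_equal(sum(run$paths$probability), 1, tolerance = 1e-9)
    ## single-angle marginals equal single-step probabilities
    one <- run_context(m, angles[1])
    st <- perception_step(m, m$rho0, m$sigma0, angles[1])
    expect_equal(one$marginals$p_L[1], st[[1]]$probability,
                 tolerance = 1e-12)
  }
})

test_that("POVM route and composite route give the same step probabilities", {
  m <- fixture_model("hysteresis")
  rho <- rand_qstate(2); sig <- rand_qstate(2)
  theta <- 42
  rho_t <- evolve(rho, unitary(m$family$fn(theta), validate = FALSE))
  p_composite <- outcome_probabilities(run_indirect(m$scheme, rho_t, sig))
  p_povm <- measure(rho_t, induced_povm(m$scheme, sig))$probabilities
  expect_lt(max(abs(p_composite - p_povm)), 1e-12)
})

test_that("each measured step restarts from an exactly disentangled product", {
  m <- fixture_model("hysteresis")
  st <- perception_step(m, m$rho0, m$sigma0, 27)
  for (o in st) {
    if (o$probability < 1e-12) next
    comp <- qtensor(o$rho, o$sigma)
    ## a product of states has purity defect determined by its factors
    expect_equal(purity_defect(comp),
                 Re(sum(diag(o$rho$matrix %*% o$rho$matrix)) *
                    sum(diag(o$sigma$matrix %*% o$sigma$matrix))) - 1,
                 tolerance = 1e-10)
  }
})

test_that("angle-independent dynamics erases the order dependence", {
  ## with a family constant in theta the process cannot see which angle is
  ## shown, so the per-step marginal sequences of the two orders coincide:
  ## genuine theta-dependence is required for hysteresis
  m <- schroeder_model(family = sensation_family(a = 0.4, b = 0),
                       interaction = controlled_rotation(c(-pi / 8, pi / 8)),
                       rho0 = pure_to_density(c(1, 0)))
  cw <- run_context(m, rotation_context(preset = "clockwise"))$marginals
  ccw <- run_context(m, rotation_context(preset = "counterclockwise"))$marginals
  expect_lt(max(abs(cw$p_L - ccw$p_L)), 1e-10)
  ## whereas the committed hysteresis fixture does depend on the order
  h <- fixture_model("hysteresis")
  cwh <- run_context(h, rotation_context(preset = "clockwise"))$marginals
  ccwh <- run_context(h, rotation_context(preset = "counterclockwise"))$marginals
  ccwh <- ccwh[match(cwh$angle_deg, ccwh$angle_deg), ]
  expect_gt(max(abs(cwh$p_L - ccwh$p_L)), 0.1)
})

test_that("trajectory sampling is seeded, reproducible and consistent", {
  m <- fixture_model("hysteresis")
  ctx <- rotation_context(preset = "clockwise")
  t1 <- sample_trajectory(m, ctx, seed = 17)
  t2 <- sample_trajectory(m, ctx, seed = 17)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 11)
  expect_true(all(t1$outcome %in% c("L", "R")))
  expect_equal(t1$p_L + t1$p_R, rep(1, 11), tolerance = 1e-10)
  ## a deterministic model yields the all-L trajectory
  det <- schroeder_model(
    family = custom_sensation_family(function(th) diag(2)),
    interaction = unitary(diag(4)),
    sigma0 = pure_to_density(c(1, 0)))
  expect_true(all(sample_trajectory(det, ctx, seed = 3)$outcome == "L"))
  ## moderate-n empirical frequencies track the exact marginals
  oc <- sample_outcomes(m, ctx$angles, 4000, seed = 19)
  exact <- run_context(m, ctx)$marginals$p_L
  expect_lt(max(abs(colMeans(oc == "L") - exact)), 0.03)
})

test_that("exact enumeration refuses oversized contexts", {
  m <- fixture_model("hysteresis")
  expect_error(run_context(m, rep(10, 17)), "sample_outcomes")
})
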