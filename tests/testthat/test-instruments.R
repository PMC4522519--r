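test_that("projective measurement follows the Born rule and Lueders update", {
  obs <- basis_observable(2, labels = c("L", "R"))
  ## amplitudes give squared-coefficient probabilities
  c0 <- complex(real = 0.6, imaginary = 0.0); c1 <- sqrt(1 - Mod(c0)^2)
  d <- measure(pure_to_density(c(c0, c1)), obs)
  expect_equal(unname(d$probabilities), c(Mod(c0)^2, Mod(c1)^2),
               tolerance = 1e-12)
  d2 <- measure(pure_to_density(c(1, 1) / sqrt(2)), obs)
  expect_equal(unname(d2$probabilities), c(0.5, 0.5), tolerance = 1e-12)
  ## eigenstate: probability one, state unchanged
  d3 <- measure(pure_to_density(c(1, 0)), obs)
  expect_equal(d3$probabilities[["L"]], 1, tolerance = 1e-12)
  expect_equal(post_state(d3, "L")$matrix, pure_to_density(c(1, 0))$matrix)
  ## zero-probability post-state is an explicit error, not junk
  expect_error(post_state(d3, "R"), "undefined")
})

test_that("atomic instruments generalize projective ones and keep purity", {
  obs <- basis_observable(2)
  inst <- atomic_instrument(obs$projectors, labels = obs$labels)
  set.seed(23)
  for (i in 1:20) {
    rho <- rand_qstate(2)
    dp <- measure(rho, obs); da <- measure(rho, inst)
    expect_lt(max(abs(dp$probabilities - da$probabilities)), 1e-12)
    for (l in obs$labels)
      if (dp$probabilities[[l]] > 1e-12)
        expect_lt(max(Mod(post_state(dp, l)$matrix -
                          post_state(da, l)$matrix)), 1e-12)
  }
  ## single unitary outcome: probability 1, post-state U rho U*
  U <- rand_unitary(2)
  one <- atomic_instrument(list(U$matrix), labels = "u")
  rho <- rand_qstate(2)
  d <- measure(rho, one)
  expect_equal(d$probabilities[["u"]], 1, tolerance = 1e-12)
  expect_lt(max(Mod(post_state(d, "u")$matrix - evolve(rho, U)$matrix)),
            1e-12)
  ## pure in, pure out; probabilities normalized
  for (i in 1:50) {
    inst <- rand_atomic_instrument(2, 2)
    psi <- rand_qstate(2, pure = TRUE)
    d <- measure(psi, inst)
    expect_equal(sum(d$probabilities), 1, tolerance = 1e-10)
    for (l in inst$labels)
      if (d$probabilities[[l]] > 1e-10)
        expect_lt(abs(purity_defect(post_state(d, l))), 1e-10)
  }
  expect_error(atomic_instrument(list(diag(2), diag(2))), "Q\\*Q = I")
})

test_that("induced POVMs reproduce instrument probabilities", {
  obs <- basis_observable(3)
  expect_equal(as_povm(obs)$effects[[2]], obs$projectors[[2]])
  set.seed(29)
  for (i in 1:100) {
    inst <- rand_atomic_instrument(2, sample(2:3, 1))
    M <- as_povm(inst)
    tot <- Reduce(`+`, M$effects)
    expect_lt(max(Mod(tot - diag(2))), 1e-10)
    rho <- rand_qstate(2)
    expect_lt(max(abs(measure(rho, M)$probabilities -
                      measure(rho, inst)$probabilities)), 1e-12)
  }
})

test_that("sequential composition obeys the quantum Bayes chain", {
  obs <- basis_observable(2, labels = c("L", "R"))
  set.seed(31)
  rho <- rand_qstate(2)
  ## identity-like second measurement marginalizes to the first
  idinst <- atomic_instrument(list(diag(2)), labels = "ok")
  j <- compose_sequential(rho, obs, idinst)
  expect_equal(unname(j$probabilities),
               unname(measure(rho, obs)$probabilities), tolerance = 1e-12)
  ## projective repeatability: off-diagonal pairs vanish
  j2 <- compose_sequential(rho, obs, obs)
  expect_lt(j2$probabilities[["L.R"]], 1e-14)
  expect_lt(j2$probabilities[["R.L"]], 1e-14)
  expect_equal(sum(j2$probabilities), 1, tolerance = 1e-10)
  ## non-projective atomic: repeated-outcome probability differs from the
  ## marginal (no repeatability).  Hand-built unsharp pair.
  s <- sqrt(c(0.8, 0.2)); t <- sqrt(c(0.2, 0.8))
  inst <- atomic_instrument(list(diag(s) + 0i, diag(t) + 0i),
                            labels = c("L", "R"))
  rho <- qstate(diag(c(0.5, 0.5)) + 0i)
  jj <- compose_sequential(rho, inst, inst)
  marg1 <- measure(rho, inst)$probabilities[["L"]]
  expect_gt(abs(jj$probabilities[["L.L"]] / marg1 - marg1), 0.05)
  expect_equal(sum(jj$probabilities), 1, tolerance = 1e-10)
  ## chain probabilities sum to one over random instruments
  for (i in 1:25) {
    r <- rand_qstate(2)
    a <- rand_atomic_instrument(2, 2); b <- rand_atomic_instrument(2, 3)
    expect_equal(sum(compose_sequential(r, a, b)$probabilities), 1,
                 tolerance = 1e-10)
  }
})

test_that("outcome probabilities are affine in the state (mixing law)", {
  set.seed(37)
  for (i in 1:50) {
    r1 <- rand_qstate(2); r2 <- rand_qstate(2); q <- runif(1)
    expect_lt(mixing_law_residual(rand_atomic_instrument(2, 2), r1, r2, q),
              1e-10)
    expect_lt(mixing_law_residual(basis_observable(2), r1, r2, q), 1e-10)
    expect_lt(mixing_law_residual(rand_dl_instrument(2, 2, 2), r1, r2, q),
              1e-10)
  }
  ## degenerate weight: residual identically 0
  expect_equal(mixing_law_residual(basis_observable(2), rand_qstate(2),
                                   rand_qstate(2), 1), 0)
})

test_that("Davies-Lewis maps preserve trace, add over subsets, and can mix", {
  set.seed(41)
  inst <- rand_dl_instrument(2, 3, 2, labels = c("a", "b", "c"))
  rho <- rand_qstate(2)
  ## empty subset: zero operator; full set: trace preserved
  expect_equal(dl_apply(inst, rho, character(0)), matrix(0 + 0i, 2, 2))
  expect_equal(Re(sum(diag(dl_apply(inst, rho)))), 1, tolerance = 1e-10)
  ## additivity over disjoint subsets
  expect_lt(max(Mod(dl_apply(inst, rho, c("a", "b")) -
                    dl_apply(inst, rho, "a") - dl_apply(inst, rho, "b"))),
            1e-15)
  expect_error(dl_apply(inst, rho, "z"), "unknown outcome")
  ## built from an atomic instrument: reproduces it bit-for-bit
  at <- rand_atomic_instrument(2, 2, labels = c("L", "R"))
  dl <- as_dl_instrument(at)
  expect_identical(dl_apply(dl, rho, "L"),
                   at$kraus[["L"]] %*% rho$matrix %*% Conj(t(at$kraus[["L"]])))
  expect_identical(measure(rho, dl)$probabilities,
                   measure(rho, at)$probabilities)
  ## a two-component outcome can send a pure state to a mixed one
  mixer <- dl_instrument(list(
    yes = list(diag(c(1, 0)) / sqrt(2), diag(c(0, 1)) / sqrt(2)),
    no = list(diag(2) / sqrt(2))))
  d <- measure(pure_to_density(c(1, 1) / sqrt(2)), mixer)
  expect_lt(purity_defect(post_state(d, "yes")), -1e-6)
})

test_that("the DL-adjoint POVM agrees with map traces for every state", {
  set.seed(43)
  ## projective case: effects are the projectors themselves
  obs <- basis_observable(2)
  dlp <- dl_instrument(lapply(obs$projectors, list), labels = obs$labels)
  M <- as_povm(dlp)
  expect_lt(max(Mod(M$effects[[1]] - obs$projectors[[1]])), 1e-12)
  for (i in 1:100) {
    inst <- rand_dl_instrument(2, 2, sample(1:3, 1))
    M <- as_povm(inst)
    expect_lt(max(Mod(Reduce(`+`, M$effects) - diag(2))), 1e-10)
    rho <- rand_qstate(2)
    for (l in inst$labels)
      expect_equal(Re(sum(diag(M$effects[[l]] %*% rho$matrix))),
                   Re(sum(diag(dl_apply(inst, rho, l)))), tolerance = 1e-10)
  }
})
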