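test_that("pure states project to valid rank-1 density operators", {
  expect_equal(pure_to_density(pure_state(c(1, 0)))$matrix,
               matrix(c(1, 0, 0, 0), 2) + 0i)
  expect_equal(pure_to_density(pure_state(c(1, 1) / sqrt(2)))$matrix,
               matrix(0.5, 2, 2) + 0i)
  ## idempotence and zero purity defect for arbitrary valid pure states
  set.seed(101)
  for (i in 1:20) {
    d <- sample(2:4, 1)
    rho <- rand_qstate(d, pure = TRUE)
    expect_lt(max(Mod(rho$matrix %*% rho$matrix - rho$matrix)), 1e-12)
    expect_lt(abs(purity_defect(rho)), 1e-12)
    expect_no_error(validate_qstate(rho))
  }
  expect_error(pure_state(c(1, 1)), "normalized")
})

test_that("purity defect separates pure from mixed states", {
  expect_equal(purity_defect(qstate(diag(2) / 2)), -0.5)
  expect_equal(purity_defect(qstate(diag(c(0.75, 0.25)) + 0i)), -0.375)
  ## equal mixture of two distinct pure states is strictly mixed
  mix <- mix_states(list(pure_to_density(c(1, 0)),
                         pure_to_density(c(1, 1) / sqrt(2))),
                    c(0.5, 0.5))
  expect_lt(purity_defect(mix), -1e-3)
  expect_false(is_pure(mix))
})

test_that("mixtures are convex combinations with validated weights", {
  b0 <- pure_to_density(c(1, 0)); b1 <- pure_to_density(c(0, 1))
  expect_equal(mix_states(list(b0, b1), c(0.5, 0.5))$matrix,
               diag(2) / 2 + 0i)
  expect_equal(mix_states(list(b0, b1), c(1, 0))$matrix, b0$matrix)
  expect_error(mix_states(list(b0, b1), c(0.6, 0.6)), "sum to 1")
  expect_error(mix_states(list(b0, qstate(diag(3) / 3)), c(0.5, 0.5)),
               "dimension")
})

test_that("tensor and partial trace are mutually inverse on product states", {
  set.seed(7)
  for (i in 1:25) {
    a <- rand_qstate(2); b <- rand_qstate(2)
    R <- qtensor(a, b)
    expect_equal(Re(sum(diag(R$matrix))), 1, tolerance = 1e-12)
    expect_lt(max(Mod(partial_trace(R, 1)$matrix - a$matrix)), 1e-12)
    expect_lt(max(Mod(partial_trace(R, 2)$matrix - b$matrix)), 1e-12)
  }
  ## pure x pure is pure
  pp <- qtensor(rand_qstate(2, pure = TRUE), rand_qstate(3, pure = TRUE))
  expect_lt(abs(purity_defect(pp)), 1e-12)
})

test_that("partial trace matches the summation oracle and handles entanglement", {
  bell <- pure_to_density(c(1, 0, 0, 1) / sqrt(2), dims = c(2, 2))
  expect_lt(max(Mod(partial_trace(bell, 1)$matrix - diag(2) / 2)), 1e-12)
  expect_lt(max(Mod(partial_trace(bell, 2)$matrix - diag(2) / 2)), 1e-12)
  set.seed(11)
  for (i in 1:100) {
    R <- rand_qstate(4, dims = c(2, 2))
    for (keep in 1:2) {
      red <- partial_trace(R, keep)
      expect_lt(max(Mod(red$matrix - ptrace_oracle(R$matrix, c(2, 2), keep))),
                1e-12)
      expect_equal(Re(sum(diag(red$matrix))), 1, tolerance = 1e-12)
      expect_no_error(validate_qstate(red))
    }
  }
  ## unequal factor dimensions
  R <- qtensor(rand_qstate(3), rand_qstate(2))
  expect_lt(max(Mod(partial_trace(R, 2)$matrix -
                    ptrace_oracle(R$matrix, c(3, 2), 2))), 1e-12)
  expect_error(partial_trace(rand_qstate(4), 1), "tensor structure")
})

test_that("unitary conjugation preserves spectrum, trace and purity", {
  rho <- qstate(diag(c(0.6, 0.4)) + 0i)
  expect_equal(evolve(rho, unitary(diag(2)))$matrix, rho$matrix)
  set.seed(13)
  for (i in 1:100) {
    d <- sample(2:3, 1)
    rho <- rand_qstate(d); U <- rand_unitary(d)
    out <- evolve(rho, U)
    expect_equal(purity_defect(out), purity_defect(rho), tolerance = 1e-10)
    ev_in <- sort(eigen(rho$matrix, symmetric = TRUE, only.values = TRUE)$values)
    ev_out <- sort(eigen(out$matrix, symmetric = TRUE, only.values = TRUE)$values)
    expect_lt(max(abs(ev_in - ev_out)), 1e-10)
  }
  expect_error(evolve(rand_qstate(2), rand_unitary(3)), "mismatch")
})

test_that("state validation rejects malformed density operators", {
  expect_error(qstate(diag(2)), "trace 1")
  expect_error(qstate(matrix(c(0.5, 0.3, 0.1, 0.5), 2)), "Hermitian")
  expect_error(qstate(diag(c(1.2, -0.2)) + 0i), "not positive")
  expect_error(unitary(matrix(1:4, 2)), "not unitary")
  ## opt-out skips checks (for internal chains)
  expect_silent(qstate(diag(2), validate = FALSE))
})
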