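test_that("the Hamiltonian is the tridiagonal crystal matrix", {
  spec <- lattice_spec()
  expect_equal(quantum_hamiltonian(spec, 0, 0), matrix(0, 99, 99))
  H <- quantum_hamiltonian(spec, 99.24, -14.57)
  expect_equal(H[99, 99], -14.57)           # potential reaches beta at i = N
  expect_equal(H[1, 1], -14.57 / 99)
  expect_equal(H, t(H))
  expect_equal(H[12, 13], 99.24)
  expect_equal(max(abs(H[abs(row(H) - col(H)) > 1])), 0)
  expect_error(quantum_hamiltonian(spec, NA, 1), "finite")
})

test_that("propagators are unitary and preserve the initial norm", {
  spec <- lattice_spec()
  expect_equal(quantum_unitary(matrix(0, 6, 6)), diag(6) + 0i)
  set.seed(31)
  psi0 <- initial_state(spec, "amplitude")
  for (i in 1:4) {
    p <- rand_params("quantum", runif(4))
    U <- quantum_unitary(quantum_hamiltonian(spec, p[1], p[2]))
    expect_lt(max(Mod(Conj(t(U)) %*% U - diag(99))), 1e-10)
    expect_equal(sum(Mod(U %*% psi0)^2), 1, tolerance = 1e-12)
  }
  expect_error(quantum_unitary(matrix(1:9, 3, 3)), "symmetric")
})

test_that("the spectral propagator matches a series-expansion exponential", {
  H <- matrix(0, 5, 5)
  for (j in 1:4) { H[j, j + 1] <- 1; H[j + 1, j] <- 1 }
  diag(H) <- 2 * (1:5) / 5
  expect_lt(max(Mod(quantum_unitary(H) - taylor_expm(-1i * H))), 1e-10)
})

test_that("joint tables normalise and same-basis questions repeat the answer", {
  spec <- lattice_spec()
  set.seed(41)
  for (i in 1:3) {
    p <- rand_params("quantum", runif(4))
    J <- quantum_joint(spec, p, sample(c("self_first", "other_first"), 1))
    expect_equal(sum(J), 1)
    expect_true(all(as.matrix(J) >= 0))
  }
  # identical Hamiltonians: measuring twice in the same basis is consistent
  J <- quantum_joint(spec, c(alpha_s = 70, beta_s = -10, alpha_o = 70, beta_o = -10),
                     "self_first")
  expect_lt(max(abs(as.matrix(J) - diag(diag(as.matrix(J))))), 1e-12)
})

test_that("the first-question marginal ignores the second question's basis", {
  spec <- lattice_spec()
  J1 <- quantum_joint(spec, c(alpha_s = 80, beta_s = -20, alpha_o = 10, beta_o = 5),
                      "self_first")
  J2 <- quantum_joint(spec, c(alpha_s = 80, beta_s = -20, alpha_o = 200, beta_o = -90),
                      "self_first")
  expect_equal(rowSums(as.matrix(J1)), rowSums(as.matrix(J2)), tolerance = 1e-12)
})

test_that("the between-question transition kernel is doubly stochastic", {
  # a quantum-specific signature the Markov walk lacks: squared moduli of
  # the basis-change unitary sum to one along rows and columns
  spec <- lattice_spec()
  p <- est_params("sse", "quantum")$params
  Us <- quantum_unitary(quantum_hamiltonian(spec, p[["alpha_s"]], p[["beta_s"]]))
  Uo <- quantum_unitary(quantum_hamiltonian(spec, p[["alpha_o"]], p[["beta_o"]]))
  W <- Mod(Uo %*% Conj(t(Us)))^2
  expect_lt(max(abs(rowSums(W) - 1)), 1e-10)
  expect_lt(max(abs(colSums(W) - 1)), 1e-10)
})

test_that("question order changes the joint distribution at the reference basis pair", {
  spec <- lattice_spec()
  p <- est_params("sse", "quantum")$params
  Jsf <- as.matrix(quantum_joint(spec, p, "self_first"))
  Jof <- as.matrix(quantum_joint(spec, p, "other_first"))
  expect_gt(max(abs(Jsf - t(Jof))), 0.001)
})

test_that("the walk agrees with an independent brute-force product at N = 9", {
  s9 <- lattice_spec(9L, 1L)
  for (pr in list(c(alpha_s = 1.2, beta_s = 2.5, alpha_o = 0.8, beta_o = -1.5),
                  c(alpha_s = 5, beta_s = -3, alpha_o = 4, beta_o = 2)))
    for (ord in c("self_first", "other_first"))
      expect_lt(max(abs(as.matrix(quantum_joint(s9, pr, ord)) -
                          oracle_quantum_joint9(pr, ord))), 1e-10)
})
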