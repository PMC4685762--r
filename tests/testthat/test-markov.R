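test_that("the intensity matrix is the hand-derived birth-death generator", {
  s3 <- lattice_spec(3L, 1L)
  K <- markov_intensity(s3, 2, 1)
  # written out by hand for 3 states: column j carries rate 2 toward the
  # low end and rate 1 toward the high end, reflecting at both ends
  expect_equal(K, rbind(c(-1, 2, 0),
                        c(1, -3, 2),
                        c(0, 1, -2)))
  expect_equal(markov_intensity(lattice_spec(), 0, 0), matrix(0, 99, 99))
  expect_error(markov_intensity(lattice_spec(), -1, 2), "nonnegative")
})

test_that("generators conserve probability and propagators are column-stochastic", {
  spec <- lattice_spec()
  set.seed(11)
  for (i in 1:5) {
    r <- runif(2, 0, 400)
    K <- markov_intensity(spec, r[1], r[2])
    expect_equal(max(abs(colSums(K))), 0)
    P <- markov_propagator(K)
    expect_true(all(P >= 0))
    expect_lt(max(abs(colSums(P) - 1)), 1e-10)
  }
  expect_equal(markov_propagator(matrix(0, 4, 4)), diag(4))
  expect_error(markov_propagator(matrix(1, 3, 3)), "generator")
})

test_that("the propagator matches an event-level simulation of the chain", {
  s3 <- lattice_spec(3L, 1L)
  P <- markov_propagator(markov_intensity(s3, 2, 1))
  set.seed(402)
  nsim <- 300000
  for (from in 1:3) {
    freq <- gillespie_ctmc(3, 2, 1, from, nsim)
    se <- sqrt(P[, from] * (1 - P[, from]) / nsim)
    expect_true(all(abs(freq - P[, from]) <= 3 * se + 1e-12))
  }
})

test_that("joint tables normalise and degenerate cases collapse correctly", {
  spec <- lattice_spec()
  set.seed(21)
  for (i in 1:3) {
    p <- rand_params("markov", runif(4))
    J <- markov_joint(spec, p, sample(c("self_first", "other_first"), 1))
    expect_s3_class(J, "joint_table")
    expect_equal(sum(J), 1)
    expect_true(all(as.matrix(J) >= 0))
  }
  # frozen second question: the second answer always repeats the first
  J <- markov_joint(spec, c(alpha_s = 30, beta_s = 20, alpha_o = 0, beta_o = 0),
                    "self_first")
  expect_lt(max(abs(as.matrix(J) - diag(diag(as.matrix(J))))), 1e-12)
})

test_that("the first-question marginal ignores the second question's rates", {
  spec <- lattice_spec()
  J1 <- markov_joint(spec, c(alpha_s = 40, beta_s = 35, alpha_o = 10, beta_o = 90),
                     "self_first")
  J2 <- markov_joint(spec, c(alpha_s = 40, beta_s = 35, alpha_o = 300, beta_o = 2),
                     "self_first")
  expect_equal(rowSums(as.matrix(J1)), rowSums(as.matrix(J2)), tolerance = 1e-12)
})

test_that("drift direction follows the rate imbalance", {
  spec <- lattice_spec()
  neutral <- spec$neutral_rating
  # balanced rates: symmetric first marginal, mean at the scale midpoint
  Jb <- markov_joint(spec, c(alpha_s = 50, beta_s = 50, alpha_o = 50, beta_o = 50),
                     "self_first")
  m <- unname(rowSums(as.matrix(Jb)))
  expect_equal(m, rev(m), tolerance = 1e-9)
  expect_equal(table_means(Jb)[["first"]], neutral, tolerance = 1e-9)
  # excess upward rate pushes the mean above neutral, excess downward below
  Ju <- markov_joint(spec, c(alpha_s = 20, beta_s = 60, alpha_o = 50, beta_o = 50),
                     "self_first")
  expect_gt(table_means(Ju)[["first"]], neutral)
  Jd <- markov_joint(spec, c(alpha_s = 60, beta_s = 20, alpha_o = 50, beta_o = 50),
                     "self_first")
  expect_lt(table_means(Jd)[["first"]], neutral)
})

test_that("question order changes the joint distribution for unequal rates", {
  spec <- lattice_spec()
  p <- est_params("sse", "markov")$params
  Jsf <- as.matrix(markov_joint(spec, p, "self_first"))
  Jof <- as.matrix(markov_joint(spec, p, "other_first"))
  expect_gt(max(abs(Jsf - t(Jof))), 1e-4)
})

test_that("the walk agrees with independent oracles", {
  # eigendecomposition-based exponential at the reference rates, full lattice
  spec <- lattice_spec()
  p <- est_params("sse", "markov")$params
  eig_propagator <- function(a, b) {
    K <- oracle_generator(99, a, b)
    e <- eigen(K)
    Re(e$vectors %*% (exp(e$values) * solve(e$vectors)))
  }
  Ts <- eig_propagator(p[["alpha_s"]], p[["beta_s"]])
  To <- eig_propagator(p[["alpha_o"]], p[["beta_o"]])
  p0 <- initial_state(spec, "probability")
  Jor <- matrix(0, 9, 9)
  for (j in 1:9) {
    v <- as.vector(Ts %*% p0)
    v[-(rating_block(spec, j)[1]:rating_block(spec, j)[2])] <- 0
    w <- as.vector(To %*% v)
    for (k in 1:9)
      Jor[j, k] <- sum(w[rating_block(spec, k)[1]:rating_block(spec, k)[2]])
  }
  expect_lt(max(abs(as.matrix(markov_joint(spec, p, "self_first")) - Jor)), 1e-8)

  # explicit operator products on the degenerate one-state-per-rating lattice
  s9 <- lattice_spec(9L, 1L)
  pr <- c(alpha_s = 2, beta_s = 3, alpha_o = 1.5, beta_o = 0.5)
  for (ord in c("self_first", "other_first"))
    expect_lt(max(abs(as.matrix(markov_joint(s9, pr, ord)) -
                        oracle_markov_joint9(pr, ord))), 1e-10)
  # motionless chain: everything stays at the neutral state, exactly
  J0 <- as.matrix(markov_joint(s9, c(alpha_s = 0, beta_s = 0,
                                     alpha_o = 0, beta_o = 0), "self_first"))
  expect_equal(J0[5, 5], 1)
  expect_equal(sum(J0), 1)
})

test_that("the posterior after the first answer is a normalised block distribution", {
  spec <- lattice_spec()
  p <- c(alpha_s = 40, beta_s = 35, alpha_o = 10, beta_o = 12)
  post <- markov_posterior(spec, p, "self_first", k = 7)
  expect_equal(sum(post), 1)
  expect_true(all(post[-(rating_block(spec, 7)[1]:rating_block(spec, 7)[2])] == 0))
})
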