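# a cheap control for fits inside the test suite; the optimiser structure
# is identical to the default, just with fewer starts and iterations
fast_ctl <- function(seed = 20160113)
  walk_fit_control(seed = seed, n_lhs = 8, grid_n = 12, n_grid_top = 3,
                   polish_top = 4, final_polish = 1, maxit = 600)

test_that("the SSE objective and its R-squared follow their definitions", {
  obs <- psa_obs
  expect_equal(sse_objective(obs, obs), list(sse = 0, tss = sse_objective(obs, obs)$tss, r2 = 1))
  # predicting every cell at the table's own mean scores exactly zero
  u <- lapply(obs, function(t)
    joint_table(matrix(1 / 81, 9, 9), attr(t, "order"), "probability"))
  expect_equal(sse_objective(obs, u)$r2, 0, tolerance = 1e-10)
  expect_error(sse_objective(obs, u["self_first"]), "different question orders")
})

test_that("the G-squared statistic is a proper lack-of-fit measure", {
  set.seed(13)
  cnt <- matrix(rpois(81, 9) + 1, 9, 9)
  obs <- joint_table(cnt, "self_first", "count")
  sat <- joint_table(cnt / sum(cnt), "self_first", "probability")
  expect_equal(g2_statistic(obs, sat), 0, tolerance = 1e-10)
  p <- matrix(rexp(81), 9, 9); p <- p / sum(p)
  mod <- joint_table(p, "self_first", "probability")
  g1 <- g2_statistic(obs, mod)
  expect_gt(g1, 0)
  # linear in the counts at fixed model probabilities
  expect_equal(g2_statistic(joint_table(2 * cnt, "self_first", "count"), mod),
               2 * g1, tolerance = 1e-10)
  # nonnegative for arbitrary models (information inequality)
  set.seed(14)
  for (i in 1:5) {
    q <- matrix(rexp(81), 9, 9); q <- q / sum(q)
    expect_gte(g2_statistic(obs, joint_table(q, "self_first", "probability")), 0)
  }
  # pure evaluation: identical inputs give bit-identical values
  expect_identical(g2_statistic(obs, mod), g1)
  expect_error(g2_statistic(sat, mod), "sample size")
})

test_that("fits are deterministic given the seed and expose their methods", {
  f1 <- walk_fit(psa_obs, model = "markov", objective = "sse",
                 control = fast_ctl())
  f2 <- walk_fit(psa_obs, model = "markov", objective = "sse",
                 control = fast_ctl())
  expect_identical(coef(f1), coef(f2))
  expect_s3_class(f1, "walk_fit")
  expect_named(coef(f1), c("alpha_s", "beta_s", "alpha_o", "beta_o", "lambda"))
  expect_true(all(coef(f1)[1:4] > 0))
  expect_true(coef(f1)[["lambda"]] >= 0 && coef(f1)[["lambda"]] <= 1)
  expect_lte(f1$fit_statistic[["r2"]], 1)
  expect_output(print(f1), "markov walk fit")
  expect_output(print(summary(f1)), "Per-table fit")
  res <- residuals(f1)
  expect_equal(names(res), c("self_first", "other_first"))
  expect_lt(max(abs(res$self_first)), 1)
  pm <- predict(f1, type = "means")
  expect_equal(dim(pm), c(2L, 2L))
  pt <- predict(f1, order = "self_first")
  expect_s3_class(pt, "joint_table")
  expect_equal(sum(pt), 1)
  expect_error(logLik(f1), "likelihood")
})

test_that("likelihood fits report G-squared and a log likelihood", {
  f <- walk_fit(psa_obs, model = "markov", objective = "likelihood",
                control = fast_ctl())
  expect_gte(f$fit_statistic[["g2"]], 0)
  ll <- logLik(f)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), 5L)
  # G2 is twice the gap to the saturated log likelihood
  sat <- sum(vapply(psa_obs, function(t) {
    cnt <- as.matrix(t) / sum(as.matrix(t)) * attr(t, "n")
    sum(cnt[cnt > 0] * log(cnt[cnt > 0] / sum(cnt)))
  }, numeric(1)))
  expect_equal(f$fit_statistic[["g2"]], 2 * (sat - as.numeric(ll)),
               tolerance = 1e-6)
  expect_error(walk_fit(lapply(psa_obs, function(t)
    joint_table(as.matrix(t) / sum(as.matrix(t)), attr(t, "order"), "probability")),
    model = "markov", objective = "likelihood", control = fast_ctl()),
    "sample size")
})

test_that("a fixed unit mixture weight yields the 4-parameter model", {
  f <- walk_fit(psa_obs$self_first, model = "markov", objective = "sse",
                lambda = 1, control = fast_ctl())
  expect_equal(coef(f)[["lambda"]], 1)
  expect_gt(f$fit_statistic[["r2"]], 0.5)
})
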