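#' Sum-of-squared-error objective and R-squared
#'
#' Squared discrepancy between observed and model joint tables, summed over
#' all cells of all supplied orders, together with its R-squared
#' `1 - SSE/TSS`.  The total sum of squares is taken around each table's own
#' mean cell value, so a model that predicts nothing but each table's mean
#' scores exactly zero.
#'
#' @param obs A [joint_table()] or list of them (observed, any kind; counts
#'   and relative frequencies are converted to proportions).
#' @param pred Matching probability-kind table(s) in the same order.
#' @return List with `sse`, `tss` and `r2`.
#' @export
sse_objective <- function(obs, pred) {
  obs <- as_table_list(obs)
  pred <- as_table_list(pred)
  align_orders(obs, pred)
  sse <- 0; tss <- 0
  for (ord in names(obs)) {
    o <- as_proportions(obs[[ord]])
    p <- as_proportions(pred[[ord]])
    sse <- sse + sum((o - p)^2)
    tss <- tss + sum((o - mean(o))^2)
  }
  list(sse = sse, tss = tss, r2 = 1 - sse / tss)
}

#' G-squared lack-of-fit statistic
#'
#' Likelihood-ratio discrepancy between observed counts and model
#' probabilities, relative to the saturated multinomial model (one free
#' probability per cell per table): `G2 = 2 * sum n_cell * log(phat / p)`,
#' where `phat` is the observed cell proportion within its table.  Cells
#' with zero observed count contribute nothing; model probabilities are
#' floored at `1e-12`, and a nonpositive model probability facing a
#' positive count yields `Inf`.  Counts need not be integers: tables
#' reconstructed from printed percentages enter as `percent / 100 * n`.
#'
#' @param obs A count- or relative-frequency-kind [joint_table()] (with
#'   sample size) or list of them.
#' @param pred Matching probability-kind table(s).
#' @return The G-squared statistic (nonnegative scalar).
#' @export
g2_statistic <- function(obs, pred) {
  obs <- as_table_list(obs)
  pred <- as_table_list(pred)
  align_orders(obs, pred)
  g2 <- 0
  for (ord in names(obs)) {
    cnt <- as_counts(obs[[ord]])
    n <- sum(cnt)
    if (n <= 0) stop("observed table for order ", ord, " has zero total count")
    p <- as_proportions(pred[[ord]])
    pos <- cnt > 0
    if (any(p[pos] <= 0)) return(Inf)
    p <- pmax(p, 1e-12)
    g2 <- g2 + 2 * sum(cnt[pos] * log((cnt[pos] / n) / p[pos]))
  }
  g2
}

# ---- fitting -------------------------------------------------------------

#' Optimiser settings for [walk_fit()]
#'
#' The objective surfaces -- especially the quantum one -- are cheap but
#' multimodal, so the fit combines three kinds of Nelder--Mead starting
#' points: (i) a deterministic coarse grid over each question's two dynamic
#' parameters, scored against that question's first-rating marginal (which
#' depends on those two parameters alone); (ii) seeded Latin-hypercube draws
#' over the full parameter box; (iii) the cross of the best grid cells of
#' the two questions.  The most promising starts are polished with
#' Nelder--Mead, and the best few survivors are polished again.
#'
#' @param seed Integer seed for the Latin-hypercube stage (the grid stage is
#'   deterministic).
#' @param n_lhs Number of Latin-hypercube starts.
#' @param grid_n Number of grid points per parameter axis in the
#'   marginal-screen stage; `0` disables the grid stage and `NULL` (default)
#'   resolves per model: 41 for the oscillatory quantum surface, 21 for the
#'   smooth Markov one.
#' @param n_grid_top Grid cells kept per question.
#' @param polish_top Number of candidate starts polished with Nelder--Mead;
#'   `NULL` (default) resolves per model: every candidate for the quantum
#'   walk (whose objective evaluations are cheap and whose surface is
#'   multimodal), the best 10 for the Markov walk (costlier matrix
#'   exponentials, well-behaved surface).
#' @param final_polish Number of polished fits re-polished from their own
#'   optimum.
#' @param maxit,reltol Passed to [stats::optim()] (Nelder--Mead).
#' @param rate_range Search box for Markov intensities (log-spaced).
#' @param alpha_range,beta_range Search box for the quantum coupling and
#'   potential slope.
#' @param lambda_range Search box for the mixture weight.
#' @return A list of class `"walk_fit_control"`.
#' @export
walk_fit_control <- function(seed = 20160113, n_lhs = 20, grid_n = NULL,
                             n_grid_top = 5, polish_top = NULL, final_polish = 4,
                             maxit = 800, reltol = 1e-9,
                             rate_range = c(1, 1000),
                             alpha_range = c(1, 300),
                             beta_range = c(-100, 100),
                             lambda_range = c(0.5, 1)) {
  ctl <- list(seed = as.integer(seed), n_lhs = n_lhs, grid_n = grid_n,
              n_grid_top = n_grid_top, polish_top = polish_top,
              final_polish = final_polish, maxit = maxit, reltol = reltol,
              rate_range = rate_range, alpha_range = alpha_range,
              beta_range = beta_range, lambda_range = lambda_range)
  class(ctl) <- "walk_fit_control"
  ctl
}

# internal parameter transforms: Markov rates live on the log scale,
# quantum parameters are unconstrained, lambda is logit-transformed.
par_to_natural <- function(par, model, lambda_fixed) {
  th <- if (model == "markov") exp(par[1:4]) else par[1:4]
  names(th) <- c("alpha_s", "beta_s", "alpha_o", "beta_o")
  lam <- if (is.null(lambda_fixed)) stats::plogis(par[5]) else lambda_fixed
  c(th, lambda = unname(lam))
}

# first-question transition operator and rating marginal (model-specific)
first_marginal <- function(model, spec, a, b, init) {
  if (model == "markov") {
    P <- markov_propagator(markov_intensity(spec, a, b))
    v <- as.vector(P %*% init)
  } else {
    U <- quantum_unitary(quantum_hamiltonian(spec, a, b))
    v <- Mod(as.vector(U %*% init))^2
  }
  vapply(seq_len(spec$n_ratings),
         function(k) sum(v[block_index(spec, k)]), numeric(1))
}

# both predicted tables (mixture applied) at natural parameters
predict_tables <- function(model, spec, theta, orders) {
  out <- lapply(orders, function(ord) {
    walk_joint(model, theta[1:4], ord, lambda = theta[["lambda"]], spec = spec)
  })
  names(out) <- orders
  out
}

#' Fit a walk model to one or two joint rating tables
#'
#' Estimates the four dynamic parameters (self and other intensity pairs
#' for the Markov walk; self and other Hamiltonian pairs for the quantum
#' walk) and, unless fixed, the non-judgemental mixture weight `lambda`,
#' jointly against the supplied order-conditioned tables.  Two objectives
#' are available: `"sse"` minimises the summed squared cell discrepancy
#' (reported as R-squared), and `"likelihood"` maximises the multinomial
#' log likelihood of the observed counts (reported as the G-squared
#' lack-of-fit against the saturated model).  Markov intensities are kept
#' positive through a log transform and `lambda` is kept in `[0, 1]` through
#' a logit transform; optimisation is multi-start Nelder--Mead and is
#' deterministic given `control$seed`.
#'
#' @param data A [joint_table()] or a list of one table per question order.
#'   The likelihood objective requires count or relative-frequency tables
#'   carrying sample sizes.
#' @param model `"quantum"` or `"markov"`.
#' @param objective `"sse"` or `"likelihood"`.
#' @param spec A [lattice_spec()].
#' @param lambda `NULL` to estimate the mixture weight, or a fixed value in
#'   `[0, 1]` (1 switches the mixture off, leaving a 4-parameter model).
#' @param control A [walk_fit_control()].
#'
#' @return An object of class `"walk_fit"` with, among others, elements
#'   `par` (named natural-scale estimates), `value` (attained objective),
#'   `fit_statistic` (named `r2` or `g2`), `fitted` (predicted tables) and
#'   `convergence`.  Supported methods: `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `predict`, `plot`, `simulate` and (for
#'   likelihood fits) `logLik`.
#'
#' @examples
#' \donttest{
#' obs <- psa_tables()
#' fit <- walk_fit(obs, model = "markov", objective = "sse",
#'                 control = walk_fit_control(n_lhs = 5, grid_n = 10))
#' fit
#' }
#' @export
walk_fit <- function(data, model = c("quantum", "markov"),
                     objective = c("sse", "likelihood"),
                     spec = lattice_spec(), lambda = NULL,
                     control = walk_fit_control()) {
  model <- match.arg(model)
  objective <- match.arg(objective)
  stopifnot(inherits(control, "walk_fit_control"))
  obs <- as_table_list(data)
  orders <- names(obs)
  if (!is.null(lambda) && (lambda < 0 || lambda > 1))
    stop("fixed 'lambda' must lie in [0, 1]")
  if (objective == "likelihood")
    lapply(obs, as_counts)  # fails early on probability-kind input

  # soft box: the simplex occasionally wanders into numerically absurd
  # regions (huge intensities make the exponential expensive and the
  # propagator indistinguishable from its stationary limit); penalise
  # instead of evaluating
  box_lo <- c(rep(if (model == "markov") log(1e-4) else -1e4, 4), -50)
  box_hi <- c(rep(if (model == "markov") log(1e4) else 1e4, 4), 50)
  objfun <- function(par) {
    k <- seq_along(par)
    if (any(par < box_lo[k]) || any(par > box_hi[k])) return(1e10)
    theta <- par_to_natural(par, model, lambda)
    pred <- predict_tables(model, spec, theta, orders)
    v <- if (objective == "sse") sse_objective(obs, pred)$sse
         else g2_statistic(obs, pred)
    if (!is.finite(v)) 1e10 else v
  }

  grid_n <- control$grid_n %||% if (model == "quantum") 41L else 21L
  n_dyn <- 4L
  n_par <- n_dyn + is.null(lambda)
  a_rng <- if (model == "markov") log(control$rate_range) else control$alpha_range
  b_rng <- if (model == "markov") log(control$rate_range) else control$beta_range
  lam_mid <- mean(control$lambda_range)

  # -- stage 1: seeded Latin-hypercube starts over the full box
  set.seed(control$seed)
  L <- lhs::randomLHS(max(control$n_lhs, 2L), n_par)
  starts <- cbind(a_rng[1] + diff(a_rng) * L[, 1],
                  b_rng[1] + diff(b_rng) * L[, 2],
                  a_rng[1] + diff(a_rng) * L[, 3],
                  b_rng[1] + diff(b_rng) * L[, 4])
  if (is.null(lambda))
    starts <- cbind(starts, stats::qlogis(
      control$lambda_range[1] + diff(control$lambda_range) * 0.998 * L[, 5] + 0.001))

  # -- stage 2: deterministic marginal grid per question
  if (grid_n > 0) {
    ag <- seq(a_rng[1], a_rng[2], length.out = grid_n)
    bg <- seq(b_rng[1], b_rng[2], length.out = grid_n)
    grid <- as.matrix(expand.grid(a = ag, b = bg))
    init <- initial_state(spec, if (model == "markov") "probability" else "amplitude")
    lam0 <- if (is.null(lambda)) lam_mid else lambda
    top <- lapply(orders, function(ord) {
      m_obs <- rowSums(as_proportions(obs[[ord]]))
      score <- apply(grid, 1, function(g) {
        a <- if (model == "markov") exp(g[1]) else g[1]
        b <- if (model == "markov") exp(g[2]) else g[2]
        m <- first_marginal(model, spec, a, b, init)
        m <- lam0 * m
        m[spec$neutral_rating] <- m[spec$neutral_rating] + (1 - lam0)
        sum((m - m_obs)^2)
      })
      grid[order(score)[seq_len(control$n_grid_top)], , drop = FALSE]
    })
    names(top) <- orders
    top_s <- if ("self_first" %in% orders) top[["self_first"]] else top[[1]]
    top_o <- if ("other_first" %in% orders) top[["other_first"]] else top[[1]]
    combos <- do.call(rbind, lapply(seq_len(nrow(top_s)), function(i)
      cbind(top_s[i, 1], top_s[i, 2], top_o[, 1], top_o[, 2])))
    if (is.null(lambda)) combos <- cbind(combos, stats::qlogis(lam_mid))
    starts <- rbind(starts, combos)
  }

  # -- stage 3: score all starts, polish the most promising with Nelder-Mead
  polish_top <- control$polish_top %||%
    if (model == "quantum") nrow(starts) else 10L
  v0 <- apply(starts, 1, objfun)
  keep <- order(v0)[seq_len(min(polish_top, nrow(starts)))]
  fits <- lapply(keep, function(i)
    stats::optim(starts[i, ], objfun, method = "Nelder-Mead",
                 control = list(maxit = control$maxit, reltol = control$reltol)))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  again <- order(vals)[seq_len(min(control$final_polish, length(fits)))]
  fits2 <- lapply(fits[again], function(f)
    stats::optim(f$par, objfun, method = "Nelder-Mead",
                 control = list(maxit = control$maxit, reltol = control$reltol)))
  all_fits <- c(fits, fits2)
  best <- all_fits[[which.min(vapply(all_fits, `[[`, numeric(1), "value"))]]

  theta <- par_to_natural(best$par, model, lambda)
  pred <- predict_tables(model, spec, theta, orders)
  stat <- if (objective == "sse") {
    c(r2 = sse_objective(obs, pred)$r2)
  } else {
    c(g2 = g2_statistic(obs, pred))
  }
  res <- list(model = model, objective = objective, par = theta,
              lambda_fixed = lambda, value = best$value,
              fit_statistic = stat, data = obs, fitted = pred, spec = spec,
              n_starts = nrow(starts), n_polished = length(keep),
              convergence = best$convergence, feval = best$counts[["function"]],
              seed = control$seed, control = control, call = match.call())
  class(res) <- "walk_fit"
  res
}

#' @export
print.walk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s walk fit (%s objective)\n", x$model,
              if (x$objective == "sse") "SSE" else "likelihood"))
  cat("Parameters:\n")
  print(round(x$par, digits))
  cat(sprintf("%s = %.4g  (objective %.6g; %d starts, convergence %d)\n",
              toupper(names(x$fit_statistic)), x$fit_statistic, x$value,
              x$n_starts, x$convergence))
  invisible(x)
}

#' @export
coef.walk_fit <- function(object, ...) object$par

#' @export
fitted.walk_fit <- function(object, ...) object$fitted

#' @export
residuals.walk_fit <- function(object, ...) {
  out <- lapply(names(object$data), function(ord) {
    as_proportions(object$data[[ord]]) - as_proportions(object$fitted[[ord]])
  })
  names(out) <- names(object$data)
  out
}

#' @export
logLik.walk_fit <- function(object, ...) {
  if (object$objective != "likelihood")
    stop("log likelihood is only defined for likelihood fits")
  ll <- 0
  for (ord in names(object$data)) {
    cnt <- as_counts(object$data[[ord]])
    p <- pmax(as_proportions(object$fitted[[ord]]), 1e-12)
    ll <- ll + sum(cnt[cnt > 0] * log(p[cnt > 0]))
  }
  structure(ll, df = 4L + is.null(object$lambda_fixed), class = "logLik")
}

#' Predicted tables or means from a fitted walk model
#'
#' @param object A [walk_fit()] result.
#' @param order Question order(s) to predict; defaults to both.
#' @param type `"table"` for the mixed joint distribution(s), `"means"` for
#'   the first/second-question mean ratings.
#' @param ... Unused.
#' @return A [joint_table()] (or named list of them), or a matrix of means.
#' @export
predict.walk_fit <- function(object, order = c("self_first", "other_first"),
                             type = c("table", "means"), ...) {
  order <- match.arg(order, several.ok = TRUE)
  type <- match.arg(type)
  pred <- predict_tables(object$model, object$spec, object$par, order)
  if (type == "means") {
    return(t(vapply(pred, table_means, numeric(2))))
  }
  if (length(pred) == 1L) pred[[1L]] else pred
}

#' @export
summary.walk_fit <- function(object, ...) {
  per_table <- t(vapply(names(object$data), function(ord) {
    o <- as_proportions(object$data[[ord]])
    p <- as_proportions(object$fitted[[ord]])
    r2 <- 1 - sum((o - p)^2) / sum((o - mean(o))^2)
    om <- table_means(object$data[[ord]])
    pm <- table_means(object$fitted[[ord]])
    c(r2 = r2, obs_first = om[[1]], pred_first = pm[[1]],
      obs_second = om[[2]], pred_second = pm[[2]])
  }, numeric(5)))
  ncell <- length(object$data[[1]])
  out <- list(fit = object, per_table = per_table,
              df_model = 4L + is.null(object$lambda_fixed),
              df_saturated = length(object$data) * ncell - length(object$data))
  class(out) <- "summary.walk_fit"
  out
}

#' @export
print.summary.walk_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("\nModel parameters: %d; saturated reference: %d free cell probabilities\n",
              x$df_model, x$df_saturated))
  cat("Per-table fit and mean ratings (first/second question asked):\n")
  print(round(x$per_table, digits))
  invisible(x)
}

#' Heatmaps of observed and fitted joint tables
#'
#' One row of panels per question order: observed proportions on the left,
#' model predictions on the right, on a shared grey scale.
#'
#' @param x A [walk_fit()] result.
#' @param ... Passed to [graphics::image()].
#' @export
plot.walk_fit <- function(x, ...) {
  orders <- names(x$data)
  op <- graphics::par(mfrow = c(length(orders), 2L), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  zmax <- max(vapply(c(x$data, x$fitted),
                     function(t) max(as_proportions(t)), numeric(1)))
  r <- seq_len(nrow(x$data[[1]]))
  for (ord in orders) {
    for (what in c("observed", "fitted")) {
      m <- as_proportions(if (what == "observed") x$data[[ord]] else x$fitted[[ord]])
      graphics::image(r, r, t(m)[, rev(r)], zlim = c(0, zmax),
                      col = grDevices::grey.colors(64, start = 1, end = 0),
                      xlab = "second rating", ylab = "first rating",
                      main = paste(ord, what), ...)
    }
  }
  invisible(x)
}

#' Simulate experiments from a fitted walk model
#'
#' Draws trial-level synthetic experiments (see [simulate_experiment()])
#' whose generating joint distributions are the fitted model's.
#'
#' @param object A [walk_fit()] result.
#' @param nsim Number of experiments.
#' @param seed Integer seed (required for reproducibility across calls).
#' @param n_participants,n_stimuli,order_probability Design of each
#'   simulated experiment; defaults follow the packaged study (131
#'   participants, 12 stimuli, equiprobable per-trial order).
#' @param ... Unused.
#' @return A trial data frame for `nsim = 1`, otherwise a list of them.
#' @export
simulate.walk_fit <- function(object, nsim = 1, seed = NULL,
                              n_participants = 131, n_stimuli = 12,
                              order_probability = 0.5, ...) {
  if (is.null(seed)) seed <- object$seed
  sims <- lapply(seq_len(nsim), function(i) {
    cfg <- experiment_config(n_participants = n_participants,
                             n_stimuli = n_stimuli,
                             order_probability = order_probability,
                             model = object$model, params = object$par[1:4],
                             lambda = object$par[["lambda"]],
                             seed = seed + i - 1L, spec = object$spec)
    simulate_experiment(cfg)
  })
  if (nsim == 1L) sims[[1L]] else sims
}

# ---- small shared helpers ------------------------------------------------

as_table_list <- function(x) {
  if (inherits(x, "joint_table")) x <- list(x)
  if (!length(x) || !all(vapply(x, inherits, logical(1), "joint_table")))
    stop("supply a joint_table or a list of joint_tables")
  ords <- vapply(x, table_order, character(1))
  if (anyDuplicated(ords)) stop("at most one table per question order")
  names(x) <- ords
  x[order(match(ords, c("self_first", "other_first")))]
}

align_orders <- function(obs, pred) {
  if (!identical(names(obs), names(pred)))
    stop("observed and predicted tables cover different question orders")
  for (ord in names(obs))
    if (!identical(dim(obs[[ord]]), dim(pred[[ord]])))
      stop("observed and predicted tables disagree in size")
  invisible(NULL)
}
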