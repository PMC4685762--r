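#' Configuration of a synthetic rating experiment
#'
#' Describes one simulated run of the two-question rating design: every
#' participant rates every stimulus once, the question order of each trial
#' is drawn independently (self-first with probability `order_probability`),
#' and the rating pair of a trial is drawn from the generating model's
#' mixed joint distribution for that trial's order.  The defaults follow
#' the packaged study: 131 participants by 12 stimuli (1572 trials) with
#' equiprobable order.
#'
#' @param n_participants,n_stimuli Positive design counts.
#' @param order_probability Probability in `[0, 1]` that a trial is
#'   self-first.
#' @param model `"quantum"` or `"markov"`.
#' @param params Named dynamic parameters for the model (see
#'   [markov_joint()] / [quantum_joint()]).
#' @param lambda Mixture weight in `[0, 1]`.
#' @param seed Integer seed; the single pseudo-random stream of the
#'   experiment.
#' @param spec A [lattice_spec()].
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(n_participants = 131, n_stimuli = 12,
                              order_probability = 0.5,
                              model = c("quantum", "markov"), params,
                              lambda = 1, seed = 1L, spec = lattice_spec()) {
  model <- match.arg(model)
  if (n_participants < 1 || n_stimuli < 1)
    stop("design counts must be positive")
  if (order_probability < 0 || order_probability > 1)
    stop("'order_probability' must lie in [0, 1]")
  check_walk_params(params)
  cfg <- list(n_participants = as.integer(n_participants),
              n_stimuli = as.integer(n_stimuli),
              order_probability = order_probability, model = model,
              params = params, lambda = lambda, seed = as.integer(seed),
              spec = spec)
  class(cfg) <- "experiment_config"
  cfg
}

#' Simulate a trial-level rating experiment
#'
#' Generates `n_participants * n_stimuli` trials from the configured model.
#' A single seeded random stream is consumed in record order, the order
#' draw of a trial before its rating draw, so runs are bit-reproducible.
#'
#' @param config An [experiment_config()].
#' @return A data frame with columns `participant`, `stimulus`, `order`,
#'   `r_first`, `r_second` (ratings of the first and second question asked).
#' @examples
#' cfg <- experiment_config(n_participants = 4, n_stimuli = 3,
#'                          model = "markov",
#'                          params = c(alpha_s = 300, beta_s = 300,
#'                                     alpha_o = 300, beta_o = 300),
#'                          lambda = 0.9, seed = 42)
#' simulate_experiment(cfg)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  tabs <- lapply(c("self_first", "other_first"), function(ord)
    as_proportions(walk_joint(config$model, config$params, ord,
                              lambda = config$lambda, spec = config$spec)))
  names(tabs) <- c("self_first", "other_first")
  cum <- lapply(tabs, function(m) cumsum(as.vector(t(m))))  # row-major cells
  n <- config$n_participants * config$n_stimuli
  nr <- config$spec$n_ratings

  set.seed(config$seed)
  u <- matrix(stats::runif(2L * n), nrow = 2L)  # per record: order then cell
  is_sf <- u[1L, ] < config$order_probability
  cell <- integer(n)
  for (ord in c(TRUE, FALSE)) {
    idx <- which(is_sf == ord)
    if (length(idx))
      cell[idx] <- findInterval(u[2L, idx],
                                cum[[if (ord) "self_first" else "other_first"]],
                                left.open = TRUE) + 1L
  }
  data.frame(
    participant = rep(seq_len(config$n_participants), each = config$n_stimuli),
    stimulus = rep(seq_len(config$n_stimuli), times = config$n_participants),
    order = ifelse(is_sf, "self_first", "other_first"),
    r_first = (cell - 1L) %/% nr + 1L,
    r_second = (cell - 1L) %% nr + 1L
  )
}

#' Aggregate trial records into order-conditioned count tables
#'
#' Pools all participants and stimuli, separately per question order, into
#' the pair of count tables that the fitting and testing functions consume.
#' Rows index the first question asked.
#'
#' @param records A trial data frame as produced by
#'   [simulate_experiment()].
#' @param n_ratings Size of the rating scale.
#' @return Named list of two count-kind [joint_table()]s, `self_first` and
#'   `other_first`.
#' @export
aggregate_tables <- function(records, n_ratings = 9L) {
  need <- c("order", "r_first", "r_second")
  if (!nrow(records) || !all(need %in% names(records)))
    stop("'records' must be a nonempty trial data frame with columns ",
         paste(need, collapse = ", "))
  if (any(records$r_first < 1 | records$r_first > n_ratings |
          records$r_second < 1 | records$r_second > n_ratings))
    stop("ratings outside the 1..", n_ratings, " scale")
  lv <- seq_len(n_ratings)
  out <- lapply(c("self_first", "other_first"), function(ord) {
    sel <- records$order == ord
    cnt <- table(factor(records$r_first[sel], levels = lv),
                 factor(records$r_second[sel], levels = lv))
    joint_table(unclass(as.matrix(cnt)), ord, "count")
  })
  names(out) <- c("self_first", "other_first")
  out
}
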