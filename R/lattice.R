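#' Evaluation-state lattice underlying both walk models
#'
#' Both the Markov and the quantum walk assume that a judge evaluates a
#' stimulus on a fine internal scale of `N` ordered evaluation states, of
#' which only a coarse partition into rating categories is observable.  Each
#' of the `n_ratings` rating levels owns a contiguous block of
#' `states_per_rating` lattice states; `states_per_rating` must be odd so
#' that every block has a midpoint.  The default lattice (9 ratings times 11
#' states) has `N = 99` states and approximates a continuum: refining it
#' further leaves the predicted joint rating distributions essentially
#' unchanged once the dynamical parameters are rescaled accordingly.
#'
#' @param n_ratings Number of observable rating levels (default 9).
#' @param states_per_rating Odd number of lattice states per rating level
#'   (default 11).
#' @param neutral_rating Rating level on which the walk starts; defaults to
#'   the scale midpoint.
#'
#' @return An object of class `"lattice_spec"`: a list with elements
#'   `n_ratings`, `states_per_rating`, `N`, `neutral_rating` and
#'   `neutral_center` (the 1-based index of the midpoint state of the
#'   neutral rating block; state 50 for the default lattice).
#'
#' @examples
#' spec <- lattice_spec()
#' spec$N              # 99
#' spec$neutral_center # 50
#' rating_block(spec, 5)
#' @export
lattice_spec <- function(n_ratings = 9L, states_per_rating = 11L,
                         neutral_rating = (n_ratings + 1L) %/% 2L) {
  n_ratings <- as.integer(n_ratings)
  states_per_rating <- as.integer(states_per_rating)
  neutral_rating <- as.integer(neutral_rating)
  if (n_ratings < 1L) stop("'n_ratings' must be a positive integer")
  if (states_per_rating < 1L || states_per_rating %% 2L == 0L)
    stop("'states_per_rating' must be an odd positive integer")
  if (neutral_rating < 1L || neutral_rating > n_ratings)
    stop("'neutral_rating' must lie between 1 and 'n_ratings'")
  spec <- list(
    n_ratings = n_ratings,
    states_per_rating = states_per_rating,
    N = n_ratings * states_per_rating,
    neutral_rating = neutral_rating,
    neutral_center = (neutral_rating - 1L) * states_per_rating +
      (states_per_rating + 1L) %/% 2L
  )
  class(spec) <- "lattice_spec"
  spec
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf(
    "Evaluation lattice: %d ratings x %d states = %d states (neutral state %d)\n",
    x$n_ratings, x$states_per_rating, x$N, x$neutral_center))
  invisible(x)
}

#' State block owned by one rating level
#'
#' Rating `k` is read out from the contiguous 1-based lattice states
#' `(k-1)*states_per_rating + 1` through `k*states_per_rating`.
#'
#' @param spec A [lattice_spec()].
#' @param k Rating level, `1 <= k <= spec$n_ratings`.
#' @return Integer vector `c(first, last)` of 1-based state indices,
#'   inclusive.
#' @examples
#' rating_block(lattice_spec(), 1) # 1 11
#' rating_block(lattice_spec(), 9) # 89 99
#' @export
rating_block <- function(spec, k) {
  stopifnot(inherits(spec, "lattice_spec"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > spec$n_ratings)
    stop(sprintf("invalid rating %s: must be an integer in 1..%d",
                 deparse(substitute(k)), spec$n_ratings))
  c((k - 1L) * spec$states_per_rating + 1L, k * spec$states_per_rating)
}

# indices of rating k's block (internal, vector form)
block_index <- function(spec, k) {
  b <- rating_block(spec, k)
  b[1L]:b[2L]
}

#' Projector onto the states of one rating level
#'
#' The measurement operator for rating `k` is the diagonal indicator matrix
#' with ones on the states belonging to `k`'s block and zeros elsewhere.
#' Projectors of distinct ratings are orthogonal and they sum to the
#' identity, so both the Markov event probabilities and the quantum squared
#' projections of a normalised state add up to one across ratings.
#'
#' @inheritParams rating_block
#' @return An `N x N` diagonal 0/1 matrix.
#' @examples
#' M5 <- rating_projector(lattice_spec(), 5)
#' sum(diag(M5)) # 11
#' @export
rating_projector <- function(spec, k) {
  d <- numeric(spec$N)
  d[block_index(spec, k)] <- 1
  diag(d, nrow = spec$N)
}

#' Initial state of the walk
#'
#' Before the stimulus appears the judge is neutral: the state occupies the
#' `states_per_rating` lattice states centred on the neutral midpoint state
#' (states 45..55 of the default lattice).  The Markov version is a uniform
#' probability distribution over that support; the quantum version is a
#' uniform real-amplitude superposition (a global phase is unobservable, so
#' amplitudes are taken real and positive).
#'
#' @param spec A [lattice_spec()].
#' @param kind `"probability"` (Markov) or `"amplitude"` (quantum).
#' @return A numeric vector of length `spec$N` with attribute `kind`.
#' @examples
#' p0 <- initial_state(lattice_spec(), "probability")
#' sum(p0)                 # 1
#' which(p0 > 0)           # 45..55
#' @export
initial_state <- function(spec, kind = c("probability", "amplitude")) {
  stopifnot(inherits(spec, "lattice_spec"))
  kind <- match.arg(kind)
  half <- (spec$states_per_rating - 1L) %/% 2L
  support <- (spec$neutral_center - half):(spec$neutral_center + half)
  v <- numeric(spec$N)
  v[support] <- if (kind == "probability") 1 / spec$states_per_rating
                else sqrt(1 / spec$states_per_rating)
  attr(v, "kind") <- kind
  v
}
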