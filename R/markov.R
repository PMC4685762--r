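#' Birth--death intensity matrix
#'
#' The Markov walk is a continuous-time birth--death process on the
#' evaluation lattice with reflecting boundaries.  Under the
#' column-stochastic convention used throughout the package (entry `(i, j)`
#' of a transition matrix is the probability of state `i` given previous
#' state `j`), column `j` of the generator carries rate `alpha` for the move
#' `j -> j - 1` (toward the low end of the scale) and rate `beta` for
#' `j -> j + 1` (toward the high end), with `-(alpha + beta)` on the
#' diagonal.  The drift of the walk is therefore `beta - alpha` in lattice
#' units: when `alpha` exceeds `beta` the evaluation drifts toward rating 1.
#' At the two reflecting ends the impossible exit is simply removed, so
#' every column sums exactly to zero.  The processing-time parameter of the
#' walk is absorbed into the rates, which is why fitted intensities are
#' large numbers.
#'
#' @param spec A [lattice_spec()].
#' @param alpha Nonnegative rate toward lower states.
#' @param beta Nonnegative rate toward higher states.
#' @return An `N x N` tridiagonal generator matrix with zero column sums.
#' @examples
#' K <- markov_intensity(lattice_spec(), 2, 1)
#' max(abs(colSums(K))) # 0
#' @export
markov_intensity <- function(spec, alpha, beta) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (!is.finite(alpha) || !is.finite(beta) || alpha < 0 || beta < 0)
    stop("intensities 'alpha' and 'beta' must be finite and nonnegative")
  N <- spec$N
  K <- matrix(0, N, N)
  idx <- seq_len(N - 1L)
  K[cbind(idx, idx + 1L)] <- alpha   # j -> j - 1
  K[cbind(idx + 1L, idx)] <- beta    # j -> j + 1
  diag(K) <- -colSums(K)
  K
}

#' Transition matrix of the Markov walk
#'
#' Solves the Kolmogorov forward equation for the birth--death generator:
#' the transition matrix is the matrix exponential `expm(K)` at unit time
#' (the timescale lives in the rates).  The result is column-stochastic.
#'
#' @param K A generator matrix as built by [markov_intensity()]: nonnegative
#'   off-diagonal entries and zero column sums.
#' @return An `N x N` column-stochastic transition matrix.
#' @examples
#' T1 <- markov_propagator(markov_intensity(lattice_spec(), 2, 1))
#' range(colSums(T1)) # 1 1
#' @export
markov_propagator <- function(K) {
  K <- as.matrix(K)
  offdiag <- K; diag(offdiag) <- 0
  scale <- max(1, max(abs(K)))
  if (any(offdiag < 0) || max(abs(colSums(K))) > 1e-8 * scale)
    stop("'K' is not a valid generator (need nonnegative off-diagonal ",
         "entries and zero column sums)")
  P <- as.matrix(Matrix::expm(K))
  # expm can leave roundoff-scale negatives in far-off-diagonal entries
  P[P < 0] <- 0
  P
}

check_walk_params <- function(params) {
  need <- c("alpha_s", "beta_s", "alpha_o", "beta_o")
  params <- unlist(params)
  if (!all(need %in% names(params)))
    stop("'params' must carry named entries ", paste(need, collapse = ", "))
  p <- params[need]
  if (any(!is.finite(p))) stop("model parameters must be finite")
  p
}

# shared collapse-and-propagate product for the Markov chain:
# row i of the result is Pr(first = i, second = j)
markov_joint_cells <- function(spec, T_first, T_second, p0) {
  nr <- spec$n_ratings
  p1 <- as.vector(T_first %*% p0)
  J <- matrix(0, nr, nr)
  for (i in seq_len(nr)) {
    v <- p1
    v[-block_index(spec, i)] <- 0       # un-normalised collapse on answer i
    w <- as.vector(T_second %*% v)
    J[i, ] <- vapply(seq_len(nr),
                     function(j) sum(w[block_index(spec, j)]), numeric(1))
  }
  J[J < 0] <- 0
  J
}

#' Joint rating distribution under the Markov walk
#'
#' Starting from the neutral initial distribution, the chain evolves under
#' the first question's transition matrix, the first rating is read out
#' through the rating projectors (an un-normalised collapse, so the chain
#' rule produces joint probabilities directly), the collapsed distribution
#' evolves under the second question's transition matrix, and the second
#' rating is read out.  Self uses rates `(alpha_s, beta_s)` and other uses
#' `(alpha_o, beta_o)`; the question order decides which matrix acts first
#' and which rating labels the rows.
#'
#' @param spec A [lattice_spec()].
#' @param params Named vector or list with nonnegative rates `alpha_s`,
#'   `beta_s`, `alpha_o`, `beta_o`.
#' @param order `"self_first"` or `"other_first"`.
#' @return A probability-kind [joint_table()]; rows index the first question
#'   asked.
#' @examples
#' J <- markov_joint(lattice_spec(),
#'                   c(alpha_s = 2, beta_s = 1, alpha_o = 1, beta_o = 2),
#'                   "self_first")
#' sum(J) # 1
#' @export
markov_joint <- function(spec, params, order = c("self_first", "other_first")) {
  stopifnot(inherits(spec, "lattice_spec"))
  order <- match.arg(order)
  p <- check_walk_params(params)
  if (any(p < 0)) stop("Markov intensities must be nonnegative")
  T_s <- markov_propagator(markov_intensity(spec, p["alpha_s"], p["beta_s"]))
  T_o <- markov_propagator(markov_intensity(spec, p["alpha_o"], p["beta_o"]))
  p0 <- initial_state(spec, "probability")
  cells <- if (order == "self_first") markov_joint_cells(spec, T_s, T_o, p0)
           else markov_joint_cells(spec, T_o, T_s, p0)
  joint_table(cells / sum(cells), order, "probability")
}

#' Normalised state after the first answer (Markov walk)
#'
#' Diagnostic accessor: the probability distribution over lattice states
#' conditional on the first question having been answered with rating `k`.
#'
#' @inheritParams markov_joint
#' @param k Observed first rating.
#' @return Probability vector of length `spec$N`.
#' @export
markov_posterior <- function(spec, params, order = c("self_first", "other_first"), k) {
  stopifnot(inherits(spec, "lattice_spec"))
  order <- match.arg(order)
  p <- check_walk_params(params)
  first <- if (order == "self_first") c(p["alpha_s"], p["beta_s"])
           else c(p["alpha_o"], p["beta_o"])
  T1 <- markov_propagator(markov_intensity(spec, first[1], first[2]))
  v <- as.vector(T1 %*% initial_state(spec, "probability"))
  v[-block_index(spec, k)] <- 0
  if (sum(v) <= 0) stop("first rating ", k, " has probability zero")
  v / sum(v)
}
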