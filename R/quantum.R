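#' Crystal Hamiltonian of the quantum walk
#'
#' The quantum walk evolves under a tridiagonal Hermitian matrix: a constant
#' coupling `alpha` on both off-diagonals lets amplitude diffuse to adjacent
#' lattice states, and a linear potential `beta * (i / N)` on the diagonal
#' (`i = 1..N`) exerts a constant force along the scale whose direction is
#' the sign of `beta`.  The band simply truncates at the lattice ends; no
#' boundary modification is needed for Hermiticity.  As with the Markov
#' rates, the processing-time parameter is absorbed into `alpha` and `beta`,
#' and both may be negative.
#'
#' @param spec A [lattice_spec()].
#' @param alpha Off-diagonal coupling (any finite real).
#' @param beta Slope of the linear diagonal potential (any finite real).
#' @return An `N x N` real symmetric tridiagonal matrix.
#' @examples
#' H <- quantum_hamiltonian(lattice_spec(), 1, -14.57)
#' H[99, 99] # -14.57
#' @export
quantum_hamiltonian <- function(spec, alpha, beta) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (!is.finite(alpha) || !is.finite(beta))
    stop("'alpha' and 'beta' must be finite reals")
  N <- spec$N
  H <- matrix(0, N, N)
  idx <- seq_len(N - 1L)
  H[cbind(idx, idx + 1L)] <- alpha
  H[cbind(idx + 1L, idx)] <- alpha
  diag(H) <- beta * seq_len(N) / N
  H
}

#' Unitary propagator of the quantum walk
#'
#' Solves the Schroedinger equation for the crystal Hamiltonian: the
#' propagator is `expm(-1i * H)` at unit time, computed through the spectral
#' decomposition of the real symmetric `H`.  Its entries are the transition
#' amplitudes between the neutral basis and the question basis, and its
#' squared moduli form a doubly stochastic matrix.
#'
#' @param H A real symmetric (Hermitian) matrix, as built by
#'   [quantum_hamiltonian()].
#' @return An `N x N` complex unitary matrix.
#' @examples
#' U <- quantum_unitary(quantum_hamiltonian(lattice_spec(), 1, 2))
#' max(abs(Conj(t(U)) %*% U - diag(99))) < 1e-10
#' @export
quantum_unitary <- function(H) {
  H <- as.matrix(H)
  if (!isSymmetric.matrix(H, tol = 1e-10))
    stop("'H' must be a real symmetric (Hermitian) matrix")
  e <- eigen(H, symmetric = TRUE)
  # V exp(-i L) V^T without forming the diagonal matrix
  e$vectors %*% (exp(-1i * e$values) * t(e$vectors))
}

# squared-modulus readout of Pr(first = i, second = j): row i is
# | M_j %*% U_change %*% M_i %*% (U_first psi0) |^2 summed over j's block
quantum_joint_cells <- function(spec, U_first, U_second, psi0) {
  nr <- spec$n_ratings
  psi1 <- as.vector(U_first %*% psi0)
  A <- U_second %*% Conj(t(U_first))   # first-question basis -> second
  J <- matrix(0, nr, nr)
  for (i in seq_len(nr)) {
    v <- psi1
    v[-block_index(spec, i)] <- 0      # projective collapse, un-normalised
    w <- as.vector(A %*% v)
    amp2 <- Mod(w)^2
    J[i, ] <- vapply(seq_len(nr),
                     function(j) sum(amp2[block_index(spec, j)]), numeric(1))
  }
  J
}

#' Joint rating distribution under the quantum walk
#'
#' The initial superposition evolves under the first question's unitary, the
#' first rating is measured projectively (collapse within the first
#' question's basis), and the collapsed amplitudes are carried to the second
#' question's basis *through the neutral basis*: the inverse of the first
#' unitary undoes the first rotation before the second unitary is applied.
#' This basis change is what distinguishes the quantum from the Markov walk
#' and is the source of its asymmetric order effects.  Probabilities are
#' squared moduli of the projected amplitudes; because the first projection
#' is left un-normalised they are joint, not conditional, probabilities.
#'
#' @param spec A [lattice_spec()].
#' @param params Named vector or list with finite reals `alpha_s`, `beta_s`,
#'   `alpha_o`, `beta_o` (self and other Hamiltonian parameters).
#' @param order `"self_first"` or `"other_first"`.
#' @return A probability-kind [joint_table()]; rows index the first question
#'   asked.
#' @examples
#' J <- quantum_joint(lattice_spec(),
#'                    c(alpha_s = 99.24, beta_s = -14.57,
#'                      alpha_o = 89.53, beta_o = -16.74),
#'                    "self_first")
#' sum(J) # 1
#' @export
quantum_joint <- function(spec, params, order = c("self_first", "other_first")) {
  stopifnot(inherits(spec, "lattice_spec"))
  order <- match.arg(order)
  p <- check_walk_params(params)
  U_s <- quantum_unitary(quantum_hamiltonian(spec, p["alpha_s"], p["beta_s"]))
  U_o <- quantum_unitary(quantum_hamiltonian(spec, p["alpha_o"], p["beta_o"]))
  psi0 <- initial_state(spec, "amplitude")
  cells <- if (order == "self_first") quantum_joint_cells(spec, U_s, U_o, psi0)
           else quantum_joint_cells(spec, U_o, U_s, psi0)
  joint_table(cells / sum(cells), order, "probability")
}

#' Model joint table for either walk family
#'
#' Convenience wrapper dispatching to [markov_joint()] or [quantum_joint()]
#' and optionally applying the non-judgemental mixture.
#'
#' @param model `"markov"` or `"quantum"`.
#' @param params Named parameter vector (see the model-specific builders).
#' @param order `"self_first"` or `"other_first"`.
#' @param lambda Mixture weight in `[0, 1]`; `1` (default) disables the
#'   mixture.
#' @param spec A [lattice_spec()].
#' @return A probability-kind [joint_table()].
#' @export
walk_joint <- function(model = c("quantum", "markov"), params,
                       order = c("self_first", "other_first"),
                       lambda = 1, spec = lattice_spec()) {
  model <- match.arg(model)
  order <- match.arg(order)
  J <- if (model == "markov") markov_joint(spec, params, order)
       else quantum_joint(spec, params, order)
  if (lambda < 1) apply_mixture(J, lambda) else J
}
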