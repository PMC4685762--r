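# Independent oracles used across the suite.  These deliberately share no
# code with the package: the matrix exponential is a scaling-and-squaring
# Taylor series, the small-lattice joints are written out as explicit
# operator products, and the continuous-time chain is simulated event by
# event.

# matrix exponential by scaling and squaring of the Taylor series;
# works for real and complex matrices of modest size/norm
taylor_expm <- function(M) {
  nrm <- max(rowSums(Mod(M)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))))
  A <- M / 2^s
  E <- diag(nrow(M)) + 0 * M
  term <- E
  for (k in 1:60) {
    term <- term %*% A / k
    E <- E + term
    if (max(Mod(term)) < 1e-18) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# generator of the birth-death walk, built independently: column j moves
# down (toward state 1) at rate alpha and up at rate beta, reflecting ends
oracle_generator <- function(N, alpha, beta) {
  K <- matrix(0, N, N)
  for (j in seq_len(N)) {
    if (j > 1) K[j - 1, j] <- alpha
    if (j < N) K[j + 1, j] <- beta
    K[j, j] <- -(alpha * (j > 1) + beta * (j < N))
  }
  K
}

# joint table on the degenerate 9-state lattice (one state per rating),
# spelled out as the full operator product with explicit projectors
oracle_markov_joint9 <- function(params, order) {
  Ts <- Re(taylor_expm(oracle_generator(9, params[["alpha_s"]], params[["beta_s"]])))
  To <- Re(taylor_expm(oracle_generator(9, params[["alpha_o"]], params[["beta_o"]])))
  if (order == "other_first") { tmp <- Ts; Ts <- To; To <- tmp }
  p0 <- numeric(9); p0[5] <- 1
  L <- matrix(1, 1, 9)
  J <- matrix(0, 9, 9)
  for (j in 1:9) {
    Mj <- diag(as.numeric(1:9 == j))
    for (k in 1:9) {
      Mk <- diag(as.numeric(1:9 == k))
      J[j, k] <- as.numeric(L %*% Mk %*% To %*% Mj %*% Ts %*% p0)
    }
  }
  J
}

oracle_quantum_joint9 <- function(params, order) {
  H9 <- function(a, b) {
    H <- matrix(0, 9, 9)
    for (j in 1:8) { H[j, j + 1] <- a; H[j + 1, j] <- a }
    diag(H) <- b * (1:9) / 9
    H
  }
  Us <- taylor_expm(-1i * H9(params[["alpha_s"]], params[["beta_s"]]))
  Uo <- taylor_expm(-1i * H9(params[["alpha_o"]], params[["beta_o"]]))
  if (order == "other_first") { tmp <- Us; Us <- Uo; Uo <- tmp }
  psi0 <- complex(real = as.numeric(1:9 == 5))
  J <- matrix(0, 9, 9)
  for (i in 1:9) {
    Mi <- diag(as.numeric(1:9 == i))
    for (j in 1:9) {
      Mj <- diag(as.numeric(1:9 == j))
      v <- Mj %*% Uo %*% Conj(t(Us)) %*% Mi %*% Us %*% psi0
      J[i, j] <- sum(Mod(v)^2)
    }
  }
  J
}

# event-by-event (Gillespie) simulation of the birth-death chain to t = 1:
# returns the empirical distribution over states for trajectories started
# in 'from'
gillespie_ctmc <- function(N, alpha, beta, from, nsim) {
  state <- rep.int(from, nsim)
  t_now <- numeric(nsim)
  alive <- rep(TRUE, nsim)
  for (step in 1:5000) {
    idx <- which(alive)
    if (!length(idx)) break
    s <- state[idx]
    r_down <- alpha * (s > 1)
    r_up <- beta * (s < N)
    tot <- r_down + r_up
    stuck <- tot == 0
    if (any(stuck)) { alive[idx[stuck]] <- FALSE; idx <- idx[!stuck]
                      s <- s[!stuck]; r_down <- r_down[!stuck]; tot <- tot[!stuck] }
    if (!length(idx)) break
    dt <- stats::rexp(length(idx), rate = tot)
    done <- t_now[idx] + dt > 1
    alive[idx[done]] <- FALSE
    mv <- !done
    if (any(mv)) {
      i2 <- idx[mv]
      t_now[i2] <- t_now[i2] + dt[mv]
      down <- stats::runif(length(i2)) < (r_down[mv] / tot[mv])
      state[i2] <- state[i2] + ifelse(down, -1L, 1L)
    }
  }
  tabulate(state, nbins = N) / nsim
}

# observed study tables and reference estimates, loaded once per run
psa_obs <- psa_tables()
psa_est <- psa_estimates()

est_params <- function(objective, model) {
  e <- psa_est[psa_est$objective == objective & psa_est$model == model, ]
  list(params = stats::setNames(as.numeric(e[c("alpha_s", "beta_s", "alpha_o", "beta_o")]),
                                c("alpha_s", "beta_s", "alpha_o", "beta_o")),
       lambda = e$lambda, value = e$value)
}

rand_params <- function(model, r) {
  if (model == "markov")
    c(alpha_s = r[1] * 50, beta_s = r[2] * 50, alpha_o = r[3] * 50, beta_o = r[4] * 50)
  else
    c(alpha_s = r[1] * 100, beta_s = (r[2] - 0.5) * 60,
      alpha_o = r[3] * 100, beta_o = (r[4] - 0.5) * 60)
}
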