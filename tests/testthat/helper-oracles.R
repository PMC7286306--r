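# Brute-force oracles, written independently of the package internals:
# explicit loops over states, pairs and paths. Used to cross-check energies,
# probabilities, moments, minima, basins and barriers on small N.

# all 2^N states as +/-1 rows, same bit convention as the package
oracle_states <- function(N) {
  out <- matrix(-1, 2^N, N)
  for (k in 0:(2^N - 1)) {
    for (i in 1:N) {
      if (bitwAnd(k, 2^(i - 1)) > 0) out[k + 1, i] <- 1
    }
  }
  out
}

oracle_energy <- function(s, h, J) {
  e <- -sum(h * s)
  N <- length(s)
  for (i in 1:N) for (j in 1:N) {
    if (i != j) e <- e - 0.5 * J[i, j] * s[i] * s[j]
  }
  e
}

oracle_energies <- function(h, J) {
  S <- oracle_states(length(h))
  apply(S, 1, oracle_energy, h = h, J = J)
}

oracle_probs <- function(h, J) {
  e <- oracle_energies(h, J)
  w <- exp(-(e - min(e)))
  w / sum(w)
}

oracle_moments <- function(h, J) {
  N <- length(h)
  S <- oracle_states(N)
  p <- oracle_probs(h, J)
  m <- numeric(N)
  C <- matrix(0, N, N)
  for (k in seq_len(nrow(S))) {
    m <- m + S[k, ] * p[k]
    C <- C + outer(S[k, ], S[k, ]) * p[k]
  }
  diag(C) <- 1
  list(mean = m, cooc = C)
}

# Hamming distance between state indices
oracle_hamming <- function(a, b, N) {
  sum(bitwAnd(bitwShiftR(bitwXor(a, b), 0:(N - 1)), 1L))
}

oracle_minima <- function(energies, N) {
  mins <- integer(0)
  for (k in 0:(2^N - 1)) {
    nb_e <- sapply(1:N, function(i) energies[bitwXor(k, 2^(i - 1)) + 1])
    if (all(energies[k + 1] < nb_e)) mins <- c(mins, k)
  }
  mins[order(energies[mins + 1])]
}

# recursive steepest descent (ties: lowest neighbour index)
oracle_basin <- function(k, energies, N) {
  repeat {
    nbs <- sapply(1:N, function(i) bitwXor(k, 2^(i - 1)))
    nbs <- sort(nbs)
    best <- nbs[which.min(energies[nbs + 1])]
    if (energies[best + 1] < energies[k + 1]) k <- best else return(k)
  }
}

# minimax barrier via threshold connectivity (BFS), independent of union-find
oracle_barrier <- function(a, b, energies, N) {
  for (thr in sort(unique(energies))) {
    keep <- which(energies <= thr) - 1L
    if (!(a %in% keep) || !(b %in% keep)) next
    # BFS from a over kept states
    seen <- a
    frontier <- a
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (k in frontier) {
        for (i in 1:N) {
          nb <- bitwXor(k, 2^(i - 1))
          if (nb %in% keep && !(nb %in% seen)) {
            seen <- c(seen, nb)
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
    }
    if (b %in% seen) return(thr)
  }
  stop("oracle_barrier: states never connect")
}

oracle_kl2 <- function(p_emp, p_mod) {
  s <- 0
  for (k in seq_along(p_emp)) {
    if (p_emp[k] > 0) s <- s + p_emp[k] * log2(p_emp[k] / p_mod[k])
  }
  s
}

# random pMEM parameter draw for property tests
random_params <- function(N, h_sd = 0.5, J_sd = 0.3) {
  J <- matrix(0, N, N)
  J[upper.tri(J)] <- rnorm(N * (N - 1) / 2, 0, J_sd)
  J <- J + t(J)
  pmem_params(rnorm(N, 0, h_sd), J)
}

# quick cohort of iid-parameter participants (exchangeable h and J entries)
random_cohort <- function(n_part, N, h_sd = 0.4, J_sd = 0.3,
                          groups = NULL) {
  params <- replicate(n_part, random_params(N, h_sd, J_sd), simplify = FALSE)
  if (is.null(groups))
    groups <- rep(c("control", "patient"), length.out = n_part)
  pmem_cohort(sprintf("p%02d", seq_len(n_part)), groups, params)
}
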