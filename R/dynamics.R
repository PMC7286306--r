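#' Metropolis-Hastings simulation of network state dynamics
#'
#' Uses a fitted pMEM as a generative model. Starting from a uniformly random
#' state, each step selects one of the current state's `N` Hamming-1
#' neighbours with probability `1/N`; the transition occurs with probability
#' `exp(E(current) - E(proposed))` when the proposal is uphill and 1
#' otherwise. Rejected proposals re-count the current state (the standard
#' Metropolis dwell-time convention), so the chain's stationary distribution
#' is the model's Boltzmann distribution. The defaults — 20,000 steps with
#' the first 1,000 discarded, leaving 19,000 retained states — follow the
#' standard protocol for basin-duration estimation.
#'
#' @param p A [pmem_params()] object or [fit_pmem()] result.
#' @param total_steps Total simulated steps (default 20000).
#' @param burn_in Initial steps discarded (default 1000);
#'   `0 <= burn_in < total_steps`.
#' @param seed Integer seed for reproducibility (optional; the current RNG
#'   stream is used when `NULL`).
#' @return Object of class `mh_trajectory`: `states` (integer vector of
#'   retained state indices, length `total_steps - burn_in`), `seed`,
#'   `burn_in`, `total_steps`, `N`.
#' @export
simulate_mh <- function(p, total_steps = 20000L, burn_in = 1000L,
                        seed = NULL) {
  if (inherits(p, "pmem_fit")) p <- p$params
  stopifnot(inherits(p, "pmem_params"))
  total_steps <- as.integer(total_steps)
  burn_in <- as.integer(burn_in)
  if (total_steps <= 0L || burn_in < 0L || burn_in >= total_steps)
    stop("simulate_mh: need total_steps > burn_in >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))

  e <- state_energies(p)
  nb <- neighbour_matrix(p$N)
  props <- sample.int(p$N, total_steps, replace = TRUE)
  us <- stats::runif(total_steps)
  states <- integer(total_steps)
  k1 <- sample.int(length(e), 1L)          # 1-based current state
  for (t in seq_len(total_steps)) {
    cand <- nb[k1, props[t]] + 1L
    dE <- e[cand] - e[k1]
    if (dE <= 0 || us[t] < exp(-dE)) k1 <- cand
    states[t] <- k1
  }
  structure(list(states = states[(burn_in + 1L):total_steps] - 1L,
                 seed = seed, burn_in = burn_in, total_steps = total_steps,
                 N = p$N),
            class = "mh_trajectory")
}

#' @export
print.mh_trajectory <- function(x, ...) {
  cat(sprintf("<mh_trajectory> %d retained steps (N = %d, burn-in %d, seed %s)\n",
              length(x$states), x$N, x$burn_in,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Proportion of simulated time spent in each energy basin
#'
#' Maps every retained trajectory state to its basin of attraction and
#' returns the fraction of steps spent in each basin — the basin duration, a
#' summary of how strongly each attractor-like minimum captures the
#' simulated dynamics.
#'
#' @param traj An [simulate_mh()] trajectory.
#' @param part A [assign_basins()] partition on the same `N` (typically from
#'   the aggregated group landscape; pass an individual landscape's partition
#'   to measure against that instead).
#' @return Tibble with `state` (minimum index), `pattern`, `proportion`
#'   (non-negative, summing to 1 over the partition's minima).
#' @export
basin_durations <- function(traj, part) {
  stopifnot(inherits(traj, "mh_trajectory"),
            inherits(part, "basin_partition"))
  if (traj$N != part$N)
    stop("basin_durations: trajectory and partition disagree on N")
  basins <- part$basin_of[traj$states + 1L]
  counts <- table(factor(basins, levels = part$minima$state))
  tibble::tibble(state = part$minima$state,
                 pattern = part$minima$pattern,
                 proportion = as.numeric(counts) / length(basins))
}
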