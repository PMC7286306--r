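#' Pairwise maximum entropy model parameters
#'
#' Parameters of the pairwise maximum entropy model (pMEM; the Ising model):
#' a bias vector `h` (intensity of oscillatory activity per region) and a
#' symmetric zero-diagonal coupling matrix `J` (co-activation strength per
#' region pair). The energy of state `s` is
#' `E(s) = - sum_i h_i r_i - (1/2) sum_{i != j} J_ij r_i r_j`,
#' and states occur with Boltzmann probability `P(s) proportional to exp(-E(s))`.
#'
#' @param h Numeric length-`N` bias vector.
#' @param J Numeric `N x N` symmetric matrix with zero diagonal.
#' @param roi_names Optional region labels.
#' @return A `pmem_params` object.
#' @examples
#' p <- pmem_params(c(0.5, -0.5), matrix(c(0, 0.25, 0.25, 0), 2))
#' state_energies(p)
#' @export
pmem_params <- function(h, J, roi_names = NULL) {
  h <- as.numeric(h)
  J <- as.matrix(J)
  N <- length(h)
  if (!all(dim(J) == N)) stop("pmem_params: J must be N x N")
  if (!isTRUE(all.equal(J, t(J), tolerance = 1e-10)))
    stop("pmem_params: J must be symmetric")
  if (any(abs(diag(J)) > 1e-12))
    stop("pmem_params: J must have zero diagonal")
  if (N > 15L)
    stop("pmem_params: exact enumeration supports at most N = 15 regions")
  if (!all(is.finite(h)) || !all(is.finite(J)))
    stop("pmem_params: parameters must be finite")
  J <- (J + t(J)) / 2
  diag(J) <- 0
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(N))
  stopifnot(length(roi_names) == N)
  structure(list(h = stats::setNames(h, roi_names), J = J,
                 roi_names = roi_names, N = N),
            class = "pmem_params")
}

#' @export
print.pmem_params <- function(x, ...) {
  cat(sprintf("<pmem_params> N = %d regions; |h| in [%.3g, %.3g]; |J| max %.3g\n",
              x$N, min(abs(x$h)), max(abs(x$h)), max(abs(x$J))))
  invisible(x)
}

# Design matrix of sufficient statistics over all 2^N states:
# columns are the N spins followed by the N(N-1)/2 upper-triangle products
# s_i s_j (column-major upper.tri order). Energies are -X %*% theta with
# theta = c(h, J[upper.tri]).
pmem_design <- function(N) {
  S <- state_matrix(N)
  ut <- which(upper.tri(diag(N)), arr.ind = TRUE)
  P <- nrow(ut)
  XP <- S[, ut[, 1], drop = FALSE] * S[, ut[, 2], drop = FALSE]
  list(S = S, X = cbind(S, XP), pairs = ut, P = P)
}

params_to_theta <- function(p) c(p$h, p$J[upper.tri(p$J)])

theta_to_params <- function(theta, N, roi_names = NULL) {
  h <- theta[seq_len(N)]
  J <- matrix(0, N, N)
  J[upper.tri(J)] <- theta[-seq_len(N)]
  J <- J + t(J)
  pmem_params(h, J, roi_names)
}

#' State energies under a pMEM
#'
#' @param p A [pmem_params()] object.
#' @return `state_energies()`: numeric vector of length `2^N`, entry `k + 1`
#'   holding `E(s_k)`. `energy_of_state()`: the energy of a single state.
#' @export
state_energies <- function(p) {
  stopifnot(inherits(p, "pmem_params"))
  d <- pmem_design(p$N)
  as.numeric(-(d$X %*% params_to_theta(p)))
}

#' @param k Integer state index in `0:(2^N - 1)` (vectorized).
#' @rdname state_energies
#' @export
energy_of_state <- function(k, p) {
  stopifnot(inherits(p, "pmem_params"), all(k >= 0), all(k < 2^p$N))
  s <- state_vector(k, p$N)
  if (!is.matrix(s)) s <- matrix(s, nrow = 1)
  as.numeric(-(s %*% p$h) - 0.5 * rowSums((s %*% p$J) * s))
}

#' Boltzmann state probabilities
#'
#' Enumerates `P(s_k) = exp(-E(s_k)) / sum_k' exp(-E(s_k'))` over all `2^N`
#' states, with max-shift stabilization so arbitrarily large |E| cannot
#' overflow.
#'
#' @param p A [pmem_params()] object (`N <= 15`).
#' @return Numeric probability vector of length `2^N` (index `k + 1` = state
#'   `k`), summing to 1.
#' @export
state_probabilities <- function(p) {
  e <- state_energies(p)
  w <- exp(-(e - min(e)))
  w / sum(w)
}

#' Exact model moments of a pMEM
#'
#' Expectations of per-region activation and pairwise co-occurrence under the
#' enumerated Boltzmann distribution.
#'
#' @param p A [pmem_params()] object.
#' @return List with `mean_activation` (length `N`) and `cooccurrence`
#'   (`N x N` symmetric, unit diagonal).
#' @export
model_moments <- function(p) {
  stopifnot(inherits(p, "pmem_params"))
  d <- pmem_design(p$N)
  pr <- state_probabilities(p)
  m <- as.numeric(crossprod(d$S, pr))
  cooc <- crossprod(d$S * pr, d$S)
  cooc <- (cooc + t(cooc)) / 2
  diag(cooc) <- 1
  list(mean_activation = stats::setNames(m, p$roi_names),
       cooccurrence = cooc)
}

clamp_means <- function(m, T_n) {
  lim <- 1 - 1 / (2 * T_n)
  out <- pmin(pmax(m, -lim), lim)
  if (any(out != m))
    warning("empirical means of +/-1 clamped to +/-(1 - 1/(2T)) before fitting")
  out
}

#' Fit the pairwise maximum entropy model by gradient ascent
#'
#' Iterates the moment-matching updates
#' `h_i <- h_i + eps (<r_i>_emp - <r_i>_mod)` and
#' `J_ij <- J_ij + eps (<r_i r_j>_emp - <r_i r_j>_mod)`
#' from `h = 0, J = 0` until the largest moment discrepancy falls below `tol`
#' or `max_iter` is reached. The default schedule adapts the learning rate
#' (halved whenever the gap increases, grown slightly while it shrinks);
#' `legacy_mode = TRUE` instead runs the fixed schedule used in the original
#' energy-landscape literature, `eps = 1e-8` for up to `5e6` iterations with
#' no adaptation.
#'
#' The maximum-entropy problem is convex, so the moment-matching solution is
#' unique; when the empirical moments are realizable the fit recovers the
#' generating parameters.
#'
#' @param stats An [empirical_stats()] object (means with `|<r_i>| = 1` are
#'   clamped to `+/-(1 - 1/(2T))`).
#' @param lr Initial learning rate (default 0.05).
#' @param max_iter Iteration cap (default 50000).
#' @param tol Convergence tolerance on the max absolute moment gap
#'   (default 1e-6).
#' @param adaptive Adapt the learning rate (default TRUE).
#' @param legacy_mode If TRUE, use `lr = 1e-8`, `max_iter = 5e6`,
#'   non-adaptive — a fidelity preset matching the literature protocol, not a
#'   practical convergence criterion.
#' @return A `pmem_fit` object: `params`, `n_iter`, `max_moment_gap`,
#'   `converged`, plus goodness of fit `accuracy_d`, `kl_pair` (D2) and
#'   `kl_indep` (D1); see [accuracy_index()].
#' @export
fit_pmem <- function(stats, lr = 0.05, max_iter = 50000L, tol = 1e-6,
                     adaptive = TRUE, legacy_mode = FALSE) {
  stopifnot(inherits(stats, "empirical_stats"))
  if (legacy_mode) {
    lr <- 1e-8
    max_iter <- 5e6
    adaptive <- FALSE
  }
  N <- length(stats$mean_activation)
  if (N > 15L) stop("fit_pmem: exact fitting supports at most N = 15 regions")
  m_emp <- clamp_means(as.numeric(stats$mean_activation), stats$T)
  cooc <- stats$cooccurrence
  if (!all(is.finite(m_emp)) || !all(is.finite(cooc)))
    stop("fit_pmem: non-finite empirical moments")
  if (any(abs(m_emp) > 1) || any(abs(cooc) > 1 + 1e-12))
    stop("fit_pmem: moments must lie in [-1, 1]")

  d <- pmem_design(N)
  target <- c(m_emp, cooc[upper.tri(cooc)])
  theta <- numeric(N + d$P)

  # per-sample log-likelihood target . theta - log Z and model moments from
  # one enumeration; the likelihood is the quantity gradient ascent
  # increases monotonically, so the adaptive schedule backtracks on it (the
  # max moment gap itself is not monotone along the ascent path)
  evaluate <- function(th) {
    e <- d$X %*% th            # = -energy
    m <- max(e)
    w <- exp(e - m)
    Z <- sum(w)
    pr <- as.numeric(w / Z)
    list(mom = as.numeric(crossprod(d$X, pr)),
         ll = sum(target * th) - (m + log(Z)))
  }

  cur <- evaluate(theta)
  grad <- target - cur$mom
  gap <- max(abs(grad))
  gap0 <- gap
  iter <- 0L
  while (gap > tol && iter < max_iter) {
    iter <- iter + 1L
    theta_new <- theta + lr * grad
    nxt <- evaluate(theta_new)
    if (adaptive && nxt$ll < cur$ll) {
      lr <- lr / 2            # overshoot: reject step, shrink
      if (lr < 1e-14) break
      next
    }
    theta <- theta_new
    cur <- nxt
    grad <- target - cur$mom
    gap <- max(abs(grad))
    if (adaptive) lr <- min(lr * 1.1, 1)
    if (gap > 10 * max(gap0, 1e-12) && !adaptive)
      stop("fit_pmem: diverging (moment gap grew 10-fold); use a smaller lr")
  }

  params <- theta_to_params(theta, N, stats$roi_names)
  fit_ind <- fit_independent(stats)
  acc <- accuracy_index(stats$state_probs, params, fit_ind)
  structure(list(params = params,
                 n_iter = iter,
                 max_moment_gap = gap,
                 converged = gap <= tol,
                 accuracy_d = acc$d,
                 kl_pair = acc$D2,
                 kl_indep = acc$D1,
                 independent = fit_ind,
                 stats = stats),
            class = "pmem_fit")
}

#' @export
print.pmem_fit <- function(x, ...) {
  cat(sprintf(
    "<pmem_fit> N = %d; %s after %d iterations (max moment gap %.2e)\n",
    x$params$N, if (x$converged) "converged" else "NOT converged",
    x$n_iter, x$max_moment_gap))
  cat(sprintf("  accuracy index d = %.4f (D1 = %.4g, D2 = %.4g bits)\n",
              x$accuracy_d, x$kl_indep, x$kl_pair))
  invisible(x)
}

#' Fit the independent maximum entropy model
#'
#' The independent MEM is the pMEM restricted to `J = 0`; its maximum-entropy
#' solution matches the empirical means exactly with
#' `h_i = artanh(<r_i>_emp)` (means of exactly +/-1 are clamped to
#' `+/-(1 - 1/(2T))` first).
#'
#' @inheritParams fit_pmem
#' @return A [pmem_params()] object with `J = 0`.
#' @export
fit_independent <- function(stats) {
  stopifnot(inherits(stats, "empirical_stats"))
  N <- length(stats$mean_activation)
  m <- clamp_means(as.numeric(stats$mean_activation), stats$T)
  pmem_params(atanh(m), matrix(0, N, N), stats$roi_names)
}

#' Accuracy index of the pairwise model fit
#'
#' Quantifies how much of the empirical state distribution the pairwise model
#' captures beyond the independent model: `d = (D1 - D2) / D1`, where `D2` is
#' the Kullback-Leibler divergence (base 2) from the empirical distribution
#' to the pairwise model and `D1` the analogue for the independent model.
#' `d = 1` when the pairwise model reproduces the empirical distribution
#' exactly; `d = 0` when pairwise interactions add nothing. Sums run over
#' states with positive empirical probability (`0 log 0 := 0`); if `D1 = 0`,
#' `d` is defined as 0.
#'
#' @param state_probs Named numeric vector of empirical state probabilities
#'   (names = state indices), or an [empirical_stats()] object.
#' @param fit_pair,fit_indep [pmem_params()] for the pairwise and independent
#'   fits (same `N`).
#' @return List with elements `d`, `D1`, `D2`.
#' @export
accuracy_index <- function(state_probs, fit_pair, fit_indep) {
  if (inherits(state_probs, "empirical_stats"))
    state_probs <- state_probs$state_probs
  stopifnot(inherits(fit_pair, "pmem_params"),
            inherits(fit_indep, "pmem_params"))
  if (fit_pair$N != fit_indep$N)
    stop("accuracy_index: models disagree on N")
  p_emp <- as.numeric(state_probs)
  if (abs(sum(p_emp) - 1) > 1e-8)
    stop("accuracy_index: empirical probabilities must sum to 1")
  k <- as.integer(names(state_probs))
  if (any(k < 0) || any(k >= 2^fit_pair$N))
    stop("accuracy_index: state index out of range for N")
  kl2 <- function(model) {
    pm <- state_probabilities(model)[k + 1]
    keep <- p_emp > 0
    sum(p_emp[keep] * (log2(p_emp[keep]) - log2(pm[keep])))
  }
  D2 <- kl2(fit_pair)
  D1 <- kl2(fit_indep)
  # a numerically vanishing D1 (factorized empirical law, matched exactly by
  # the analytic independent fit) defines d = 0; without the threshold the
  # ratio is 0/0 against the pairwise fit's convergence error
  d <- if (D1 <= 1e-10) 0 else (D1 - D2) / D1
  list(d = d, D1 = D1, D2 = D2)
}

#' Empirical statistics implied by a known state distribution
#'
#' Builds an [empirical_stats()] object whose moments are the exact
#' expectations under a given distribution over the `2^N` states — useful for
#' fitting to a target distribution directly (e.g. a Boltzmann or factorized
#' law) rather than to sampled data.
#'
#' @param probs Numeric vector of length `2^N` (index `k + 1` = state `k`),
#'   non-negative, summing to 1; or a named sparse vector with state-index
#'   names.
#' @param N Number of regions.
#' @param T Nominal sample count recorded in the result (default `1e6`); it
#'   only affects the clamp applied to degenerate means of exactly +/-1.
#' @param roi_names Optional labels.
#' @return An `empirical_stats` object.
#' @export
empirical_stats_from_probs <- function(probs, N, T = 1e6, roi_names = NULL) {
  if (is.null(names(probs))) {
    stopifnot(length(probs) == 2^N)
    k <- 0:(2^N - 1)
    p <- as.numeric(probs)
  } else {
    k <- as.integer(names(probs))
    p <- as.numeric(probs)
  }
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(N))
  S <- state_matrix(N)[k + 1, , drop = FALSE]
  m <- as.numeric(crossprod(S, p))
  cooc <- crossprod(S * p, S)
  cooc <- (cooc + t(cooc)) / 2
  diag(cooc) <- 1
  keep <- p > 0
  structure(list(mean_activation = stats::setNames(m, roi_names),
                 cooccurrence = cooc,
                 state_probs = stats::setNames(p[keep], k[keep]),
                 T = T,
                 roi_names = roi_names),
            class = "empirical_stats")
}
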