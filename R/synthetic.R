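#' Specification of a synthetic cohort
#'
#' Collects the ground-truth settings for synthetic data generation:
#' network size, dispersion of the ground-truth parameters, sampling mode,
#' and an optional planted group effect (an energy increment at chosen
#' minima for the patient group, mirroring elevated minimum energies in a
#' clinical group).
#'
#' @param N Number of regions (<= 15). Default 6 (sensorimotor-network
#'   sized); use 10 for fronto-parietal/default-mode-sized networks.
#' @param h_scale,J_scale Standard deviations of the ground-truth bias and
#'   coupling entries (defaults 0.3 and 0.15).
#' @param J_sparsity Fraction of couplings set exactly to zero (default 0).
#' @param T Samples per participant (default 20000).
#' @param mode Sampling mode: `"iid"` (independent Boltzmann draws) or
#'   `"mh"` (thinned Metropolis-Hastings, temporally correlated).
#' @param effect Optional planted effect: list with `delta` (energy
#'   increment, >= 0) and either `target_states` (integer state indices) or
#'   `n_targets` (number of non-global aggregated minima to perturb,
#'   default 1).
#' @param n_per_group Participants per group (default 26).
#' @param jitter_sd Between-participant parameter jitter s.d. (default 0.05).
#' @param seed Integer seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(N = 6L, h_scale = 0.3, J_scale = 0.15,
                           J_sparsity = 0, T = 20000L,
                           mode = c("iid", "mh"), effect = NULL,
                           n_per_group = 26L, jitter_sd = 0.05,
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(N >= 2L, N <= 15L, T >= 1L, h_scale >= 0, J_scale >= 0,
            J_sparsity >= 0, J_sparsity <= 1, n_per_group >= 1L,
            jitter_sd >= 0)
  if (!is.null(effect)) {
    stopifnot(is.list(effect), !is.null(effect$delta), effect$delta >= 0)
    if (is.null(effect$target_states) && is.null(effect$n_targets))
      effect$n_targets <- 1L
  }
  structure(list(N = as.integer(N), h_scale = h_scale, J_scale = J_scale,
                 J_sparsity = J_sparsity, T = as.integer(T), mode = mode,
                 effect = effect, n_per_group = as.integer(n_per_group),
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Draw a ground-truth pMEM
#'
#' Biases `h_i ~ N(0, h_scale^2)` and symmetric couplings
#' `J_ij ~ N(0, J_scale^2)` with a fraction `J_sparsity` of the pairs set to
#' zero. Reproducible from the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [pmem_params()] object.
#' @export
sample_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  N <- spec$N
  h <- stats::rnorm(N, 0, spec$h_scale)
  P <- N * (N - 1) / 2
  jvals <- stats::rnorm(P, 0, spec$J_scale)
  if (spec$J_sparsity > 0) {
    nzero <- round(spec$J_sparsity * P)
    jvals[sample.int(P, nzero)] <- 0
  }
  J <- matrix(0, N, N)
  J[upper.tri(J)] <- jvals
  J <- J + t(J)
  pmem_params(h, J)
}

#' Sample binary state series from a pMEM
#'
#' Draws `T` network states from a model's Boltzmann distribution, either
#' independently (`mode = "iid"`, exact enumeration sampler) or as a thinned
#' Metropolis-Hastings chain (`mode = "mh"`), which carries the temporal
#' autocorrelation of the sampler's single-flip dynamics.
#'
#' @param p A [pmem_params()] object.
#' @param T Number of samples.
#' @param mode `"iid"` or `"mh"`.
#' @param seed Optional integer seed.
#' @param thin Thinning factor for MH mode (default 10 accepted-step
#'   spacing).
#' @return A [binary_states()] matrix of dimension `T x N`.
#' @export
sample_state_series <- function(p, T, mode = c("iid", "mh"), seed = NULL,
                                thin = 10L) {
  if (inherits(p, "pmem_fit")) p <- p$params
  stopifnot(inherits(p, "pmem_params"), T >= 1L)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (mode == "iid") {
    pr <- state_probabilities(p)
    k <- sample.int(length(pr), T, replace = TRUE, prob = pr) - 1L
  } else {
    total <- 1000L + T * as.integer(thin)
    traj <- simulate_mh(p, total_steps = total, burn_in = 1000L)
    k <- traj$states[seq.int(thin, length(traj$states), by = thin)][seq_len(T)]
  }
  binary_states(state_vector(k, p$N), p$roi_names)
}

#' Continuous band-limited signals realizing a binary state pattern
#'
#' Constructs per-region narrowband signals whose amplitude envelopes encode
#' a target binary series: each target state is held for
#' `samples_per_state` samples; the envelope takes a high or low log-normal
#' level where the target is +1 or -1, smoothed with a short moving average;
#' the envelope multiplies a band-centred cosine carrier (random phase per
#' region) and white noise is added at the requested signal-to-noise ratio.
#' Running `bandpass_filter() |> hilbert_envelope() |> binarize_median()` on
#' the result recovers at least ~90% of the target labels at `snr >= 10`
#' when the target series is balanced per column, as median-split-derived
#' series are by construction (the median threshold cannot reproduce an
#' imbalanced high/low split); `snr = 0` produces pure noise and chance
#' recovery.
#'
#' @param b A [binary_states()] target series.
#' @param fs Sampling rate in Hz (default 250).
#' @param band A [frequency_band()] (default alpha 8-12 Hz).
#' @param snr Envelope-power to noise-power ratio; `0` yields pure noise,
#'   `Inf` no noise. Default 10.
#' @param seed Optional integer seed.
#' @param samples_per_state Samples each binary state is held for
#'   (default 125, i.e. 500 ms at 250 Hz — long against the inverse analysis
#'   bandwidth, so the amplitude modulation survives narrowband filtering).
#' @return A [roi_timeseries()] of length `nrow(b$states) * samples_per_state`.
#' @export
synth_envelope_signals <- function(b, fs = 250, band = frequency_band("alpha", 8, 12),
                                   snr = 10, seed = NULL,
                                   samples_per_state = 125L) {
  stopifnot(inherits(b, "binary_states"), inherits(band, "frequency_band"),
            snr >= 0, samples_per_state >= 1L)
  if (band$hi >= fs / 2) stop("synth_envelope_signals: band exceeds Nyquist")
  if (!is.null(seed)) set.seed(as.integer(seed))
  S <- b$states
  if (any(colSums(S > 0) %in% c(0L, nrow(S))))
    warning("synth_envelope_signals: degenerate all-high or all-low column(s); recovery guarantee void")
  n <- nrow(S) * samples_per_state
  t_idx <- seq_len(n)
  fc <- (band$lo + band$hi) / 2
  # log-normal high/low envelope levels (factor ~2.7 apart)
  lo_lvl <- exp(-0.5)
  hi_lvl <- exp(0.5)
  width <- max(3L, round(samples_per_state / 3))
  kern <- rep(1 / width, width)
  out <- matrix(0, n, ncol(S))
  for (j in seq_len(ncol(S))) {
    env <- ifelse(rep(S[, j], each = samples_per_state) > 0, hi_lvl, lo_lvl)
    # pad with edge values so the moving average has no NA ends
    padded <- c(rep(env[1], width), env, rep(env[length(env)], width))
    sm <- as.numeric(stats::filter(padded, kern, sides = 2))
    env <- sm[(width + 1):(width + length(env))]
    phase <- stats::runif(1, 0, 2 * pi)
    clean <- env * cos(2 * pi * fc * t_idx / fs + phase)
    if (snr == 0) {
      out[, j] <- stats::rnorm(n, 0, 1)
    } else if (is.infinite(snr)) {
      out[, j] <- clean
    } else {
      noise_sd <- sqrt(stats::var(clean) / snr)
      out[, j] <- clean + stats::rnorm(n, 0, noise_sd)
    }
  }
  roi_timeseries(out, fs, b$roi_names)
}

#' Plant an exact energy increment at target states
#'
#' Adjusts `(h, J)` by the minimum-norm parameter change that raises the
#' energy of each target state by exactly `delta`, leaving the rest of the
#' landscape to absorb the (reported) spillover. Because energies are linear
#' in the parameters, the adjustment solves
#' `min ||dtheta||  s.t.  X_T dtheta = -delta` where `X_T` holds the target
#' states' sufficient statistics; this makes the planted effect the exact
#' quantity the pipeline later measures.
#'
#' @param p A [pmem_params()] object.
#' @param target_states Integer state indices to perturb.
#' @param delta Energy increment (scalar or per-target vector).
#' @return A `pmem_params` object with attributes `"spillover_rms"` (rms
#'   energy change over non-target states) and `"delta"`. Errors if the
#'   targets' statistics are linearly dependent (increment not realizable
#'   exactly).
#' @export
plant_energy_effect <- function(p, target_states, delta) {
  stopifnot(inherits(p, "pmem_params"), length(target_states) >= 1L,
            all(target_states >= 0), all(target_states < 2^p$N))
  delta <- rep_len(delta, length(target_states))
  d <- pmem_design(p$N)
  XT <- d$X[target_states + 1L, , drop = FALSE]
  G <- XT %*% t(XT)
  sol <- tryCatch(solve(G, delta), error = function(e)
    stop("plant_energy_effect: target energies not exactly realizable ",
         "(dependent targets); residual system singular"))
  dtheta <- -as.numeric(t(XT) %*% sol)
  theta_new <- params_to_theta(p) + dtheta
  out <- theta_to_params(theta_new, p$N, p$roi_names)
  dE <- -as.numeric(d$X %*% dtheta)
  attr(out, "spillover_rms") <-
    sqrt(mean(dE[-(target_states + 1L)]^2))
  attr(out, "delta") <- delta
  out
}

#' Generate a two-group synthetic cohort with a planted landscape effect
#'
#' Builds a cohort emulating a patient/control study: every participant's
#' ground truth is a jittered copy of one base model (between-participant
#' variability `jitter_sd` on `h` and the upper-triangle of `J`); patients
#' are additionally perturbed so chosen non-global local minima of the base
#' landscape gain energy `+delta` (via [plant_energy_effect()], the exact
#' quantity the downstream pipeline estimates). With `delta = 0` (or no
#' `effect`), the two groups are identically distributed. Per-participant
#' binary state series are sampled from each ground-truth model.
#'
#' @param spec A [synthetic_spec()] with an optional `effect`.
#' @param fit Also fit the pMEM to each participant's sampled series
#'   (default TRUE); set FALSE to receive ground-truth parameters only.
#' @param ... Passed to [fit_pmem()] (e.g. `tol`).
#' @return List with `cohort` (a [pmem_cohort()] of fitted — or ground-truth,
#'   when `fit = FALSE` — parameters), `truth` (cohort of ground-truth
#'   parameters), `target_states` (planted minima indices, if any) and
#'   `base` (the unperturbed base model).
#' @export
make_cohort <- function(spec, fit = TRUE, ...) {
  stopifnot(inherits(spec, "synthetic_spec"))
  base <- sample_ground_truth(spec)
  set.seed(spec$seed + 1L)
  N <- spec$N
  P <- N * (N - 1) / 2

  target_states <- integer(0)
  if (!is.null(spec$effect) && spec$effect$delta > 0) {
    L_base <- energy_landscape(base)
    if (!is.null(spec$effect$target_states)) {
      target_states <- as.integer(spec$effect$target_states)
    } else {
      mins <- find_local_minima(L_base)
      gmin <- global_minimum(L_base)$state
      cand <- setdiff(mins$state, gmin)
      if (length(cand) < spec$effect$n_targets)
        stop("make_cohort: base landscape has too few non-global minima to perturb; ",
             "increase J_scale or pass explicit target_states")
      # prefer targets with the largest local depth (margin to the lowest
      # neighbour), so the elevated minimum survives the perturbation
      depth <- vapply(cand, function(k) {
        min(L_base$energies[adjacent_states(k, N) + 1L]) -
          L_base$energies[k + 1L]
      }, numeric(1))
      target_states <- cand[order(-depth)][seq_len(spec$effect$n_targets)]
    }
    # feasibility: each target must remain a strict local minimum after the
    # full elevation (the aggregated cohort sees only half of it)
    planted_base <- plant_energy_effect(base, target_states,
                                        spec$effect$delta)
    Lp <- energy_landscape(planted_base)
    still_min <- target_states %in% find_local_minima(Lp)$state
    if (!all(still_min))
      stop("make_cohort: delta = ", spec$effect$delta,
           " destroys the targeted minimum (residual depth <= 0); ",
           "use a smaller delta or a deeper target")
  }

  n_total <- 2L * spec$n_per_group
  group <- rep(c("control", "patient"), each = spec$n_per_group)
  ids <- sprintf("S%02d", seq_len(n_total))
  jitter_params <- function() {
    th <- params_to_theta(base) +
      stats::rnorm(N + P, 0, spec$jitter_sd)
    theta_to_params(th, N, base$roi_names)
  }
  truth_params <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    pi_ <- jitter_params()
    if (group[i] == "patient" && length(target_states) > 0)
      pi_ <- plant_energy_effect(pi_, target_states, spec$effect$delta)
    attributes(pi_)[c("spillover_rms", "delta")] <- NULL
    truth_params[[i]] <- pi_
  }
  truth <- pmem_cohort(ids, group, truth_params)

  series_seeds <- sample.int(2^30, n_total)
  fitted_params <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    b <- sample_state_series(truth_params[[i]], spec$T, mode = spec$mode,
                             seed = series_seeds[i])
    if (fit) {
      fitted_params[[i]] <- fit_pmem(empirical_stats(b), ...)$params
    }
  }
  cohort <- if (fit) pmem_cohort(ids, group, fitted_params) else truth
  list(cohort = cohort, truth = truth, target_states = target_states,
       base = base)
}
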