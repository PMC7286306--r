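two_roi_example <- function() {
  pmem_params(c(0.5, -0.5), matrix(c(0, 0.25, 0.25, 0), 2))
}

test_that("energies reproduce the hand-evaluated two-ROI table", {
  p <- two_roi_example()
  expect_equal(energy_of_state(state_index(c(1, 1)), p), -0.25)
  expect_equal(energy_of_state(state_index(c(1, -1)), p), -0.75)
  expect_equal(energy_of_state(state_index(c(-1, 1)), p), 1.25)
  expect_equal(energy_of_state(state_index(c(-1, -1)), p), -0.25)

  p0 <- pmem_params(numeric(3), matrix(0, 3, 3))
  expect_equal(state_energies(p0), rep(0, 8))
})

test_that("energy matches the brute-force double-sum for random draws, with sign symmetry", {
  withr::with_seed(10, {
    for (rep in 1:20) {
      N <- sample(2:5, 1)
      p <- random_params(N)
      k <- sample(0:(2^N - 1), 1)
      s <- state_vector(k, N)
      expect_equal(energy_of_state(k, p), oracle_energy(s, p$h, p$J))
      # E(s; h, J) = E(-s; -h, J)
      pneg <- pmem_params(-p$h, p$J)
      expect_equal(energy_of_state(k, p),
                   energy_of_state(state_index(-s), pneg))
    }
  })
})

test_that("invalid J matrices are rejected", {
  expect_error(pmem_params(c(0, 0), matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(pmem_params(c(0, 0), matrix(c(1, 0, 0, 1), 2)), "diagonal")
})

test_that("Boltzmann probabilities are normalized, ordered by energy, gauge invariant", {
  p0 <- pmem_params(numeric(3), matrix(0, 3, 3))
  expect_equal(state_probabilities(p0), rep(1 / 8, 8))

  p <- two_roi_example()
  pr <- state_probabilities(p)
  expect_equal(which.max(pr) - 1L, state_index(c(1, -1)))
  expect_equal(pr, oracle_probs(p$h, p$J))

  withr::with_seed(11, {
    for (rep in 1:10) {
      q <- random_params(sample(2:5, 1))
      prq <- state_probabilities(q)
      expect_equal(sum(prq), 1, tolerance = 1e-12)
      e <- state_energies(q)
      # strictly decreasing in energy
      expect_equal(order(e), order(-prq))
      # adding a constant to all energies leaves probabilities unchanged
      w <- exp(-(e + 123.4 - min(e + 123.4)))
      expect_equal(w / sum(w), prq, tolerance = 1e-12)
    }
  })
})

test_that("probabilities survive extreme energies without overflow", {
  p <- pmem_params(c(350, -350), matrix(0, 2, 2))
  pr <- state_probabilities(p)
  expect_true(all(is.finite(pr)))
  expect_equal(sum(pr), 1)
})

test_that("model moments match enumeration and the independent-spin closed form", {
  p0 <- pmem_params(numeric(4), matrix(0, 4, 4))
  mm0 <- model_moments(p0)
  expect_equal(as.numeric(mm0$mean_activation), rep(0, 4))
  expect_equal(mm0$cooccurrence, diag(4), ignore_attr = TRUE)

  h <- c(0.8, -0.3, 1.2)
  pi_ <- pmem_params(h, matrix(0, 3, 3))
  expect_equal(as.numeric(model_moments(pi_)$mean_activation), tanh(h))

  p <- two_roi_example()
  mm <- model_moments(p)
  om <- oracle_moments(p$h, p$J)
  expect_equal(as.numeric(mm$mean_activation), om$mean)
  expect_equal(mm$cooccurrence, om$cooc, ignore_attr = TRUE)
})

test_that("gradient-ascent fit recovers generating parameters from exact moments", {
  withr::with_seed(12, {
    for (N in c(4, 6)) {
      truth <- random_params(N, h_sd = 0.4, J_sd = 0.3)
      st <- empirical_stats_from_probs(state_probabilities(truth), N)
      fit <- fit_pmem(st, tol = 1e-6)
      expect_true(fit$converged)
      expect_lt(max(abs(fit$params$h - truth$h)), 1e-3)
      expect_lt(max(abs(fit$params$J - truth$J)), 1e-3)
      # fitted moments reproduce the empirical ones within tol
      mm <- model_moments(fit$params)
      expect_lt(max(abs(mm$mean_activation - st$mean_activation)), 1e-5)
    }
  })
})

test_that("zero moments fit to the uniform model", {
  st <- empirical_stats(binary_states(cbind(c(1, 1, -1, -1),
                                            c(1, -1, 1, -1))))
  fit <- fit_pmem(st)
  expect_lt(max(abs(fit$params$h)), 1e-8)
  expect_lt(max(abs(fit$params$J)), 1e-8)
})

test_that("fit from sampled data recovers parameters within 3 Fisher standard errors", {
  withr::with_seed(13, truth <- random_params(6, h_sd = 0.3, J_sd = 0.2))
  T_n <- 50000
  b <- sample_state_series(truth, T_n, seed = 77)
  fit <- fit_pmem(empirical_stats(b), tol = 1e-6)
  # asymptotic covariance of the MLE: inverse Fisher information / T,
  # Fisher info = covariance of the sufficient statistics under the model
  d <- energyscape:::pmem_design(6)
  pr <- state_probabilities(truth)
  mu <- as.numeric(crossprod(d$X, pr))
  I_fish <- crossprod(d$X * pr, d$X) - tcrossprod(mu)
  se <- sqrt(diag(solve(I_fish)) / T_n)
  err <- abs(energyscape:::params_to_theta(fit$params) -
               energyscape:::params_to_theta(truth))
  expect_true(all(err < 3 * se))
})

test_that("degenerate inputs are clamped or rejected", {
  st <- empirical_stats(binary_states(matrix(1, 10, 2)))
  expect_warning(fi <- fit_independent(st), "clamped")
  expect_equal(as.numeric(fi$h), rep(atanh(1 - 1 / 20), 2))

  bad <- st
  bad$mean_activation[1] <- NaN
  expect_error(suppressWarnings(fit_pmem(bad)), "non-finite")
})

test_that("independent fit inverts the mean via artanh", {
  b <- binary_states(cbind(rep(c(1, 1, 1, 1, -1), 4),
                           rep(c(1, -1, 1, -1, 1), 4)))
  st <- empirical_stats(b)
  fi <- fit_independent(st)
  expect_equal(as.numeric(fi$h), atanh(as.numeric(st$mean_activation)))
  expect_true(all(fi$J == 0))
  # round trip: model means equal empirical means
  expect_equal(as.numeric(model_moments(fi)$mean_activation),
               as.numeric(st$mean_activation), tolerance = 1e-12)
  # the printed value: artanh(0.6)
  expect_equal(atanh(0.6), 0.6931, tolerance = 1e-4)
})

test_that("accuracy index hits its defining limits and matches a brute-force KL", {
  # d = 1: empirical distribution equals the pairwise model's own law
  withr::with_seed(14, truth <- random_params(4, h_sd = 0.4, J_sd = 0.35))
  st <- empirical_stats_from_probs(state_probabilities(truth), 4)
  fit <- fit_pmem(st, tol = 1e-8)
  acc <- accuracy_index(st$state_probs, fit$params, fit_independent(st))
  expect_equal(acc$d, 1, tolerance = 1e-3)
  expect_lt(acc$D2, 1e-3)

  # d = 0: factorized empirical distribution
  m <- c(0.3, -0.2, 0.5, 0.1)
  p1 <- (1 + m) / 2
  S <- state_matrix(4)
  probs <- apply(S, 1, function(s) prod(ifelse(s > 0, p1, 1 - p1)))
  stf <- empirical_stats_from_probs(probs, 4)
  fitf <- fit_pmem(stf, tol = 1e-8)
  accf <- accuracy_index(stf$state_probs, fitf$params, fit_independent(stf))
  expect_equal(accf$d, 0, tolerance = 1e-3)

  # Parity (XOR-like) law on N=3, uniform over even-parity states: all
  # first- and second-order moments vanish, so both fits reduce to the
  # uniform model, D1 = D2 = 1 bit exactly (KL from 4 to 8 equiprobable
  # states) and d = 0 — the structure is purely third-order
  par_states <- which(rowSums(state_matrix(3) > 0) %% 2 == 0) - 1L
  probs3 <- numeric(8)
  probs3[par_states + 1] <- 1 / length(par_states)
  st3 <- empirical_stats_from_probs(probs3, 3)
  fit3 <- fit_pmem(st3, tol = 1e-8)
  fi3 <- fit_independent(st3)
  acc3 <- accuracy_index(st3$state_probs, fit3$params, fi3)
  k3 <- as.integer(names(st3$state_probs))
  D2_o <- oracle_kl2(as.numeric(st3$state_probs),
                     state_probabilities(fit3$params)[k3 + 1])
  D1_o <- oracle_kl2(as.numeric(st3$state_probs),
                     state_probabilities(fi3)[k3 + 1])
  expect_equal(acc3$D2, D2_o)
  expect_equal(acc3$D1, D1_o)
  expect_equal(acc3$D1, 1, tolerance = 1e-8)
  expect_equal(acc3$d, 0)

  # a genuinely pairwise-structured law sits strictly between the limits:
  # Boltzmann of a coupled model blended with the uniform distribution
  withr::with_seed(16, q <- random_params(3, h_sd = 0.3, J_sd = 0.6))
  blend <- 0.7 * state_probabilities(q) + 0.3 / 8
  stb <- empirical_stats_from_probs(blend, 3)
  fitb <- fit_pmem(stb, tol = 1e-8)
  fib <- fit_independent(stb)
  accb <- accuracy_index(stb$state_probs, fitb$params, fib)
  kb <- as.integer(names(stb$state_probs))
  expect_equal(accb$D2,
               oracle_kl2(as.numeric(stb$state_probs),
                          state_probabilities(fitb$params)[kb + 1]))
  expect_gt(accb$d, 0)
  expect_lt(accb$d, 1)
  expect_true(accb$D1 >= accb$D2 && accb$D2 >= 0)
})

test_that("D1 >= D2 >= 0 so d lies in [0, 1] on fitted data", {
  withr::with_seed(15, {
    for (rep in 1:5) {
      b <- sample_state_series(random_params(4), 2000, seed = rep)
      fit <- fit_pmem(empirical_stats(b))
      expect_gte(fit$kl_indep, fit$kl_pair - 1e-9)
      expect_gte(fit$kl_pair, 0)
      expect_gte(fit$accuracy_d, -1e-6)
      expect_lte(fit$accuracy_d, 1 + 1e-6)
    }
  })
})

test_that("legacy-mode preset runs the fixed small-step schedule", {
  b <- binary_states(cbind(c(1, 1, -1, -1), c(1, -1, 1, -1)))
  st <- empirical_stats(b)
  # uniform target: converged at iteration 0 even with the tiny step
  fit <- fit_pmem(st, legacy_mode = TRUE)
  expect_true(fit$converged)
  expect_equal(fit$n_iter, 0L)
})
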