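#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted pMEM
#'
#' One row per model parameter: the `N` biases (`term = "h"`) and the
#' `N(N-1)/2` couplings (`term = "J"`, upper triangle).
#'
#' @param x A [fit_pmem()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `roi`, `roi2` (NA for biases), `estimate`.
#' @export
tidy.pmem_fit <- function(x, ...) {
  p <- x$params
  ut <- which(upper.tri(p$J), arr.ind = TRUE)
  dplyr::bind_rows(
    tibble::tibble(term = "h", roi = p$roi_names, roi2 = NA_character_,
                   estimate = as.numeric(p$h)),
    tibble::tibble(term = "J",
                   roi = p$roi_names[ut[, 1]],
                   roi2 = p$roi_names[ut[, 2]],
                   estimate = p$J[ut])
  )
}

#' Glance at a fitted pMEM
#'
#' @param x A [fit_pmem()] result.
#' @param ... Unused.
#' @return One-row tibble: `N`, `n_iter`, `max_moment_gap`, `converged`,
#'   `accuracy_d`, `kl_indep` (D1), `kl_pair` (D2).
#' @export
glance.pmem_fit <- function(x, ...) {
  tibble::tibble(N = x$params$N, n_iter = x$n_iter,
                 max_moment_gap = x$max_moment_gap,
                 converged = x$converged, accuracy_d = x$accuracy_d,
                 kl_indep = x$kl_indep, kl_pair = x$kl_pair)
}

#' Tidy an energy landscape
#'
#' @param x An [energy_landscape()].
#' @param ... Unused.
#' @return Tibble with one row per state: `state`, `pattern`, `energy`,
#'   `probability` (Boltzmann weight of the landscape's energies) and
#'   `is_minimum`.
#' @export
tidy.energy_landscape <- function(x, ...) {
  w <- exp(-(x$energies - min(x$energies)))
  minima <- find_local_minima(x)
  k <- 0:(2^x$N - 1)
  tibble::tibble(state = k, pattern = state_pattern(k, x$N),
                 energy = x$energies,
                 probability = w / sum(w),
                 is_minimum = k %in% minima$state)
}

#' Tidy a leave-one-out classification result
#'
#' @param x A [loo_svm_classify()] result.
#' @param ... Unused.
#' @return The per-fold tibble (`id`, `truth`, `predicted`, `n_features`).
#' @export
tidy.loo_classification <- function(x, ...) x$folds

#' @rdname tidy.loo_classification
#' @return `glance()`: one-row tibble with `accuracy`, `sensitivity`,
#'   `specificity`, `n`.
#' @export
glance.loo_classification <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity, n = nrow(x$folds))
}
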