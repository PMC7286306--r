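#' Cohort of fitted participants
#'
#' A labelled collection of participants' fitted pMEM parameters for one
#' network/band, used for landscape aggregation, permutation testing and
#' classification.
#'
#' @param id Character/integer participant identifiers.
#' @param group Group labels, coerced to factor with levels
#'   `c("control", "patient")` ("patient" is the positive class for
#'   sensitivity/specificity).
#' @param params List of [pmem_params()] (one per participant, shared `N` and
#'   region order).
#' @param network,band Optional tags.
#' @return A `pmem_cohort` object; its `$participants` is a tibble with
#'   list-column `params`.
#' @export
pmem_cohort <- function(id, group, params, network = NULL, band = NULL) {
  stopifnot(length(id) == length(group), length(id) == length(params),
            all(vapply(params, inherits, logical(1), "pmem_params")))
  group <- factor(as.character(group), levels = c("control", "patient"))
  if (anyNA(group))
    stop("pmem_cohort: group labels must be 'control' or 'patient'")
  Ns <- vapply(params, function(p) p$N, integer(1))
  if (length(unique(Ns)) != 1L)
    stop("pmem_cohort: participants disagree on N")
  rois <- vapply(params, function(p) paste(p$roi_names, collapse = "|"),
                 character(1))
  if (length(unique(rois)) != 1L)
    stop("pmem_cohort: participants disagree on ROI order")
  structure(list(
    participants = tibble::tibble(id = as.character(id), group = group,
                                  params = params),
    N = Ns[1], roi_names = params[[1]]$roi_names,
    network = network, band = band),
    class = "pmem_cohort")
}

#' @export
print.pmem_cohort <- function(x, ...) {
  cat(sprintf("<pmem_cohort> %d participants (%d control / %d patient), N = %d\n",
              nrow(x$participants),
              sum(x$participants$group == "control"),
              sum(x$participants$group == "patient"), x$N))
  invisible(x)
}

# energy vectors of all participants as a 2^N x P matrix
cohort_energy_matrix <- function(cohort) {
  vapply(cohort$participants$params, state_energies, numeric(2^cohort$N))
}

#' Aggregated (group) energy landscape of a cohort
#'
#' Mean energy of every network state across the cohort's participants; used
#' to identify common local minima shared by the groups.
#'
#' @param cohort A [pmem_cohort()].
#' @param ids Optional subset of participant ids (e.g. a training fold).
#' @return An [energy_landscape()].
#' @export
aggregate_cohort <- function(cohort, ids = NULL) {
  stopifnot(inherits(cohort, "pmem_cohort"))
  keep <- if (is.null(ids)) rep(TRUE, nrow(cohort$participants))
          else cohort$participants$id %in% ids
  aggregate_landscapes(lapply(cohort$participants$params[keep],
                              energy_landscape))
}

# Batched null landscapes: for each permutation, independently shuffle each
# participant's h entries (across regions) and upper-triangle J entries
# (across region pairs, symmetry preserved), and average the resulting
# energy vectors across participants. Energies are linear in theta =
# c(h, J_upper), so the mean null landscape per permutation is
# -X %*% rowMeans(shuffled thetas), one matrix product for all permutations.
# Returns a 2^N x n_perm matrix of null mean energies.
null_mean_energies <- function(cohort, n_perm, design = pmem_design(cohort$N)) {
  N <- cohort$N
  P <- design$P
  thetas <- vapply(cohort$participants$params, params_to_theta,
                   numeric(N + P))
  n_part <- ncol(thetas)
  theta_bar <- matrix(0, N + P, n_perm)
  for (b in seq_len(n_perm)) {
    acc <- numeric(N + P)
    for (pp in seq_len(n_part)) {
      acc <- acc + c(thetas[sample.int(N), pp],
                     thetas[N + sample.int(P), pp])
    }
    theta_bar[, b] <- acc / n_part
  }
  -design$X %*% theta_bar
}

#' Permutation test of local minima against a parameter-shuffling null
#'
#' Tests whether each local minimum of the cohort's aggregated landscape
#' reflects the observed regional activity and co-activation structure. For
#' each of `n_perm` permutations, every participant's fitted `h` entries are
#' shuffled across regions and the upper-triangle `J` entries across region
#' pairs (independently per participant, symmetry preserved); the shuffled
#' landscapes are averaged and the mean energy of each observed minimum
#' recorded. The p-value is the fraction of null samples greater than or
#' equal to the observed mean energy (ties count as exceeding; set
#' `plus_one = TRUE` for the conservative `(x+1)/(n+1)` variant). Bonferroni
#' correction is applied across the minima tested.
#'
#' The all-off and all-on states are exactly invariant under this shuffle
#' (their energies depend only on the sums of `h` and of `J`), so they always
#' come out non-significant (p = 1 under the tie rule).
#'
#' @param cohort A [pmem_cohort()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param alpha Significance level after Bonferroni correction (default 0.05).
#' @param plus_one Use the conservative `(x+1)/(n_perm+1)` p-value (default
#'   FALSE).
#' @param alternative `"greater"` tests whether observed energies are lower
#'   than the null (null samples >= observed), as in the standard procedure;
#'   `"less"` is the reversed direction.
#' @return Object of class `minima_test`: a tibble with one row per minimum
#'   (`state`, `pattern`, `energy`, `relative_energy`, `p_value`, `p_bonf`,
#'   `significant`), plus attributes `n_perm` and `seed`. Empty (with a
#'   warning) when the aggregated landscape has no minima.
#' @export
permutation_test_minima <- function(cohort, n_perm = 1000L, seed = NULL,
                                    alpha = 0.05, plus_one = FALSE,
                                    alternative = c("greater", "less")) {
  stopifnot(inherits(cohort, "pmem_cohort"), n_perm >= 1L)
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(as.integer(seed))
  agg <- aggregate_cohort(cohort)
  minima <- find_local_minima(agg)
  if (nrow(minima) == 0L) {
    warning("permutation_test_minima: aggregated landscape has no local minima")
    out <- dplyr::mutate(minima, p_value = numeric(0), p_bonf = numeric(0),
                         significant = logical(0))
    return(structure(out, class = c("minima_test", class(out)),
                     n_perm = n_perm, seed = seed))
  }
  nullE <- null_mean_energies(cohort, n_perm)[minima$state + 1L, ,
                                              drop = FALSE]
  obs <- minima$energy
  exceed <- if (alternative == "greater") nullE >= obs - 1e-12
            else nullE <= obs + 1e-12
  x <- rowSums(exceed)
  p <- if (plus_one) (x + 1) / (n_perm + 1) else x / n_perm
  out <- dplyr::mutate(minima,
                       p_value = p,
                       p_bonf = pmin(1, p * nrow(minima)),
                       significant = .data$p_bonf < alpha)
  structure(out, class = c("minima_test", class(out)),
            n_perm = n_perm, seed = seed)
}

#' Relative-energy feature matrix for classification
#'
#' For each participant and each tested minimum state, the feature is the
#' participant's own energy at that state minus the participant's global
#' minimum energy (their individual landscape's lowest value).
#'
#' @param cohort A [pmem_cohort()].
#' @param minima_states Integer state indices of the minima to use (e.g. the
#'   significant rows of a [permutation_test_minima()] result).
#' @return Numeric matrix, participants x minima, with participant ids as row
#'   names and state patterns as column names.
#' @export
extract_features <- function(cohort, minima_states) {
  stopifnot(inherits(cohort, "pmem_cohort"), length(minima_states) >= 1L)
  E <- cohort_energy_matrix(cohort)           # 2^N x P
  gmin <- apply(E, 2, min)
  feats <- t(E[minima_states + 1L, , drop = FALSE]) - gmin
  rownames(feats) <- cohort$participants$id
  colnames(feats) <- state_pattern(minima_states, cohort$N)
  feats
}

# RBF bandwidth by the median heuristic: gamma = 1 / (2 * median squared
# pairwise distance) on the training features.
median_heuristic_gamma <- function(x) {
  d2 <- as.numeric(stats::dist(x))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) return(1 / max(1L, ncol(x)))
  1 / (2 * m)
}

#' Leave-one-out SVM classification on relative-energy features
#'
#' Classifies participants (patient vs control) with a radial-basis-function
#' support vector machine (`C = 1`) under leave-one-out cross-validation.
#' To avoid leakage, each fold re-identifies its feature space from the
#' training participants only: the training cohort's landscapes are
#' aggregated, local minima found, and the parameter-shuffling permutation
#' test run in-fold to select significant minima; relative-energy features at
#' those minima are then extracted for the training set and the held-out
#' participant. Folds with no significant minima predict the training
#' majority class.
#'
#' In-fold selection defaults to `alternative = "less"` (minima whose energy
#' sits below the shuffled null are the characteristic features); see
#' [permutation_test_minima()] for the direction conventions.
#'
#' @param cohort A [pmem_cohort()] with at least 2 participants per group.
#' @param seed Optional integer seed (controls the in-fold permutation
#'   tests).
#' @param cost SVM error/margin trade-off (default 1).
#' @param n_perm_select Permutations for in-fold minima selection (default
#'   200; set 1000 for the full-fidelity protocol).
#' @param alpha In-fold Bonferroni significance level (default 0.05).
#' @param standardize Z-score features using training-fold means/sds
#'   (default TRUE).
#' @param gamma RBF kernel width; default `NULL` = median heuristic on the
#'   training features, per fold.
#' @param alternative Direction passed to the in-fold
#'   [permutation_test_minima()] (default `"less"`).
#' @return Object of class `loo_classification`: list with `folds` (tibble:
#'   `id`, `truth`, `predicted`, `n_features`), `accuracy`, `sensitivity`,
#'   `specificity` (patient = positive class), `seed`.
#' @export
loo_svm_classify <- function(cohort, seed = NULL, cost = 1,
                             n_perm_select = 200L, alpha = 0.05,
                             standardize = TRUE, gamma = NULL,
                             alternative = "less") {
  stopifnot(inherits(cohort, "pmem_cohort"))
  tab <- table(cohort$participants$group)
  if (any(tab < 2L))
    stop("loo_svm_classify: need at least 2 participants per group")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- cohort$participants$id
  truth <- cohort$participants$group
  fold_seeds <- sample.int(.Machine$integer.max, length(ids))

  predicted <- character(length(ids))
  n_feat <- integer(length(ids))
  for (i in seq_along(ids)) {
    train_ids <- ids[-i]
    train <- subset_cohort(cohort, train_ids)
    sel <- permutation_test_minima(train, n_perm = n_perm_select,
                                   seed = fold_seeds[i], alpha = alpha,
                                   alternative = alternative)
    sig <- sel$state[sel$significant]
    n_feat[i] <- length(sig)
    y_train <- droplevels(truth[-i])
    if (length(sig) == 0L) {
      maj <- names(sort(table(truth[-i]), decreasing = TRUE))[1]
      predicted[i] <- maj
      next
    }
    ftr <- extract_features(train, sig)
    fte <- extract_features(subset_cohort(cohort, ids[i]), sig)
    if (standardize) {
      mu <- colMeans(ftr)
      sg <- apply(ftr, 2, stats::sd)
      sg[sg == 0 | !is.finite(sg)] <- 1
      ftr <- scale(ftr, mu, sg)
      fte <- scale(fte, mu, sg)
    }
    g <- if (is.null(gamma)) median_heuristic_gamma(ftr) else gamma
    fit <- e1071::svm(x = ftr, y = factor(truth[-i]), kernel = "radial",
                      cost = cost, gamma = g, scale = FALSE)
    predicted[i] <- as.character(stats::predict(fit, fte))
  }
  folds <- tibble::tibble(id = ids, truth = as.character(truth),
                          predicted = predicted, n_features = n_feat)
  acc <- mean(folds$predicted == folds$truth)
  sens <- mean(folds$predicted[folds$truth == "patient"] == "patient")
  spec <- mean(folds$predicted[folds$truth == "control"] == "control")
  structure(list(folds = folds, accuracy = acc, sensitivity = sens,
                 specificity = spec, seed = seed, cost = cost,
                 n_perm_select = n_perm_select),
            class = "loo_classification")
}

#' @export
print.loo_classification <- function(x, ...) {
  cat(sprintf(
    "<loo_classification> accuracy %.1f%% (sensitivity %.1f%%, specificity %.1f%%) over %d folds\n",
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
    nrow(x$folds)))
  invisible(x)
}

#' Subset a cohort by participant id
#'
#' @param cohort A [pmem_cohort()].
#' @param ids Participant ids to keep (order preserved as in the cohort).
#' @return A `pmem_cohort` restricted to `ids`.
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "pmem_cohort"))
  keep <- cohort$participants$id %in% ids
  if (!any(keep)) stop("subset_cohort: no matching participants")
  pmem_cohort(cohort$participants$id[keep],
              as.character(cohort$participants$group[keep]),
              cohort$participants$params[keep],
              network = cohort$network, band = cohort$band)
}

#' Label-permutation significance of a classification result
#'
#' Compares the observed leave-one-out accuracy with its null distribution
#' under no group difference: group labels are shuffled `n_perm` times and
#' the accuracy of the fixed per-fold predictions recomputed against each
#' shuffled labelling. The p-value is the fraction of permuted accuracies
#' greater than or equal to the observed one.
#'
#' @param result A [loo_svm_classify()] result.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional integer seed.
#' @return List with `p_value`, `observed`, `null_accuracies`, `n_perm`,
#'   `seed`.
#' @export
classification_permutation <- function(result, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(result, "loo_classification"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  truth <- result$folds$truth
  pred <- result$folds$predicted
  obs <- mean(pred == truth)
  null_acc <- vapply(seq_len(n_perm),
                     function(b) mean(pred == sample(truth)), numeric(1))
  list(p_value = mean(null_acc >= obs - 1e-12), observed = obs,
       null_accuracies = null_acc, n_perm = n_perm, seed = seed)
}

#' Per-participant count of local minima
#'
#' Number of strict local minima on each participant's individual landscape —
#' the simplest per-participant landscape summary, exported for downstream
#' group statistics.
#'
#' @param cohort A [pmem_cohort()].
#' @return Tibble with `id`, `group`, `n_minima`.
#' @export
count_minima <- function(cohort) {
  stopifnot(inherits(cohort, "pmem_cohort"))
  n <- vapply(cohort$participants$params,
              function(p) nrow(find_local_minima(energy_landscape(p))),
              integer(1))
  tibble::tibble(id = cohort$participants$id,
                 group = as.character(cohort$participants$group),
                 n_minima = n)
}
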