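#' Energy landscape over all network states
#'
#' The energy landscape is the energy function over all `2^N` network states
#' together with the Hamming-1 adjacency between states: a graph on which
#' lower-energy states are more probable and local minima act as attractors.
#'
#' `energy_landscape()` builds the landscape of a fitted model;
#' `new_energy_landscape()` wraps a raw energy vector (useful for constructed
#' or aggregated landscapes).
#'
#' @param p A [pmem_params()] object or a [fit_pmem()] result.
#' @return An `energy_landscape` object with fields `energies` (length
#'   `2^N`, index `k + 1` = state `k`), `N` and `roi_names`.
#' @export
energy_landscape <- function(p) {
  if (inherits(p, "pmem_fit")) p <- p$params
  stopifnot(inherits(p, "pmem_params"))
  new_energy_landscape(state_energies(p), p$roi_names)
}

#' @param energies Numeric vector of length `2^N`, all finite.
#' @param roi_names Optional labels (length `N`).
#' @rdname energy_landscape
#' @export
new_energy_landscape <- function(energies, roi_names = NULL) {
  energies <- as.numeric(energies)
  N <- as.integer(round(log2(length(energies))))
  if (2^N != length(energies))
    stop("new_energy_landscape: length must be a power of 2")
  if (!all(is.finite(energies)))
    stop("new_energy_landscape: energies must be finite")
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(N))
  stopifnot(length(roi_names) == N)
  structure(list(energies = energies, N = N, roi_names = roi_names),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  nmin <- nrow(find_local_minima(x))
  cat(sprintf("<energy_landscape> N = %d (%d states); E in [%.3f, %.3f]; %d local minima\n",
              x$N, 2^x$N, min(x$energies), max(x$energies), nmin))
  invisible(x)
}

#' Local minima of an energy landscape
#'
#' Exhaustively scans all `2^N` states for local minima: states with strictly
#' lower energy than all `N` Hamming-1 neighbours. Such states have higher
#' occurrence probability than every adjacent state and are interpreted as
#' attractor-like stable activity patterns. A flat neighbourhood disqualifies
#' a state (strict inequality).
#'
#' @param L An [energy_landscape()].
#' @return A tibble sorted by energy (ascending) with columns `state`
#'   (integer index), `pattern` (e.g. `"-++-"`, region order), `energy` and
#'   `relative_energy` (energy above the global landscape minimum).
#' @export
find_local_minima <- function(L) {
  stopifnot(inherits(L, "energy_landscape"))
  nb <- neighbour_matrix(L$N)
  e <- L$energies
  nbmin <- apply(matrix(e[nb + 1L], nrow = length(e)), 1, min)
  is_min <- e < nbmin
  k <- which(is_min) - 1L
  out <- tibble::tibble(
    state = k,
    pattern = state_pattern(k, L$N),
    energy = e[k + 1L],
    relative_energy = e[k + 1L] - min(e)
  )
  dplyr::arrange(out, .data$energy, .data$state)
}

#' Global minimum of an energy landscape
#'
#' The state with the lowest energy on the landscape. Exact ties are broken
#' by the lowest state index (with a warning), so the result is
#' deterministic.
#'
#' @param L An [energy_landscape()].
#' @return One-row tibble with `state`, `pattern`, `energy`.
#' @export
global_minimum <- function(L) {
  stopifnot(inherits(L, "energy_landscape"))
  e <- L$energies
  k <- which(e == min(e)) - 1L
  if (length(k) > 1L) {
    warning("global_minimum: ties at the global minimum; lowest state index returned")
    k <- k[1]
  }
  tibble::tibble(state = k, pattern = state_pattern(k, L$N),
                 energy = e[k + 1L])
}

#' Energies relative to the global minimum
#'
#' Sets each local minimum's `relative_energy` to its energy minus the global
#' landscape minimum (the depth-corrected quantity used for group comparison
#' and classification).
#'
#' @param L An [energy_landscape()].
#' @param minima Tibble from [find_local_minima()] (defaults to computing it).
#' @return The minima tibble with `relative_energy` filled in (all `>= 0`).
#' @export
relative_energies <- function(L, minima = find_local_minima(L)) {
  stopifnot(inherits(L, "energy_landscape"))
  dplyr::mutate(minima, relative_energy = .data$energy - min(L$energies))
}

#' Basins of attraction by steepest descent
#'
#' Assigns every state to the basin of the local minimum reached by steepest
#' descent: from each state, repeatedly move to the lowest-energy neighbour
#' while it is strictly lower than the current state. Ties among equally
#' lowest neighbours are broken by the lowest state index; plateau states (no
#' strictly lower neighbour, not a strict minimum) follow tie-break descent
#' and are flagged with a warning.
#'
#' @param L An [energy_landscape()] with at least one strict local minimum.
#' @return Object of class `basin_partition`: list with `basin_of` (integer
#'   vector of length `2^N`; entry `k + 1` = the minimum-state index owning
#'   state `k`) and `minima` (the [find_local_minima()] tibble).
#' @export
assign_basins <- function(L) {
  stopifnot(inherits(L, "energy_landscape"))
  minima <- find_local_minima(L)
  if (nrow(minima) == 0L)
    stop("assign_basins: landscape has no strict local minima")
  e <- L$energies
  n_states <- length(e)
  nb <- neighbour_matrix(L$N)
  is_min <- logical(n_states)
  is_min[minima$state + 1L] <- TRUE

  # steepest-descent target per state: lowest-energy neighbour (lowest index
  # wins ties among neighbours)
  nbe <- matrix(e[nb + 1L], nrow = n_states)
  best_col <- max.col(-nbe, ties.method = "first")
  next_state <- nb[cbind(seq_len(n_states), best_col)]
  next_e <- nbe[cbind(seq_len(n_states), best_col)]

  basin_of <- rep(NA_integer_, n_states)
  basin_of[is_min] <- which(is_min) - 1L
  plateau_seen <- FALSE

  resolve <- function(k1) {          # 1-based position
    path <- integer(0)
    while (is.na(basin_of[k1])) {
      path <- c(path, k1)
      if (next_e[k1] > e[k1]) {
        # no downhill or equal neighbour at all, yet not flagged a minimum:
        # cannot happen (min over neighbours >= own energy => strict minimum)
        stop("assign_basins: inconsistent landscape state")
      }
      if (next_e[k1] == e[k1]) plateau_seen <<- TRUE
      k1 <- next_state[k1] + 1L
      if (k1 %in% path)
        stop("assign_basins: descent cycled on a plateau; landscape too flat")
    }
    basin_of[path] <<- basin_of[k1]
  }
  for (k1 in order(e)) if (is.na(basin_of[k1])) resolve(k1)
  if (plateau_seen)
    warning("assign_basins: plateau state(s) assigned by tie-break descent")
  structure(list(basin_of = basin_of, minima = minima, N = L$N),
            class = "basin_partition")
}

#' @export
print.basin_partition <- function(x, ...) {
  cat(sprintf("<basin_partition> %d states in %d basins\n",
              length(x$basin_of), nrow(x$minima)))
  invisible(x)
}

#' Disconnectivity graph of local minima
#'
#' Summarizes the hierarchy of local minima: the barrier between two minima
#' is the minimax energy over Hamming-1 paths connecting them (the lowest
#' possible highest-energy state en route). Barriers are computed by sorting
#' states by increasing energy and merging connected components
#' incrementally (union-find threshold sweep, equivalent to minimax-path
#' search), which yields an ultrametric merge tree with minima as leaves.
#'
#' @param L An [energy_landscape()].
#' @param minima Optional tibble from [find_local_minima()].
#' @return Object of class `disconnectivity`: `leaves` (the minima tibble),
#'   `merges` (tibble: `a`, `b` cluster ids, `height` barrier energy; cluster
#'   ids follow `stats::hclust` conventions — negative = leaf, positive =
#'   prior merge row), and `barriers` (symmetric matrix of pairwise minimax
#'   barriers between minima). A single minimum yields a one-leaf tree with
#'   no merges.
#' @export
disconnectivity_graph <- function(L, minima = find_local_minima(L)) {
  stopifnot(inherits(L, "energy_landscape"))
  e <- L$energies
  n_states <- length(e)
  nb <- neighbour_matrix(L$N)
  n_min <- nrow(minima)
  min_pos <- match(minima$state, 0:(n_states - 1))   # row in landscape
  leaf_id <- rep(NA_integer_, n_states)
  leaf_id[min_pos] <- seq_len(n_min)

  barriers <- matrix(NA_real_, n_min, n_min)
  diag(barriers) <- minima$energy
  merges <- list()

  parent <- seq_len(n_states)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # cluster bookkeeping: for each union-find root, which minima it contains
  # and its current hclust node id (negative leaf / positive merge row)
  comp_minima <- vector("list", n_states)
  comp_node <- rep(NA_integer_, n_states)
  added <- logical(n_states)

  ord <- order(e, seq_len(n_states))
  for (k1 in ord) {
    added[k1] <- TRUE
    comp_minima[[k1]] <- if (is.na(leaf_id[k1])) integer(0) else leaf_id[k1]
    comp_node[k1] <- if (is.na(leaf_id[k1])) NA_integer_ else -leaf_id[k1]
    for (nbk1 in nb[k1, ] + 1L) {
      if (!added[nbk1]) next
      ra <- find(k1)
      rb <- find(nbk1)
      if (ra == rb) next
      ma <- comp_minima[[ra]]
      mb <- comp_minima[[rb]]
      if (length(ma) > 0 && length(mb) > 0) {
        barriers[ma, mb] <- e[k1]
        barriers[mb, ma] <- e[k1]
        merges[[length(merges) + 1L]] <- tibble::tibble(
          a = comp_node[ra], b = comp_node[rb], height = e[k1])
        new_node <- length(merges)
      } else {
        new_node <- if (length(ma) > 0) comp_node[ra] else comp_node[rb]
      }
      parent[ra] <- rb
      root <- find(rb)
      comp_minima[[root]] <- c(ma, mb)
      comp_node[root] <- new_node
    }
  }
  merges <- if (length(merges)) dplyr::bind_rows(merges) else
    tibble::tibble(a = integer(0), b = integer(0), height = numeric(0))
  structure(list(leaves = minima, merges = merges, barriers = barriers,
                 N = L$N, roi_names = L$roi_names),
            class = "disconnectivity")
}

#' @export
print.disconnectivity <- function(x, ...) {
  cat(sprintf("<disconnectivity> %d minima, %d merges\n",
              nrow(x$leaves), nrow(x$merges)))
  invisible(x)
}

#' Aggregate energy landscapes across participants
#'
#' Builds the group landscape as the elementwise mean energy of each network
#' state across participants' landscapes (no refitting of pooled data).
#'
#' @param landscapes List of [energy_landscape()] objects sharing `N` and
#'   region order.
#' @return An `energy_landscape` of the mean energies.
#' @export
aggregate_landscapes <- function(landscapes) {
  stopifnot(length(landscapes) >= 1L,
            all(vapply(landscapes, inherits, logical(1), "energy_landscape")))
  Ns <- vapply(landscapes, function(l) l$N, integer(1))
  if (length(unique(Ns)) != 1L)
    stop("aggregate_landscapes: landscapes disagree on N")
  E <- vapply(landscapes, function(l) l$energies, numeric(2^Ns[1]))
  new_energy_landscape(rowMeans(E), landscapes[[1]]$roi_names)
}
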