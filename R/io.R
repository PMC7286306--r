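#' Read a delimited ROI time-series matrix
#'
#' Reads a TSV/CSV file with a header row of ROI names and one numeric row
#' per sample. Ragged rows and non-numeric cells produce parse errors naming
#' the offending line.
#'
#' @param path File path (delimiter inferred from extension: `.csv` = comma,
#'   otherwise tab).
#' @param fs Sampling rate in Hz.
#' @param band Optional [frequency_band()].
#' @return A [roi_timeseries()].
#' @export
read_roi_matrix <- function(path, fs, band = NULL) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- suppressWarnings(
    readr::read_delim(path, delim = delim, col_types = readr::cols(
      .default = readr::col_double()), progress = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0)
    stop(sprintf("read_roi_matrix: parse error at line %d of %s: %s",
                 probs$row[1] + 1L, path, probs$expected[1]))
  roi_timeseries(as.matrix(df), fs = fs, roi_names = names(df), band = band)
}

#' Write an ROI or binary-state matrix to a delimited file
#'
#' @param x A [roi_timeseries()] or [binary_states()] object.
#' @param path Output path (`.csv` writes comma-separated, otherwise tab).
#'   For binarized output, a JSON sidecar `<path>.thresholds.json` with the
#'   per-ROI median thresholds is written when these are recorded.
#' @return `path`, invisibly.
#' @export
write_roi_matrix <- function(x, path) {
  m <- if (inherits(x, "binary_states")) x$states
       else if (inherits(x, "roi_timeseries")) x$data
       else stop("write_roi_matrix: unsupported object")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(tibble::as_tibble(m), path, delim = delim)
  thr <- attr(x, "thresholds")
  if (!is.null(thr))
    jsonlite::write_json(as.list(thr), paste0(path, ".thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize pMEM parameters to JSON
#'
#' Writes `roi_names`, `h`, `J` (row-major) and any fit metadata with a
#' deterministic field order, so outputs are diffable across runs.
#'
#' @param p A [pmem_params()] or [fit_pmem()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmem_json <- function(p, path) {
  meta <- NULL
  if (inherits(p, "pmem_fit")) {
    meta <- list(n_iter = p$n_iter, max_moment_gap = p$max_moment_gap,
                 converged = p$converged, accuracy_d = p$accuracy_d,
                 kl_indep = p$kl_indep, kl_pair = p$kl_pair)
    p <- p$params
  }
  stopifnot(inherits(p, "pmem_params"))
  obj <- list(roi_names = p$roi_names,
              h = as.numeric(p$h),
              J = as.numeric(t(p$J)),
              N = p$N)
  if (!is.null(meta)) obj$fit <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pmem_json
#' @export
read_pmem_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  J <- matrix(obj$J, obj$N, obj$N, byrow = TRUE)
  pmem_params(obj$h, J, obj$roi_names)
}

#' Export a minima table as TSV
#'
#' Writes one row per local minimum: the state bit pattern (one +1/-1 column
#' per ROI), energy, relative energy and — when present — permutation
#' p-values and significance flags.
#'
#' @param minima Tibble from [find_local_minima()] or
#'   [permutation_test_minima()].
#' @param roi_names Region labels (length `N`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_minima_tsv <- function(minima, roi_names, path) {
  N <- length(roi_names)
  bits <- state_vector(minima$state, N)
  if (!is.matrix(bits)) bits <- matrix(bits, nrow = nrow(minima))
  colnames(bits) <- roi_names
  out <- dplyr::bind_cols(tibble::as_tibble(bits),
                          dplyr::select(minima, -dplyr::any_of("pattern")))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Convert a disconnectivity graph to a phylogenetic tree object
#'
#' Minima become tips and merge barriers internal nodes; branch lengths are
#' the energy drops from a merge barrier down to each child (minimum energy
#' for leaves, lower barrier for nested merges). Useful for Newick export
#' ([write_disconnectivity_newick()]) and tree plotting.
#'
#' @param dg A [disconnectivity_graph()] result with >= 2 minima.
#' @return An [ape::as.phylo] `phylo` object with tip labels = minima state
#'   patterns.
#' @export
disconnectivity_phylo <- function(dg) {
  stopifnot(inherits(dg, "disconnectivity"))
  n_tip <- nrow(dg$leaves)
  if (n_tip < 2L)
    stop("disconnectivity_phylo: need at least 2 minima for a tree")
  n_merge <- nrow(dg$merges)
  # ape node numbering: tips 1..n_tip, root n_tip + 1, internals onward.
  # merge rows are processed in order; the last merge is the root.
  merge_node <- integer(n_merge)
  merge_node[n_merge] <- n_tip + 1L
  if (n_merge > 1L)
    merge_node[seq_len(n_merge - 1L)] <- n_tip + 1L + seq_len(n_merge - 1L)
  edges <- matrix(0L, 2L * n_merge, 2L)
  lens <- numeric(2L * n_merge)
  row <- 1L
  for (r in seq_len(n_merge)) {
    for (child in c(dg$merges$a[r], dg$merges$b[r])) {
      if (child < 0) {
        node <- -child
        h_child <- dg$leaves$energy[-child]
        lab <- TRUE
      } else {
        node <- merge_node[child]
        h_child <- dg$merges$height[child]
      }
      edges[row, ] <- c(merge_node[r], node)
      lens[row] <- dg$merges$height[r] - h_child
      row <- row + 1L
    }
  }
  tr <- list(edge = edges, edge.length = lens,
             tip.label = dg$leaves$pattern,
             Nnode = n_merge)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' @param path Output path for the Newick file.
#' @rdname disconnectivity_phylo
#' @export
write_disconnectivity_newick <- function(dg, path) {
  ape::write.tree(disconnectivity_phylo(dg), file = path)
  invisible(path)
}
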