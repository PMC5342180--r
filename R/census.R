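#' Ward clustering of the pairwise trail distances
#'
#' Agglomerative clustering of trails under Ward's minimum-variance
#' criterion, with the Lance-Williams update applied to the pairwise
#' canonical centroid distances as given (`stats::hclust`, method
#' `"ward.D"`). Merge heights are the Ward distances at which the
#' dendrogram is cut by [estimate_individuals()].
#'
#' @param d symmetric, zero-diagonal, non-negative distance matrix (or a
#'   [pairwise_matrix()] object, whose `distance` element is used).
#' @return an `hclust` object.
#' @export
ward_cluster <- function(d) {
  if (inherits(d, "pairwise_matrix")) d <- d$distance
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
    stop("non-finite distances for pair(s): ",
         paste(sprintf("%s/%s", rownames(d)[bad[, 1]],
                       colnames(d)[bad[, 2]]), collapse = ", "))
  }
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d)))) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  stats::hclust(stats::as.dist(d), method = "ward.D")
}

#' Estimate the number of individuals at a threshold
#'
#' Cuts the Ward dendrogram at the given threshold: merges with height
#' above the threshold are undone, each remaining connected component is
#' one predicted individual.
#'
#' @param linkage an `hclust` object from [ward_cluster()].
#' @param threshold Ward-distance threshold (>= 0).
#' @return object of class `census_result`: list with `count`,
#'   `assignment` (named integer cluster id per trail), `threshold`,
#'   `linkage`.
#' @export
estimate_individuals <- function(linkage, threshold) {
  stopifnot(inherits(linkage, "hclust"), is.numeric(threshold),
            threshold >= 0)
  assignment <- stats::cutree(linkage, h = threshold)
  structure(list(count = length(unique(assignment)),
                 assignment = assignment,
                 threshold = threshold, linkage = linkage),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat("<census_result> ", x$count, " individuals at Ward threshold ",
      format(x$threshold, digits = 4), " (", length(x$assignment),
      " trails)\n", sep = "")
  invisible(x)
}

#' Tune the Ward threshold against known identities
#'
#' Grid search for the threshold that maximises [trail_placement_accuracy()]
#' on trails of known individuals (the training step of the published
#' procedure: the threshold giving the highest classification accuracy is
#' retained). Ties are broken toward the smallest threshold.
#'
#' @param linkage an `hclust` from [ward_cluster()].
#' @param truth named character/factor vector: true animal id per trail
#'   (names = trail labels of the linkage).
#' @param grid optional numeric vector of candidate thresholds; defaults to
#'   0 and the midpoints between consecutive merge heights plus a value
#'   above the top merge.
#' @return the selected threshold (numeric scalar), with attributes
#'   `accuracy` (best accuracy, %) and `grid`.
#' @export
tune_threshold <- function(linkage, truth, grid = NULL) {
  stopifnot(inherits(linkage, "hclust"))
  if (is.null(grid)) {
    h <- sort(unique(linkage$height))
    grid <- c(0, (h[-length(h)] + h[-1]) / 2, max(h) * 1.05 + 1e-9)
  }
  if (length(grid) == 0L) stop("empty threshold grid")
  grid <- sort(grid)
  truth <- truth[linkage$labels]
  acc <- vapply(grid, function(th) {
    trail_placement_accuracy(stats::cutree(linkage, h = th), truth)
  }, numeric(1))
  best <- which(acc == max(acc))[1]   # smallest threshold among ties
  structure(grid[best], accuracy = acc[best], grid = grid)
}

#' Trail placement accuracy
#'
#' Fraction of trails assigned to the correct individual, after matching
#' predicted clusters one-to-one to true animals by maximum-weight
#' bipartite assignment on the contingency counts (so the metric is
#' invariant to cluster relabelling and does not reward splitting).
#'
#' @param assignment integer/character cluster label per trail.
#' @param truth true animal id per trail (same order).
#' @return accuracy in percent (matched trails / total trails * 100).
#' @export
trail_placement_accuracy <- function(assignment, truth) {
  stopifnot(length(assignment) == length(truth))
  tab <- table(assignment, truth)
  nc <- nrow(tab); na <- ncol(tab)
  el <- which(tab > 0, arr.ind = TRUE)
  edges <- as.vector(t(cbind(el[, 1], nc + el[, 2])))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nc), rep(TRUE, na)), edges)
  m <- igraph::max_bipartite_match(g, weights = tab[el])
  100 * m$matching_weight / length(assignment)
}

#' Relative-likelihood profile over candidate individual counts
#'
#' Bootstrap analogue of the interactive likelihood slider: footprints are
#' resampled with replacement within each trail, the pairwise distance
#' matrix and Ward clustering are recomputed, and the dendrogram is cut at
#' the configured threshold. The relative likelihood of a count `k` is its
#' bootstrap frequency divided by the frequency of the modal count, so the
#' modal count scores exactly 1.
#'
#' @param table feature data.frame.
#' @param config an [algorithm_config()] whose `ward_threshold` is numeric.
#' @param n_bootstrap number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return named numeric vector: relative likelihood per observed count.
#' @export
likelihood_profile <- function(table, config, n_bootstrap = 200L, seed) {
  stopifnot(inherits(config, "algorithm_config"))
  if (!is.numeric(config$ward_threshold)) {
    stop("likelihood_profile needs a numeric ward_threshold (tune first)")
  }
  if (n_bootstrap < 100L) stop("n_bootstrap must be >= 100")
  set.seed(as.integer(seed))
  sizes <- table(table$trail_id)
  usable <- names(sizes)[sizes >= 3L]
  counts <- integer(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    idx <- unlist(lapply(usable, function(tr) {
      rows <- which(table$trail_id == tr)
      sample(rows, length(rows), replace = TRUE)
    }), use.names = FALSE)
    boot <- table[idx, , drop = FALSE]
    pm <- suppressWarnings(pairwise_matrix(boot, config))
    hc <- ward_cluster(pm)
    counts[b] <- estimate_individuals(hc, config$ward_threshold)$count
  }
  freq <- table(counts)
  out <- as.numeric(freq) / max(freq)
  names(out) <- names(freq)
  out
}
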