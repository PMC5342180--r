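#' Sequential holdback validation of the individual census
#'
#' Animals (not trails) are apportioned at random into a training and a
#' test set, repeatedly, over a range of test-set sizes. For each
#' iteration the Ward threshold is tuned on the training animals (against
#' their known identities), the pairwise distance matrix of the test
#' trails is computed with the reference centroid group drawn from the
#' training rows (so test animals never leak into the reference group or
#' the tuning), the dendrogram is cut at the tuned threshold, and the
#' predicted number of individuals is compared with the true number of
#' test animals. Per-iteration accuracy is
#' `100 - 100 * |predicted - true| / true` (the package's documented
#' relative-error metric).
#'
#' @param table feature data.frame with `animal_id` and `trail_id`.
#' @param test_sizes integer vector of test-set sizes (animals).
#' @param iterations random iterations per size (default 10).
#' @param config an [algorithm_config()]; its `ward_threshold` is ignored
#'   (re-tuned per iteration) unless `rcv_from_test = TRUE` leaves no
#'   training rows.
#' @param seed integer seed.
#' @param rcv_from_test use the test rows themselves for the reference
#'   group instead of the training rows (the alternative reading of the
#'   original procedure; default `FALSE`, no leakage).
#' @return object of class `holdback_report`: data.frame `results` with
#'   one row per iteration (`size`, `iteration`, `true`, `predicted`,
#'   `threshold`, `accuracy`), plus `config` and `seed`.
#' @export
holdback_trial <- function(table, test_sizes, iterations = 10L,
                           config = algorithm_config(), seed,
                           rcv_from_test = FALSE) {
  stopifnot(inherits(config, "algorithm_config"))
  set.seed(as.integer(seed))
  sizes_tab <- table(table$trail_id)
  usable_trails <- names(sizes_tab)[sizes_tab >= 3L]
  tab <- table[table$trail_id %in% usable_trails, , drop = FALSE]
  animals <- unique(tab$animal_id)
  n_animals <- length(animals)
  if (any(test_sizes >= n_animals - 1L)) {
    stop("test sizes must leave >= 2 training animals (library has ",
         n_animals, ")")
  }
  rows <- vector("list", 0L)
  for (size in test_sizes) {
    for (it in seq_len(iterations)) {
      test_animals <- sample(animals, size)
      train <- tab[!(tab$animal_id %in% test_animals), , drop = FALSE]
      test <- tab[tab$animal_id %in% test_animals, , drop = FALSE]

      pm_train <- suppressWarnings(pairwise_matrix(train, config))
      hc_train <- ward_cluster(pm_train)
      truth <- vapply(hc_train$labels, function(tr) {
        unique(train$animal_id[train$trail_id == tr])[1]
      }, character(1))
      th <- tune_threshold(hc_train, truth)

      rcv_tab <- if (rcv_from_test) test else train
      n_test_trails <- length(unique(test$trail_id))
      if (n_test_trails >= 2L) {
        pm_test <- suppressWarnings(
          pairwise_matrix(test, config, rcv_table = rcv_tab))
        predicted <- estimate_individuals(ward_cluster(pm_test),
                                          as.numeric(th))$count
      } else {
        predicted <- n_test_trails
      }
      true <- length(unique(test$animal_id))
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, iteration = it, true = true, predicted = predicted,
        threshold = as.numeric(th),
        accuracy = 100 - 100 * abs(predicted - true) / true)
    }
  }
  structure(list(results = do.call(rbind, rows), config = config,
                 seed = as.integer(seed)),
            class = "holdback_report")
}

#' @export
print.holdback_report <- function(x, ...) {
  cat("<holdback_report> ", nrow(x$results), " iterations, sizes ",
      paste(unique(x$results$size), collapse = ", "), " (seed ", x$seed,
      ")\n", sep = "")
  s <- summarize_holdback(x)
  agg <- unique(s[, c("size", "expected", "mean_predicted")])
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Summarise a holdback report
#'
#' Tidies a [holdback_trial()] report into the table behind the standard
#' validation plot: one row per iteration with the test-set size plotted
#' against itself (`expected`), the per-iteration prediction and the mean
#' prediction for that size.
#'
#' @param report a `holdback_report`.
#' @return data.frame with columns `size`, `expected`, `predicted`,
#'   `mean_predicted`.
#' @export
summarize_holdback <- function(report) {
  stopifnot(inherits(report, "holdback_report"))
  r <- report$results
  if (nrow(r) == 0L) stop("empty holdback report")
  mp <- stats::ave(r$predicted, r$size)
  data.frame(size = r$size, expected = r$true, predicted = r$predicted,
             mean_predicted = mp)
}
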