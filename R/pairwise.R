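#' Algorithm configuration: the three tuning elements
#'
#' The pairwise classifier has three tunable elements: the number of
#' stepwise-selected variables (the puma algorithm was optimised in the
#' 14-20 band; default 15), the contour probability governing the size of
#' the centroid confidence ellipses (default 0.95), and the Ward-distance
#' threshold at which the dendrogram is cut to count individuals
#' (`"auto"` = tune against training truth, see [tune_threshold()]).
#'
#' @param n_variables number of variables selected per pairwise comparison
#'   (1-128).
#' @param contour_probability ellipse coverage level in (0, 1).
#' @param ward_threshold numeric threshold, or `"auto"`.
#' @param rcv_mode how the reference centroid group is built:
#'   `"all-other-animals"` (default; every footprint of the library except
#'   those of the two animals under comparison) or
#'   `"whole-table-duplicate"` (a copy of every library row, mirroring the
#'   original copy-paste construction).
#' @param selection_scope where the stepwise selection looks:
#'   `"reference"` (default) selects the variables that best discriminate
#'   the known reference individuals (the RCV rows, grouped by animal) so
#'   that the selected set -- the species algorithm -- is independent of
#'   the two trails being compared; `"pair"` recomputes the selection per
#'   pair on the three analysis groups (trail A / trail B / RCV), which
#'   maximises apparent separation but over-fits trail differences (see
#'   the methods vignette).
#' @param seed integer seed recorded with results.
#' @return object of class `algorithm_config`.
#' @export
algorithm_config <- function(n_variables = 15L, contour_probability = 0.95,
                             ward_threshold = "auto",
                             rcv_mode = c("all-other-animals",
                                          "whole-table-duplicate"),
                             selection_scope = c("reference", "pair"),
                             seed = 1L) {
  rcv_mode <- match.arg(rcv_mode)
  selection_scope <- match.arg(selection_scope)
  stopifnot(n_variables >= 1, n_variables <= 128,
            contour_probability > 0, contour_probability < 1)
  if (!(identical(ward_threshold, "auto") ||
        (is.numeric(ward_threshold) && ward_threshold >= 0))) {
    stop("ward_threshold must be a non-negative number or \"auto\"")
  }
  structure(list(n_variables = as.integer(n_variables),
                 contour_probability = contour_probability,
                 ward_threshold = ward_threshold,
                 rcv_mode = rcv_mode, selection_scope = selection_scope,
                 seed = as.integer(seed)),
            class = "algorithm_config")
}

#' @export
print.algorithm_config <- function(x, ...) {
  cat("<algorithm_config> n_variables = ", x$n_variables,
      ", contour_probability = ", x$contour_probability,
      ", ward_threshold = ", as.character(x$ward_threshold),
      ", rcv_mode = ", x$rcv_mode, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

.feature_cols <- function(table) {
  grep("^V[0-9]+$", names(table), value = TRUE)
}

.feature_matrix <- function(table) {
  as.matrix(table[, .feature_cols(table), drop = FALSE])
}

# group labels for reference-scope selection: animal identity where known,
# trail identity otherwise
.rcv_group_labels <- function(rcv) {
  g <- as.character(rcv$animal_id)
  bad <- is.na(g) | g == "" | g == "NA"
  g[bad] <- as.character(rcv$trail_id)[bad]
  g
}

#' Build the reference centroid group (RCV)
#'
#' The RCV is a third analysis group that anchors the canonical space so
#' that pairwise verdicts do not depend on which other trails happen to be
#' in the library. In `"all-other-animals"` mode it holds every footprint
#' of the library except those belonging to the animals that own the two
#' trails under comparison (falling back to trail-level exclusion when
#' animal identity is unknown); in `"whole-table-duplicate"` mode it is a
#' copy of every library row.
#'
#' @param table library feature data.frame.
#' @param trail_a,trail_b the two trail ids under comparison.
#' @param mode RCV construction mode (see [algorithm_config()]).
#' @return data.frame of RCV rows.
#' @export
build_rcv <- function(table, trail_a, trail_b,
                      mode = c("all-other-animals", "whole-table-duplicate")) {
  mode <- match.arg(mode)
  if (mode == "whole-table-duplicate") {
    rcv <- table
  } else {
    own <- unique(table$animal_id[table$trail_id %in% c(trail_a, trail_b)])
    own <- own[!is.na(own) & own != "NA"]
    if (length(own) > 0L) {
      keep <- !(table$animal_id %in% own) &
        !(table$trail_id %in% c(trail_a, trail_b))
    } else {
      keep <- !(table$trail_id %in% c(trail_a, trail_b))
    }
    rcv <- table[keep, , drop = FALSE]
  }
  if (nrow(rcv) == 0L) {
    stop("library too small: empty reference centroid group for trails '",
         trail_a, "' / '", trail_b, "'")
  }
  rcv
}

# Selection of the discriminating variable set for one comparison.
# "reference" scope: stepwise on the reference rows grouped by individual
# (trail as a proxy when animal identity is unknown), so the selection is
# blind to the pair under test; "pair" scope: stepwise on the three
# analysis groups. Falls back to pair scope when the reference carries
# fewer than two usable groups.
.select_variables <- function(Xr, rcv_groups, X, grp, n_variables, scope) {
  max_vars <- min(n_variables, nrow(X) - 4L)   # rows - groups - 1
  if (scope == "reference") {
    rg <- droplevels(as.factor(rcv_groups))
    if (nlevels(rg) >= 2L && min(table(rg)) >= 2L) {
      max_ref <- min(n_variables, nrow(Xr) - nlevels(rg) - 1L, max_vars)
      if (max_ref >= 1L) return(stepwise_select(Xr, rg, max_ref))
    }
    warning("reference group unusable for variable selection; ",
            "falling back to pair-scope selection")
  }
  stepwise_select(X, grp, max_vars)
}

# Fast core shared by compare_trails() and pairwise_matrix(): operates on a
# pre-extracted numeric matrix. Returns minimal results.
.compare_core <- function(Xa, Xb, Xr, n_variables, contour_probability,
                          rcv_groups, scope, selection = NULL) {
  na <- nrow(Xa); nb <- nrow(Xb)
  X <- rbind(Xa, Xb, Xr)
  grp <- factor(rep(c("A", "B", "RCV"), c(na, nb, nrow(Xr))),
                levels = c("A", "B", "RCV"))
  sel <- if (is.null(selection)) {
    .select_variables(Xr, rcv_groups, X, grp, n_variables, scope)
  } else selection
  if (nrow(sel) == 0L) stop("stepwise selection found no usable variable")
  cv <- canonical_variates(X[, sel$index, drop = FALSE], grp, ncomp = 2L)
  sc <- cv$scores
  ia <- seq_len(na); ib <- na + seq_len(nb)
  ea <- centroid_ellipse(sc[ia, , drop = FALSE], contour_probability)
  eb <- centroid_ellipse(sc[ib, , drop = FALSE], contour_probability)
  ov <- ellipses_overlap(ea, eb)
  dist <- sqrt(sum((ea$center - eb$center)^2))

  # leave-one-footprint-out assignment diagnostic: drop each print from its
  # own trail centroid (canonical space held fixed) and assign to the
  # nearer of the two trail centroids
  ok <- 0L
  for (i in ia) {
    own <- (colSums(sc[ia, , drop = FALSE]) - sc[i, ]) / (na - 1)
    ok <- ok + (sum((sc[i, ] - own)^2) <= sum((sc[i, ] - eb$center)^2))
  }
  for (i in ib) {
    own <- (colSums(sc[ib, , drop = FALSE]) - sc[i, ]) / (nb - 1)
    ok <- ok + (sum((sc[i, ] - own)^2) <= sum((sc[i, ] - ea$center)^2))
  }
  list(selected = sel, eigenvalues = cv$eigenvalues[seq_len(2)],
       centroids = cv$group_centroids, ellipse_a = ea, ellipse_b = eb,
       overlap = ov, centroid_distance = dist,
       cv_rate = 100 * ok / (na + nb))
}

#' Compare two footprint trails: same or different individual?
#'
#' The core pairwise classifier. The two trails and the reference centroid
#' group form three groups; forward stepwise selection picks the
#' `n_variables` most discriminating variables; canonical variates map all
#' footprints into 2-D; a confidence ellipse at the configured contour
#' probability is drawn around each trail centroid; the verdict is
#' `"same"` exactly when the two ellipses overlap.
#'
#' @param table library feature data.frame (must contain both trails unless
#'   `rcv_table` is supplied).
#' @param trail_a,trail_b trail ids; each trail needs >= 3 footprints.
#' @param config an [algorithm_config()].
#' @param rcv_table optional separate library used to build the RCV (e.g.
#'   training rows during holdback validation, so that test animals never
#'   enter the reference group).
#' @return object of class `pair_result`: trail ids, selected variables
#'   with F-ratios, canonical eigenvalues, the three group centroids, both
#'   ellipses, `overlap`, `verdict` (`"same"`/`"different"`),
#'   `centroid_distance`, and `cv_rate`, the leave-one-footprint-out rate
#'   (%) at which footprints are assigned to their own trail centroid.
#' @examples
#' pop <- generate_population(population_spec(n_individuals = 6, seed = 42))
#' tr <- unique(pop$table$trail_id)[1:2]
#' compare_trails(pop$table, tr[1], tr[2],
#'                algorithm_config(seed = 1))
#' @export
compare_trails <- function(table, trail_a, trail_b, config = algorithm_config(),
                           rcv_table = NULL) {
  stopifnot(inherits(config, "algorithm_config"))
  rows_a <- table[table$trail_id == trail_a, , drop = FALSE]
  rows_b <- table[table$trail_id == trail_b, , drop = FALSE]
  for (tr in list(list(trail_a, rows_a), list(trail_b, rows_b))) {
    if (nrow(tr[[2]]) < 3L) {
      stop("trail '", tr[[1]], "' has ", nrow(tr[[2]]),
           " footprints; >= 3 required for a pairwise comparison")
    }
  }
  lib <- if (is.null(rcv_table)) table else rcv_table
  rcv <- build_rcv(lib, trail_a, trail_b, config$rcv_mode)
  res <- tryCatch(
    .compare_core(.feature_matrix(rows_a), .feature_matrix(rows_b),
                  .feature_matrix(rcv), config$n_variables,
                  config$contour_probability, .rcv_group_labels(rcv),
                  config$selection_scope),
    error = function(e) {
      stop("comparison of trails '", trail_a, "' and '", trail_b,
           "' failed: ", conditionMessage(e), call. = FALSE)
    })
  structure(c(list(trail_a = trail_a, trail_b = trail_b,
                   verdict = if (res$overlap) "same" else "different",
                   config = config),
              res),
            class = "pair_result")
}

#' @export
print.pair_result <- function(x, ...) {
  cat("<pair_result> ", x$trail_a, " vs ", x$trail_b, ": ", x$verdict,
      "\n", sep = "")
  cat("  centroid distance ", format(x$centroid_distance, digits = 4),
      " | ellipses ", if (x$overlap) "overlap" else "disjoint",
      " (p = ", x$config$contour_probability, ")",
      " | LOO self-assignment ", format(x$cv_rate, digits = 4), "%\n",
      sep = "")
  cat("  variables: ", paste(x$selected$variable, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' All pairwise trail comparisons
#'
#' Runs [compare_trails()] for every unordered pair of trails and returns
#' the symmetric matrix of canonical centroid distances and the symmetric
#' logical matrix of "same individual" verdicts. Trails with fewer than 3
#' footprints are excluded with a warning. A failing pair is reported as a
#' warning and its entries left `NA`.
#'
#' @param table feature data.frame of the trails to compare.
#' @param config an [algorithm_config()].
#' @param rcv_table optional separate library for the RCV (see
#'   [compare_trails()]); defaults to `table` itself.
#' @param trails optional character vector restricting/ordering the trails.
#' @return object of class `pairwise_matrix`: list with `distance`
#'   (numeric matrix, zero diagonal), `same` (logical matrix, `TRUE`
#'   diagonal) and `trails`.
#' @export
pairwise_matrix <- function(table, config = algorithm_config(),
                            rcv_table = NULL, trails = NULL) {
  stopifnot(inherits(config, "algorithm_config"))
  if (is.null(trails)) trails <- unique(table$trail_id)
  sizes <- table(factor(table$trail_id, levels = trails))
  small <- names(sizes)[sizes < 3L]
  if (length(small) > 0L) {
    warning("excluding trail(s) with < 3 footprints: ",
            paste(small, collapse = ", "))
    trails <- setdiff(trails, small)
  }
  k <- length(trails)
  if (k < 2L) stop("need >= 2 usable trails")

  X <- .feature_matrix(table)
  lib <- if (is.null(rcv_table)) table else rcv_table
  Xlib <- .feature_matrix(lib)
  lib_groups <- .rcv_group_labels(lib)
  idx <- lapply(trails, function(tr) which(table$trail_id == tr))
  owner <- vapply(trails, function(tr) {
    a <- unique(table$animal_id[table$trail_id == tr])
    if (length(a) == 1L && !is.na(a)) a else NA_character_
  }, character(1))

  D <- matrix(0, k, k, dimnames = list(trails, trails))
  S <- matrix(TRUE, k, k, dimnames = list(trails, trails))
  sel_cache <- new.env(parent = emptyenv())  # selection reuse per animal pair
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (config$rcv_mode == "whole-table-duplicate") {
        ridx <- seq_len(nrow(Xlib))
      } else {
        own <- stats::na.omit(c(owner[i], owner[j]))
        if (length(own) > 0L) {
          ridx <- which(!(lib$animal_id %in% own) &
                          !(lib$trail_id %in% trails[c(i, j)]))
        } else {
          ridx <- which(!(lib$trail_id %in% trails[c(i, j)]))
        }
      }
      if (length(ridx) == 0L) {
        warning("pair ", trails[i], " / ", trails[j],
                ": empty reference group; entry set to NA")
        D[i, j] <- D[j, i] <- NA_real_
        S[i, j] <- S[j, i] <- NA
        next
      }
      # reference-scope selection depends only on the excluded animals, so
      # trails of the same animal pair can share one stepwise run
      selection <- NULL
      key <- NULL
      if (config$selection_scope == "reference" &&
          !anyNA(owner[c(i, j)])) {
        key <- paste(sort(owner[c(i, j)]), collapse = "|")
        selection <- sel_cache[[key]]
      }
      res <- tryCatch(
        .compare_core(X[idx[[i]], , drop = FALSE], X[idx[[j]], , drop = FALSE],
                      Xlib[ridx, , drop = FALSE], config$n_variables,
                      config$contour_probability, lib_groups[ridx],
                      config$selection_scope, selection = selection),
        error = function(e) e)
      if (!inherits(res, "error") && !is.null(key) && is.null(selection)) {
        sel_cache[[key]] <- res$selected
      }
      if (inherits(res, "error")) {
        warning("pair ", trails[i], " / ", trails[j], " failed: ",
                conditionMessage(res), "; entry set to NA")
        D[i, j] <- D[j, i] <- NA_real_
        S[i, j] <- S[j, i] <- NA
      } else {
        D[i, j] <- D[j, i] <- res$centroid_distance
        S[i, j] <- S[j, i] <- res$overlap
      }
    }
  }
  structure(list(distance = D, same = S, trails = trails, config = config),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  k <- length(x$trails)
  cat("<pairwise_matrix> ", k, " trails, ", k * (k - 1) / 2, " pairs\n",
      sep = "")
  same <- x$same[upper.tri(x$same)]
  cat("  verdicts: ", sum(same, na.rm = TRUE), " same, ",
      sum(!same, na.rm = TRUE), " different, ", sum(is.na(same)),
      " missing\n", sep = "")
  invisible(x)
}
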