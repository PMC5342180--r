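#' Fit the sex classifier (stepwise linear discriminant)
#'
#' Two-class linear discriminant analysis on stepwise-selected variables.
#' Selection uses the same partial-F forward engine as the pairwise
#' classifier ([stepwise_select()]) with the two sexes as groups; the
#' discriminant weights are the closed-form pooled-covariance solution
#' `w = Sp^{-1} (mu_M - mu_F)` with equal priors for the two sexes
#' regardless of training imbalance. The default of 20 variables is the
#' plateau of the accuracy-vs-variable-count curve; the fixed 20-variable
#' preset from the published variable table is available via
#' `preset = "table1-sex"`, and a 10-variable model via `n_vars = 10`.
#'
#' @param table feature data.frame with a `sex` column coded `"F"`/`"M"`.
#' @param n_vars number of variables to select (default 20).
#' @param preset `NULL`, or `"table1-sex"` to use the fixed 20-variable
#'   sex-flagged catalog subset instead of data-driven selection.
#' @param variables optional explicit character vector of variables
#'   (overrides selection and preset).
#' @return object of class `sex_model`: selected variables (with entry
#'   F-ratios where selected stepwise), class means, pooled covariance,
#'   weight vector, offset, training counts.
#' @export
fit_sex_model <- function(table, n_vars = 20L, preset = NULL,
                          variables = NULL) {
  sex <- table$sex
  keep <- sex %in% c("F", "M")
  if (!all(keep)) table <- table[keep, , drop = FALSE]
  sex <- factor(table$sex, levels = c("F", "M"))
  if (nlevels(droplevels(sex)) < 2L) {
    stop("training table must contain both sexes")
  }
  if (min(table(sex)) < 2L) stop("need >= 2 footprints per sex")
  stopifnot(n_vars >= 1)
  X <- .feature_matrix(table)

  if (!is.null(variables)) {
    sel <- data.frame(variable = variables,
                      index = match(variables, colnames(X)), F = NA_real_)
    if (anyNA(sel$index)) {
      stop("unknown variable(s): ",
           paste(variables[is.na(sel$index)], collapse = ", "))
    }
  } else if (!is.null(preset)) {
    preset <- match.arg(preset, "table1-sex")
    vars <- variable_catalog()$sex_vars
    sel <- data.frame(variable = vars, index = match(vars, colnames(X)),
                      F = NA_real_)
  } else {
    sel <- stepwise_select(X, sex, n_vars)
  }
  Xs <- X[, sel$index, drop = FALSE]
  lda <- .lda_fit(Xs, sex)
  structure(c(list(selected = sel, n_train = table(sex)), lda),
            class = "sex_model")
}

# closed-form two-class LDA with equal priors
.lda_fit <- function(X, y) {
  lev <- levels(y)
  n1 <- sum(y == lev[1]); n2 <- sum(y == lev[2])
  m1 <- colMeans(X[y == lev[1], , drop = FALSE])
  m2 <- colMeans(X[y == lev[2], , drop = FALSE])
  X1 <- sweep(X[y == lev[1], , drop = FALSE], 2, m1)
  X2 <- sweep(X[y == lev[2], , drop = FALSE], 2, m2)
  Sp <- (crossprod(X1) + crossprod(X2)) / (n1 + n2 - 2)
  ch <- tryCatch(chol(Sp), error = function(e) NULL)
  if (is.null(ch)) {
    eps <- 1e-8 * sum(diag(Sp)) / ncol(X)
    Sp <- Sp + diag(eps, ncol(X))
    ch <- chol(Sp)
  }
  w <- backsolve(ch, backsolve(ch, m2 - m1, transpose = TRUE))
  offset <- sum(w * (m1 + m2)) / 2
  list(levels = lev, means = rbind(m1, m2), pooled_cov = Sp,
       weights = drop(w), offset = offset)
}

#' @export
print.sex_model <- function(x, ...) {
  cat("<sex_model> ", nrow(x$selected), " variables, trained on ",
      x$n_train[1], " F / ", x$n_train[2], " M footprints\n", sep = "")
  cat("  variables: ", paste(x$selected$variable, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Predict sex for footprints and trails
#'
#' Per-footprint label by the sign of the linear discriminant score, with
#' the posterior probability from the equal-prior Gaussian equal-covariance
#' model (`plogis` of the discriminant). The per-trail label is the
#' majority of its footprints; ties go to the sex with the higher mean
#' posterior.
#'
#' @param model a [fit_sex_model()].
#' @param table feature data.frame; must contain every model variable.
#' @return list with `footprints` (data.frame: `footprint_id`, `trail_id`,
#'   `sex_pred`, `posterior_M`) and `trails` (data.frame: `trail_id`,
#'   `sex_pred`, `mean_posterior_M`, `n_footprints`).
#' @export
predict_sex <- function(model, table) {
  stopifnot(inherits(model, "sex_model"))
  missing_vars <- setdiff(model$selected$variable, names(table))
  if (length(missing_vars) > 0L) {
    stop("table is missing model variable(s): ",
         paste(missing_vars, collapse = ", "))
  }
  X <- as.matrix(table[, model$selected$variable, drop = FALSE])
  d <- drop(X %*% model$weights) - model$offset
  post_m <- stats::plogis(d)
  lab <- ifelse(d > 0, model$levels[2], model$levels[1])
  fp <- data.frame(footprint_id = table$footprint_id,
                   trail_id = table$trail_id,
                   sex_pred = lab, posterior_M = post_m,
                   stringsAsFactors = FALSE)
  agg <- lapply(split(fp, fp$trail_id), function(g) {
    nm <- sum(g$sex_pred == model$levels[2])
    nf <- nrow(g) - nm
    pred <- if (nm > nf) model$levels[2]
            else if (nf > nm) model$levels[1]
            else if (mean(g$posterior_M) > 0.5) model$levels[2]
            else model$levels[1]
    data.frame(trail_id = g$trail_id[1], sex_pred = pred,
               mean_posterior_M = mean(g$posterior_M),
               n_footprints = nrow(g), stringsAsFactors = FALSE)
  })
  trails <- do.call(rbind, agg)
  rownames(trails) <- NULL
  list(footprints = fp, trails = trails)
}

#' Jackknife (leave-one-footprint-out) sex accuracy
#'
#' Every footprint is excluded in sequence, the discriminant weights are
#' refitted on the remainder, and the held-out footprint is classified. By
#' default the variable selection is held fixed from the full dataset
#' (only the LDA weights are refitted per fold); `strict = TRUE` re-runs
#' the stepwise selection inside every fold as well.
#'
#' @param table feature data.frame with `sex`.
#' @param n_vars number of variables (as [fit_sex_model()]).
#' @param preset,variables forwarded to [fit_sex_model()].
#' @param strict logical; re-select variables within each fold.
#' @return percent of footprints classified correctly.
#' @export
jackknife_accuracy <- function(table, n_vars = 20L, preset = NULL,
                               variables = NULL, strict = FALSE) {
  keep <- table$sex %in% c("F", "M")
  table <- table[keep, , drop = FALSE]
  sex <- factor(table$sex, levels = c("F", "M"))
  n <- nrow(table)
  if (strict) {
    ok <- vapply(seq_len(n), function(i) {
      m <- fit_sex_model(table[-i, , drop = FALSE], n_vars = n_vars,
                         preset = preset, variables = variables)
      predict_sex(m, table[i, , drop = FALSE])$footprints$sex_pred ==
        as.character(sex[i])
    }, logical(1))
    return(100 * mean(ok))
  }
  model <- fit_sex_model(table, n_vars = n_vars, preset = preset,
                         variables = variables)
  X <- as.matrix(table[, model$selected$variable, drop = FALSE])
  ok <- vapply(seq_len(n), function(i) {
    lda <- .lda_fit(X[-i, , drop = FALSE], sex[-i])
    d <- sum(X[i, ] * lda$weights) - lda$offset
    lab <- if (d > 0) lda$levels[2] else lda$levels[1]
    lab == as.character(sex[i])
  }, logical(1))
  100 * mean(ok)
}

#' Accuracy versus number of variables
#'
#' Jackknife accuracy for a sequence of variable counts, with nested
#' selections: the stepwise ordering is computed once at the largest
#' requested count and truncated, so the model at `n` and at `n + 1`
#' differ only by the added variable. Used to locate the accuracy plateau
#' (20 variables for the puma data).
#'
#' @param table feature data.frame with `sex`.
#' @param var_counts integer vector of counts to evaluate.
#' @return data.frame with columns `n_vars`, `accuracy` (%).
#' @export
accuracy_curve <- function(table, var_counts = c(1:10, 12, 15, 20, 25, 30)) {
  stopifnot(length(var_counts) >= 1)
  keep <- table$sex %in% c("F", "M")
  table <- table[keep, , drop = FALSE]
  sex <- factor(table$sex, levels = c("F", "M"))
  X <- .feature_matrix(table)
  sel <- stepwise_select(X, sex, max(var_counts))
  acc <- vapply(var_counts, function(k) {
    k_eff <- min(k, nrow(sel))
    jackknife_accuracy(table, variables = sel$variable[seq_len(k_eff)])
  }, numeric(1))
  data.frame(n_vars = var_counts, accuracy = acc)
}
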