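#' Forward stepwise variable selection by partial F-ratio
#'
#' Greedy forward selection of the variables with the highest discriminatory
#' power for a grouping factor. At each step every remaining candidate is
#' residualised on the variables already selected (ordinary least squares
#' with intercept) and the one-way ANOVA F statistic of the group effect on
#' the residuals is computed with denominator degrees of freedom
#' `n - g - q` (`q` = number already selected). The candidate with the
#' largest partial F enters; ties break to the lowest column index; the
#' procedure stops at `max_vars` or when no candidate has positive F.
#' Constant (zero-residual-variance) candidates are skipped with a warning.
#' The first selected variable is exactly the one-way ANOVA F argmax.
#'
#' @param x numeric matrix (rows = observations, named columns = candidate
#'   variables).
#' @param groups factor of group labels, length `nrow(x)`.
#' @param max_vars maximum number of variables to select (>= 1).
#' @return data.frame with columns `variable`, `index`, `F` (partial
#'   F-ratio at entry), in selection order.
#' @export
stepwise_select <- function(x, groups, max_vars) {
  x <- as.matrix(x)
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  n <- nrow(x)
  stopifnot(max_vars >= 1, g >= 2, length(groups) == n)
  if (min(table(groups)) < 2L) stop("every group needs >= 2 rows")
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))

  G <- stats::model.matrix(~ groups - 1)
  ng <- colSums(G)
  p <- ncol(x)
  # residual matrix after projecting out intercept + selected variables,
  # maintained against an orthonormal basis Q
  q1 <- rep(1 / sqrt(n), n)
  R <- x - tcrossprod(q1, colSums(x) / sqrt(n))
  Q <- matrix(q1, n, 1)
  eligible <- rep(TRUE, p)
  sel <- integer(0)
  Fsel <- numeric(0)
  warned_const <- FALSE
  # per-column degeneracy tolerance, relative to each variable's initial
  # centred sum of squares (so mm^2-scale areas and degree-scale angles are
  # judged on their own scale)
  tol <- pmax(1e-10 * colSums(R^2), 1e-12)

  for (step in seq_len(min(max_vars, p))) {
    q <- length(sel)
    df2 <- n - g - q
    if (df2 < 1L) break
    rss <- colSums(R^2)
    const <- eligible & rss <= tol
    if (any(const)) {
      if (!warned_const) {
        warning("skipping constant/collinear variable(s): ",
                paste(colnames(x)[const], collapse = ", "))
        warned_const <- TRUE
      }
      eligible[const] <- FALSE
    }
    cand <- which(eligible)
    if (length(cand) == 0L) break
    M <- crossprod(G, R[, cand, drop = FALSE]) / ng   # group means of residuals
    ssb <- colSums(ng * M^2)
    ssw <- pmax(rss[cand] - ssb, 0)
    Fstat <- (ssb / (g - 1)) / (ssw / df2)
    Fstat[!is.finite(Fstat)] <- Inf   # perfect separation: ssw == 0
    # ties (exact or to floating-point noise) break to the lowest index
    fmax <- max(Fstat)
    best <- if (is.finite(fmax)) {
      which(Fstat >= fmax - abs(fmax) * 1e-9)[1]
    } else {
      which(Fstat == fmax)[1]
    }
    if (Fstat[best] <= 0) break
    j <- cand[best]
    sel <- c(sel, j)
    Fsel <- c(Fsel, Fstat[best])
    # extend the orthonormal basis with the chosen column and update residuals
    v <- R[, j]
    nv <- sqrt(sum(v^2))
    qnew <- v / nv
    R <- R - tcrossprod(qnew, crossprod(qnew, R)[1, ])
    Q <- cbind(Q, qnew)
    eligible[j] <- FALSE
  }
  data.frame(variable = colnames(x)[sel], index = sel, F = Fsel,
             stringsAsFactors = FALSE)
}

#' Canonical variates (canonical discriminant analysis)
#'
#' Computes Fisher's canonical variates for grouped multivariate data:
#' variables are standardised by their pooled within-group standard
#' deviations, then the generalised eigenproblem `B a = lambda W a` is
#' solved, with `W` the pooled within-group covariance and `B` the
#' between-group scatter of group means about the grand mean divided by
#' `g - 1`. Eigenvectors are scaled to unit pooled within-group variance of
#' the scores (`a' W a = 1`); the top two define the 2-D canonical space in
#' which trail centroids and confidence ellipses are drawn. A singular `W`
#' is ridge-regularised (`epsilon = 1e-8 * trace/dim`) with a warning.
#'
#' @param x numeric matrix of the selected variables.
#' @param groups factor of group labels.
#' @param ncomp number of canonical axes to return (default 2).
#' @return object of class `canonical_variates`: list with `scores`
#'   (n x ncomp), `eigenvalues` (all, non-increasing, >= 0), `loadings`
#'   (p x ncomp, on the standardised scale), `groups`, `center` (grand
#'   mean), `scale` (pooled s.d.), `group_centroids` (g x ncomp).
#' @export
canonical_variates <- function(x, groups, ncomp = 2L) {
  x <- as.matrix(x)
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(g >= 2, n > g)

  G <- stats::model.matrix(~ groups - 1)
  ng <- colSums(G)
  means <- crossprod(G, x) / ng                       # g x p group means
  Xw <- x - means[as.integer(groups), , drop = FALSE]
  Wscat <- crossprod(Xw)
  sdp <- sqrt(diag(Wscat) / (n - g))
  sdp[sdp <= 0] <- 1
  xs <- sweep(x, 2, sdp, "/")
  center <- colMeans(xs)

  means_s <- sweep(sweep(means, 2, sdp, "/"), 2, center)
  W <- crossprod(sweep(xs, 2, center) -
                 means_s[as.integer(groups), , drop = FALSE]) / (n - g)
  B <- crossprod(sweep(means_s, 1, sqrt(ng), "*")) / (g - 1)

  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) {
    # absolute floor covers the exactly-zero scatter of noise-free data
    eps <- max(1e-8 * sum(diag(W)) / p, 1e-12)
    warning("singular within-group scatter; ridge-regularising (epsilon = ",
            format(eps, digits = 3), ")")
    W <- W + diag(eps, p)
    ch <- tryCatch(chol(W), error = function(e) NULL)
    while (is.null(ch)) {
      eps <- eps * 100
      W <- W + diag(eps, p)
      ch <- tryCatch(chol(W), error = function(e) NULL)
    }
  }
  # symmetric reduction: M = R^-T B R^-1, eigen, a = R^-1 u  => a' W a = 1
  Minner <- backsolve(ch, t(backsolve(ch, t(B), transpose = TRUE)),
                      transpose = TRUE)
  eg <- eigen((Minner + t(Minner)) / 2, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  ncomp_eff <- min(ncomp, p, g - 1)
  A <- backsolve(ch, eg$vectors[, seq_len(ncomp_eff), drop = FALSE])
  if (ncomp_eff < ncomp) {  # pad degenerate axes with zeros
    A <- cbind(A, matrix(0, p, ncomp - ncomp_eff))
  }
  scores <- sweep(xs, 2, center) %*% A
  colnames(scores) <- paste0("Can", seq_len(ncol(scores)))
  centroids <- crossprod(G, scores) / ng
  rownames(centroids) <- levels(groups)

  structure(list(scores = scores, eigenvalues = lambda, loadings = A,
                 groups = groups, center = center, scale = sdp,
                 group_centroids = centroids),
            class = "canonical_variates")
}

#' @export
print.canonical_variates <- function(x, ...) {
  cat("<canonical_variates> ", nrow(x$scores), " rows, ",
      nlevels(x$groups), " groups\n", sep = "")
  cat("  eigenvalues:",
      paste(format(x$eigenvalues[seq_len(min(3, length(x$eigenvalues)))],
                   digits = 4), collapse = ", "), "\n")
  invisible(x)
}
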