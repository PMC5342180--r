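#' Confidence ellipse for a trail centroid
#'
#' Builds the confidence region for a group's mean in the 2-D canonical
#' space: a Hotelling-type region with centre the group mean, shape the
#' group sample covariance divided by `n`, and scale constant
#' `c = 2 (n - 1) / (n - 2) * qf(p, 2, n - 2)`, so that the boundary is
#' `(z - m)' (S/n)^{-1} (z - m) = c`. This is the small-sample-correct
#' confidence region for the centroid at coverage `p` (the contour
#' probability) under bivariate normality, with the trail's own covariance.
#'
#' @param scores n x 2 matrix of a single group's canonical scores (n >= 3).
#' @param contour_probability coverage level in (0, 1), default 0.95.
#' @return object of class `fit_ellipse`: list with `center` (2-vector),
#'   `shape` (2 x 2 SPD matrix), `scale` (quantile constant), `n`,
#'   `contour_probability`.
#' @export
centroid_ellipse <- function(scores, contour_probability = 0.95) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2, contour_probability > 0,
            contour_probability < 1)
  n <- nrow(scores)
  if (n < 3L) stop("trail too short for ellipse (n = ", n, ", need >= 3)")
  center <- colMeans(scores)
  shape <- stats::cov(scores) / n
  # numerical floor: a trail with (near-)zero score scatter (e.g. noise-free
  # synthetic data, duplicated bootstrap rows) still gets a valid, tiny SPD
  # shape instead of a degenerate one
  floor_eps <- 1e-10 * max(sum(diag(shape)), sum(center^2), 1)
  ev <- eigen(shape, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= floor_eps) shape <- shape + diag(floor_eps, 2)
  scale <- 2 * (n - 1) / (n - 2) *
    stats::qf(contour_probability, 2, n - 2)
  structure(list(center = center, shape = shape, scale = scale, n = n,
                 contour_probability = contour_probability),
            class = "fit_ellipse")
}

#' @export
print.fit_ellipse <- function(x, ...) {
  cat("<fit_ellipse> center (", paste(format(x$center, digits = 4),
                                      collapse = ", "),
      "), n = ", x$n, ", coverage ", x$contour_probability, "\n", sep = "")
  invisible(x)
}

#' Points on an ellipse boundary
#'
#' @param e a `fit_ellipse`.
#' @param n_points number of boundary points.
#' @return n_points x 2 matrix tracing the boundary.
#' @export
ellipse_boundary <- function(e, n_points = 256L) {
  stopifnot(inherits(e, "fit_ellipse"))
  L <- t(chol(e$shape * e$scale))
  theta <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  t(e$center + L %*% rbind(cos(theta), sin(theta)))
}

#' Do two confidence ellipses overlap?
#'
#' Exact geometric test for non-empty intersection of two filled ellipses
#' (containment counts as overlap). The first ellipse is affinely mapped to
#' the unit disk; overlap then reduces to the distance from the origin to
#' the image of the second ellipse, computed by solving the standard
#' point-to-ellipse secular equation with a safeguarded root finder.
#'
#' @param e1,e2 `fit_ellipse` objects.
#' @return logical; `TRUE` iff the two (filled) ellipses intersect.
#' @export
ellipses_overlap <- function(e1, e2) {
  stopifnot(inherits(e1, "fit_ellipse"), inherits(e2, "fit_ellipse"))
  M1 <- e1$shape * e1$scale
  M2 <- e2$shape * e2$scale
  for (M in list(M1, M2)) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (any(!is.finite(ev)) || min(ev) <= 0) {
      stop("ellipse shape matrix is not positive definite")
    }
  }
  # map e1 to the unit disk: y = L^{-1} (z - c1), M1 = L L'
  L <- t(chol(M1))
  m <- forwardsolve(L, e2$center - e1$center)
  Li <- forwardsolve(L, diag(2))
  M2y <- Li %*% M2 %*% t(Li)
  M2y <- (M2y + t(M2y)) / 2
  eg <- eigen(M2y, symmetric = TRUE)
  ab2 <- pmax(eg$values, .Machine$double.xmin)   # semi-axes^2 of E2 image
  pt <- drop(crossprod(eg$vectors, -m))          # origin in E2's frame
  # origin inside E2?
  if (sum(pt^2 / ab2) <= 1) return(TRUE)
  dist2 <- .point_ellipse_dist2(ab2[1], ab2[2], pt[1], pt[2])
  dist2 <= 1
}

# squared distance from point (u, v) to the origin-centred ellipse
# x^2/a2 + y^2/b2 = 1, for a point strictly outside: unique root t > 0 of
# f(t) = a2 u^2/(t + a2)^2 + b2 v^2/(t + b2)^2 - 1.
.point_ellipse_dist2 <- function(a2, b2, u, v) {
  f <- function(t) a2 * u^2 / (t + a2)^2 + b2 * v^2 / (t + b2)^2 - 1
  hi <- sqrt(a2 * u^2 + b2 * v^2)   # f(hi) <= 0
  if (f(hi) > 0) {                  # numerical safety: expand
    while (f(hi) > 0) hi <- hi * 2
  }
  t <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  (u * t / (t + a2))^2 + (v * t / (t + b2))^2
}
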