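# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations (brute force / dense algebra / dense
# sampling) and share no code with the implementation paths they check.

# -- geometry ----------------------------------------------------------------

oracle_dist <- function(p, q) sqrt(sum((p - q)^2))

oracle_angle_deg <- function(v1, v2) {
  # atan2-based, independent of the acos implementation
  a <- atan2(v1[2], v1[1]) - atan2(v2[2], v2[1])
  a <- abs(a %% (2 * pi))
  if (a > pi) a <- 2 * pi - a
  a * 180 / pi
}

oracle_polygon_area <- function(pts) {
  # triangle fan decomposition from the centroid (signed, then abs)
  c0 <- colMeans(pts)
  n <- nrow(pts)
  s <- 0
  for (i in seq_len(n)) {
    a <- pts[i, ] - c0
    b <- pts[if (i == n) 1 else i + 1, ] - c0
    s <- s + (a[1] * b[2] - a[2] * b[1]) / 2
  }
  abs(s)
}

# -- ellipse overlap: dense boundary sampling + containment ------------------

oracle_ellipse_overlap <- function(e1, e2, n_points = 4096L) {
  inside <- function(Z, e) {
    d <- sweep(Z, 2, e$center)
    rowSums((d %*% solve(e$shape)) * d) <= e$scale * (1 + 1e-9)
  }
  if (any(inside(rbind(e1$center), e2)) ||
      any(inside(rbind(e2$center), e1))) return(TRUE)
  if (any(inside(ellipse_boundary(e1, n_points), e2))) return(TRUE)
  any(inside(ellipse_boundary(e2, n_points), e1))
}

random_ellipse <- function(center_range = 3) {
  A <- matrix(stats::rnorm(4), 2)
  shape <- crossprod(A) + diag(0.05, 2)
  structure(list(center = stats::runif(2, -center_range, center_range),
                 shape = shape, scale = stats::runif(1, 0.2, 2.5),
                 n = 10L, contour_probability = 0.95),
            class = "fit_ellipse")
}

# -- Ward agglomeration: naive O(n^3) Lance-Williams -------------------------

oracle_ward <- function(D) {
  n <- nrow(D)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  d <- D
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    bd <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (d[i, j] < bd) { bd <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- bd
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d[i, k] <- d[k, i] <-
        ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
        (ni + nj + nk)
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
    partitions[[step]] <- lapply(c(active), function(a) sort(members[[a]]))
  }
  list(heights = heights, partitions = partitions)
}

# partition of leaves after the first `step` merges of an hclust
hclust_partition <- function(hc, step) {
  k <- length(hc$height) + 1 - step
  cl <- stats::cutree(hc, k = k)
  unname(lapply(split(seq_along(cl), cl), sort))
}

same_partition <- function(a, b) {
  key <- function(p) sort(vapply(p, function(x) paste(x, collapse = ","),
                                 character(1)))
  identical(key(a), key(b))
}

# -- dense generalized-eigen oracle for canonical variates -------------------

oracle_cva <- function(x, groups) {
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  n <- nrow(x)
  G <- stats::model.matrix(~ groups - 1)
  ng <- colSums(G)
  means <- crossprod(G, x) / ng
  Xw <- x - means[as.integer(groups), , drop = FALSE]
  sdp <- sqrt(diag(crossprod(Xw)) / (n - g))
  xs <- sweep(x, 2, sdp, "/")
  ms <- crossprod(G, xs) / ng
  grand <- colMeans(xs)
  W <- crossprod(sweep(xs, 2, grand) -
                 sweep(ms, 2, grand)[as.integer(groups), , drop = FALSE]) /
    (n - g)
  B <- crossprod(sweep(sweep(ms, 2, grand), 1, sqrt(ng), "*")) / (g - 1)
  # explicit inversion, non-symmetric eigen
  eg <- eigen(solve(W) %*% B)
  ord <- order(Re(eg$values), decreasing = TRUE)
  list(values = Re(eg$values)[ord], vectors = Re(eg$vectors)[, ord,
                                                             drop = FALSE],
       W = W, B = B)
}

# brute-force one-way ANOVA F
oracle_anova_F <- function(v, groups) {
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  n <- length(v)
  m <- mean(v)
  mk <- tapply(v, groups, mean)
  nk <- tabulate(groups)
  ssb <- sum(nk * (mk - m)^2)
  ssw <- sum((v - mk[as.integer(groups)])^2)
  (ssb / (g - 1)) / (ssw / (n - g))
}

# closed-form LDA weights by explicit inversion
oracle_lda_weights <- function(X, y) {
  lev <- levels(y)
  m1 <- colMeans(X[y == lev[1], , drop = FALSE])
  m2 <- colMeans(X[y == lev[2], , drop = FALSE])
  n1 <- sum(y == lev[1]); n2 <- sum(y == lev[2])
  S1 <- stats::cov(X[y == lev[1], , drop = FALSE]) * (n1 - 1)
  S2 <- stats::cov(X[y == lev[2], , drop = FALSE]) * (n2 - 1)
  Sp <- (S1 + S2) / (n1 + n2 - 2)
  drop(solve(Sp) %*% (m2 - m1))
}

# -- fixture builders --------------------------------------------------------

# jittered template landmark set (guaranteed non-degenerate constructions)
jittered_landmarks <- function(id = "fp", trail = "t", jitter = 1,
                               calibrated = TRUE) {
  pts <- puma_template() + matrix(stats::rnorm(50, sd = jitter), 25, 2)
  landmark_set(pts, rbind(c(0, 0), c(10, 0)), id, trail,
               calibrated = calibrated)
}

# small feature table with groups but no footprint geometry
toy_table <- function(n_per = 5, p = 6, groups = c("a", "b", "c"),
                      shift = 0) {
  n <- n_per * length(groups)
  X <- matrix(stats::rnorm(n * p), n, p)
  grp <- rep(groups, each = n_per)
  X[, 1] <- X[, 1] + shift * as.integer(factor(grp))
  colnames(X) <- paste0("V", seq_len(p))
  df <- data.frame(footprint_id = sprintf("fp%02d", seq_len(n)),
                   trail_id = grp, animal_id = grp, sex = "unknown",
                   age_years = NA_real_, side = "LH",
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(X))
}

default_pop <- function(seed, n_individuals = 8, ...) {
  generate_population(population_spec(n_individuals = n_individuals,
                                      seed = seed, ...))
}

pair_truth <- function(tab, trails) {
  owner <- vapply(trails, function(t) {
    unique(tab$animal_id[tab$trail_id == t])[1]
  }, character(1))
  outer(owner, owner, "==")
}
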