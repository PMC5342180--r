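test_that("Ward clustering handles the stated edge cases", {
  D <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- ward_cluster(D)
  expect_equal(hc$height[1], 0)                    # A,B merge first at 0
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))
  # equidistant trails all merge; single cluster at a large threshold
  n <- 6
  E <- matrix(5, n, n); diag(E) <- 0
  dimnames(E) <- list(paste0("t", 1:n), paste0("t", 1:n))
  hcE <- ward_cluster(E)
  expect_equal(estimate_individuals(hcE, max(hcE$height) + 1)$count, 1L)
  # validation errors
  bad <- D; bad[1, 2] <- bad[2, 1] <- NaN
  expect_error(ward_cluster(bad), "A/B")
  asym <- D; asym[1, 2] <- 3
  expect_error(ward_cluster(asym), "symmetric")
  neg <- D; neg[1, 3] <- neg[3, 1] <- -1
  expect_error(ward_cluster(neg), "non-negative")
})

test_that("Ward linkage matches the naive O(n^3) agglomeration oracle", {
  for (seed in 1:10) {
    set.seed(200 + seed)
    n <- 8
    M <- matrix(runif(n * n, 1, 10), n, n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    hc <- ward_cluster(D)
    or <- oracle_ward(D)
    expect_equal(sort(hc$height), sort(or$heights), tolerance = 1e-10)
    for (step in seq_len(n - 1)) {
      expect_true(same_partition(hclust_partition(hc, step),
                                 or$partitions[[step]]))
    }
  }
})

test_that("threshold cutting and count monotonicity", {
  set.seed(77)
  n <- 9
  M <- matrix(runif(n * n, 1, 10), n, n)
  D <- (M + t(M)) / 2; diag(D) <- 0
  dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
  hc <- ward_cluster(D)
  expect_equal(estimate_individuals(hc, 0)$count, n)   # all distances > 0
  expect_equal(estimate_individuals(hc, max(hc$height))$count, 1L)
  counts <- vapply(seq(0, max(hc$height) * 1.1, length.out = 40),
                   function(th) estimate_individuals(hc, th)$count,
                   integer(1))
  expect_true(all(diff(counts) <= 0))                  # non-increasing
})

test_that("threshold tuning maximises placement accuracy", {
  pop <- default_pop(seed = 81, n_individuals = 6)
  pm <- suppressWarnings(pairwise_matrix(pop$table, algorithm_config(seed = 1)))
  hc <- ward_cluster(pm)
  truth <- vapply(hc$labels, function(t) {
    unique(pop$table$animal_id[pop$table$trail_id == t])[1]
  }, character(1))
  th <- tune_threshold(hc, truth)
  expect_equal(attr(th, "accuracy"), 100)
  cens <- estimate_individuals(hc, as.numeric(th))
  expect_equal(cens$count, 6L)
  # ties resolve to the smallest candidate threshold
  grid <- attr(th, "grid")
  accs <- vapply(grid, function(g) {
    trail_placement_accuracy(cutree(hc, h = g), truth)
  }, numeric(1))
  expect_equal(as.numeric(th), min(grid[accs == max(accs)]))
  # one-animal truth forces a merge-everything threshold
  th1 <- tune_threshold(hc, setNames(rep("A1", length(truth)), names(truth)))
  expect_gte(as.numeric(th1), max(hc$height))
  expect_error(tune_threshold(hc, truth, grid = numeric(0)), "empty")
})

test_that("placement accuracy: optimal matching, relabel-invariant", {
  truth <- rep(c("a", "b", "c"), each = 4)
  expect_equal(trail_placement_accuracy(rep(1:3, each = 4), truth), 100)
  # permuting cluster labels changes nothing
  expect_equal(trail_placement_accuracy(rep(c(9, 2, 7), each = 4), truth),
               100)
  # 3 of 12 misplaced
  ass <- rep(1:3, each = 4)
  ass[c(1, 5, 9)] <- c(3, 1, 2)
  expect_equal(trail_placement_accuracy(ass, truth), 75)
  # one-to-one matching: splitting an animal across clusters is penalised
  t2 <- c("a", "a", "a", "b")
  a2 <- c(1, 1, 2, 1)
  expect_equal(trail_placement_accuracy(a2, t2), 50)  # 1->a only
  # random labels on 2 balanced clusters sit near 50% on average
  set.seed(5)
  accs <- replicate(400, {
    trail_placement_accuracy(sample(rep(1:2, 10)), rep(c("x", "y"), 10))
  })
  expect_gt(mean(accs), 50)        # optimal matching never scores below 50
  expect_lt(mean(accs), 62)
})

test_that("bootstrap likelihood profile behaves", {
  # noise-free: every resample identical, all mass on the true count
  pop <- generate_population(population_spec(
    n_individuals = 3, seed = 91, sigma_noise = 0,
    trails_per_individual = c(2, 2), prints_per_trail = c(4, 4)))
  pm <- suppressWarnings(pairwise_matrix(pop$table, algorithm_config(seed = 1)))
  hc <- ward_cluster(pm)
  truth <- vapply(hc$labels, function(t) {
    unique(pop$table$animal_id[pop$table$trail_id == t])[1]
  }, character(1))
  th <- as.numeric(tune_threshold(hc, truth))
  cfg <- algorithm_config(ward_threshold = th, seed = 1)
  prof <- suppressWarnings(likelihood_profile(pop$table, cfg,
                                              n_bootstrap = 100, seed = 4))
  expect_equal(names(prof), "3")
  expect_equal(unname(prof), 1)
  # normalisation and reproducibility on noisy data
  pop2 <- generate_population(population_spec(
    n_individuals = 3, seed = 92,
    trails_per_individual = c(2, 2), prints_per_trail = c(4, 4)))
  pm2 <- suppressWarnings(pairwise_matrix(pop2$table, algorithm_config(seed = 1)))
  hc2 <- ward_cluster(pm2)
  truth2 <- vapply(hc2$labels, function(t) {
    unique(pop2$table$animal_id[pop2$table$trail_id == t])[1]
  }, character(1))
  cfg2 <- algorithm_config(
    ward_threshold = as.numeric(tune_threshold(hc2, truth2)), seed = 1)
  p1 <- suppressWarnings(likelihood_profile(pop2$table, cfg2,
                                            n_bootstrap = 100, seed = 7))
  p2 <- suppressWarnings(likelihood_profile(pop2$table, cfg2,
                                            n_bootstrap = 100, seed = 7))
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_equal(max(p1), 1)
  expect_error(likelihood_profile(pop2$table, cfg2, n_bootstrap = 50,
                                  seed = 1), ">= 100")
  expect_error(likelihood_profile(pop2$table, algorithm_config(), 100, 1),
               "numeric ward_threshold")
})
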