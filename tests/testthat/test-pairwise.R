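test_that("algorithm config validates its fields", {
  cfg <- algorithm_config()
  expect_equal(cfg$n_variables, 15L)
  expect_equal(cfg$contour_probability, 0.95)
  expect_equal(cfg$selection_scope, "reference")
  expect_error(algorithm_config(n_variables = 0))
  expect_error(algorithm_config(contour_probability = 1))
  expect_error(algorithm_config(ward_threshold = -2), "ward_threshold")
  expect_error(algorithm_config(rcv_mode = "bogus"))
})

test_that("RCV construction: set difference and duplicate modes", {
  pop <- default_pop(seed = 51, n_individuals = 5)
  tab <- pop$table
  trails <- unique(tab$trail_id)
  own <- unique(tab$animal_id[tab$trail_id %in% trails[1:2]])
  rcv <- build_rcv(tab, trails[1], trails[2], "all-other-animals")
  expect_false(any(rcv$animal_id %in% own))
  expect_equal(nrow(rcv), sum(!tab$animal_id %in% own))
  # whole-table-duplicate returns a copy of every row
  dup <- build_rcv(tab, trails[1], trails[2], "whole-table-duplicate")
  expect_equal(nrow(dup), nrow(tab))
  # two-animal library cannot build an all-other reference
  two <- tab[tab$animal_id %in% own, ]
  expect_error(build_rcv(two, trails[1], trails[2], "all-other-animals"),
               "library too small")
})

test_that("split halves of one trail are judged the same individual", {
  pop <- default_pop(seed = 52, n_individuals = 6)
  tab <- pop$table
  tr <- names(which(table(tab$trail_id) >= 6))[1]
  sp <- split_trail(tab, tr, seed = 3)
  res <- suppressWarnings(compare_trails(sp, paste0(tr, ".a"),
                                         paste0(tr, ".b"),
                                         algorithm_config(seed = 1)))
  expect_s3_class(res, "pair_result")
  expect_equal(res$verdict, "same")
  expect_true(res$overlap)
  expect_gte(res$centroid_distance, 0)
})

test_that("well-separated individuals are judged different", {
  pop <- generate_population(population_spec(
    n_individuals = 6, seed = 53, sigma_individual = 4, sigma_noise = 0.3))
  tab <- pop$table
  a <- unique(tab$trail_id[tab$animal_id == "A001"])[1]
  b <- unique(tab$trail_id[tab$animal_id == "A002"])[1]
  res <- suppressWarnings(compare_trails(tab, a, b,
                                         algorithm_config(seed = 1)))
  expect_equal(res$verdict, "different")
  expect_false(res$overlap)
  # verdict/distance symmetric in trail order
  res2 <- suppressWarnings(compare_trails(tab, b, a,
                                          algorithm_config(seed = 1)))
  expect_equal(res2$verdict, res$verdict)
  expect_equal(res2$centroid_distance, res$centroid_distance,
               tolerance = 1e-9)
  # short trails are refused
  short <- tab[c(which(tab$trail_id == a)[1:2], which(tab$trail_id != a)), ]
  expect_error(suppressWarnings(compare_trails(short, a, b,
                                               algorithm_config(seed = 1))),
               ">= 3 required")
})

test_that("verdict is invariant to RCV row duplication", {
  pop <- default_pop(seed = 54, n_individuals = 6)
  tab <- pop$table
  trails <- unique(tab$trail_id)
  cfg <- algorithm_config(seed = 1)
  res <- suppressWarnings(compare_trails(tab, trails[1], trails[3], cfg))
  # duplicate every row of every *other* animal (the RCV pool)
  own <- unique(tab$animal_id[tab$trail_id %in% trails[c(1, 3)]])
  extra <- tab[!(tab$animal_id %in% own), ]
  dup <- rbind(tab, extra)
  res2 <- suppressWarnings(compare_trails(dup, trails[1], trails[3], cfg))
  expect_equal(res2$verdict, res$verdict)
  expect_equal(res2$selected$variable, res$selected$variable)
  # group means are unchanged; distances shift only via the pooled df
  # reweighting, so they stay close but are not bit-identical
  expect_equal(res2$centroid_distance, res$centroid_distance,
               tolerance = 0.05)
})

test_that("verdict is invariant under per-variable affine rescaling", {
  pop <- default_pop(seed = 55, n_individuals = 6)
  tab <- pop$table
  trails <- unique(tab$trail_id)
  cfg <- algorithm_config(seed = 1)
  res <- suppressWarnings(compare_trails(tab, trails[1], trails[2], cfg))
  vcols <- grep("^V", names(tab), value = TRUE)
  set.seed(99)
  a <- runif(length(vcols), 0.2, 5)
  b <- rnorm(length(vcols), 0, 10)
  tab2 <- tab
  for (i in seq_along(vcols)) {
    tab2[[vcols[i]]] <- a[i] * tab[[vcols[i]]] + b[i]
  }
  res2 <- suppressWarnings(compare_trails(tab2, trails[1], trails[2], cfg))
  expect_equal(res2$verdict, res$verdict)
  expect_equal(res2$selected$variable, res$selected$variable)
  expect_equal(res2$centroid_distance, res$centroid_distance,
               tolerance = 1e-6)
})

test_that("overlap is monotone in the contour probability", {
  pop <- default_pop(seed = 56, n_individuals = 6)
  tab <- pop$table
  trails <- unique(tab$trail_id)
  probs <- c(0.5, 0.8, 0.9, 0.95, 0.99, 0.999)
  for (pair in list(trails[1:2], trails[c(1, 4)], trails[c(2, 5)])) {
    ov <- vapply(probs, function(p) {
      suppressWarnings(compare_trails(
        tab, pair[1], pair[2],
        algorithm_config(contour_probability = p, seed = 1)))$overlap
    }, logical(1))
    # once overlapping, stays overlapping as p grows
    expect_true(all(diff(as.integer(ov)) >= 0))
  }
})

test_that("pairwise matrix is symmetric and consistent with single calls", {
  pop <- default_pop(seed = 57, n_individuals = 5)
  tab <- pop$table
  cfg <- algorithm_config(seed = 1)
  pm <- suppressWarnings(pairwise_matrix(tab, cfg))
  D <- pm$distance
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, nrow(D)))
  expect_equal(pm$same, t(pm$same))
  # entries equal individual compare_trails calls
  for (pair in list(c(1, 2), c(2, 5))) {
    i <- pm$trails[pair[1]]; j <- pm$trails[pair[2]]
    res <- suppressWarnings(compare_trails(tab, i, j, cfg))
    expect_equal(D[i, j], res$centroid_distance, tolerance = 1e-9)
    expect_equal(pm$same[i, j], res$overlap)
  }
  # reordering trails permutes, not changes, the matrix
  pm2 <- suppressWarnings(pairwise_matrix(tab, cfg,
                                          trails = rev(pm$trails)))
  expect_equal(pm2$distance[pm$trails, pm$trails], D, tolerance = 1e-9)
  # 2-trail edge case
  two <- tab[tab$trail_id %in% pm$trails[1:2], ]
  pm3 <- suppressWarnings(pairwise_matrix(two, cfg, rcv_table = tab))
  expect_equal(dim(pm3$distance), c(2L, 2L))
  # trails with < 3 prints are dropped with a warning
  crip <- tab[-(which(tab$trail_id == pm$trails[1])[-(1:2)]), ]
  expect_warning(pairwise_matrix(crip, cfg), "< 3 footprints")
})

test_that("cross-validated footprint rate is reported and sane", {
  pop <- generate_population(population_spec(
    n_individuals = 6, seed = 58, sigma_individual = 4, sigma_noise = 0.3))
  tab <- pop$table
  a <- unique(tab$trail_id[tab$animal_id == "A001"])[1]
  b <- unique(tab$trail_id[tab$animal_id == "A003"])[1]
  res <- suppressWarnings(compare_trails(tab, a, b,
                                         algorithm_config(seed = 1)))
  expect_gte(res$cv_rate, 0)
  expect_lte(res$cv_rate, 100)
  # strongly separated trails classify their own prints correctly
  expect_gte(res$cv_rate, 90)
})
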