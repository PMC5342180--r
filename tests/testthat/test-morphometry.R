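test_that("variable catalog has the documented composition", {
  cat128 <- variable_catalog()
  tab <- cat128$table
  expect_equal(nrow(tab), 128L)
  expect_equal(sum(tab$kind == "length"), 102L)
  expect_equal(tab$name[tab$kind == "angle_intersection"], paste0("V", 81:88))
  expect_equal(tab$name[tab$kind == "angle_vertex"], paste0("V", 89:96))
  expect_equal(tab$name[tab$kind == "area"], paste0("V", 119:128))
  expect_equal(sum(tab$sex), 20L)
  # masking preserves order and rejects unknowns
  sub <- variable_catalog(mask = c("V5", "V1"))
  expect_equal(sub$table$name, c("V5", "V1"))
  expect_error(variable_catalog(mask = "V999"), "unknown variable")
})

test_that("calibration rescales by the scale-point ratio", {
  pts <- puma_template() * 10          # pretend pixels
  pts[1, ] <- c(250, 130)
  ls <- landmark_set(pts, rbind(c(0, 0), c(100, 0)), "f1", "t1")
  cal <- calibrate(ls, known_separation_mm = 10)   # factor 0.1
  expect_true(cal$calibrated)
  expect_equal(unname(cal$points[1, ]), c(25, 13))
  # identity calibration
  ls2 <- landmark_set(puma_template(), rbind(c(0, 0), c(10, 0)), "f2", "t1")
  cal2 <- calibrate(ls2, 10)
  expect_equal(cal2$points, ls2$points)
  # property: every pairwise distance scales by exactly the factor
  set.seed(41)
  pts3 <- matrix(runif(50, 0, 500), 25, 2)
  ls3 <- landmark_set(pts3, rbind(c(10, 20), c(10, 95)), "f3", "t1")
  cal3 <- calibrate(ls3, known_separation_mm = 30)
  f <- 30 / 75
  d_raw <- unname(as.matrix(dist(pts3)))
  d_cal <- unname(as.matrix(dist(cal3$points)))
  expect_equal(d_cal, d_raw * f, tolerance = 1e-12)
  # degenerate scale
  ls4 <- landmark_set(pts3, rbind(c(5, 5), c(5, 5)), "f4", "t1")
  expect_error(calibrate(ls4, 10), "degenerate scale")
  expect_error(calibrate(cal2, -1), "must be > 0")
})

test_that("derived points are deterministic and rigid-motion equivariant", {
  set.seed(42)
  ls <- jittered_landmarks("f1", "t1")
  d1 <- derive_points(ls)
  d2 <- derive_points(ls)
  expect_identical(d1$points, d2$points)      # bit-exact repeatability
  expect_equal(nrow(d1$points), 40L)
  # midpoint construction: point 26 = midpoint of 01 and 05
  expect_equal(d1$points[26, ],
               (d1$points[1, ] + d1$points[5, ]) / 2)
  # rotation by 30 degrees + translation commutes with derivation
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(7, -3)
  rot <- ls
  rot$points <- sweep(ls$points %*% R, 2, shift, "+")
  drot <- derive_points(rot)
  expect_equal(drot$points[26:40, ],
               sweep(d1$points[26:40, ] %*% R, 2, shift, "+"),
               tolerance = 1e-9)
  # degenerate intersection: pad axis parallel to the distal toe line
  bad <- ls
  bad$points[3, ] <- c(5, 0); bad$points[15, ] <- c(5, 80)  # line x = 5
  bad$points[22, ] <- c(0, -40)
  bad$points[17, ] <- c(-1, 0); bad$points[18, ] <- c(1, 0) # axis x = 0
  expect_error(derive_points(bad), "derived point 35")
})

test_that("feature extraction matches an independent geometry oracle", {
  set.seed(43)
  cat128 <- variable_catalog()
  for (rep in 1:5) {
    ls <- derive_points(jittered_landmarks(sprintf("f%d", rep), "t1"))
    fv <- extract_features(ls, cat128)
    pts <- ls$points
    for (i in seq_len(nrow(cat128$table))) {
      row <- cat128$table[i, ]
      expected <- switch(row$kind,
        length = oracle_dist(pts[row$p1, ], pts[row$p2, ]),
        angle_intersection = oracle_angle_deg(
          pts[row$p2, ] - pts[row$p1, ], pts[row$p4, ] - pts[row$p3, ]),
        angle_vertex = oracle_angle_deg(
          pts[row$p1, ] - pts[row$p2, ], pts[row$p3, ] - pts[row$p2, ]),
        area = oracle_polygon_area(pts[cat128$areas[[row$name]], ,
                                       drop = FALSE]))
      expect_equal(fv[[row$name]], unname(expected), tolerance = 1e-9,
                   label = row$name)
    }
    # domain invariants
    vals <- unlist(fv[cat128$table$name])
    expect_true(all(is.finite(vals)))
    expect_true(all(vals[cat128$table$kind == "length"] >= 0))
    expect_true(all(vals[cat128$table$kind == "area"] >= 0))
    ang <- vals[grepl("angle", cat128$table$kind)]
    expect_true(all(ang >= 0 & ang <= 180))
  }
})

test_that("named examples: 3-4-5 length and unit-square toe area", {
  ls <- derive_points(jittered_landmarks("f1", "t1"))
  pts <- ls$points
  pts[1, ] <- c(0, 0); pts[3, ] <- c(3, 4)
  ls$points <- pts
  fv <- extract_features(ls)
  expect_equal(fv$V1, 5)                      # L 01-03
  # toe 5 polygon (points 13-16) as a unit square -> V120 = 1
  pts[13, ] <- c(20, 10); pts[14, ] <- c(21, 10)
  pts[15, ] <- c(21, 11); pts[16, ] <- c(20, 11)
  ls$points <- pts
  expect_equal(extract_features(ls)$V120, 1)
})

test_that("all variables are rigid-motion invariant; scaling behaves", {
  set.seed(44)
  ls <- derive_points(jittered_landmarks("f1", "t1"))
  fv <- extract_features(ls)
  cat128 <- variable_catalog()
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- ls
  rot$points <- sweep(ls$points %*% R, 2, c(-11, 4), "+")
  fv_rot <- extract_features(rot)
  nm <- cat128$table$name
  expect_equal(unlist(fv_rot[nm]), unlist(fv[nm]), tolerance = 1e-9)
  # uniform scaling: lengths linear, areas quadratic, angles unchanged
  sc <- ls
  sc$points <- ls$points * 3
  fv_sc <- extract_features(sc)
  kind <- cat128$table$kind
  expect_equal(unlist(fv_sc[nm[kind == "length"]]),
               unlist(fv[nm[kind == "length"]]) * 3, tolerance = 1e-9)
  expect_equal(unlist(fv_sc[nm[kind == "area"]]),
               unlist(fv[nm[kind == "area"]]) * 9, tolerance = 1e-9)
  expect_equal(unlist(fv_sc[nm[grepl("angle", kind)]]),
               unlist(fv[nm[grepl("angle", kind)]]), tolerance = 1e-9)
  # purity: identical input -> bit-identical output
  expect_identical(extract_features(ls), fv)
})

test_that("vertex angles satisfy the law of cosines", {
  set.seed(45)
  ls <- derive_points(jittered_landmarks("f1", "t1"))
  fv <- extract_features(ls)
  tab <- variable_catalog()$table
  for (i in which(tab$kind == "angle_vertex")) {
    a <- oracle_dist(ls$points[tab$p1[i], ], ls$points[tab$p2[i], ])
    b <- oracle_dist(ls$points[tab$p3[i], ], ls$points[tab$p2[i], ])
    cc <- oracle_dist(ls$points[tab$p1[i], ], ls$points[tab$p3[i], ])
    loc <- acos((a^2 + b^2 - cc^2) / (2 * a * b)) * 180 / pi
    expect_equal(fv[[tab$name[i]]], loc, tolerance = 1e-9)
  }
})

test_that("landmark validation and RH mirroring", {
  expect_error(landmark_set(matrix(0, 24, 2), rbind(c(0, 0), c(1, 0)),
                            "f", "t"), "25 landmark")
  pts <- puma_template()
  pts[3, 1] <- NA
  expect_error(landmark_set(pts, rbind(c(0, 0), c(1, 0)), "f", "t"),
               "non-finite")
  # a right-hind print is mirrored on construction and flagged
  rh <- landmark_set(puma_template(), rbind(c(0, 0), c(10, 0)),
                     "f", "t", side = "RH", calibrated = TRUE)
  expect_true(rh$mirrored)
  expect_equal(rh$points[, 1], -puma_template()[, 1], ignore_attr = TRUE)
  # features of the mirrored RH print equal the LH original's
  lh <- landmark_set(puma_template(), rbind(c(0, 0), c(10, 0)),
                     "f", "t", side = "LH", calibrated = TRUE)
  nm <- variable_catalog()$table$name
  expect_equal(unlist(extract_features(derive_points(rh))[nm]),
               unlist(extract_features(derive_points(lh))[nm]),
               tolerance = 1e-9)
  expect_error(extract_features(lh), "derive_points")
  un <- landmark_set(puma_template(), rbind(c(0, 0), c(10, 0)), "f", "t")
  expect_error(derive_points(un), "calibrate")
})
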