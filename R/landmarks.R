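#' Create a landmark set for one footprint
#'
#' A `landmark_set` holds the 25 placed landmark points of one left-hind
#' footprint, the two scale points with their known real-world separation,
#' and (after [derive_points()]) the 15 derived points 26-40.
#'
#' @param points 25 x 2 numeric matrix of landmark coordinates (pixels
#'   before calibration, mm after). Row order is point order 01..25.
#' @param scale_points 2 x 2 numeric matrix, the two scale (ruler) points in
#'   the same units as `points`.
#' @param footprint_id,trail_id identifiers (character scalars).
#' @param animal_id,sex,age_years optional metadata; `sex` is one of
#'   `"F"`, `"M"`, `"unknown"`.
#' @param side footprint side; the technique is built on left-hind (`"LH"`)
#'   prints. Right-side prints must be mirrored (x -> -x) before feature
#'   extraction; passing `side = "RH"` mirrors automatically and flags it.
#' @param calibrated logical; `TRUE` when coordinates are already mm.
#' @return object of class `landmark_set`.
#' @seealso [calibrate()], [derive_points()], [extract_features()]
#' @export
landmark_set <- function(points, scale_points, footprint_id, trail_id,
                         animal_id = NA_character_, sex = "unknown",
                         age_years = NA_real_, side = "LH",
                         calibrated = FALSE) {
  points <- as.matrix(points)
  scale_points <- as.matrix(scale_points)
  if (nrow(points) != 25L || ncol(points) != 2L) {
    stop("exactly 25 landmark points (25 x 2 matrix) required, got ",
         nrow(points), " x ", ncol(points))
  }
  if (nrow(scale_points) != 2L || ncol(scale_points) != 2L) {
    stop("exactly 2 scale points required")
  }
  if (!all(is.finite(points)) || !all(is.finite(scale_points))) {
    stop("non-finite coordinates in landmark set '", footprint_id, "'")
  }
  side <- match.arg(side, c("LH", "RH"))
  mirrored <- FALSE
  if (side == "RH") {
    points[, 1] <- -points[, 1]
    scale_points[, 1] <- -scale_points[, 1]
    mirrored <- TRUE
  }
  sex <- match.arg(sex, c("F", "M", "unknown"))
  rownames(points) <- sprintf("%02d", 1:25)
  colnames(points) <- c("x", "y")
  structure(list(
    footprint_id = as.character(footprint_id),
    trail_id = as.character(trail_id),
    animal_id = as.character(animal_id),
    sex = sex,
    age_years = age_years,
    side = side,
    mirrored = mirrored,
    points = points,
    scale_points = scale_points,
    calibrated = isTRUE(calibrated)
  ), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> footprint ", x$footprint_id, " (trail ", x$trail_id,
      ")\n", sep = "")
  cat("  ", nrow(x$points), " points, ",
      if (x$calibrated) "calibrated (mm)" else "uncalibrated (px)",
      if (x$mirrored) ", mirrored from RH" else "", "\n", sep = "")
  invisible(x)
}

#' Calibrate landmark coordinates from pixels to millimetres
#'
#' Rescales every point by `known_separation_mm / d`, where `d` is the pixel
#' distance between the two scale points. Lengths scale linearly, areas
#' quadratically, angles are unchanged. If a second scale separation is
#' supplied (rulers are photographed along both image axes) the two implied
#' factors are compared and a warning is issued when they disagree by more
#' than 2%, a sign of perspective distortion in the photograph.
#'
#' @param x a [landmark_set()].
#' @param known_separation_mm real separation of the two scale points (mm).
#' @param second_separation_mm optional second scale distance (mm) paired
#'   with `second_scale_points` for the anisotropy check.
#' @param second_scale_points optional 2 x 2 matrix for the check.
#' @return the calibrated `landmark_set` (coordinates in mm).
#' @export
calibrate <- function(x, known_separation_mm,
                      second_separation_mm = NULL,
                      second_scale_points = NULL) {
  stopifnot(inherits(x, "landmark_set"))
  if (!is.numeric(known_separation_mm) || known_separation_mm <= 0) {
    stop("known_separation_mm must be > 0")
  }
  px <- sqrt(sum((x$scale_points[1, ] - x$scale_points[2, ])^2))
  if (px <= .Machine$double.eps * 100) {
    stop("degenerate scale: scale points coincide in footprint '",
         x$footprint_id, "'")
  }
  f <- known_separation_mm / px
  if (!is.null(second_separation_mm) && !is.null(second_scale_points)) {
    px2 <- sqrt(sum((second_scale_points[1, ] - second_scale_points[2, ])^2))
    if (px2 > 0) {
      f2 <- second_separation_mm / px2
      if (abs(f2 - f) / f > 0.02) {
        warning(sprintf(
          "anisotropic calibration in footprint '%s': X/Y scale factors differ by %.1f%%",
          x$footprint_id, 100 * abs(f2 - f) / f))
      }
    }
  }
  x$points <- x$points * f
  x$scale_points <- x$scale_points * f
  x$calibrated <- TRUE
  x
}

#' Generate the 15 derived points (26-40)
#'
#' Augments the 25 placed landmarks with 15 derived points via the fixed
#' construction table documented in the catalog source: midpoints of the
#' toe-base pairs, the toe-base centroid, midpoints of the pad boundary, the
#' intersection of the pad axis (points 22 to 31) with the outer distal toe
#' line (points 3 to 15), and projections of the outer toe flanks onto the
#' pad axis. The construction is deterministic and translation/rotation
#' equivariant; the original software does not publish its constructions, so
#' this table is a package convention (see the methods vignette).
#'
#' @param x a calibrated [landmark_set()].
#' @return the `landmark_set` with a 40 x 2 `points` matrix.
#' @export
derive_points <- function(x) {
  stopifnot(inherits(x, "landmark_set"))
  if (!x$calibrated) stop("calibrate() the landmark set before derive_points()")
  if (nrow(x$points) != 25L) stop("landmark set already has derived points")
  pts <- rbind(x$points, matrix(NA_real_, 15L, 2L))
  rownames(pts) <- sprintf("%02d", 1:40)
  for (nm in names(.derived_defs)) {
    d <- .derived_defs[[nm]]
    i <- as.integer(nm)
    a <- d$args
    pts[i, ] <- switch(d$op,
      midpoint = (pts[a[1], ] + pts[a[2], ]) / 2,
      centroid = colMeans(pts[a, , drop = FALSE]),
      intersect = .line_intersect(pts[a[1], ], pts[a[2], ],
                                  pts[a[3], ], pts[a[4], ], nm),
      project = .project_on_line(pts[a[1], ], pts[a[2], ], pts[a[3], ], nm),
      stop("unknown construction op: ", d$op)
    )
  }
  x$points <- pts
  x
}

.line_intersect <- function(p1, p2, q1, q2, point_name) {
  d1 <- p2 - p1
  d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  scale <- max(abs(c(d1, d2)), 1e-12)
  if (abs(den) <= 1e-10 * scale^2) {
    stop("derived point ", point_name,
         " degenerate: defining lines are parallel or coincident")
  }
  t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  p1 + t * d1
}

.project_on_line <- function(p, a, b, point_name) {
  d <- b - a
  dd <- sum(d^2)
  if (dd <= 1e-20) {
    stop("derived point ", point_name,
         " degenerate: axis points coincide")
  }
  a + d * sum((p - a) * d) / dd
}

#' Extract the 128 footprint variables
#'
#' Computes the full measurement vector for one footprint: lengths as
#' Euclidean distances between the catalog's point pairs, intersection
#' angles between two inter-point direction vectors and vertex angles at a
#' point (both in degrees, range 0-180), and region areas by the absolute
#' shoelace formula over the catalog's ordered peripheral points.
#'
#' @param x a calibrated [landmark_set()] with derived points (40 points).
#' @param catalog a [variable_catalog()]; defaults to the full 128-variable
#'   catalog.
#' @return one-row `data.frame`: metadata columns (`footprint_id`,
#'   `trail_id`, `animal_id`, `sex`, `age_years`, `side`) then the variables.
#' @examples
#' ls <- landmark_set(puma_template(), rbind(c(0, 0), c(10, 0)),
#'                    "fp1", "trail1", calibrated = TRUE)
#' fv <- extract_features(derive_points(ls))
#' fv$V1   # toe-2 length, mm
#' @export
extract_features <- function(x, catalog = variable_catalog()) {
  stopifnot(inherits(x, "landmark_set"), inherits(catalog, "variable_catalog"))
  if (!x$calibrated) stop("landmark set must be calibrated")
  if (nrow(x$points) != 40L) stop("derive_points() must be applied first")
  pts <- x$points
  if (!all(is.finite(pts))) {
    bad <- which(!is.finite(pts[, 1]) | !is.finite(pts[, 2]))
    tab <- catalog$table
    hit <- tab$name[tab$p1 %in% bad | tab$p2 %in% bad |
                    tab$p3 %in% bad | tab$p4 %in% bad]
    stop("non-finite point(s) ", paste(sprintf("%02d", bad), collapse = ", "),
         " in footprint '", x$footprint_id, "'; affected variables: ",
         paste(hit, collapse = ", "))
  }
  tab <- catalog$table
  vals <- numeric(nrow(tab))
  names(vals) <- tab$name

  len <- tab$kind == "length"
  if (any(len)) {
    d <- pts[tab$p1[len], , drop = FALSE] - pts[tab$p2[len], , drop = FALSE]
    vals[len] <- sqrt(rowSums(d^2))
  }
  ai <- which(tab$kind == "angle_intersection")
  for (i in ai) {
    v1 <- pts[tab$p2[i], ] - pts[tab$p1[i], ]
    v2 <- pts[tab$p4[i], ] - pts[tab$p3[i], ]
    vals[i] <- .vec_angle_deg(v1, v2)
  }
  av <- which(tab$kind == "angle_vertex")
  for (i in av) {
    v1 <- pts[tab$p1[i], ] - pts[tab$p2[i], ]
    v2 <- pts[tab$p3[i], ] - pts[tab$p2[i], ]
    vals[i] <- .vec_angle_deg(v1, v2)
  }
  ar <- which(tab$kind == "area")
  for (i in ar) {
    poly <- catalog$areas[[tab$name[i]]]
    vals[i] <- .shoelace(pts[poly, , drop = FALSE])
  }

  out <- data.frame(
    footprint_id = x$footprint_id, trail_id = x$trail_id,
    animal_id = x$animal_id, sex = x$sex, age_years = x$age_years,
    side = x$side, stringsAsFactors = FALSE
  )
  out[names(vals)] <- as.list(vals)
  out
}

.vec_angle_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length vector in angle computation")
  ct <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, ct))) * 180 / pi
}

.shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Extract features for many footprints
#'
#' @param landmark_sets list of calibrated, derived [landmark_set()]s.
#' @param catalog a [variable_catalog()].
#' @return data.frame, one row per footprint (see [extract_features()]).
#' @export
extract_features_table <- function(landmark_sets, catalog = variable_catalog()) {
  do.call(rbind, lapply(landmark_sets, extract_features, catalog = catalog))
}
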