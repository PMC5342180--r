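#' Variable catalog: the 128 footprint variables
#'
#' Builds the catalog describing how each of the 128 morphometric variables
#' (V1..V128) is computed from the 40 footprint points (25 placed landmarks
#' plus 15 derived points). 102 variables are inter-point lengths (mm), 8 are
#' angles at the intersection of two inter-point vectors (degrees), 8 are
#' angles at a vertex point (degrees) and 10 are polygon areas (mm^2) over
#' the peripheral points of a footprint region (whole print, the four toes,
#' the pad, and four toe/pad composites).
#'
#' Twenty variables carry a `sex` flag: the stepwise-selected set used for
#' sex discrimination, available as a fixed preset in [fit_sex_model()].
#'
#' @param mask optional character vector of variable names; the catalog is
#'   restricted to this subset (order preserved).
#' @return An object of class `variable_catalog`: a list with elements
#'   `table` (data.frame, one row per variable: `name`, `kind`, defining
#'   point indices), `areas` (named list of ordered point-index polygons)
#'   and `sex_vars` (character vector of the 20 sex-flagged variables).
#' @examples
#' cat128 <- variable_catalog()
#' nrow(cat128$table)            # 128
#' cat128$table[1, ]             # V1: length between points 01 and 03
#' @export
variable_catalog <- function(mask = NULL) {
  cat128 <- .catalog_env$catalog
  if (is.null(cat128)) {
    cat128 <- .build_catalog()
    .catalog_env$catalog <- cat128
  }
  if (!is.null(mask)) {
    bad <- setdiff(mask, cat128$table$name)
    if (length(bad) > 0L) {
      stop("unknown variable name(s): ", paste(bad, collapse = ", "))
    }
    cat128$table <- cat128$table[match(mask, cat128$table$name), , drop = FALSE]
    rownames(cat128$table) <- NULL
  }
  cat128
}

.catalog_env <- new.env(parent = emptyenv())

# Length variables: (index, point a, point b). V1-V80 and V97-V118.
.length_defs <- matrix(c(
   1, 1, 3,    2, 5, 7,    3, 9, 11,   4, 13, 15,  5, 2, 4,
   6, 6, 8,    7, 10, 12,  8, 14, 16,  9, 17, 18, 10, 19, 25,
  11, 22, 24, 12, 20, 22, 13, 21, 23, 14, 1, 22,  15, 5, 22,
  16, 9, 22,  17, 13, 22, 18, 22, 31, 19, 5, 31,  20, 22, 33,
  21, 9, 33,  22, 22, 32, 23, 32, 34, 24, 34, 35, 25, 26, 35,
  26, 1, 5,   27, 5, 9,   28, 9, 13,  29, 13, 19, 30, 19, 20,
  31, 24, 25, 32, 1, 25,  33, 3, 7,   34, 7, 11,  35, 11, 15,
  36, 15, 19, 37, 3, 25,  38, 17, 27, 39, 17, 28, 40, 17, 29,
  41, 17, 30, 42, 18, 27, 43, 18, 28, 44, 18, 29, 45, 18, 30,
  46, 5, 25,  47, 9, 25,  48, 13, 25, 49, 1, 19,  50, 5, 19,
  51, 9, 19,  52, 1, 2,   53, 2, 3,   54, 3, 4,   55, 1, 4,
  56, 5, 6,   57, 6, 7,   58, 7, 8,   59, 5, 8,   60, 9, 10,
  61, 10, 11, 62, 11, 12, 63, 9, 12,  64, 13, 14, 65, 14, 15,
  66, 15, 16, 67, 13, 16, 68, 17, 19, 69, 18, 25, 70, 27, 28,
  71, 28, 29, 72, 29, 30, 73, 1, 31,  74, 31, 32, 75, 32, 33,
  76, 13, 33, 77, 2, 34,  78, 16, 34, 79, 3, 35,  80, 15, 35,
  97, 2, 37,  98, 2, 36,  99, 26, 36, 100, 11, 26, 101, 11, 39,
 102, 16, 39, 103, 16, 38, 104, 24, 38, 105, 24, 37, 106, 18, 40,
 107, 13, 24, 108, 9, 24, 109, 5, 24, 110, 1, 24, 111, 1, 13,
 112, 36, 37, 113, 2, 16, 114, 3, 15, 115, 3, 24, 116, 7, 24,
 117, 11, 24, 118, 15, 24
), ncol = 3, byrow = TRUE)

# Intersection-angle variables V81-V88: angle between vector a1->a2 and
# vector b1->b2 (degrees, in [0, 180], order of the two vectors immaterial).
.inter_defs <- matrix(c(
  81,  1, 5,  9, 13,
  82,  3, 7, 11, 15,
  83,  5, 1, 24, 20,
  84,  9, 13, 20, 24,
  85,  3, 1,  1, 13,
  86,  7, 5,  1, 13,
  87, 11, 9,  1, 13,
  88, 15, 13, 13, 1
), ncol = 5, byrow = TRUE)

# Vertex-angle variables V89-V96: angle a-b-c at vertex b (degrees).
.vertex_defs <- matrix(c(
  89, 1, 22, 5,
  90, 5, 22, 9,
  91, 9, 22, 13,
  92, 2, 25, 19,
  93, 16, 19, 25,
  94, 1, 24, 5,
  95, 5, 24, 9,
  96, 9, 24, 13
), ncol = 4, byrow = TRUE)

# Area polygons V119-V128, ordered peripheral points (absolute shoelace).
# Area 1 whole print; 2-5 the four toes (outermost toe 5 down to innermost
# toe 2); 6 the pad; 7-10 toe-base / pad composites.
.area_defs <- list(
  V119 = c(20, 19, 2, 3, 6, 7, 11, 15, 16, 25, 24, 23, 22, 21),
  V120 = c(13, 14, 15, 16),
  V121 = c(9, 10, 11, 12),
  V122 = c(5, 6, 7, 8),
  V123 = c(1, 2, 3, 4),
  V124 = c(17, 19, 20, 21, 22, 23, 24, 25, 18),
  V125 = c(1, 5, 9, 13, 24, 23, 22, 21, 20),
  V126 = c(1, 13, 24, 23, 22, 21, 20),
  V127 = c(1, 5, 9, 13, 25, 19),
  V128 = c(1, 3, 7, 11, 15, 13)
)

# The 20 variables flagged for sex discrimination.
.sex_flagged <- paste0("V", c(1, 3, 9, 13, 23, 30, 38, 52, 59, 67, 73,
                              85, 88, 89, 93, 95, 101, 120, 121, 122))

.build_catalog <- function() {
  tab <- data.frame(
    name = paste0("V", 1:128),
    kind = NA_character_,
    p1 = NA_integer_, p2 = NA_integer_, p3 = NA_integer_, p4 = NA_integer_,
    sex = FALSE,
    stringsAsFactors = FALSE
  )
  i <- .length_defs[, 1]
  tab$kind[i] <- "length"
  tab$p1[i] <- .length_defs[, 2]
  tab$p2[i] <- .length_defs[, 3]

  i <- .inter_defs[, 1]
  tab$kind[i] <- "angle_intersection"
  tab$p1[i] <- .inter_defs[, 2]
  tab$p2[i] <- .inter_defs[, 3]
  tab$p3[i] <- .inter_defs[, 4]
  tab$p4[i] <- .inter_defs[, 5]

  i <- .vertex_defs[, 1]
  tab$kind[i] <- "angle_vertex"
  tab$p1[i] <- .vertex_defs[, 2]
  tab$p2[i] <- .vertex_defs[, 3]  # vertex point
  tab$p3[i] <- .vertex_defs[, 4]

  tab$kind[119:128] <- "area"
  tab$sex <- tab$name %in% .sex_flagged

  structure(list(table = tab, areas = .area_defs, sex_vars = .sex_flagged,
                 version = "1"),
            class = "variable_catalog")
}

#' @export
print.variable_catalog <- function(x, ...) {
  k <- table(x$table$kind)
  cat("Footprint variable catalog (version ", x$version, "): ",
      nrow(x$table), " variables\n", sep = "")
  cat("  ", paste(sprintf("%s: %d", names(k), as.integer(k)), collapse = ", "),
      "\n", sep = "")
  cat("  sex-flagged: ", sum(x$table$sex), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Derived-point construction table (points 26-40). The original software
# displays these points but does not publish their constructions; this table
# is this package's own fixed, versioned convention. All constructions are
# translation/rotation equivariant. "axis" is the pad axis, the line through
# point 22 (proximal pad apex) and derived point 31 (anterior pad midpoint).
#
#   midpoint  p = (a + b) / 2
#   centroid  p = mean of listed points
#   intersect p = intersection of line(a, b) with line(c, d)
#   project   p = orthogonal projection of a onto line(b, c)
# ---------------------------------------------------------------------------
.derived_defs <- list(
  `26` = list(op = "midpoint",  args = c(1, 5)),
  `27` = list(op = "midpoint",  args = c(5, 9)),
  `28` = list(op = "midpoint",  args = c(9, 13)),
  `29` = list(op = "midpoint",  args = c(1, 13)),
  `30` = list(op = "centroid",  args = c(1, 5, 9, 13)),
  `31` = list(op = "midpoint",  args = c(17, 18)),
  `32` = list(op = "midpoint",  args = c(19, 25)),
  `33` = list(op = "midpoint",  args = c(20, 24)),
  `34` = list(op = "midpoint",  args = c(21, 23)),
  `35` = list(op = "intersect", args = c(22, 31, 3, 15)),
  `36` = list(op = "project",   args = c(2, 22, 31)),
  `37` = list(op = "project",   args = c(16, 22, 31)),
  `38` = list(op = "midpoint",  args = c(16, 25)),
  `39` = list(op = "midpoint",  args = c(11, 15)),
  `40` = list(op = "midpoint",  args = c(18, 24))
)

#' Reference left-hind puma footprint template
#'
#' A fixed 25-point left-hind footprint configuration (mm, +y toward the
#' toes) used as the population mean by the synthetic generator. Geometry
#' follows the documented left-hind cues: four toes with toe 3 the longest,
#' toes slightly skewed to the inside of the trail, and a trapezoidal heel
#' pad with two anterior lobes. Each toe is a four-point diamond
#' (proximal, inner, distal, outer); points 17-25 outline the pad.
#' The exact coordinates are a package convention, not a biological claim.
#'
#' @return 25 x 2 numeric matrix, rownames `"01".."25"`.
#' @examples
#' tpl <- puma_template()
#' plot(tpl, asp = 1, pch = 19)
#' @export
puma_template <- function() {
  pts <- matrix(c(
    # toe 2 (innermost, points 1-4)
    -30, 17,   -38, 28,   -31, 39,   -22, 28,
    # toe 3 (longest, points 5-8)
    -11, 29,   -19, 40,   -11, 52,    -3, 40,
    # toe 4 (points 9-12)
      8, 27,     0, 38,     8, 49,    16, 38,
    # toe 5 (outermost, points 13-16)
     26, 15,    19, 26,    28, 37,    35, 26,
    # pad: anterior lobes 17-18, sides 19 & 25, proximal boundary 20-24
     -8,  3,     8,  3,   -25, -5,   -20, -40,
    -10, -45,    0, -46,   10, -45,   20, -40,
     25, -5
  ), ncol = 2, byrow = TRUE)
  rownames(pts) <- sprintf("%02d", 1:25)
  colnames(pts) <- c("x", "y")
  pts
}
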