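#' Specification of a synthetic footprint population
#'
#' Describes the hierarchical variance structure the identification pipeline
#' assumes: a fixed species template, an individual landmark signature drawn
#' once per animal, and per-footprint substrate/placement noise, plus a
#' multiplicative size dimorphism and a fixed shape displacement for males.
#' Defaults emulate the captive study population: 35 animals, 19:16
#' female:male, 1-4 trails per animal, 4-8 prints per trail (about 15 prints
#' per animal), individual signatures (2 mm at landmark level) clearly
#' larger than per-print noise (0.5 mm), and an 8% male size advantage.
#'
#' @param n_individuals number of animals (>= 2).
#' @param sex_ratio proportion of females in `[0, 1]`.
#' @param trails_per_individual integer range `c(min, max)` of trails.
#' @param prints_per_trail integer range `c(min, max)` of prints per trail.
#' @param sigma_individual s.d. (mm) of per-animal landmark offsets.
#' @param sigma_noise s.d. (mm) of per-footprint landmark noise.
#' @param male_scale multiplicative male size factor (1 = monomorphic).
#' @param shape_shift magnitude (mm) of the fixed male shape displacement.
#' @param seed integer RNG seed (mandatory: every generated dataset is
#'   reproducible).
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_individuals = 35L, sex_ratio = 19 / 35,
                            trails_per_individual = c(1L, 4L),
                            prints_per_trail = c(4L, 8L),
                            sigma_individual = 2, sigma_noise = 0.5,
                            male_scale = 1.08, shape_shift = 0.5,
                            seed) {
  if (missing(seed)) stop("population_spec requires an explicit seed")
  stopifnot(n_individuals >= 2, sex_ratio >= 0, sex_ratio <= 1,
            sigma_individual >= 0, sigma_noise >= 0, male_scale > 0,
            shape_shift >= 0,
            length(trails_per_individual) == 2,
            length(prints_per_trail) == 2,
            trails_per_individual[1] >= 1, prints_per_trail[1] >= 1,
            trails_per_individual[1] <= trails_per_individual[2],
            prints_per_trail[1] <= prints_per_trail[2])
  structure(list(
    n_individuals = as.integer(n_individuals), sex_ratio = sex_ratio,
    trails_per_individual = as.integer(trails_per_individual),
    prints_per_trail = as.integer(prints_per_trail),
    sigma_individual = sigma_individual, sigma_noise = sigma_noise,
    male_scale = male_scale, shape_shift = shape_shift,
    seed = as.integer(seed)
  ), class = "population_spec")
}

# uniform draw over an inclusive integer range (safe for collapsed ranges)
.sample_range <- function(range, n) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# Fixed male shape-displacement field (25 x 2, unit maximum displacement):
# males get a relatively broader pad and slightly more splayed outer toes.
.male_shape_field <- function() {
  tpl <- puma_template()
  u <- matrix(0, 25, 2)
  pad <- 17:25
  padc <- colMeans(tpl[pad, ])
  dirs <- sweep(tpl[pad, ], 2, padc)
  u[pad, ] <- dirs / max(sqrt(rowSums(dirs^2)))
  u[c(13:16), 1] <- u[c(13:16), 1] + 0.5   # outer toe splay
  u[c(1:4), 1] <- u[c(1:4), 1] - 0.5
  u
}

#' Generate a synthetic footprint population
#'
#' Simulates landmark configurations under the hierarchical model
#' `P = s_sex * (T + D_i) + shape_shift * U * [male] + E_f`, where `T` is
#' the fixed left-hind template ([puma_template()]), `D_i` an i.i.d. Gaussian
#' 25-point offset drawn once per animal (s.d. `sigma_individual`), `s_sex`
#' the male size factor, `U` a fixed shape-displacement field, and `E_f`
#' i.i.d. Gaussian per-footprint noise (s.d. `sigma_noise`). Footprints are
#' grouped into trails and measured with [extract_features()].
#'
#' @param spec a [population_spec()].
#' @param layout optional explicit layout: a data.frame with columns
#'   `animal_id`, `sex`, `n_trails`, `n_prints` (total prints for the
#'   animal, distributed across its trails as evenly as possible). Overrides
#'   the random trail/print counts; used e.g. to reproduce a published
#'   collection structure exactly (see [table2_layout()]).
#' @return list with elements `landmarks` (list of [landmark_set()]s,
#'   carrying true `animal_id`/`sex`), `table` (feature data.frame, one row
#'   per footprint) and `spec`.
#' @examples
#' pop <- generate_population(population_spec(n_individuals = 3, seed = 1))
#' table(pop$table$animal_id)
#' @export
generate_population <- function(spec, layout = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  tpl <- puma_template()
  U <- .male_shape_field()
  catalog <- variable_catalog()

  if (is.null(layout)) {
    n <- spec$n_individuals
    n_f <- round(spec$sex_ratio * n)
    sexes <- c(rep("F", n_f), rep("M", n - n_f))
    layout <- data.frame(
      animal_id = sprintf("A%03d", seq_len(n)),
      sex = sexes,
      n_trails = .sample_range(spec$trails_per_individual, n),
      stringsAsFactors = FALSE
    )
    layout$n_prints <- NA_integer_   # drawn per trail below
  } else {
    stopifnot(all(c("animal_id", "sex", "n_trails", "n_prints") %in%
                    names(layout)))
  }

  landmarks <- vector("list", 0L)
  fp_counter <- 0L
  for (i in seq_len(nrow(layout))) {
    aid <- layout$animal_id[i]
    sex <- layout$sex[i]
    D <- matrix(stats::rnorm(50, sd = spec$sigma_individual), 25, 2)
    s <- if (sex == "M") spec$male_scale else 1
    shift <- if (sex == "M") spec$shape_shift * U else 0
    base <- s * (tpl + D) + shift
    age <- round(stats::runif(1, 1, 20), 1)

    nt <- layout$n_trails[i]
    if (is.na(layout$n_prints[i])) {
      prints <- .sample_range(spec$prints_per_trail, nt)
    } else {
      # distribute the animal's total prints as evenly as possible
      tot <- layout$n_prints[i]
      prints <- rep(tot %/% nt, nt)
      extra <- tot %% nt
      if (extra > 0) prints[seq_len(extra)] <- prints[seq_len(extra)] + 1L
    }
    for (t in seq_len(nt)) {
      tid <- sprintf("%s_T%d", aid, t)
      for (p in seq_len(prints[t])) {
        fp_counter <- fp_counter + 1L
        P <- base + matrix(stats::rnorm(50, sd = spec$sigma_noise), 25, 2)
        ls <- landmark_set(P, rbind(c(0, 0), c(10, 0)),
                           footprint_id = sprintf("FP%05d", fp_counter),
                           trail_id = tid, animal_id = aid, sex = sex,
                           age_years = age, calibrated = TRUE)
        landmarks[[fp_counter]] <- derive_points(ls)
      }
    }
  }
  tab <- extract_features_table(landmarks, catalog)
  rownames(tab) <- NULL
  list(landmarks = landmarks, table = tab, spec = spec)
}

#' Per-animal layout reproducing the captive study's collection structure
#'
#' A deterministic allocation matching the published collection summary
#' exactly: 19 females with 300 footprints in 45 trails (per-animal ranges
#' 6-23 prints, 1-3 trails) and 16 males with 235 footprints in 34 trails
#' (7-25 prints, 1-4 trails), totalling 35 animals, 535 footprints and 79
#' trails, i.e. 15.29 prints/animal and 2.26 trails/animal.
#'
#' @return data.frame suitable as the `layout` argument of
#'   [generate_population()].
#' @export
table2_layout <- function() {
  f_prints <- c(rep(16L, 15), rep(15L, 4))          # 300
  f_trails <- c(rep(3L, 7), rep(2L, 12))            # 45
  m_prints <- c(rep(15L, 11), rep(14L, 5))          # 235
  m_trails <- c(rep(3L, 2), rep(2L, 14))            # 34
  data.frame(
    animal_id = sprintf("A%03d", 1:35),
    sex = c(rep("F", 19), rep("M", 16)),
    n_trails = c(f_trails, m_trails),
    n_prints = c(f_prints, m_prints),
    stringsAsFactors = FALSE
  )
}

#' Split one trail into two disjoint pseudo-trails
#'
#' Used to manufacture known "self" pairs: the two halves of a genuine trail
#' must be classified as the same individual. Footprints are apportioned at
#' random into two halves of (near-)equal size, each with at least two
#' prints.
#'
#' @param table feature data.frame (as produced by [generate_population()]
#'   or [read_footprint_table()]).
#' @param trail_id the trail to split (must have >= 4 footprints).
#' @param seed integer seed for the random split.
#' @return the table with the chosen trail's rows relabelled
#'   `<trail_id>.a` / `<trail_id>.b`.
#' @export
split_trail <- function(table, trail_id, seed) {
  idx <- which(table$trail_id == trail_id)
  n <- length(idx)
  if (n < 4L) {
    stop("trail '", trail_id, "' has ", n,
         " footprints; >= 4 required to split")
  }
  set.seed(as.integer(seed))
  half <- sample(idx, n %/% 2)
  table$trail_id[half] <- paste0(trail_id, ".a")
  table$trail_id[setdiff(idx, half)] <- paste0(trail_id, ".b")
  table
}
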