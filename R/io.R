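.meta_cols <- c("footprint_id", "trail_id", "animal_id", "sex",
                "age_years", "side")

#' Read a footprint measurement table
#'
#' Reads a measurement table (one row per footprint: metadata columns plus
#' the V1..V128 variables) from CSV, or from the deposited XLSX layout via
#' the `s1-xlsx` dialect (requires the readxl package; since the deposited
#' file's exact headers are not published, a user-editable column-mapping
#' file translates its headers to the package schema). Footprints with
#' missing or non-numeric variable values are rejected with a warning and
#' counted in the ingest report, mirroring the field policy of discarding
#' distorted prints.
#'
#' @param path file path.
#' @param dialect `"csv"` (default) or `"s1-xlsx"`.
#' @param mapping optional path to a two-column CSV (`from`, `to`) renaming
#'   source columns to the package schema. A default mapping file ships in
#'   `inst/extdata/s1_column_mapping.csv`.
#' @return validated data.frame with an `ingest` attribute (see
#'   [ingest_report()]).
#' @export
read_footprint_table <- function(path, dialect = c("csv", "s1-xlsx"),
                                 mapping = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("the 's1-xlsx' dialect requires the readxl package")
    }
    raw <- as.data.frame(readxl::read_excel(path),
                         stringsAsFactors = FALSE)
    if (is.null(mapping)) {
      mapping <- system.file("extdata", "s1_column_mapping.csv",
                             package = "pugmark")
    }
  }
  if (!is.null(mapping)) {
    map <- utils::read.csv(mapping, stringsAsFactors = FALSE)
    stopifnot(all(c("from", "to") %in% names(map)))
    hit <- match(names(raw), map$from)
    names(raw)[!is.na(hit)] <- map$to[hit[!is.na(hit)]]
  }
  .validate_table(raw, source = path)
}

.validate_table <- function(raw, source = "<table>") {
  vcols <- grep("^V[0-9]+$", names(raw), value = TRUE)
  required <- c("footprint_id", "trail_id")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0L || length(vcols) == 0L) {
    stop("unmappable columns in ", source, ": missing ",
         paste(c(miss, if (length(vcols) == 0L) "V1..V128"),
               collapse = ", "))
  }
  for (m in setdiff(.meta_cols, names(raw))) {
    raw[[m]] <- if (m == "age_years") NA_real_
                else if (m == "sex") "unknown"
                else if (m == "side") "LH" else NA_character_
  }
  for (v in vcols) raw[[v]] <- suppressWarnings(as.numeric(raw[[v]]))
  bad_trail <- is.na(raw$trail_id) | raw$trail_id == ""
  if (any(bad_trail)) {
    warning(sum(bad_trail), " row(s) with empty trail_id rejected")
  }
  vm <- as.matrix(raw[, vcols, drop = FALSE])
  bad_v <- rowSums(!is.finite(vm)) > 0
  if (any(bad_v & !bad_trail)) {
    miss_by_row <- apply(!is.finite(vm[bad_v & !bad_trail, , drop = FALSE]),
                         1, function(z) paste(vcols[z], collapse = ","))
    warning("rejecting ", sum(bad_v & !bad_trail),
            " footprint(s) with missing variables (",
            paste(utils::head(unique(miss_by_row), 3), collapse = "; "),
            ")")
  }
  keep <- !bad_trail & !bad_v
  out <- raw[keep, c(.meta_cols, vcols), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ingest") <- list(
    source = source, n_read = nrow(raw), n_kept = nrow(out),
    n_rejected = sum(!keep))
  out
}

#' Write a footprint measurement table to CSV
#'
#' Numbers are written with 6 significant digits (lengths mm, angles
#' degrees, areas mm^2).
#'
#' @param table feature data.frame.
#' @param path output path.
#' @export
write_footprint_table <- function(table, path) {
  vcols <- grep("^V[0-9]+$", names(table), value = TRUE)
  out <- table
  for (v in vcols) out[[v]] <- signif(out[[v]], 6)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Ingest report: dataset summary statistics
#'
#' Summarises a measurement table the way the published collection table
#' does: footprint, animal and trail counts (overall and per sex) and the
#' mean footprints/individual and trails/individual.
#'
#' @param table feature data.frame (from [read_footprint_table()] or
#'   [generate_population()]).
#' @return list of class `ingest_report` with elements `n_footprints`,
#'   `n_animals`, `n_trails`, `footprints_per_individual`,
#'   `trails_per_individual`, `per_sex` (data.frame), `n_rejected`.
#' @export
ingest_report <- function(table) {
  ing <- attr(table, "ingest")
  per_sex <- do.call(rbind, lapply(split(table, table$sex), function(g) {
    data.frame(sex = g$sex[1], n_footprints = nrow(g),
               n_animals = length(unique(g$animal_id)),
               n_trails = length(unique(g$trail_id)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_sex) <- NULL
  n_an <- length(unique(table$animal_id))
  structure(list(
    n_footprints = nrow(table),
    n_animals = n_an,
    n_trails = length(unique(table$trail_id)),
    footprints_per_individual = nrow(table) / n_an,
    trails_per_individual = length(unique(table$trail_id)) / n_an,
    per_sex = per_sex,
    n_rejected = if (is.null(ing)) 0L else ing$n_rejected
  ), class = "ingest_report")
}

#' @export
print.ingest_report <- function(x, ...) {
  cat("<ingest_report> ", x$n_footprints, " footprints, ", x$n_animals,
      " animals, ", x$n_trails, " trails (", x$n_rejected,
      " rejected)\n", sep = "")
  cat("  footprints/individual ", format(x$footprints_per_individual,
                                         digits = 4),
      ", trails/individual ", format(x$trails_per_individual, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Read landmark files (TPS or JSON)
#'
#' TPS is the community-standard landmark exchange format: `LM=25`
#' followed by 25 `x y` coordinate rows, then optional `IMAGE=`, `ID=` and
#' `SCALE=` lines, one block per specimen. The `SCALE=` value is the mm
#' size of one coordinate unit; when absent, `default_scale` must be
#' supplied. Scale points are synthesised on that basis (TPS carries a
#' scalar, not two ruler points). The JSON schema is explicit: an array of
#' objects with `footprint_id`, `trail_id`, optional metadata, `landmarks`
#' (object mapping `"01".."25"` to `[x, y]`) and `scale_points` +
#' `scale_mm`.
#'
#' @param path file path.
#' @param format `"tps"` or `"json"` (default: by file extension).
#' @param default_scale mm per coordinate unit when the file has no scale.
#' @return list of calibrated [landmark_set()]s.
#' @export
read_landmarks <- function(path, format = NULL, default_scale = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "tps"
  }
  format <- match.arg(format, c("tps", "json"))
  if (format == "tps") .read_tps(path, default_scale)
  else .read_landmarks_json(path, default_scale)
}

.read_tps <- function(path, default_scale) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  starts <- grep("^LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) stop("no LM= record in TPS file ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    nlm <- as.integer(sub("^LM\\s*=\\s*", "", block[1], ignore.case = TRUE))
    if (is.na(nlm) || nlm != 25L) {
      stop("TPS record ", b, " has LM=", nlm, "; 25 landmarks required")
    }
    coords <- do.call(rbind, lapply(block[2:(1 + nlm)], function(l) {
      as.numeric(strsplit(l, "\\s+")[[1]][1:2])
    }))
    if (any(!is.finite(coords))) {
      stop("non-numeric coordinates in TPS record ", b)
    }
    rest <- block[-(1:(1 + nlm))]
    getfield <- function(key) {
      ln <- grep(paste0("^", key, "\\s*="), rest, ignore.case = TRUE,
                 value = TRUE)
      if (length(ln) == 0L) NULL else sub("^[^=]*=\\s*", "", ln[1])
    }
    scale <- getfield("SCALE")
    scale <- if (is.null(scale)) default_scale else as.numeric(scale)
    if (is.null(scale) || !is.finite(scale) || scale <= 0) {
      stop("TPS record ", b,
           " has no SCALE= and no default_scale was supplied")
    }
    id <- getfield("ID")
    image <- getfield("IMAGE")
    fid <- if (!is.null(id)) id
           else if (!is.null(image)) tools::file_path_sans_ext(image)
           else sprintf("%s#%d", basename(path), b)
    # TPS scale: mm per unit; synthesise two scale points one unit apart
    ls <- landmark_set(coords, rbind(c(0, 0), c(1, 0)),
                       footprint_id = fid, trail_id = fid)
    out[[b]] <- calibrate(ls, known_separation_mm = scale)
  }
  out
}

.read_landmarks_json <- function(path, default_scale) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    lm <- r$landmarks
    nms <- sprintf("%02d", 1:25)
    if (is.null(lm) || !all(nms %in% names(lm))) {
      stop("JSON record ", i, " must name landmarks \"01\"..\"25\"")
    }
    coords <- t(vapply(nms, function(nm) as.numeric(lm[[nm]]), numeric(2)))
    sp <- if (!is.null(r$scale_points)) {
      do.call(rbind, lapply(r$scale_points, as.numeric))
    } else rbind(c(0, 0), c(1, 0))
    scale_mm <- r$scale_mm
    if (is.null(scale_mm)) scale_mm <- default_scale
    if (is.null(scale_mm)) {
      stop("JSON record ", i, " has no scale_mm and no default_scale")
    }
    ls <- landmark_set(coords, sp,
                       footprint_id = r$footprint_id %||% sprintf("fp%d", i),
                       trail_id = r$trail_id %||% "unknown",
                       animal_id = r$animal_id %||% NA_character_,
                       sex = r$sex %||% "unknown",
                       age_years = as.numeric(r$age_years %||% NA_real_))
    calibrate(ls, known_separation_mm = as.numeric(scale_mm))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a dendrogram as Newick
#'
#' @param linkage an `hclust` from [ward_cluster()].
#' @param path output file path.
#' @export
export_newick <- function(linkage, path) {
  stopifnot(inherits(linkage, "hclust"))
  ape::write.tree(ape::as.phylo(linkage), file = path)
  invisible(path)
}

#' Read a run configuration file (JSON or YAML)
#'
#' The configuration carries the [algorithm_config()] fields. Unknown keys
#' are rejected.
#'
#' @param path path to a `.json` (or `.yaml`/`.yml`, when the yaml package
#'   is installed) file.
#' @return an [algorithm_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the yaml package; use JSON instead")
    }
    cfg <- yaml::read_yaml(path)
  } else {
    cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  allowed <- c("n_variables", "contour_probability", "ward_threshold",
               "rcv_mode", "selection_scope", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(algorithm_config, cfg)
}
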