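# Plain-text artifact I/O. Conventions: CSV missing values are empty
# cells (never sentinel numbers); polygons in JSON are lists of [x, y]
# 0-based pixel coordinates; every JSON artifact carries the tool version,
# the seed, and a short configuration fingerprint so runs can be matched
# to their inputs.

artifact_meta <- function(seed = NULL, config = NULL) {
  list(tool = "petalfall",
       version = as.character(utils::packageVersion("petalfall")),
       seed = seed,
       config_hash = fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE,
                                              digits = NA)))
}

#' Write / read a flower cohort CSV
#'
#' The cohort table schema is fixed (see [simulate_cohort()]); absent
#' values are written as empty cells. `read_cohort()` checks the header
#' exactly, reports unknown or missing columns, and reports the rows of
#' any value that fails numeric/logical conversion.
#'
#' @param cohort cohort data.frame.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the typed cohort data.frame with a [validate_records()] report
#'   attached as attribute `"validation"`.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  write.csv(cohort[, COHORT_COLUMNS], path, row.names = FALSE, na = "",
            quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(read.csv(path, colClasses = "character", check.names = FALSE),
                  error = function(e) stop("cannot parse CSV '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  unknown <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(unknown))
    stop("unknown columns in '", path, "': ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("missing columns in '", path, "': ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- c("petal_abscission_dpa", "flowerPP_dpa", "calyx_dpa",
                "fruitPP_dpa", "fruit_size_mm", "seed_size_mm",
                "n_petals_at_flowerPP")
  lgl_cols <- c("pollinated", "retained")
  out <- raw
  for (col in num_cols) {
    x <- raw[[col]]
    x[x == ""] <- NA
    conv <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(conv))
    if (length(bad))
      stop("non-numeric value in column '", col, "' of '", path,
           "' at row(s) ", paste(head(bad, 5), collapse = ", "), call. = FALSE)
    out[[col]] <- conv
  }
  for (col in lgl_cols) {
    x <- toupper(raw[[col]])
    x[x == ""] <- NA
    conv <- x == "TRUE"
    bad <- which(!is.na(x) & !x %in% c("TRUE", "FALSE"))
    if (length(bad))
      stop("non-logical value in column '", col, "' of '", path,
           "' at row(s) ", paste(head(bad, 5), collapse = ", "), call. = FALSE)
    out[[col]] <- conv
  }
  out$n_petals_at_flowerPP <- as.integer(out$n_petals_at_flowerPP)
  attr(out, "validation") <- validate_records(out)
  out
}

#' Write / read a peduncle event CSV
#'
#' @param peduncles per-peduncle event table (see [cohort_peduncles()]).
#' @param path CSV file path.
#' @export
write_peduncles <- function(peduncles, path) {
  write.csv(peduncles, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_peduncles
#' @export
read_peduncles <- function(path) {
  raw <- read.csv(path, colClasses = "character")
  if (!all(c("peduncle_id", "peduncle_abscised") %in% names(raw)))
    stop("'", path, "' lacks peduncle_id / peduncle_abscised columns",
         call. = FALSE)
  raw$peduncle_abscised <- toupper(raw$peduncle_abscised) == "TRUE"
  for (col in intersect(c("n_pedicels", "n_pedicels_shed"), names(raw)))
    raw[[col]] <- as.integer(raw[[col]])
  if ("all_pedicels_shed" %in% names(raw))
    raw$all_pedicels_shed <- toupper(raw$all_pedicels_shed) == "TRUE"
  if ("peduncle_dpa" %in% names(raw)) {
    x <- raw$peduncle_dpa; x[x == ""] <- NA
    raw$peduncle_dpa <- suppressWarnings(as.numeric(x))
  }
  raw
}

#' JSON artifacts: correction matrix, palette, ROIs, chart, funnel
#'
#' Writers stamp every artifact with the package version, the seed (when
#' given) and a configuration hash; readers reverse the mapping
#' losslessly. Matrix entries are stored row-major.
#'
#' @param x object to serialize.
#' @param path JSON file path.
#' @param seed optional integer recorded in the artifact.
#' @name artifacts
NULL

#' @rdname artifacts
#' @export
write_correction_json <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "correction_matrix"))
  obj <- list(meta = artifact_meta(seed, list(n_patches = x$n_patches)),
              matrix_row_major = as.vector(t(x$M)),
              residual_rms = x$residual_rms,
              condition_number = x$condition_number,
              n_patches = x$n_patches)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname artifacts
#' @export
read_correction_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(M = matrix(obj$matrix_row_major, 3, 3, byrow = TRUE),
                 residual_rms = obj$residual_rms,
                 condition_number = obj$condition_number,
                 n_patches = obj$n_patches),
            class = "correction_matrix")
}

#' @rdname artifacts
#' @export
write_palette_json <- function(x, path, seed = NULL) {
  entries <- lapply(seq_len(nrow(x)), function(i)
    list(rgb = c(x$r[i], x$g[i], x$b[i]), count = x$count[i], roi = x$roi[i]))
  obj <- list(meta = artifact_meta(seed, list(n_entries = nrow(x))),
              entries = entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname artifacts
#' @export
read_palette_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- do.call(rbind, lapply(obj$entries, function(e)
    data.frame(r = e$rgb[[1]], g = e$rgb[[2]], b = e$rgb[[3]],
               count = e$count, roi = e$roi)))
  class(out) <- c("petal_palette", "data.frame")
  out
}

#' @rdname artifacts
#' @export
read_rois_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(p) {
    m <- do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
    colnames(m) <- c("x", "y")
    m
  })
}

#' @rdname artifacts
#' @export
write_rois_json <- function(x, path) {
  jsonlite::write_json(lapply(x, function(p) unname(as.matrix(p))), path,
                       digits = NA)
  invisible(path)
}

#' @rdname artifacts
#' @export
read_chart_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- obj$patches$polygon
  targets <- obj$patches$target_rgb
  patches <- lapply(seq_along(polys), function(i) {
    m <- do.call(rbind, lapply(polys[[i]], function(v) as.numeric(unlist(v))))
    colnames(m) <- c("x", "y")
    list(polygon = m, target_rgb = as.numeric(unlist(targets[[i]])))
  })
  chart_spec(patches)
}

#' @rdname artifacts
#' @export
write_chart_json <- function(x, path) {
  stopifnot(inherits(x, "chart_spec"))
  obj <- list(patches = list(
    polygon = lapply(x$patches, function(p) unname(as.matrix(p$polygon))),
    target_rgb = lapply(x$patches, function(p) as.numeric(p$target_rgb))))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname artifacts
#' @export
write_funnel_json <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "funnel_summary"))
  obj <- list(meta = artifact_meta(seed, list(n_total = x$n_total)),
              n_total = x$n_total, n_censored = x$n_censored,
              gates = x$gates, retained = x$retained,
              fate_counts = as.list(x$fate_counts), timing = x$timing)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration file (YAML key-value)
#'
#' @param path YAML file with any subset of [cohort_params()] /
#'   [palette_params()] fields plus `seed`.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
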