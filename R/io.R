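# Readers and writers for the pipeline's tabular and GeoJSON formats.
# CSV dialect: UTF-8, comma-separated, "." decimal mark by default; a
# `decimal_mark` argument normalises files written with a "," decimal
# separator on read. All readers validate the schema and report bad rows by
# line number.

.read_validated <- function(path, required, numeric_cols,
                            decimal_mark = ".") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = decimal_mark),
    progress = FALSE
  )
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(
      "schema error: ", path, " missing column(s) ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in numeric_cols) {
    raw <- df[[col]]
    if (decimal_mark != ".") raw <- gsub(decimal_mark, ".", raw, fixed = TRUE)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      stop(
        sprintf(
          "parse error at line %d: column '%s' value '%s' is not numeric",
          bad[1] + 1L, col, raw[bad[1]]
        ),
        call. = FALSE
      )
    }
    df[[col]] <- val
  }
  tibble::as_tibble(df)
}

#' Read surface points (x, y, z) from CSV
#' @param path CSV file with header `x,y,z` (metres).
#' @param decimal_mark Decimal separator used in the file (default `"."`).
#' @return Tibble `x`, `y`, `z`.
#' @export
read_points <- function(path, decimal_mark = ".") {
  df <- .read_validated(path, c("x", "y", "z"), c("x", "y", "z"), decimal_mark)
  bad <- which(!stats::complete.cases(df[, c("x", "y", "z")]))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: missing coordinate", bad[1] + 1L),
      call. = FALSE
    )
  }
  df
}

#' Read bank segments from CSV
#' @inheritParams read_points
#' @return Tibble with the bank-segment schema (`segment_id`, `x0`, `y0`,
#'   `x1`, `y1`, `K`, `riverbed_z`, `zone`, and any of `bank`, `kp_start`,
#'   `kp_end`, `L` present in the file).
#' @export
read_segments <- function(path, decimal_mark = ".") {
  num <- c("x0", "y0", "x1", "y1", "K", "riverbed_z")
  df <- .read_validated(
    path, c("segment_id", num, "zone"), num, decimal_mark
  )
  for (col in intersect(c("kp_start", "kp_end", "L"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Read interstitial fauna samples from CSV
#' @inheritParams read_points
#' @return Tibble `site_id`, `kp`, `habitat`, `date`, `taxon`, `status`,
#'   `count`.
#' @export
read_samples <- function(path, decimal_mark = ".") {
  df <- .read_validated(
    path,
    c("site_id", "kp", "habitat", "date", "taxon", "status", "count"),
    c("kp", "count"),
    decimal_mark
  )
  bad <- which(!is.na(df$count) & df$count < 0)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: negative count", bad[1] + 1L),
      call. = FALSE
    )
  }
  df
}

#' Read floristic releves from CSV
#' @inheritParams read_points
#' @return Tibble `site_id`, `species`, `bb_code`.
#' @export
read_releves <- function(path, decimal_mark = ".") {
  .read_validated(
    path, c("site_id", "species", "bb_code"), character(), decimal_mark
  )
}

#' Read a long site-environment table from CSV
#' @inheritParams read_points
#' @return Tibble `site_id`, `variable`, `value` (plus `month`/`date` when
#'   present).
#' @export
read_environment <- function(path, decimal_mark = ".") {
  .read_validated(
    path, c("site_id", "variable", "value"), "value", decimal_mark
  )
}

#' Read and validate a run configuration (YAML)
#'
#' @param path YAML file. Recognised keys: `seed`, `alpha`, `s_min`,
#'   `n_min`, `min_sites`, `bb_conversion` (named map), `paths` (named map
#'   of input files), `out_dir`. Unknown keys are rejected.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c(
    "seed", "alpha", "s_min", "n_min", "min_sites",
    "bb_conversion", "paths", "out_dir"
  )
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop(
      "unknown configuration key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  defaults <- list(
    seed = 1L, alpha = 0.05, s_min = 2, n_min = 10, min_sites = 5,
    bb_conversion = as.list(bb_conversion()), paths = list(), out_dir = "."
  )
  utils::modifyList(defaults, cfg)
}

# ---- GeoJSON output (RFC 7946) ----------------------------------------

.feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

.write_fc <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a TIN as a GeoJSON FeatureCollection of triangles
#'
#' One Polygon feature per triangle with `elevation`, `slope` and `aspect`
#' properties.
#'
#' @param surface A [tin_surface()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_tin_geojson <- function(surface, path) {
  stopifnot(inherits(surface, "tin_surface"))
  p <- surface$points
  feats <- lapply(seq_len(nrow(surface$triangles)), function(i) {
    tr <- surface$triangles[i, ]
    ring <- lapply(c(tr$v1, tr$v2, tr$v3, tr$v1), function(v) c(p$x[v], p$y[v]))
    .feature(
      list(type = "Polygon", coordinates = list(ring)),
      list(
        triangle = tr$triangle, elevation = tr$elevation,
        slope = tr$slope,
        aspect = if (tr$defined_aspect) tr$aspect else NULL
      )
    )
  })
  .write_fc(feats, path)
}

#' Write per-segment exchange estimates as GeoJSON LineStrings
#' @param estimates Per-segment tibble from [run_exchange_diagnosis()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_segments_geojson <- function(estimates, path) {
  feats <- lapply(seq_len(nrow(estimates)), function(i) {
    e <- estimates[i, ]
    .feature(
      list(
        type = "LineString",
        coordinates = list(c(e$x0, e$y0), c(e$x1, e$y1))
      ),
      list(
        segment_id = e$segment_id, zone = e$zone, Qe = e$Qe,
        direction = e$direction
      )
    )
  })
  .write_fc(feats, path)
}

#' Write section classifications as GeoJSON LineStrings along the KP axis
#'
#' Sections are one-dimensional KP intervals; they are written as
#' LineStrings in corridor coordinates (x = KP * 1000 m, y = 0) with their
#' category and thresholds as properties.
#'
#' @param sections Tibble from [classify_sections()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_sections_geojson <- function(sections, path) {
  feats <- lapply(seq_len(nrow(sections)), function(i) {
    s <- sections[i, ]
    .feature(
      list(
        type = "LineString",
        coordinates = list(c(s$kp_min * 1000, 0), c(s$kp_max * 1000, 0))
      ),
      list(
        section_id = s$section_id, category = s$category,
        s_min = s$s_min, n_min = s$n_min
      )
    )
  })
  .write_fc(feats, path)
}

#' Write an aligned zone table (with verdicts if present) as GeoJSON
#' @param zone_table Tibble from [build_zone_table()] or [verdict()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_zones_geojson <- function(zone_table, path) {
  feats <- lapply(seq_len(nrow(zone_table)), function(i) {
    z <- zone_table[i, ]
    props <- list(
      zone_id = z$zone_id, bank = z$bank,
      Qf = if (is.na(z$Qf)) NULL else z$Qf,
      Qu = if (is.na(z$Qu)) NULL else z$Qu,
      influence_class = if (is.na(z$influence_class)) NULL else z$influence_class,
      invert_category = if (is.na(z$invert_category)) NULL else z$invert_category
    )
    if ("verdict" %in% names(z)) props$verdict <- z$verdict
    .feature(
      list(
        type = "LineString",
        coordinates = list(c(z$kp_min * 1000, 0), c(z$kp_max * 1000, 0))
      ),
      props
    )
  })
  .write_fc(feats, path)
}

#' Write a run manifest next to pipeline outputs
#'
#' Records the package version, R version, a hash of the effective
#' configuration and the thresholds in force, for reproducibility audits.
#' The timestamp is isolated in its own field (one line in the pretty JSON)
#' so diffs of two otherwise identical runs differ in a single line.
#'
#' @param out_dir Output directory.
#' @param config Named list of the effective configuration.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, config = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    package = "gwex",
    version = as.character(utils::packageVersion("gwex")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_md5 = hash,
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
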