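# Stygobite community indices. Stygobites are obligate groundwater species;
# their richness and abundance in interstitial (hyporheic) samples indicate
# groundwater upwelling, while their absence suggests downwelling or clogged
# sediments.

#' Stygobite richness and abundance metrics
#'
#' Computes, per pooled unit, the stygobite taxon richness `S`, the relative
#' richness `S_rel = 100 * S / (total taxon richness)` and the summed
#' stygobite abundance `N_styg`. A taxon counts as present in a pool when
#' its pooled count is positive; repeated visits to the same unit are
#' summed, not averaged, so integer counts are preserved.
#'
#' @param samples Data frame of interstitial samples with columns `site_id`,
#'   `kp` (kilometric point, km), `habitat`, `date`, `taxon`,
#'   `status` (`"stygobite"` or `"epigean"`) and `count` (non-negative).
#' @param pooling One of `"per_site"`, `"per_sample"` (site x date),
#'   `"per_section"` (requires `sections`).
#' @param sections For `pooling = "per_section"`: data frame with
#'   `section_id`, `kp_min`, `kp_max` (sites assigned by `kp`).
#' @return Tibble with one row per pooled unit: `S`, `S_total`, `S_rel`,
#'   `s_rel_defined` (FALSE when no taxon at all is present in the pool,
#'   where the relative richness is undefined), `N_styg`, plus `kp` (mean of
#'   member sites).
#' @export
stygo_metrics <- function(samples,
                          pooling = c("per_site", "per_sample", "per_section"),
                          sections = NULL) {
  pooling <- match.arg(pooling)
  samples <- tibble::as_tibble(as.data.frame(samples))
  need <- c("site_id", "taxon", "status", "count")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop(
      "schema error: samples missing column(s) ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(unique(samples$status), c("stygobite", "epigean"))
  if (length(bad)) {
    stop(
      "unclassified taxon: unknown status label(s) ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(samples$count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (nrow(samples) == 0) stop("empty sample set", call. = FALSE)

  samples <- switch(pooling,
    per_site = dplyr::mutate(samples, unit = .data$site_id),
    per_sample = dplyr::mutate(
      samples,
      unit = paste(.data$site_id, .data$date, sep = "|")
    ),
    per_section = {
      if (is.null(sections)) {
        stop("per_section pooling needs a sections table", call. = FALSE)
      }
      kp <- samples$kp
      sec <- vapply(kp, function(k) {
        hit <- which(k >= sections$kp_min & k <= sections$kp_max)
        if (length(hit) == 0) NA_character_ else as.character(sections$section_id[hit[1]])
      }, character(1))
      dplyr::mutate(samples, unit = sec) |>
        dplyr::filter(!is.na(.data$unit))
    }
  )

  if (!"kp" %in% names(samples)) samples$kp <- NA_real_

  samples |>
    dplyr::group_by(.data$unit, .data$taxon, .data$status) |>
    dplyr::summarise(
      count = sum(.data$count),
      kp = mean(.data$kp),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(
      kp = mean(.data$kp),
      S = dplyr::n_distinct(.data$taxon[.data$status == "stygobite" & .data$count > 0]),
      S_total = dplyr::n_distinct(.data$taxon[.data$count > 0]),
      N_styg = sum(.data$count[.data$status == "stygobite"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      s_rel_defined = .data$S_total > 0,
      S_rel = ifelse(.data$s_rel_defined, 100 * .data$S / .data$S_total, NA_real_)
    ) |>
    dplyr::select(
      "unit", "kp", "S", "S_total", "S_rel", "s_rel_defined", "N_styg"
    )
}

#' Classify river/canal sections by inferred groundwater exchange
#'
#' Pools per-site stygobite indices into KP sections and assigns each
#' section a category: `"none"` when no member site holds any stygobite
#' (`S = 0` everywhere), `"upwelling"` when at least one site reaches both
#' the richness and abundance cut-offs, `"mixed"` otherwise. The cut-offs
#' used are echoed in the output so verdicts stay auditable.
#'
#' @param indices Per-site tibble from [stygo_metrics()] (needs `kp`, `S`,
#'   `N_styg`).
#' @param partition Data frame of sections: `section_id`, `kp_min`,
#'   `kp_max`, optionally `channel`.
#' @param s_min Minimum stygobite richness at one site for "upwelling"
#'   (taxa; default 2).
#' @param n_min Minimum stygobite abundance at one site for "upwelling"
#'   (individuals; default 10).
#' @return Tibble with one row per section: `category`, `n_sites`,
#'   `S_max`, `N_max`, `s_min`, `n_min`.
#' @export
classify_sections <- function(indices, partition, s_min = 2, n_min = 10) {
  indices <- as.data.frame(indices)
  partition <- as.data.frame(partition)
  rows <- lapply(seq_len(nrow(partition)), function(j) {
    sec <- partition[j, , drop = FALSE]
    inside <- indices$kp >= sec$kp_min & indices$kp <= sec$kp_max
    if (!any(inside)) {
      stop(
        sprintf("no sites in section %s", sec$section_id),
        call. = FALSE
      )
    }
    sub <- indices[inside, , drop = FALSE]
    category <- if (all(sub$S == 0)) {
      "none"
    } else if (any(sub$S >= s_min & sub$N_styg >= n_min)) {
      "upwelling"
    } else {
      "mixed"
    }
    tibble::tibble(
      section_id = sec$section_id,
      kp_min = sec$kp_min,
      kp_max = sec$kp_max,
      channel = if ("channel" %in% names(sec)) sec$channel else NA_character_,
      n_sites = nrow(sub),
      S_max = max(sub$S),
      N_max = max(sub$N_styg),
      category = category,
      s_min = s_min,
      n_min = n_min
    )
  })
  dplyr::bind_rows(rows)
}

#' Reference list of stygobite species for the study corridor
#'
#' The nine obligate-groundwater species recorded in the corridor's
#' interstitial habitats, with the kilometric-point intervals where each was
#' found. Useful to seed the `status` column of sample tables.
#'
#' @return Tibble with `species`, `order_group` and `kp_occurrence`
#'   (semicolon-separated `lo-hi` KP intervals, km).
#' @export
stygobite_species <- function() {
  path <- system.file("extdata", "stygobite_species.csv", package = "gwex")
  readr::read_csv(path, show_col_types = FALSE)
}
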