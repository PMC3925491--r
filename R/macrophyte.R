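# Macrophyte-based bioindication. Species ecological profiles are affinity
# distributions over ordered environmental classes (5 thermal-stability
# classes, 5 phosphorus classes, 4 ammonia classes), estimated from mean
# abundances per class with a Levene-gated ANOVA / Kruskal-Wallis test of
# non-random distribution. Site relevés are then scored by
# abundance-weighted profile sums (trophic level) and by counting species of
# contrasting thermal preference (groundwater influence).

#' Relative standard deviation (coefficient of variation, percent)
#'
#' `100 * sd(x) / mean(x)` with the sample standard deviation. Used on the
#' monthly temperature series of a wetland: groundwater-fed wetlands are
#' thermally stable (low value), wetlands cut off from the aquifer track air
#' temperature (high value).
#'
#' @param x Numeric series, length `>= 2`.
#' @return Percent value; scale-invariant (`relative_sd(c * x)` is unchanged
#'   for `c > 0`).
#' @export
relative_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need >= 2 values", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("undefined coefficient of variation: mean is 0", call. = FALSE)
  100 * stats::sd(x) / m
}

#' Equilibrated (balanced-quantile) classes
#'
#' Bins site values into `k` ordered classes with as equal site counts as
#' possible (counts differ by at most 1 when values are distinct). Tied
#' values always share a class: a tie spanning a provisional boundary falls
#' entirely in the lower class.
#'
#' @param values Numeric vector, one per site; `length(values) >= k`.
#' @param k Number of classes (`>= 2`); 5 for temperature stability and
#'   phosphorus, 4 for ammonia.
#' @return Integer vector of class labels `1..k` ordered by increasing
#'   value.
#' @export
equilibrated_classes <- function(values, k) {
  if (k < 2) stop("invalid class count: k must be >= 2", call. = FALSE)
  n <- length(values)
  if (n < k) stop("fewer sites than classes", call. = FALSE)
  if (anyNA(values)) stop("missing values in class variable", call. = FALSE)
  ord <- order(values)
  # balanced target sizes, remainder spread from the lowest class up
  base <- n %/% k
  sizes <- rep(base, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  prov <- rep(seq_len(k), times = sizes) # provisional label by rank
  lab_sorted <- prov
  # ties: every copy of a value takes the lowest provisional label among them
  v_sorted <- values[ord]
  lab_sorted <- stats::ave(prov, match(v_sorted, unique(v_sorted)), FUN = min)
  labels <- integer(n)
  labels[ord] <- lab_sorted
  labels
}

#' Species response to an ordered class gradient
#'
#' For every species occurring in at least `min_sites` sites, tests whether
#' its abundance is non-randomly distributed across the classes and builds
#' its affinity profile. Variance homogeneity across classes is tested with
#' a mean-centred Levene test at `alpha`: homogeneous variances gate to a
#' one-way ANOVA, heterogeneous ones to a Kruskal-Wallis test. The profile
#' weight of class `c` is the species' mean abundance over the sites of
#' class `c`, normalised so the weights sum to 1. Sites where the species is
#' absent count as abundance 0.
#'
#' @param abundance Long data frame: `site_id`, `species`, `abundance`
#'   (numeric cover/abundance, e.g. converted Braun-Blanquet codes).
#' @param classes Data frame: `site_id`, `class` (integer labels from
#'   [equilibrated_classes()]).
#' @param alpha Significance level for the Levene gate and the gated test
#'   (default 0.05).
#' @param min_sites Occurrence floor: species present in fewer sites are
#'   excluded (default 5).
#' @return Object of class `ecological_profiles`: long tibble with one row
#'   per retained species x class: `species`, `class`, `mean_abundance`,
#'   `weight`, and per-species columns `n_occupied`, `levene_p`, `test`
#'   (`"anova"` or `"kruskal"`), `p_value`, `significant`. Excluded species
#'   and their reasons are attached as attribute `"excluded"`.
#' @export
species_class_response <- function(abundance, classes, alpha = 0.05,
                                   min_sites = 5) {
  abundance <- tibble::as_tibble(as.data.frame(abundance))
  classes <- tibble::as_tibble(as.data.frame(classes))
  stopifnot(all(c("site_id", "species", "abundance") %in% names(abundance)))
  stopifnot(all(c("site_id", "class") %in% names(classes)))
  k_levels <- sort(unique(classes$class))

  # complete site x species grid: absence = 0 abundance
  grid <- tidyr::expand_grid(
    site_id = classes$site_id,
    species = unique(abundance$species)
  ) |>
    dplyr::left_join(abundance, by = c("site_id", "species")) |>
    dplyr::mutate(abundance = tidyr::replace_na(.data$abundance, 0)) |>
    dplyr::left_join(classes, by = "site_id")

  res <- list()
  excluded <- list()
  for (sp in unique(grid$species)) {
    g <- grid[grid$species == sp, , drop = FALSE]
    n_occ <- sum(g$abundance > 0)
    if (n_occ < min_sites) {
      excluded[[sp]] <- sprintf(
        "occurs in %d sites (< %d)", n_occ, min_sites
      )
      next
    }
    tst <- .gated_class_test(g$abundance, g$class, alpha)
    means <- vapply(
      k_levels,
      function(cl) mean(g$abundance[g$class == cl]),
      numeric(1)
    )
    tot <- sum(means)
    w <- if (tot > 0) means / tot else rep(1 / length(k_levels), length(k_levels))
    res[[sp]] <- tibble::tibble(
      species = sp,
      class = k_levels,
      mean_abundance = means,
      weight = w,
      n_occupied = n_occ,
      levene_p = tst$levene_p,
      test = tst$test,
      p_value = tst$p,
      significant = tst$p < alpha
    )
  }
  out <- dplyr::bind_rows(res)
  attr(out, "excluded") <- tibble::tibble(
    species = names(excluded),
    reason = unlist(excluded, use.names = FALSE)
  )
  attr(out, "alpha") <- alpha
  class(out) <- c("ecological_profiles", class(out))
  out
}

# Levene (mean-centred) gate, then one-way ANOVA or Kruskal-Wallis.
# Degenerate inputs (zero overall variance, or classes that cannot be
# tested) come back as p = 1, never significant.
.gated_class_test <- function(ab, cl, alpha) {
  f <- factor(cl)
  tab <- table(f[!is.na(ab)])
  if (stats::var(ab) == 0 || sum(tab >= 2) < 2) {
    return(list(levene_p = 1, test = "none", p = 1))
  }
  lev <- tryCatch(
    car::leveneTest(ab ~ f, center = mean)[["Pr(>F)"]][1],
    error = function(e) NA_real_
  )
  if (is.na(lev)) lev <- 1
  if (lev >= alpha) {
    p <- stats::anova(stats::lm(ab ~ f))[["Pr(>F)"]][1]
    test <- "anova"
  } else {
    p <- stats::kruskal.test(ab ~ f)$p.value
    test <- "kruskal"
  }
  if (is.na(p)) p <- 1
  list(levene_p = lev, test = test, p = p)
}

#' @export
print.ecological_profiles <- function(x, ...) {
  sp <- unique(x$species)
  sig <- unique(x$species[x$significant])
  cat(sprintf(
    "<ecological_profiles: %d species, %d with significant class response>\n",
    length(sp), length(sig)
  ))
  NextMethod()
}

#' @rdname species_class_response
#' @param x,object An `ecological_profiles` object.
#' @param ... Unused.
#' @export
glance.ecological_profiles <- function(x, ...) {
  per <- dplyr::distinct(
    tibble::as_tibble(x),
    .data$species, .data$test, .data$significant
  )
  tibble::tibble(
    n_species = nrow(per),
    n_significant = sum(per$significant),
    n_anova = sum(per$test == "anova"),
    n_kruskal = sum(per$test == "kruskal"),
    n_excluded = nrow(attr(x, "excluded")),
    alpha = attr(x, "alpha")
  )
}

#' Combined phosphorus score per site
#'
#' Monthly soluble phosphate concentrations are log10-transformed and
#' averaged per site; substrate total-phosphorus replicates are averaged
#' per site, log10-transformed and standardised (z-score across sites);
#' the two components are summed. Zero concentrations are shifted by half
#' the smallest positive value of the variable before the log.
#'
#' @param po4 Long data frame: `site_id`, `value` (monthly PO4, mg/L).
#' @param totalp Long data frame: `site_id`, `value` (substrate total P
#'   replicates).
#' @return Tibble `site_id`, `po4_component`, `totalp_component`, `p_score`.
#' @export
phosphorus_score <- function(po4, totalp) {
  po4 <- as.data.frame(po4)
  totalp <- as.data.frame(totalp)
  if (all(po4$value == 0) || all(totalp$value == 0)) {
    stop("no phosphorus signal: all concentrations are zero", call. = FALSE)
  }
  shift <- function(v) {
    if (any(v == 0)) {
      v[v == 0] <- min(v[v > 0]) / 2
    }
    v
  }
  po4$value <- shift(po4$value)
  a <- po4 |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(po4_component = mean(log10(.data$value)), .groups = "drop")
  b <- totalp |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(mean_tp = mean(.data$value), .groups = "drop")
  b$mean_tp <- shift(b$mean_tp)
  ltp <- log10(b$mean_tp)
  s <- stats::sd(ltp)
  b$totalp_component <- if (is.na(s) || s == 0) 0 else (ltp - mean(ltp)) / s
  dplyr::inner_join(a, b[, c("site_id", "totalp_component")], by = "site_id") |>
    dplyr::mutate(p_score = .data$po4_component + .data$totalp_component)
}

#' Map an ordered k-class profile onto m classes by quantile overlap
#'
#' Class `j` of `k` is identified with the quantile interval
#' `[(j-1)/k, j/k]`; entry `(c, j)` of the matrix is the fraction of that
#' interval overlapping target interval `[(c-1)/m, c/m]`. Columns sum to 1,
#' so mapped profiles keep their total weight.
#'
#' @param from,to Source and target class counts.
#' @return `to` x `from` matrix.
#' @export
class_mapping_matrix <- function(from, to) {
  m <- matrix(0, nrow = to, ncol = from)
  for (j in seq_len(from)) {
    lo_j <- (j - 1) / from
    hi_j <- j / from
    for (c in seq_len(to)) {
      ov <- max(0, min(hi_j, c / to) - max(lo_j, (c - 1) / to))
      m[c, j] <- ov * from
    }
  }
  m
}

#' Combine phosphorus and ammonia affinity profiles into a trophic profile
#'
#' Maps the 5-class phosphorus profile onto the 4 trophic classes
#' (oligotrophic, mesotrophic, eutrophic, hyper-eutrophic) by ordered
#' quantile correspondence ([class_mapping_matrix()]), averages it with the
#' 4-class ammonia profile and renormalises. When only one profile is
#' available it passes through (mapped if needed) and the output is flagged.
#'
#' @param p_profile Numeric phosphorus affinity weights (length 5, sum 1),
#'   or `NULL`.
#' @param n_profile Numeric ammonia affinity weights (length 4, sum 1), or
#'   `NULL`.
#' @param mapping Mapping matrix, default `class_mapping_matrix(5, 4)`.
#' @return Numeric length-4 trophic weights summing to 1, with attribute
#'   `"combined"` (TRUE when both sources were present).
#' @export
combine_trophic_profile <- function(p_profile = NULL, n_profile = NULL,
                                    mapping = class_mapping_matrix(5, 4)) {
  if (is.null(p_profile) && is.null(n_profile)) {
    stop("at least one source profile required", call. = FALSE)
  }
  p4 <- if (!is.null(p_profile)) as.vector(mapping %*% p_profile) else NULL
  if (is.null(p4)) {
    out <- n_profile
  } else if (is.null(n_profile)) {
    out <- p4
  } else {
    out <- (p4 + n_profile) / 2
  }
  out <- out / sum(out)
  attr(out, "combined") <- !is.null(p_profile) && !is.null(n_profile)
  out
}

#' Default Braun-Blanquet cover-abundance conversion
#'
#' Numeric values for the ordinal cover codes: `r` = 0.1, `+` = 0.5 and
#' `1`..`5` mapped to their face value (`0` = absent). Overridable wherever
#' a conversion is taken as an argument.
#'
#' @return Named numeric vector.
#' @export
bb_conversion <- function() {
  c("0" = 0, "r" = 0.1, "+" = 0.5, "1" = 1, "2" = 2, "3" = 3, "4" = 4, "5" = 5)
}

#' Numeric abundance from Braun-Blanquet codes
#' @param code Character vector of codes.
#' @param conversion Named conversion vector, default [bb_conversion()].
#' @return Numeric abundances; unknown codes are an error.
#' @export
bb_numeric <- function(code, conversion = bb_conversion()) {
  code <- as.character(code)
  unknown <- setdiff(unique(code), names(conversion))
  if (length(unknown)) {
    stop(
      "unknown Braun-Blanquet code(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  unname(conversion[code])
}

#' Trophic level of wetland relevés
#'
#' Scores each site by multiplying every species' (numeric) abundance by its
#' trophic affinity weights and summing over species; the assigned trophic
#' class is the one with the highest total score. Ties resolve toward the
#' more eutrophic (higher) class and are flagged. Species without a profile
#' are skipped (and reported); a site with no profiled species is
#' unscorable.
#'
#' @param releve Data frame: `site_id`, `species`, `bb_code`.
#' @param profiles Data frame: `species`, `class` (1..4, 1 = oligotrophic),
#'   `weight` — e.g. combined trophic profiles.
#' @param conversion Braun-Blanquet conversion, default [bb_conversion()].
#' @return Object of class `trophic_assessment`: tibble with one row per
#'   site x class (`score`) plus per-site `assigned_class`, `tie` and
#'   `scorable`. Attribute `"unprofiled"` lists skipped species.
#' @export
site_trophic_level <- function(releve, profiles, conversion = bb_conversion()) {
  releve <- tibble::as_tibble(as.data.frame(releve))
  profiles <- tibble::as_tibble(as.data.frame(profiles))
  stopifnot(all(c("site_id", "species", "bb_code") %in% names(releve)))
  stopifnot(all(c("species", "class", "weight") %in% names(profiles)))
  releve$abundance <- bb_numeric(releve$bb_code, conversion)
  unprofiled <- setdiff(unique(releve$species), unique(profiles$species))
  scored <- releve |>
    dplyr::inner_join(profiles, by = "species", relationship = "many-to-many") |>
    dplyr::group_by(.data$site_id, .data$class) |>
    dplyr::summarise(
      score = sum(.data$abundance * .data$weight),
      .groups = "drop"
    )
  if (nrow(scored) == 0) {
    stop("unscorable releve: no species with a trophic profile", call. = FALSE)
  }
  assign_one <- function(d) {
    best <- max(d$score)
    winners <- d$class[d$score == best]
    tibble::tibble(
      assigned_class = max(winners), # tie -> more eutrophic
      tie = length(winners) > 1
    )
  }
  assigned <- scored |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(~ assign_one(.x)) |>
    dplyr::ungroup()
  out <- dplyr::left_join(scored, assigned, by = "site_id") |>
    dplyr::mutate(scorable = TRUE)
  unscorable <- setdiff(unique(releve$site_id), unique(out$site_id))
  attr(out, "unprofiled") <- unprofiled
  attr(out, "unscorable_sites") <- unscorable
  class(out) <- c("trophic_assessment", class(out))
  out
}

#' @rdname site_trophic_level
#' @param x A `trophic_assessment`.
#' @param ... Unused.
#' @export
glance.trophic_assessment <- function(x, ...) {
  per <- dplyr::distinct(
    tibble::as_tibble(x), .data$site_id, .data$assigned_class, .data$tie
  )
  tibble::tibble(
    n_sites = nrow(per),
    n_tied = sum(per$tie),
    n_unprofiled_species = length(attr(x, "unprofiled")),
    n_unscorable_sites = length(attr(x, "unscorable_sites"))
  )
}

#' Thermal preference category from temperature-stability profiles
#'
#' Species whose significant affinity profile over the five
#' temperature-stability classes (class 1 = most stable = groundwater-fed)
#' is centred low are tagged `groundwater_preferring`; centred high
#' (thermally variable sites only) are `stenothermy_intolerant`; all others
#' `indifferent`. The centre is the weight-averaged class.
#'
#' @param profiles `ecological_profiles` over the 5 stability classes.
#' @param low_max Centre at or below this value -> groundwater_preferring
#'   (default 2.25).
#' @param high_min Centre at or above this value -> stenothermy_intolerant
#'   (default 3.75).
#' @return Tibble `species`, `centre`, `thermal_category`.
#' @export
thermal_categories <- function(profiles, low_max = 2.25, high_min = 3.75) {
  tibble::as_tibble(profiles) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      centre = sum(.data$class * .data$weight),
      significant = .data$significant[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      thermal_category = dplyr::case_when(
        .data$significant & .data$centre <= low_max ~ "groundwater_preferring",
        .data$significant & .data$centre >= high_min ~ "stenothermy_intolerant",
        TRUE ~ "indifferent"
      )
    )
}

#' Groundwater-influence index of wetland relevés
#'
#' Counts, per site, the species preferentially occurring in
#' groundwater-fed ecosystems and those intolerant of stenothermic (thermally
#' stable) waters; the index is the first count minus the second, floored at
#' zero. Classes: 0 = null, 1-4 = low, 5-9 = intermediate, above 9 = high.
#' (The index is oriented so that a larger value means more groundwater
#' influence; the floor and the 1-4 "low" band close gaps the verbal class
#' definition leaves open, and are echoed in the output.)
#'
#' @param releve Data frame: `site_id`, `species`, `bb_code` (any non-absent
#'   code counts as presence).
#' @param thermal Data frame: `species`, `thermal_category`.
#' @param conversion Braun-Blanquet conversion, default [bb_conversion()].
#' @return Tibble per site: `n_groundwater`, `n_intolerant`, `index`,
#'   `influence_class` (factor null < low < intermediate < high),
#'   `floored` (TRUE when the raw difference was negative).
#' @export
groundwater_influence <- function(releve, thermal,
                                  conversion = bb_conversion()) {
  releve <- tibble::as_tibble(as.data.frame(releve))
  thermal <- tibble::as_tibble(as.data.frame(thermal))
  releve$present <- bb_numeric(releve$bb_code, conversion) > 0
  df <- releve |>
    dplyr::filter(.data$present) |>
    dplyr::left_join(
      thermal[, c("species", "thermal_category")],
      by = "species"
    ) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_groundwater = dplyr::n_distinct(
        .data$species[.data$thermal_category %in% "groundwater_preferring"]
      ),
      n_intolerant = dplyr::n_distinct(
        .data$species[.data$thermal_category %in% "stenothermy_intolerant"]
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      raw = .data$n_groundwater - .data$n_intolerant,
      floored = .data$raw < 0,
      index = pmax(.data$raw, 0L),
      influence_class = influence_class(.data$index)
    ) |>
    dplyr::select(-"raw")
  df
}

#' Groundwater-influence class from an index value
#' @param index Non-negative integer index.
#' @return Ordered factor null < low < intermediate < high
#'   (0; 1-4; 5-9; >9).
#' @export
influence_class <- function(index) {
  cls <- dplyr::case_when(
    index == 0 ~ "null",
    index <= 4 ~ "low",
    index <= 9 ~ "intermediate",
    TRUE ~ "high"
  )
  factor(cls, levels = c("null", "low", "intermediate", "high"), ordered = TRUE)
}

#' @rdname site_trophic_level
#' @param object A `trophic_assessment`.
#' @export
autoplot.trophic_assessment <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$class), y = .data$score, fill = .data$class == .data$assigned_class
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$site_id)) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#1b7837", `FALSE` = "grey70"), guide = "none"
    ) +
    ggplot2::labs(
      x = "trophic class (1 = oligotrophic, 4 = hyper-eutrophic)",
      y = "affinity score"
    ) +
    ggplot2::theme_minimal()
}

#' Combine phosphorus and ammonia profiles for a set of species
#'
#' Applies [combine_trophic_profile()] species by species. Species present
#' in only one source pass through (flagged `combined = FALSE`).
#'
#' @param p_profiles Long tibble `species`, `class` (1..5), `weight`.
#' @param n_profiles Long tibble `species`, `class` (1..4), `weight`.
#' @param mapping Mapping matrix, default `class_mapping_matrix(5, 4)`.
#' @return Long tibble `species`, `class` (1..4), `weight`, `combined`.
#' @export
combine_trophic_profiles <- function(p_profiles, n_profiles,
                                     mapping = class_mapping_matrix(5, 4)) {
  p_profiles <- tibble::as_tibble(as.data.frame(p_profiles))
  n_profiles <- tibble::as_tibble(as.data.frame(n_profiles))
  species <- union(unique(p_profiles$species), unique(n_profiles$species))
  rows <- lapply(species, function(sp) {
    p <- p_profiles[p_profiles$species == sp, ]
    n <- n_profiles[n_profiles$species == sp, ]
    pv <- if (nrow(p)) p$weight[order(p$class)] else NULL
    nv <- if (nrow(n)) n$weight[order(n$class)] else NULL
    w <- combine_trophic_profile(pv, nv, mapping)
    tibble::tibble(
      species = sp, class = seq_along(w), weight = as.numeric(w),
      combined = attr(w, "combined")
    )
  })
  dplyr::bind_rows(rows)
}

#' Full macrophyte assessment of a wetland set
#'
#' Runs the whole vegetation chain on an environment table and a relevé
#' table: temperature-stability, phosphorus and ammonia site classes
#' ([relative_sd()], [phosphorus_score()], [equilibrated_classes()]);
#' species affinity profiles on each gradient ([species_class_response()]);
#' thermal preference categories; combined trophic profiles; site trophic
#' levels and groundwater-influence indices.
#'
#' @param environment Long data frame `site_id`, `variable`, `value` with
#'   variables `temperature`, `po4`, `nh3` (monthly series) and `totalp`
#'   (replicates).
#' @param releves Data frame `site_id`, `species`, `bb_code`.
#' @param alpha Significance level for the Levene gate and gated tests.
#' @param min_sites Occurrence floor for profiling (default 5).
#' @param conversion Braun-Blanquet conversion, default [bb_conversion()].
#' @return List with `site_classes` (per-site class labels and underlying
#'   values), `profiles` (list `thermal`, `phosphorus`, `ammonia`),
#'   `thermal_categories`, `trophic_profiles` (combined 4-class),
#'   `trophic` (a `trophic_assessment`), and `influence`
#'   (per-site groundwater-influence tibble).
#' @export
macrophyte_assessment <- function(environment, releves, alpha = 0.05,
                                  min_sites = 5,
                                  conversion = bb_conversion()) {
  env <- tibble::as_tibble(as.data.frame(environment))
  stopifnot(all(c("site_id", "variable", "value") %in% names(env)))
  releves <- tibble::as_tibble(as.data.frame(releves))

  pull_var <- function(v) env[env$variable == v, c("site_id", "value")]
  temp <- pull_var("temperature")
  po4 <- pull_var("po4")
  nh3 <- pull_var("nh3")
  totalp <- pull_var("totalp")
  sites <- sort(unique(env$site_id))

  cv <- vapply(sites, function(s) {
    relative_sd(temp$value[temp$site_id == s])
  }, numeric(1))
  ps <- phosphorus_score(po4, totalp)
  p_score <- ps$p_score[match(sites, ps$site_id)]
  nh3_level <- vapply(sites, function(s) {
    mean(log10(pmax(nh3$value[nh3$site_id == s], 1e-12)))
  }, numeric(1))

  site_classes <- tibble::tibble(
    site_id = sites,
    cv = cv,
    thermal_class = equilibrated_classes(cv, 5),
    p_score = p_score,
    p_class = equilibrated_classes(p_score, 5),
    nh3_level = nh3_level,
    n_class = equilibrated_classes(nh3_level, 4)
  )

  ab <- releves |>
    dplyr::mutate(abundance = bb_numeric(.data$bb_code, conversion)) |>
    dplyr::select("site_id", "species", "abundance")
  classes_of <- function(col) {
    tibble::tibble(site_id = sites, class = site_classes[[col]])
  }
  prof_thermal <- species_class_response(
    ab, classes_of("thermal_class"), alpha, min_sites
  )
  prof_p <- species_class_response(ab, classes_of("p_class"), alpha, min_sites)
  prof_n <- species_class_response(ab, classes_of("n_class"), alpha, min_sites)

  thermal <- thermal_categories(prof_thermal)
  trophic_profiles <- combine_trophic_profiles(
    dplyr::filter(tibble::as_tibble(prof_p), TRUE),
    dplyr::filter(tibble::as_tibble(prof_n), TRUE)
  )
  trophic <- site_trophic_level(releves, trophic_profiles, conversion)
  influence <- groundwater_influence(releves, thermal, conversion)

  list(
    site_classes = site_classes,
    profiles = list(
      thermal = prof_thermal, phosphorus = prof_p, ammonia = prof_n
    ),
    thermal_categories = thermal,
    trophic_profiles = trophic_profiles,
    trophic = trophic,
    influence = influence
  )
}
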