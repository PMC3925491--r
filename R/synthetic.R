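# Seed-reproducible synthetic scenes with closed-form expectations.
# These are analytic scene builders, not flow models: the piezometric and
# river-stage surfaces are piecewise-planar by construction, so the exchange
# flux of every bank segment has an exact closed form against which the TIN
# pipeline can be validated.

#' Configuration for a synthetic glaciated-valley scene
#'
#' A straight river along `y = 0` flowing in `+x`, with the aquifer
#' extending on both sides. The piezometric surface is a regional plane
#' (downstream slope `piezo_slope`, transverse gradient `g` per reach) that
#' matches the river stage at the bank; `g > 0` makes heads rise away from
#' the river (gaining reach), `g < 0` the opposite (losing reach). Adjacent
#' reaches are joined by a narrow linear transition band. The riverbed lies
#' a constant `A0` below the bank head, so the saturated cross-section is
#' `A0` everywhere by construction. Defaults mirror an alluvial reach of a
#' large regulated river: permeabilities of 1e-4 to a few 1e-3 m/s,
#' gradients of about 1e-3 and a saturated thickness of about 4 m.
#'
#' @param x_max Domain length along the river (m).
#' @param y_min,y_max Transverse domain extent (m); the river is at `y = 0`.
#' @param stage0 River stage at `x = 0` (m above datum).
#' @param stage_slope Downstream water-surface slope of the river
#'   (dimensionless; default 5e-4).
#' @param piezo_slope Downstream component of the piezometric gradient
#'   (default: equal to `stage_slope`).
#' @param reaches Tibble with one row per reach: `zone`, `x_min`, `x_max`,
#'   `K` (m/s), `g` (transverse head gradient, positive = gaining).
#' @param A0 Saturated exchange cross-section thickness (m; default 4.2).
#' @param transition_halfwidth Half-width of the band blending adjacent
#'   reaches (m); segments inside it are tagged zone `"transition"` and
#'   carry no closed-form expectation.
#' @param segment_length Bank segment length (m; default 100).
#' @param n_points Number of random interior piezometric points, in addition
#'   to the structured rows along the bank, the reach boundaries and the
#'   domain border.
#' @param noise_sd Gaussian head noise (m) added to the piezometric points
#'   (default 0 so oracle comparisons stay tight).
#' @param kp0 Kilometric point at `x = 0`; KP decreases downstream.
#' @param seed Integer seed fixing all randomness.
#' @return A `valley_config` list.
#' @export
valley_config <- function(x_max = 4000, y_min = -150, y_max = 1000,
                          stage0 = 210, stage_slope = 5e-4,
                          piezo_slope = stage_slope,
                          reaches = tibble::tibble(
                            zone = c("gaining", "losing"),
                            x_min = c(0, x_max / 2),
                            x_max = c(x_max / 2, x_max),
                            K = c(1.3e-3, 3.9e-4),
                            g = c(2e-3, -2e-3)
                          ),
                          A0 = 4.2, transition_halfwidth = 60,
                          segment_length = 100, n_points = 600,
                          noise_sd = 0, kp0 = 116, seed = 1) {
  stopifnot(all(reaches$K > 0), A0 >= 0, n_points >= 0)
  if (any(reaches$x_min >= reaches$x_max) ||
    any(reaches$x_min < 0) || any(reaches$x_max > x_max)) {
    stop("invalid geometry: reaches must partition [0, x_max]", call. = FALSE)
  }
  structure(
    list(
      x_max = x_max, y_min = y_min, y_max = y_max,
      stage0 = stage0, stage_slope = stage_slope, piezo_slope = piezo_slope,
      reaches = tibble::as_tibble(reaches),
      A0 = A0, transition_halfwidth = transition_halfwidth,
      segment_length = segment_length, n_points = n_points,
      noise_sd = noise_sd, kp0 = kp0, seed = seed
    ),
    class = "valley_config"
  )
}

# transverse head gradient at x: reach value, blended linearly across the
# transition band at each interior reach boundary
.valley_g <- function(config, x) {
  r <- config$reaches
  w <- config$transition_halfwidth
  g_of <- function(xi) {
    xi <- min(max(xi, r$x_min[1]), r$x_max[nrow(r)])
    k <- which(r$x_min <= xi & xi <= r$x_max)[1]
    g <- r$g[k]
    if (k > 1 && xi < r$x_min[k] + w) {
      t <- (xi - (r$x_min[k] - w)) / (2 * w)
      g <- r$g[k - 1] + t * (r$g[k] - r$g[k - 1])
    } else if (k < nrow(r) && xi > r$x_max[k] - w) {
      t <- (xi - (r$x_max[k] - w)) / (2 * w)
      g <- r$g[k] + t * (r$g[k + 1] - r$g[k])
    }
    g
  }
  vapply(x, g_of, numeric(1))
}

.valley_piezo_z <- function(config, x, y) {
  config$stage0 - config$piezo_slope * x + .valley_g(config, x) * y
}

.valley_stage_z <- function(config, x) {
  config$stage0 - config$stage_slope * x
}

#' Generate a synthetic valley scene with closed-form zone fluxes
#'
#' Builds the piezometric and river-stage point clouds, the bank segment
#' table and the analytic per-zone exchange fluxes of a [valley_config()].
#' The point cloud combines structured rows (symmetric rows straddling the
#' bank line, columns along the reach-transition edges, a border frame) with
#' `n_points` random interior points, the layout of a piezometric survey
#' densified along the river. Pure function of the config (all randomness
#' seeded).
#'
#' @param config A [valley_config()].
#' @return List with `piezo_points`, `river_points` (tibbles `x, y, z`),
#'   `segments` (bank segment table ready for [run_exchange_diagnosis()]),
#'   `expected` (closed-form per-zone tibble: `i`, `D`, `Qe`, `L`, `Qf`;
#'   transition-band segments excluded) and `config`.
#' @export
generate_valley <- function(config = valley_config()) {
  stopifnot(inherits(config, "valley_config"))
  set.seed(config$seed)
  w <- config$transition_halfwidth
  dy <- 60

  # structured rows: bank-straddling rows, reach-boundary columns, border
  xs <- seq(0, config$x_max, by = 50)
  bank_rows <- tidyr::expand_grid(x = xs, y = c(-dy, 0, dy))
  inner_bounds <- setdiff(
    unique(c(config$reaches$x_min, config$reaches$x_max)),
    c(0, config$x_max)
  )
  crease <- if (length(inner_bounds)) {
    tidyr::expand_grid(
      x = as.vector(vapply(inner_bounds, function(b) c(b - w, b + w), numeric(2))),
      y = seq(config$y_min, config$y_max, by = 50)
    )
  } else {
    tibble::tibble(x = numeric(), y = numeric())
  }
  border <- dplyr::bind_rows(
    tidyr::expand_grid(x = seq(0, config$x_max, by = 200), y = c(config$y_min, config$y_max)),
    tidyr::expand_grid(x = c(0, config$x_max), y = seq(config$y_min, config$y_max, by = 100))
  )
  n_sc <- config$n_points
  scatter <- tibble::tibble(
    x = stats::runif(n_sc, 0, config$x_max),
    y = stats::runif(n_sc, config$y_min, config$y_max)
  ) |>
    dplyr::filter(abs(.data$y) >= dy) # keep the bank band symmetric

# micro-jitter (1e-5 m) breaks exact lattice degeneracies for the
  # triangulation; z is evaluated on the jittered coordinates so the
  # surfaces stay exactly piecewise planar
  piezo <- dplyr::bind_rows(bank_rows, crease, border, scatter) |>
    dplyr::distinct(.data$x, .data$y) |>
    dplyr::mutate(
      x = .data$x + stats::runif(dplyr::n(), -1e-5, 1e-5),
      y = .data$y + stats::runif(dplyr::n(), -1e-5, 1e-5),
      z = .valley_piezo_z(config, .data$x, .data$y) +
        stats::rnorm(dplyr::n(), 0, config$noise_sd)
    )

  river <- tidyr::expand_grid(
    x = seq(0, config$x_max, by = 100),
    y = seq(-100, 100, by = 50)
  ) |>
    dplyr::mutate(
      x = .data$x + stats::runif(dplyr::n(), -1e-5, 1e-5),
      y = .data$y + stats::runif(dplyr::n(), -1e-5, 1e-5),
      z = .valley_stage_z(config, .data$x)
    )

  # bank segments along y = 0
  brk <- seq(0, config$x_max, by = config$segment_length)
  xm <- (brk[-length(brk)] + brk[-1]) / 2
  reach_of <- function(xi) {
    which(config$reaches$x_min <= xi & xi <= config$reaches$x_max)[1]
  }
  k_idx <- vapply(xm, reach_of, integer(1))
  in_transition <- vapply(xm, function(xi) {
    any(abs(xi - inner_bounds) <= w)
  }, logical(1))
  segments <- tibble::tibble(
    segment_id = sprintf("seg%03d", seq_along(xm)),
    x0 = brk[-length(brk)], y0 = 0, x1 = brk[-1], y1 = 0,
    L = diff(brk),
    bank = "left",
    zone = ifelse(in_transition, "transition", config$reaches$zone[k_idx]),
    kp_start = config$kp0 - brk[-length(brk)] / 1000,
    kp_end = config$kp0 - brk[-1] / 1000,
    K = config$reaches$K[k_idx],
    riverbed_z = .valley_piezo_z(config, xm, 0) - config$A0
  )

  expected <- .valley_expected(config, segments)
  list(
    piezo_points = piezo, river_points = river,
    segments = segments, expected = expected, config = config
  )
}

# closed-form per-zone fluxes for the non-transition segments
.valley_expected <- function(config, segments) {
  r <- config$reaches
  sr <- config$stage_slope
  sp <- config$piezo_slope
  rows <- lapply(seq_len(nrow(r)), function(k) {
    g <- r$g[k]
    i <- sqrt(sp^2 + g^2)
    if (i == 0 || sr == 0) {
      # flat piezometric or flat river surface: undefined flow angle, no flux
      qe <- 0
      d <- NA_real_
    } else {
      aspect_p <- .azimuth(sp, -g)
      aspect_r <- .azimuth(sr, 0)
      d <- angle_d(aspect_p, aspect_r)
      qe <- 86400 * r$K[k] * i * config$A0 * sin(d * pi / 180)
    }
    L <- sum(segments$L[segments$zone == r$zone[k]])
    tibble::tibble(
      zone = r$zone[k], K = r$K[k], i = i, D = d, A = config$A0,
      Qe = qe, L = L, Qf = qe * L
    )
  })
  dplyr::bind_rows(rows)
}

#' Configuration for a synthetic wetland community
#'
#' Emulates a set of floodplain wetlands along two environmental gradients:
#' a thermal-stability gradient (monthly temperature series whose relative
#' standard deviation spans `cv_range`; low variability = groundwater-fed)
#' and a trophic gradient (soluble phosphate, substrate total phosphorus and
#' ammonia all increasing with the site's trophic level). Species are
#' indicator species planted on one gradient: their expected abundance
#' decays geometrically (`breadth` per class step) away from their optimum
#' class, with negative-binomial count noise.
#'
#' @param n_sites Number of wetlands (default 36).
#' @param n_thermal,n_trophic Numbers of thermal- and trophic-indicator
#'   species (defaults 15 each).
#' @param mu_max Expected count at the optimum class (default 30).
#' @param breadth Geometric decay of expected abundance per class step away
#'   from the optimum, in `[0, 1)`; 0 plants each species only at its
#'   optimum class (default 0.3).
#' @param nb_size Negative-binomial size (inverse overdispersion) of the
#'   count noise; `Inf` gives Poisson counts (default 5).
#' @param temp_mean Annual mean temperature, degrees C (default 12).
#' @param cv_range Range of the temperature relative standard deviation
#'   across sites, percent (default 2 to 40).
#' @param seed Integer seed.
#' @return A `community_config` list.
#' @export
community_config <- function(n_sites = 36, n_thermal = 15, n_trophic = 15,
                             mu_max = 30, breadth = 0.3, nb_size = 5,
                             temp_mean = 12, cv_range = c(2, 40), seed = 1) {
  stopifnot(n_sites >= 8, breadth >= 0, breadth < 1, mu_max > 0)
  structure(
    list(
      n_sites = n_sites, n_thermal = n_thermal, n_trophic = n_trophic,
      mu_max = mu_max, breadth = breadth, nb_size = nb_size,
      temp_mean = temp_mean, cv_range = cv_range, seed = seed
    ),
    class = "community_config"
  )
}

#' Generate a synthetic wetland community with planted structure
#'
#' Draws site environments over the configured gradients, plants indicator
#' species on the realised environmental classes, and emits the ground
#' truth needed for recovery tests. The environmental class labels in the
#' truth tables are computed from the generated series with
#' [relative_sd()], [phosphorus_score()] and [equilibrated_classes()], so a
#' pipeline re-deriving them from the emitted tables reproduces them
#' exactly; the species' expected per-class argmax is computed analytically
#' from the planted response before any noise is drawn.
#'
#' @param config A [community_config()].
#' @return List with `environment` (long tibble `site_id`, `variable`,
#'   `month`, `value`; variables `temperature`, `po4`, `nh3` monthly and
#'   `totalp` replicates), `releves` (`site_id`, `species`, `bb_code`),
#'   `truth_sites` (`site_id`, `trophic_class`, `thermal_class`,
#'   `p_class`, `n_class`, `cv`), and `truth_species` (`species`, `guild`,
#'   `optimum`, `expected_argmax`, `thermal_category`).
#' @export
generate_community <- function(config = community_config()) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  n <- config$n_sites
  site_id <- sprintf("W%02d", seq_len(n))

  # latent gradients: thermal CV spread over cv_range, trophic level 1..4
  cv <- stats::runif(n, config$cv_range[1], config$cv_range[2])
  trophic <- sample(rep(1:4, length.out = n))

  # monthly temperature: sinusoidal annual cycle scaled to the target CV
  months <- 1:12
  pattern <- sin(2 * pi * (months - 4) / 12)
  pattern <- (pattern - mean(pattern)) / stats::sd(pattern)
  temp <- purrr::map2_dfr(site_id, cv, function(s, cvi) {
    tibble::tibble(
      site_id = s, variable = "temperature", month = months,
      value = config$temp_mean * (1 + cvi / 100 * pattern)
    )
  })

  # chemistry increasing with trophic level; lognormal within-site noise
  po4_mu <- 10^(-2 + 0.5 * (trophic - 1))     # 0.01 .. 0.32 mg/L
  nh3_mu <- 0.02 * 3^(trophic - 1)            # 0.02 .. 0.54 mg/L
  tp_mu <- 100 * 2^(trophic - 1)              # 100 .. 800 (substrate total P)
  chem <- function(var, mu, n_rep, sdlog) {
    purrr::map2_dfr(site_id, mu, function(s, m) {
      tibble::tibble(
        site_id = s, variable = var, month = seq_len(n_rep),
        value = m * exp(stats::rnorm(n_rep, 0, sdlog))
      )
    })
  }
  po4 <- chem("po4", po4_mu, 12, 0.15)
  nh3 <- chem("nh3", nh3_mu, 12, 0.10)
  totalp <- chem("totalp", tp_mu, 3, 0.10)
  environment <- dplyr::bind_rows(temp, po4, nh3, totalp)

  # realised class labels (exactly reproducible from the emitted tables)
  cv_real <- vapply(site_id, function(s) {
    relative_sd(temp$value[temp$site_id == s])
  }, numeric(1))
  thermal_class <- equilibrated_classes(cv_real, 5)
  ps <- phosphorus_score(
    po4[, c("site_id", "value")], totalp[, c("site_id", "value")]
  )
  p_score <- ps$p_score[match(site_id, ps$site_id)]
  p_class <- equilibrated_classes(p_score, 5)
  nh3_mean <- vapply(site_id, function(s) {
    mean(log10(nh3$value[nh3$site_id == s]))
  }, numeric(1))
  n_class <- equilibrated_classes(nh3_mean, 4)

  # species planted on the realised classes
  guilds <- tibble::tibble(
    species = c(
      sprintf("Thermophyte_%02d", seq_len(config$n_thermal)),
      sprintf("Trophophyte_%02d", seq_len(config$n_trophic))
    ),
    guild = rep(c("thermal", "trophic"), c(config$n_thermal, config$n_trophic)),
    optimum = c(
      rep(1:5, length.out = config$n_thermal),
      rep(1:4, length.out = config$n_trophic)
    )
  )
# thermal species respond to the realised thermal-stability class;
  # trophic species respond to the latent trophic status of the site (the
  # quantity the chemistry expresses), which is what the analysis then
  # recovers through the phosphorus and ammonia class gradients. The
  # expected profile argmax is computed analytically in the class space the
  # analysis bins by (5 phosphorus classes for trophic species).
  response_class <- function(guild) {
    if (guild == "thermal") thermal_class else trophic
  }
  profile_class <- function(guild) {
    if (guild == "thermal") thermal_class else p_class
  }
  mu_of <- function(opt, cls) config$mu_max * config$breadth^abs(cls - opt)

  rel_rows <- list()
  expected_argmax <- integer(nrow(guilds))
  for (j in seq_len(nrow(guilds))) {
    mu <- mu_of(guilds$optimum[j], response_class(guilds$guild[j]))
    mu[mu < config$mu_max * 1e-6] <- 0
    cls <- profile_class(guilds$guild[j])
    k <- max(cls)
    exp_means <- vapply(seq_len(k), function(c) mean(mu[cls == c]), numeric(1))
    expected_argmax[j] <- which.max(exp_means)
    counts <- if (is.infinite(config$nb_size)) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, mu = mu, size = config$nb_size)
    }
    counts[mu == 0] <- 0L
    keep <- counts > 0
    if (any(keep)) {
      rel_rows[[j]] <- tibble::tibble(
        site_id = site_id[keep],
        species = guilds$species[j],
        bb_code = .count_to_bb(counts[keep])
      )
    }
  }
  releves <- dplyr::bind_rows(rel_rows) |>
    dplyr::arrange(.data$site_id, .data$species)

  truth_species <- guilds |>
    dplyr::mutate(
      expected_argmax = expected_argmax,
      thermal_category = dplyr::case_when(
        .data$guild == "thermal" & .data$optimum <= 2 ~ "groundwater_preferring",
        .data$guild == "thermal" & .data$optimum >= 4 ~ "stenothermy_intolerant",
        TRUE ~ "indifferent"
      )
    )
  truth_sites <- tibble::tibble(
    site_id = site_id,
    trophic_class = trophic,
    thermal_class = thermal_class,
    p_class = p_class,
    n_class = n_class,
    cv = cv_real,
    p_score = p_score
  )
  list(
    environment = environment, releves = releves,
    truth_sites = truth_sites, truth_species = truth_species,
    config = config
  )
}

# ordinal Braun-Blanquet code from a count
.count_to_bb <- function(count) {
  cut(
    count,
    breaks = c(0, 1, 3, 8, 17, 30, 50, Inf),
    labels = c("r", "+", "1", "2", "3", "4", "5"),
    include.lowest = FALSE, right = TRUE
  ) |> as.character()
}

#' Generate synthetic interstitial fauna samples
#'
#' Draws stygobite counts whose per-sample total is Poisson with mean equal
#' to the zone's configured upwelling intensity (split multinomially across
#' the packaged stygobite species), on top of an epigean background
#' community. Zero-intensity zones yield strictly stygobite-free samples.
#'
#' @param zones Data frame: `section_id`, `kp_min`, `kp_max`, `intensity`
#'   (expected stygobite individuals per sample, `>= 0`), optionally
#'   `habitat`.
#' @param n_sites Sampling sites per zone (default 3).
#' @param epigean_lambda Expected count per epigean taxon per sample
#'   (default 4, over 6 background taxa).
#' @param seed Integer seed.
#' @return Long tibble in the interstitial-sample schema: `site_id`, `kp`,
#'   `habitat`, `date`, `taxon`, `status`, `count`.
#' @export
generate_stygofauna <- function(zones, n_sites = 3, epigean_lambda = 4,
                                seed = 1) {
  zones <- tibble::as_tibble(as.data.frame(zones))
  stopifnot(all(zones$intensity >= 0))
  set.seed(seed)
  styg <- stygobite_species()$species
  epi <- sprintf("Epigean_taxon_%d", 1:6)
  rows <- list()
  for (j in seq_len(nrow(zones))) {
    kp_sites <- seq(zones$kp_min[j], zones$kp_max[j], length.out = n_sites + 2)
    kp_sites <- kp_sites[-c(1, n_sites + 2)]
    hab <- if ("habitat" %in% names(zones)) zones$habitat[j] else "main_channel"
    for (s in seq_len(n_sites)) {
      sid <- sprintf("%s_s%d", zones$section_id[j], s)
      total <- if (zones$intensity[j] > 0) {
        stats::rpois(1, zones$intensity[j])
      } else {
        0L
      }
      scounts <- if (total > 0) {
        as.integer(stats::rmultinom(1, total, rep(1, length(styg))))
      } else {
        integer(length(styg))
      }
      ecounts <- stats::rpois(length(epi), epigean_lambda)
      rows[[length(rows) + 1]] <- tibble::tibble(
        site_id = sid, kp = kp_sites[s], habitat = hab, date = "2008-07-01",
        taxon = c(styg, epi),
        status = rep(c("stygobite", "epigean"), c(length(styg), length(epi))),
        count = c(scounts, ecounts)
      )
    }
  }
  dplyr::bind_rows(rows)
}
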