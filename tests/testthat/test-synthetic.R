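test_that("generators are pure functions of config and seed", {
  v1 <- generate_valley(valley_config(seed = 9, n_points = 100, x_max = 1000))
  v2 <- generate_valley(valley_config(seed = 9, n_points = 100, x_max = 1000))
  expect_identical(v1$piezo_points, v2$piezo_points)
  expect_identical(v1$segments, v2$segments)

  c1 <- generate_community(community_config(seed = 12))
  c2 <- generate_community(community_config(seed = 12))
  expect_identical(c1$environment, c2$environment)
  expect_identical(c1$releves, c2$releves)

  zones <- tibble::tibble(
    section_id = "z", kp_min = 100, kp_max = 102, intensity = 8
  )
  f1 <- generate_stygofauna(zones, seed = 4)
  f2 <- generate_stygofauna(zones, seed = 4)
  expect_identical(f1, f2)
})

test_that("a flat valley produces zero expected and zero computed flux", {
  cfg <- valley_config(
    x_max = 1000, stage_slope = 0, piezo_slope = 0,
    reaches = tibble::tibble(
      zone = "flat", x_min = 0, x_max = 1000, K = 1e-3, g = 0
    ),
    n_points = 100, seed = 2
  )
  v <- generate_valley(cfg)
  expect_equal(v$expected$Qf, 0)
  d <- run_exchange_diagnosis(
    tin_surface(v$piezo_points, "piezometric"),
    tin_surface(v$river_points, "river_stage"),
    v$segments
  )
  expect_equal(d$estimates$Qe, rep(0, nrow(d$estimates)))
  expect_true(all(d$estimates$direction == "none"))
})

test_that("a purely transverse gradient gives the D = 90 closed form", {
  cfg <- valley_config(
    x_max = 1000, stage_slope = 5e-4, piezo_slope = 0,
    reaches = tibble::tibble(
      zone = "gain", x_min = 0, x_max = 1000, K = 1e-3, g = 1e-3
    ),
    n_points = 120, seed = 6
  )
  v <- generate_valley(cfg)
  e <- v$expected
  expect_equal(e$D, 90, tolerance = 1e-9)
  expect_equal(e$Qf, 86400 * 1e-3 * 1e-3 * cfg$A0 * e$L, tolerance = 1e-12)
})

test_that("the pipeline recovers closed-form zone fluxes within 1 percent", {
  v <- generate_valley(valley_config(seed = 3))
  expect_gte(nrow(v$piezo_points), 500)
  d <- run_exchange_diagnosis(
    tin_surface(v$piezo_points, "piezometric"),
    tin_surface(v$river_points, "river_stage"),
    v$segments
  )
  for (zz in v$expected$zone) {
    got <- with(d$zones, Qf_pos[zone == zz] + Qf_neg[zone == zz])
    want <- v$expected$Qf[v$expected$zone == zz]
    expect_equal(got, want, tolerance = 0.01)
  }
})

test_that("zero niche breadth plants species only at their optimum class", {
  comm <- generate_community(community_config(seed = 5, breadth = 0, nb_size = Inf))
  joined <- dplyr::inner_join(
    comm$releves, comm$truth_species,
    by = "species"
  ) |>
    dplyr::inner_join(comm$truth_sites, by = "site_id")
  th <- joined[joined$guild == "thermal", ]
  expect_true(all(th$thermal_class == th$optimum))
  tr <- joined[joined$guild == "trophic", ]
  expect_true(all(tr$trophic_class == tr$optimum))
})

test_that("profile recovery degrades as niche breadth grows", {
  rate_at <- function(breadth) {
    comm <- generate_community(community_config(seed = 20, breadth = breadth))
    res <- macrophyte_assessment(comm$environment, comm$releves, min_sites = 3)
    prof <- tibble::as_tibble(res$profiles$thermal) |>
      dplyr::group_by(species) |>
      dplyr::summarise(argmax = class[which.max(weight)])
    cmp <- dplyr::inner_join(
      prof,
      dplyr::filter(comm$truth_species, .data$guild == "thermal"),
      by = "species"
    )
    mean(cmp$argmax == cmp$expected_argmax)
  }
  r_tight <- rate_at(0.05)
  r_wide <- rate_at(0.75)
  expect_gte(r_tight, r_wide)
  expect_gte(r_tight, 0.9)
})

test_that("stygofauna counts track the configured upwelling intensity", {
  zones <- tibble::tibble(
    section_id = c("up", "none"), kp_min = c(100, 104),
    kp_max = c(102, 106), intensity = c(20, 0)
  )
  smp <- generate_stygofauna(zones, n_sites = 3, seed = 7)
  styg <- smp[smp$status == "stygobite", ]
  by_zone <- tapply(styg$count, substr(styg$site_id, 1, 2), sum)
  expect_equal(unname(by_zone[["no"]]), 0) # zero intensity -> stygobite-free
  expect_gt(unname(by_zone[["up"]]), 0)

  # designed separation drives the section classifier
  idx <- stygo_metrics(smp, pooling = "per_site")
  cls <- classify_sections(idx, zones[, c("section_id", "kp_min", "kp_max")])
  expect_equal(cls$category[cls$section_id == "up"], "upwelling")
  expect_equal(cls$category[cls$section_id == "none"], "none")

  # Monte-Carlo: mean per-sample total within 2 SE of the configured mean
  big <- generate_stygofauna(
    tibble::tibble(section_id = "mc", kp_min = 0, kp_max = 100, intensity = 12),
    n_sites = 500, seed = 13
  )
  totals <- tapply(
    big$count[big$status == "stygobite"],
    big$site_id[big$status == "stygobite"], sum
  )
  se <- sqrt(12 / 500)
  expect_lt(abs(mean(totals) - 12), 2 * se)
})

test_that("end-to-end overlay converges where the planted signals agree", {
  # hydraulic: two-reach valley, gaining upstream (kp 116-114), losing below
  v <- generate_valley(valley_config(seed = 3))
  d <- run_exchange_diagnosis(
    tin_surface(v$piezo_points, "piezometric"),
    tin_surface(v$river_points, "river_stage"),
    v$segments
  )
  hyd <- d$zones[d$zones$zone != "transition", ]

  # macrophytes: high influence sites in the gaining reach, null elsewhere
  comm <- generate_community(community_config(seed = 3))
  res <- macrophyte_assessment(comm$environment, comm$releves)
  infl <- res$influence
  stable <- comm$truth_sites$site_id[comm$truth_sites$thermal_class <= 2]
  unstable <- comm$truth_sites$site_id[comm$truth_sites$thermal_class >= 4]
  macro <- dplyr::bind_rows(
    dplyr::mutate(infl[infl$site_id %in% stable, ], kp = 115),
    dplyr::mutate(infl[infl$site_id %in% unstable, ], kp = 113)
  )

  # stygofauna: strong upwelling planted in the gaining reach only
  zones <- tibble::tibble(
    section_id = c("gain_sec", "lose_sec"),
    kp_min = c(114.05, 112), kp_max = c(116, 113.95),
    intensity = c(25, 0)
  )
  smp <- generate_stygofauna(zones, seed = 3)
  cls <- classify_sections(stygo_metrics(smp, "per_site"), zones)

  part <- tibble::tibble(
    zone_id = c("upstream", "downstream"), bank = "left",
    kp_min = c(114, 112), kp_max = c(116, 113.999)
  )
  zt <- build_zone_table(part,
    hydraulic = hyd, macro = macro, invert = cls
  )
  vt <- verdict(zt)
  up <- vt[vt$zone_id == "upstream", ]
  # all three planted signals say gain: hydraulic +, macro influence, upwelling
  expect_equal(up$sign_hydraulic, "gain")
  expect_equal(up$sign_macro, "gain")
  expect_equal(up$sign_invert, "gain")
  expect_equal(up$verdict, "convergent")
  # downstream: hydraulic loss against biological "no groundwater signal"
  down <- vt[vt$zone_id == "downstream", ]
  expect_equal(down$sign_hydraulic, "loss")
  expect_false(identical(down$verdict, "convergent"))
})
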