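# Overlay of the three indicator maps on one zone partition: a synthesis
# table (hydraulic flux, macrophyte influence class, invertebrate section
# category per zone), convergence/divergence verdicts, and cross-metric
# correlations on ordinal encodings.

#' Align the three indicator maps on a common zone partition
#'
#' Assigns every hydraulic zone summary, macrophyte site class and
#' invertebrate section classification to the partition interval containing
#' its KP midpoint (per bank where banks are given), and returns one aligned
#' record per zone. Metrics absent from a zone are explicitly `NA`; input
#' records whose midpoint falls in no interval are reported in the
#' `"unassigned"` attribute rather than dropped silently.
#'
#' @param partition Data frame: `zone_id`, `kp_min`, `kp_max`, optionally
#'   `bank` and `reach_type`. Intervals must not overlap within a bank.
#' @param hydraulic Optional [zone_qf()]-style tibble with `kp_min`,
#'   `kp_max`, `Qf_pos`, `Qf_neg`, `L_pos`, `L_neg` (and optionally `bank`).
#'   `Qf` and `Qu` per record are the signed net totals.
#' @param macro Optional tibble of macrophyte site results: `site_id`, `kp`,
#'   `index`, `influence_class` (and optionally `bank`).
#' @param invert Optional [classify_sections()] tibble: `section_id`,
#'   `kp_min`, `kp_max`, `category` (and optionally `bank`).
#' @return Tibble of `ZoneRecord`s ordered upstream to downstream
#'   (decreasing KP): `zone_id`, `bank`, `kp_min`, `kp_max`, `reach_type`,
#'   `Qf`, `Qu`, `macro_index` (median site index), `influence_class`,
#'   `invert_category`. Attribute `"unassigned"` holds unmatched inputs.
#' @export
build_zone_table <- function(partition, hydraulic = NULL, macro = NULL,
                             invert = NULL) {
  partition <- tibble::as_tibble(as.data.frame(partition))
  stopifnot(all(c("zone_id", "kp_min", "kp_max") %in% names(partition)))
  if (!"bank" %in% names(partition)) partition$bank <- "unspecified"
  if (!"reach_type" %in% names(partition)) partition$reach_type <- NA_character_
  # overlap check per bank
  for (b in unique(partition$bank)) {
    p <- partition[partition$bank == b, ]
    p <- p[order(p$kp_min), ]
    if (nrow(p) > 1 && any(p$kp_min[-1] < p$kp_max[-nrow(p)])) {
      stop("ambiguous partition: overlapping KP intervals on bank ", b,
        call. = FALSE
      )
    }
  }

  match_zone <- function(kp, bank) {
    cand <- which(
      partition$kp_min <= kp & kp <= partition$kp_max &
        (is.na(bank) | partition$bank == bank | partition$bank == "unspecified")
    )
    if (length(cand) == 0) NA_integer_ else cand[1]
  }

  unassigned <- list()
  out <- partition |>
    dplyr::mutate(
      Qf = NA_real_, Qu = NA_real_,
      macro_index = NA_real_, influence_class = NA_character_,
      invert_category = NA_character_
    )

  if (!is.null(hydraulic)) {
    h <- tibble::as_tibble(as.data.frame(hydraulic))
    if (!"bank" %in% names(h)) h$bank <- NA_character_
    h$Qf_net <- h$Qf_pos + h$Qf_neg
    h$L_tot <- h$L_pos + h$L_neg
    h$.zone <- mapply(match_zone, (h$kp_min + h$kp_max) / 2, h$bank)
    unassigned$hydraulic <- h[is.na(h$.zone), , drop = FALSE]
    hh <- h[!is.na(h$.zone), , drop = FALSE]
    agg <- hh |>
      dplyr::group_by(.data$.zone) |>
      dplyr::summarise(
        Qf = sum(.data$Qf_net),
        L = sum(.data$L_tot),
        .groups = "drop"
      )
    out$Qf[agg$.zone] <- agg$Qf
    out$Qu[agg$.zone] <- ifelse(agg$L > 0, unit_flow(agg$Qf, agg$L), NA_real_)
  }

  if (!is.null(macro)) {
    m <- tibble::as_tibble(as.data.frame(macro))
    if (!"bank" %in% names(m)) m$bank <- NA_character_
    m$.zone <- mapply(match_zone, m$kp, m$bank)
    unassigned$macro <- m[is.na(m$.zone), , drop = FALSE]
    mm <- m[!is.na(m$.zone), , drop = FALSE]
    if (nrow(mm)) {
      agg <- mm |>
        dplyr::group_by(.data$.zone) |>
        dplyr::summarise(
          macro_index = stats::median(.data$index),
          .groups = "drop"
        )
      out$macro_index[agg$.zone] <- agg$macro_index
      out$influence_class[agg$.zone] <-
        as.character(influence_class(round(agg$macro_index)))
    }
  }

  if (!is.null(invert)) {
    v <- tibble::as_tibble(as.data.frame(invert))
    if (!"bank" %in% names(v)) v$bank <- NA_character_
    v$.zone <- mapply(match_zone, (v$kp_min + v$kp_max) / 2, v$bank)
    unassigned$invert <- v[is.na(v$.zone), , drop = FALSE]
    vv <- v[!is.na(v$.zone), , drop = FALSE]
    for (r in seq_len(nrow(vv))) {
      out$invert_category[vv$.zone[r]] <- vv$category[r]
    }
  }

  out <- out[order(-(out$kp_min + out$kp_max) / 2), , drop = FALSE]
  attr(out, "unassigned") <- unassigned
  out
}

#' Default reduction of metric values to exchange signs
#'
#' Maps each indicator to `"gain"` (aquifer feeds the surface water),
#' `"loss"` (surface water feeds the aquifer) or `"none"`. Hydraulic fluxes
#' reduce by sign; macrophyte influence classes `low`/`intermediate`/`high`
#' read as groundwater input (`gain`) and `null` as no input (`none`);
#' invertebrate `upwelling` and `mixed` read as `gain`, `none` as `none`.
#' Override any entry to encode a different field interpretation.
#'
#' @return Named list of named character vectors (`macro`, `invert`).
#' @export
verdict_reduction <- function() {
  list(
    macro = c(
      null = "none", low = "gain", intermediate = "gain", high = "gain"
    ),
    invert = c(none = "none", mixed = "gain", upwelling = "gain")
  )
}

#' Convergence verdicts between the three indicators
#'
#' Reduces each present metric of a zone record to a sign
#' (`gain`/`loss`/`none`) and issues a verdict: `convergent` when all
#' present signs agree; `divergent` when a gain and a loss co-occur;
#' `partial` when the directional signs agree but at least one metric says
#' `none`; `incomparable` when fewer than two metrics are present. The
#' verdict is order-invariant and idempotent.
#'
#' @param zone_table Tibble from [build_zone_table()].
#' @param reduction Sign-reduction tables, default [verdict_reduction()].
#' @return The zone table with added `sign_hydraulic`, `sign_macro`,
#'   `sign_invert`, `n_metrics`, `verdict`, `rationale` columns.
#' @export
verdict <- function(zone_table, reduction = verdict_reduction()) {
  zt <- tibble::as_tibble(zone_table)
  red_sign <- function(x, tab) {
    ifelse(is.na(x), NA_character_, unname(tab[x]))
  }
  zt$sign_hydraulic <- dplyr::case_when(
    is.na(zt$Qf) ~ NA_character_,
    zt$Qf > 0 ~ "gain",
    zt$Qf < 0 ~ "loss",
    TRUE ~ "none"
  )
  zt$sign_macro <- red_sign(zt$influence_class, reduction$macro)
  zt$sign_invert <- red_sign(zt$invert_category, reduction$invert)

  one <- function(s) {
    s <- s[!is.na(s)]
    n <- length(s)
    if (n < 2) {
      return(tibble::tibble(
        n_metrics = n, verdict = "incomparable",
        rationale = "fewer than two indicators present"
      ))
    }
    has_gain <- any(s == "gain")
    has_loss <- any(s == "loss")
    if (has_gain && has_loss) {
      v <- "divergent"
      r <- "gain and loss indicated by different methods"
    } else if (length(unique(s)) == 1) {
      v <- "convergent"
      r <- sprintf("all %d indicators agree (%s)", n, s[1])
    } else {
      v <- "partial"
      r <- "directional indicators agree; at least one indicates no exchange"
    }
    tibble::tibble(n_metrics = n, verdict = v, rationale = r)
  }
  verdicts <- dplyr::bind_rows(lapply(
    seq_len(nrow(zt)),
    function(i) one(c(zt$sign_hydraulic[i], zt$sign_macro[i], zt$sign_invert[i]))
  ))
  dplyr::bind_cols(zt, verdicts)
}

#' Default ordinal encoding of qualitative classes
#'
#' For correlations: `none`/`null` = 0, `low`/`weak`/`mixed` = 1,
#' `intermediate`/`medium` = 2, `high`/`upwelling` = 3.
#'
#' @return Named numeric vector.
#' @export
ordinal_encoding <- function() {
  c(
    none = 0, null = 0,
    low = 1, weak = 1, mixed = 1,
    intermediate = 2, medium = 2,
    high = 3, upwelling = 3
  )
}

#' Correlation between two zone-level metrics
#'
#' Ordinary least-squares fit of `y` on `x` over the zones where both
#' metrics are present; reports the squared Pearson correlation and the
#' two-sided p-value of the slope t-test. Qualitative classes are encoded
#' ordinally ([ordinal_encoding()]) before fitting. R-squared is invariant
#' under affine rescaling of either metric.
#'
#' @param zone_table Tibble from [build_zone_table()].
#' @param x,y Column names among `"Qu"`, `"Qf"`, `"macro_index"`,
#'   `"influence_class"`, `"invert_category"`, or any numeric column.
#' @param encoding Ordinal encoding for class columns.
#' @return One-row tibble of class `exchange_correlation`: `pair`, `n`,
#'   `r2`, `p`, `slope`.
#' @export
correlate <- function(zone_table, x, y, encoding = ordinal_encoding()) {
  zt <- tibble::as_tibble(zone_table)
  enc <- function(col) {
    v <- zt[[col]]
    if (is.numeric(v)) {
      return(v)
    }
    out <- unname(encoding[as.character(v)])
    out
  }
  xv <- enc(x)
  yv <- enc(y)
  keep <- !is.na(xv) & !is.na(yv)
  n <- sum(keep)
  if (n < 3) stop("need >= 3 zones with both metrics", call. = FALSE)
  xv <- xv[keep]
  yv <- yv[keep]
  if (stats::var(xv) == 0 || stats::var(yv) == 0) {
    stop("degenerate correlation: zero variance in a metric", call. = FALSE)
  }
  fit <- stats::lm(yv ~ xv)
  sm <- summary(fit)
  out <- tibble::tibble(
    pair = paste(x, y, sep = " ~ "),
    n = n,
    r2 = sm$r.squared,
    p = sm$coefficients["xv", "Pr(>|t|)"],
    slope = stats::coef(fit)[["xv"]]
  )
  class(out) <- c("exchange_correlation", class(out))
  out
}

#' Glance at an exchange correlation
#' @param x An `exchange_correlation`.
#' @param ... Unused.
#' @return The correlation row as a plain tibble.
#' @export
glance.exchange_correlation <- function(x, ...) {
  tibble::as_tibble(x)
}
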