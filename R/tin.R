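# Triangulated irregular network (TIN) surfaces over scattered head/stage
# points. Each triangle carries the plane through its three vertices, from
# which elevation, slope (hydraulic gradient magnitude) and aspect (downslope
# azimuth, the direction water flows) are derived.

#' Build a TIN surface from scattered elevation points
#'
#' Triangulates the `(x, y)` projections of a point cloud (Delaunay) and
#' attaches to every triangle the plane through its three vertices:
#' mean elevation, slope (gradient magnitude, dimensionless rise/run) and
#' aspect (downslope azimuth in degrees clockwise from grid north).
#' Coordinates must be planar projected metres; geographic coordinates are
#' not supported because gradients need metric units.
#'
#' @param points A data frame with numeric columns `x`, `y`, `z`
#'   (easting, northing, elevation or head, all in metres).
#' @param kind Surface tag, `"piezometric"` or `"river_stage"`.
#' @return An object of class `tin_surface`: a list with `points` (tibble of
#'   vertices), `triangles` (tibble with vertex indices `v1:v3`, plane
#'   coefficients `a`, `b`, `c` of `z = a*x + b*y + c`, `area`, `elevation`,
#'   `slope`, `aspect`, `defined_aspect`) and `kind`.
#' @details Duplicate `(x, y)` locations with identical `z` are collapsed;
#'   duplicates with conflicting `z` are an error ("ambiguous elevation").
#'   Fewer than three points, or an all-collinear cloud, is an error
#'   ("degenerate point set"). Flat triangles (all vertices at the same
#'   elevation) report `slope = 0` with `defined_aspect = FALSE` and
#'   `aspect = NA`; downstream flux code treats them as exchanging nothing.
#' @examples
#' pts <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1), z = c(0, 0, 1, 1))
#' tin <- tin_surface(pts, kind = "piezometric")
#' tidy(tin)
#' @export
tin_surface <- function(points, kind = c("piezometric", "river_stage")) {
  kind <- match.arg(kind)
  points <- as.data.frame(points)
  need <- c("x", "y", "z")
  if (!all(need %in% names(points))) {
    stop("schema error: points need columns x, y, z", call. = FALSE)
  }
  pts <- tibble::tibble(
    x = as.numeric(points$x),
    y = as.numeric(points$y),
    z = as.numeric(points$z)
  )
  if (!all(is.finite(pts$x) & is.finite(pts$y) & is.finite(pts$z))) {
    stop("non-finite coordinates in point set", call. = FALSE)
  }
  key <- paste(pts$x, pts$y)
  if (anyDuplicated(key)) {
    zr <- tapply(pts$z, key, function(z) diff(range(z)))
    if (any(zr > 0)) {
      stop("ambiguous elevation: duplicate (x, y) with conflicting z",
        call. = FALSE
      )
    }
    pts <- pts[!duplicated(key), , drop = FALSE]
  }
  if (nrow(pts) < 3 || .collinear(pts$x, pts$y)) {
    stop("degenerate point set: need >= 3 non-collinear points", call. = FALSE)
  }

  tm <- .delaunay(pts$x, pts$y)
  tri <- .triangle_planes(pts, tm)

  structure(
    list(points = pts, triangles = tri, kind = kind),
    class = "tin_surface"
  )
}

# Delaunay triangulation of the (x, y) projections (sweep-hull algorithm;
# robust to regular lattices and collinear point rows). Returns an n x 3
# matrix of vertex indices.
.delaunay <- function(x, y) {
  # the swap-retry notice from shull is an internal detail of the backend
  tr <- suppressWarnings(interp::tri.mesh(x, y))
  m <- interp::triangles(tr)
  matrix(m[, c("node1", "node2", "node3")], ncol = 3)
}

.collinear <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  # rank of the centred coordinate matrix < 2 means all points on one line
  m <- cbind(xc, yc)
  s <- svd(m, nu = 0, nv = 0)$d
  s[2] <= max(s[1], 1) * 1e-12
}

# Plane z = a*x + b*y + c through each triangle's vertices, plus the derived
# attributes. Vertices are reordered counter-clockwise so the barycentric
# sign tests in the samplers share one orientation.
.triangle_planes <- function(pts, tm) {
  x1 <- pts$x[tm[, 1]]; y1 <- pts$y[tm[, 1]]
  x2 <- pts$x[tm[, 2]]; y2 <- pts$y[tm[, 2]]
  x3 <- pts$x[tm[, 3]]; y3 <- pts$y[tm[, 3]]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  flip <- det < 0
  if (any(flip)) {
    tmp <- tm[flip, 2]
    tm[flip, 2] <- tm[flip, 3]
    tm[flip, 3] <- tmp
  }
  v1 <- tm[, 1]; v2 <- tm[, 2]; v3 <- tm[, 3]
  x1 <- pts$x[v1]; y1 <- pts$y[v1]; z1 <- pts$z[v1]
  x2 <- pts$x[v2]; y2 <- pts$y[v2]; z2 <- pts$z[v2]
  x3 <- pts$x[v3]; y3 <- pts$y[v3]; z3 <- pts$z[v3]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  if (any(abs(det) <= 0)) {
    stop("degenerate triangle with zero area in triangulation", call. = FALSE)
  }
  a <- ((z2 - z1) * (y3 - y1) - (z3 - z1) * (y2 - y1)) / det
  b <- ((x2 - x1) * (z3 - z1) - (x3 - x1) * (z2 - z1)) / det
  cc <- z1 - a * x1 - b * y1
  slope <- sqrt(a^2 + b^2)
  defined <- slope > 1e-12
  aspect <- ifelse(defined, .azimuth(-a, -b), NA_real_)
  tibble::tibble(
    triangle = seq_along(v1),
    v1 = v1, v2 = v2, v3 = v3,
    a = a, b = b, c = cc,
    area = abs(det) / 2,
    elevation = (z1 + z2 + z3) / 3,
    slope = slope,
    aspect = aspect,
    defined_aspect = defined
  )
}

# Azimuth of the vector (vx, vy): degrees clockwise from grid north, in
# [0, 360). Grid north is +y.
.azimuth <- function(vx, vy) {
  (atan2(vx, vy) * 180 / pi) %% 360
}

#' Attributes of one TIN triangle
#'
#' @param surface A [tin_surface()].
#' @param triangle_index Integer triangle index (1-based).
#' @return One-row tibble with `triangle`, `elevation`, `slope`, `aspect`,
#'   `defined_aspect`, `area`.
#' @export
triangle_attributes <- function(surface, triangle_index) {
  stopifnot(inherits(surface, "tin_surface"))
  n <- nrow(surface$triangles)
  if (any(triangle_index < 1 | triangle_index > n)) {
    stop("triangle index out of bounds", call. = FALSE)
  }
  surface$triangles[triangle_index,
    c("triangle", "elevation", "slope", "aspect", "defined_aspect", "area")
  ]
}

#' Sample TIN attributes at points
#'
#' Looks up the triangle containing each `(x, y)` and returns its attributes.
#' Points on a shared edge or vertex resolve to the adjacent triangle with
#' the lowest index (deterministic tie-break).
#'
#' @param surface A [tin_surface()].
#' @param x,y Numeric vectors of query coordinates (metres).
#' @return Tibble with one row per query: `x`, `y`, `triangle`, `elevation`,
#'   `slope`, `aspect`, `defined_aspect`.
#' @export
tin_sample <- function(surface, x, y) {
  stopifnot(inherits(surface, "tin_surface"))
  stopifnot(length(x) == length(y))
  idx <- vapply(
    seq_along(x),
    function(i) .containing_triangle(surface, x[i], y[i]),
    integer(1)
  )
  out <- surface$triangles[idx,
    c("triangle", "elevation", "slope", "aspect", "defined_aspect")
  ]
  dplyr::bind_cols(tibble::tibble(x = x, y = y), out)
}

# Lowest-index triangle containing (px, py); errors when outside the hull.
.containing_triangle <- function(surface, px, py) {
  tr <- surface$triangles
  p <- surface$points
  tol <- .geom_tol(surface)
  s1 <- (p$x[tr$v2] - p$x[tr$v1]) * (py - p$y[tr$v1]) -
    (p$y[tr$v2] - p$y[tr$v1]) * (px - p$x[tr$v1])
  s2 <- (p$x[tr$v3] - p$x[tr$v2]) * (py - p$y[tr$v2]) -
    (p$y[tr$v3] - p$y[tr$v2]) * (px - p$x[tr$v2])
  s3 <- (p$x[tr$v1] - p$x[tr$v3]) * (py - p$y[tr$v3]) -
    (p$y[tr$v1] - p$y[tr$v3]) * (px - p$x[tr$v3])
  inside <- s1 >= -tol & s2 >= -tol & s3 >= -tol
  if (!any(inside)) {
    stop(
      sprintf("outside surface extent: point (%g, %g)", px, py),
      call. = FALSE
    )
  }
  which(inside)[1L]
}

.geom_tol <- function(surface) {
  ext <- max(
    diff(range(surface$points$x)),
    diff(range(surface$points$y))
  )
  max(ext, 1)^2 * 1e-12
}

#' Sample TIN attributes along polyline segments
#'
#' Clips each segment against the triangulation and returns, per segment,
#' the crossed-length-weighted mean slope and elevation and the
#' length-weighted circular mean of the crossed triangles' aspects. A
#' zero-length segment degenerates to [tin_sample()] at the point; a segment
#' lying inside one triangle returns that triangle's attributes exactly.
#' A segment lying exactly on a shared edge is weighted over both adjacent
#' triangles.
#'
#' @param surface A [tin_surface()].
#' @param segments Data frame with numeric columns `x0`, `y0`, `x1`, `y1`
#'   (segment endpoints, metres).
#' @return Tibble with one row per segment: `elevation`, `slope`, `aspect`,
#'   `defined_aspect`, `covered` (fraction of the segment length inside the
#'   triangulation).
#' @export
tin_sample_segment <- function(surface, segments) {
  stopifnot(inherits(surface, "tin_surface"))
  segments <- as.data.frame(segments)
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(segments))) {
    stop("schema error: segments need columns x0, y0, x1, y1", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    .sample_one_segment(
      surface,
      segments$x0[i], segments$y0[i], segments$x1[i], segments$y1[i]
    )
  })
  dplyr::bind_rows(rows)
}

.sample_one_segment <- function(surface, x0, y0, x1, y1) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len <= 0) {
    s <- tin_sample(surface, x0, y0)
    return(tibble::tibble(
      elevation = s$elevation, slope = s$slope, aspect = s$aspect,
      defined_aspect = s$defined_aspect, covered = 1
    ))
  }
  tr <- surface$triangles
  p <- surface$points
  tol <- .geom_tol(surface)

  # Each CCW edge gives a half-plane constraint f(t) = f0 + t * (f1 - f0) >= 0
  # along the segment P0 + t (P1 - P0); their intersection is the t-interval
  # the segment spends in the triangle.
  edge_f <- function(va, vb, px, py) {
    (p$x[vb] - p$x[va]) * (py - p$y[va]) - (p$y[vb] - p$y[va]) * (px - p$x[va])
  }
  f10 <- edge_f(tr$v1, tr$v2, x0, y0); f11 <- edge_f(tr$v1, tr$v2, x1, y1)
  f20 <- edge_f(tr$v2, tr$v3, x0, y0); f21 <- edge_f(tr$v2, tr$v3, x1, y1)
  f30 <- edge_f(tr$v3, tr$v1, x0, y0); f31 <- edge_f(tr$v3, tr$v1, x1, y1)

  clip <- function(f0, f1, lo, hi) {
    d <- f1 - f0
    flat <- abs(d) <= tol
    # constraint inactive along t where d ~ 0: inside iff f0 >= -tol
    lo_new <- ifelse(flat, ifelse(f0 >= -tol, lo, 1), ifelse(d > 0, pmax(lo, -f0 / d), lo))
    hi_new <- ifelse(flat, ifelse(f0 >= -tol, hi, 0), ifelse(d < 0, pmin(hi, -f0 / d), hi))
    list(lo = lo_new, hi = hi_new)
  }
  iv <- clip(f10, f11, 0, 1)
  iv <- clip(f20, f21, iv$lo, iv$hi)
  iv <- clip(f30, f31, iv$lo, iv$hi)
  w <- pmax(iv$hi - iv$lo, 0) * len
  hit <- w > len * 1e-12
  if (!any(hit)) {
    # fall back to a midpoint lookup (errors if outside the hull)
    s <- tin_sample(surface, (x0 + x1) / 2, (y0 + y1) / 2)
    return(tibble::tibble(
      elevation = s$elevation, slope = s$slope, aspect = s$aspect,
      defined_aspect = s$defined_aspect, covered = 0
    ))
  }
  w <- w[hit]
  slope <- tr$slope[hit]
  elev <- tr$elevation[hit]
  asp <- tr$aspect[hit]
  defined <- tr$defined_aspect[hit]
  wt <- sum(w)
  wd <- w[defined]
  if (length(wd) > 0) {
    rad <- asp[defined] * pi / 180
    ux <- sum(wd * sin(rad))
    uy <- sum(wd * cos(rad))
    has_dir <- sqrt(ux^2 + uy^2) > sum(wd) * 1e-9
    aspect <- if (has_dir) .azimuth(ux, uy) else NA_real_
  } else {
    has_dir <- FALSE
    aspect <- NA_real_
  }
  # union of per-triangle intervals for coverage (overlaps collapse)
  covered <- .interval_union(iv$lo[hit], iv$hi[hit])
  tibble::tibble(
    elevation = sum(w * elev) / wt,
    slope = sum(w * slope) / wt,
    aspect = aspect,
    defined_aspect = has_dir,
    covered = covered
  )
}

.interval_union <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  total <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  if (length(lo) > 1) {
    for (i in 2:length(lo)) {
      if (lo[i] > cur_hi) {
        total <- total + (cur_hi - cur_lo)
        cur_lo <- lo[i]; cur_hi <- hi[i]
      } else {
        cur_hi <- max(cur_hi, hi[i])
      }
    }
  }
  min(total + (cur_hi - cur_lo), 1)
}

#' @export
print.tin_surface <- function(x, ...) {
  cat(
    sprintf(
      "<tin_surface: %s>\n  %d vertices, %d triangles, total area %.6g m^2\n",
      x$kind, nrow(x$points), nrow(x$triangles), sum(x$triangles$area)
    )
  )
  invisible(x)
}

#' @rdname tin_surface
#' @param x A `tin_surface`.
#' @param ... Unused.
#' @export
tidy.tin_surface <- function(x, ...) {
  x$triangles[, c(
    "triangle", "v1", "v2", "v3", "area",
    "elevation", "slope", "aspect", "defined_aspect"
  )]
}

#' @rdname tin_surface
#' @export
glance.tin_surface <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_points = nrow(x$points),
    n_triangles = nrow(x$triangles),
    total_area = sum(x$triangles$area),
    mean_slope = stats::weighted.mean(x$triangles$slope, x$triangles$area)
  )
}

#' @rdname tin_surface
#' @param object A `tin_surface`.
#' @param fill Triangle attribute to colour by (`"elevation"`, `"slope"`
#'   or `"aspect"`).
#' @export
autoplot.tin_surface <- function(object, fill = "elevation", ...) {
  tr <- object$triangles
  p <- object$points
  poly <- tibble::tibble(
    triangle = rep(tr$triangle, each = 3L),
    x = as.vector(rbind(p$x[tr$v1], p$x[tr$v2], p$x[tr$v3])),
    y = as.vector(rbind(p$y[tr$v1], p$y[tr$v2], p$y[tr$v3])),
    value = rep(tr[[fill]], each = 3L)
  )
  ggplot2::ggplot(poly, ggplot2::aes(
    x = .data$x, y = .data$y,
    group = .data$triangle, fill = .data$value
  )) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = fill, x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}
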