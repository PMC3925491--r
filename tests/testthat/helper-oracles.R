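# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plane fits go through lm(), point-in-triangle
# through a sign test written here, regression statistics through the
# closed-form textbook formulas.

# least-squares plane fit z ~ x + y over a triangle's three vertices
oracle_plane_fit <- function(x, y, z) {
  fit <- stats::lm(z ~ x + y)
  unname(stats::coef(fit)[c("x", "y")])
}

# azimuth of (vx, vy), degrees clockwise from +y, in [0, 360)
oracle_azimuth <- function(vx, vy) {
  (atan2(vx, vy) * 180 / pi) %% 360
}

# brute-force point-in-triangle scan: returns indices of all triangles
# containing (px, py), same-sign cross-product test
oracle_triangles_containing <- function(tin, px, py) {
  tr <- tin$triangles
  p <- tin$points
  hits <- integer()
  for (i in seq_len(nrow(tr))) {
    xs <- p$x[c(tr$v1[i], tr$v2[i], tr$v3[i])]
    ys <- p$y[c(tr$v1[i], tr$v2[i], tr$v3[i])]
    s <- numeric(3)
    for (e in 1:3) {
      j <- e %% 3 + 1
      s[e] <- (xs[j] - xs[e]) * (py - ys[e]) - (ys[j] - ys[e]) * (px - xs[e])
    }
    if (all(s >= -1e-9) || all(s <= 1e-9)) hits <- c(hits, i)
  }
  hits
}

# numerical integration of slope along a segment by dense midpoint sampling,
# with bisection refinement of the subintervals where the containing
# triangle changes (drives the quadrature error to machine precision)
oracle_segment_slope <- function(tin, x0, y0, x1, y1, n = 1000) {
  tq <- seq(0, 1, length.out = n + 1)
  pt_tri <- function(t) {
    s <- tin_sample(tin, x0 + t * (x1 - x0), y0 + t * (y1 - y0))
    c(s$triangle, s$slope)
  }
  mids <- (tq[-1] + tq[-(n + 1)]) / 2
  info <- vapply(mids, pt_tri, numeric(2))
  tri <- info[1, ]
  total <- 0
  weight <- 0
  bounds <- tq
  # refine boundaries between consecutive subintervals with different triangles
  for (i in seq_len(n)) {
    lo <- bounds[i]
    hi <- bounds[i + 1]
    if (i < n && tri[i] != tri[i + 1]) {
      a <- mids[i]
      b <- mids[i + 1]
      for (r in 1:60) {
        m <- (a + b) / 2
        if (pt_tri(m)[1] == tri[i]) a <- m else b <- m
      }
      hi <- (a + b) / 2
    }
    if (i > 1 && tri[i] != tri[i - 1]) {
      a <- mids[i - 1]
      b <- mids[i]
      for (r in 1:60) {
        m <- (a + b) / 2
        if (pt_tri(m)[1] == tri[i - 1]) a <- m else b <- m
      }
      lo <- (a + b) / 2
    }
    total <- total + info[2, i] * (hi - lo)
    weight <- weight + (hi - lo)
  }
  total / weight
}

# shoelace area of the convex hull of a point set
oracle_hull_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  xs <- x[h]
  ys <- y[h]
  n <- length(h)
  j <- c(2:n, 1)
  abs(sum(xs * ys[j] - xs[j] * ys)) / 2
}

# textbook OLS: R^2 = squared Pearson correlation, two-sided slope t-test
oracle_regression <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r2 <- r^2
  tstat <- r * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r2 = r2, p = p)
}

# independent re-implementation of balanced binning with the lower-class tie
# rule: assign provisional balanced labels by rank, then give every tied
# value the minimum provisional label found among its copies
oracle_equilibrated <- function(values, k) {
  n <- length(values)
  ord <- order(values)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  prov <- rep(seq_len(k), sizes)
  lab <- integer(n)
  for (v in unique(values[ord])) {
    idx <- which(values == v)
    ranks <- match(idx, ord)
    lab[idx] <- min(prov[ranks])
  }
  lab
}

# double-loop releve scoring oracle
oracle_trophic_scores <- function(releve, profiles, conversion) {
  sites <- unique(releve$site_id)
  classes <- sort(unique(profiles$class))
  out <- list()
  for (s in sites) {
    rs <- releve[releve$site_id == s, ]
    scores <- stats::setNames(numeric(length(classes)), classes)
    for (i in seq_len(nrow(rs))) {
      pr <- profiles[profiles$species == rs$species[i], ]
      if (nrow(pr) == 0) next
      ab <- unname(conversion[as.character(rs$bb_code[i])])
      for (j in seq_len(nrow(pr))) {
        cc <- as.character(pr$class[j])
        scores[cc] <- scores[cc] + ab * pr$weight[j]
      }
    }
    out[[s]] <- scores
  }
  out
}

# a small deterministic TIN with varied slopes for sampler tests
make_test_tin <- function(seed = 42, n = 40, extent = 100) {
  set.seed(seed)
  pts <- data.frame(
    x = c(0, extent, 0, extent, stats::runif(n, 0, extent)),
    y = c(0, 0, extent, extent, stats::runif(n, 0, extent))
  )
  pts$z <- 0.002 * pts$x + 0.001 * pts$y +
    0.0005 * extent * sin(pts$x / extent * pi) * cos(pts$y / extent * pi)
  tin_surface(pts, kind = "piezometric")
}
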