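# Exact convex-polygon geometry used by the synthetic-tissue generator.
# Polygons are n x 2 matrices of (x, y) vertices in um, convex, either
# orientation; all operations preserve convexity.

# clip polygon to the half-plane {x : a . x <= b} (Sutherland-Hodgman)
.clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  d <- poly %*% a - b
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    din <- d[i] <= 1e-12; djn <- d[j] <= 1e-12
    if (din) out <- rbind(out, poly[i, ])
    if (din != djn) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

.poly_signed_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]) / 2
}

.poly_area <- function(poly) abs(.poly_signed_area(poly))

.poly_centroid <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(colMeans(poly))
  j <- c(2:n, 1)
  cr <- poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((poly[, 1] + poly[j, 1]) * cr) / (6 * a),
    sum((poly[, 2] + poly[j, 2]) * cr) / (6 * a))
}

# inward offset (Minkowski erosion by a disk of radius r) of a convex
# polygon: move every edge line inward by r and re-intersect; this reduces
# every width -- in particular the minimum Feret diameter -- by exactly 2r
.poly_offset_in <- function(poly, r) {
  if (r <= 0) return(poly)
  n <- nrow(poly)
  cen <- .poly_centroid(poly)
  out <- poly
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-9) next
    nrm <- c(-e[2], e[1]) / len
    if (sum(nrm * (cen - poly[i, ])) < 0) nrm <- -nrm # make it inward
    # keep points with nrm . x >= nrm . p + r  <=>  (-nrm) . x <= -(...)
    out <- .clip_halfplane(out, -nrm, -(sum(nrm * poly[i, ]) + r))
    if (nrow(out) < 3) return(out)
  }
  out
}

# outward offset (Minkowski-like dilation) of a convex polygon: every edge
# line moved outward by r, re-intersected from an enclosing box
.poly_offset_out <- function(poly, r) {
  if (r <= 0) return(poly)
  n <- nrow(poly)
  cen <- .poly_centroid(poly)
  pad <- r + 1
  out <- matrix(c(min(poly[, 1]) - pad, min(poly[, 2]) - pad,
                  max(poly[, 1]) + pad, min(poly[, 2]) - pad,
                  max(poly[, 1]) + pad, max(poly[, 2]) + pad,
                  min(poly[, 1]) - pad, max(poly[, 2]) + pad),
                ncol = 2, byrow = TRUE)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-9) next
    nrm <- c(-e[2], e[1]) / len
    if (sum(nrm * (cen - poly[i, ])) < 0) nrm <- -nrm # inward normal
    # keep points with nrm . x >= nrm . p - r
    out <- .clip_halfplane(out, -nrm, -(sum(nrm * poly[i, ]) - r))
    if (nrow(out) < 3) break
  }
  out
}

# distance from point p to a convex polygon (0 if inside)
.point_poly_dist <- function(p, poly) {
  n <- nrow(poly)
  if (n == 0) return(Inf)
  if (n == 1) return(sqrt(sum((p - poly[1, ])^2)))
  dmin <- Inf
  inside <- TRUE
  sgn <- sign(.poly_signed_area(poly))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    w <- p - poly[i, ]
    len2 <- sum(e^2)
    t <- if (len2 > 0) max(0, min(1, sum(w * e) / len2)) else 0
    proj <- poly[i, ] + t * e
    dmin <- min(dmin, sqrt(sum((p - proj)^2)))
    if (sgn * (e[1] * w[2] - e[2] * w[1]) < 0) inside <- FALSE
  }
  if (inside) 0 else dmin
}

# scale polygon about its centroid
.poly_scale <- function(poly, s) {
  cen <- .poly_centroid(poly)
  sweep(sweep(poly, 2, cen, "-") * s, 2, cen, "+")
}

# Feret diameters of polygon vertices: c(max, min, angle)
.poly_feret <- function(poly) .feret_of_points(poly)

# raster pixel (row, col) indices whose centres fall inside a convex
# polygon; pixel centre of (r, c) sits at ((c-1)*mpp, (r-1)*mpp)
.poly_raster <- function(poly, mpp, nr, nc) {
  if (nrow(poly) < 3) return(matrix(integer(0), ncol = 2))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  c0 <- max(1L, floor(xr[1] / mpp) + 1L)
  c1 <- min(nc, ceiling(xr[2] / mpp) + 1L)
  r0 <- max(1L, floor(yr[1] / mpp) + 1L)
  r1 <- min(nr, ceiling(yr[2] / mpp) + 1L)
  if (c1 < c0 || r1 < r0) return(matrix(integer(0), ncol = 2))
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  x <- (cc - 1) * mpp; y <- (rr - 1) * mpp
  keep <- rep(TRUE, length(x))
  n <- nrow(poly)
  sgn <- sign(.poly_signed_area(poly))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    keep <- keep &
      sgn * (e[1] * (y - poly[i, 2]) - e[2] * (x - poly[i, 1])) >= 0
    if (!any(keep)) break
  }
  cbind(row = rr[keep], col = cc[keep])
}

# raster of an ellipse (centre cx/cy, semi-axes a/b, rotation theta)
.ellipse_raster <- function(cx, cy, a, b, theta, mpp, nr, nc) {
  ext <- max(a, b)
  c0 <- max(1L, floor((cx - ext) / mpp) + 1L)
  c1 <- min(nc, ceiling((cx + ext) / mpp) + 1L)
  r0 <- max(1L, floor((cy - ext) / mpp) + 1L)
  r1 <- min(nr, ceiling((cy + ext) / mpp) + 1L)
  if (c1 < c0 || r1 < r0) return(matrix(integer(0), ncol = 2))
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  x <- (cc - 1) * mpp - cx; y <- (rr - 1) * mpp - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rr[keep], col = cc[keep])
}

.disk_raster <- function(cx, cy, r, mpp, nr, nc)
  .ellipse_raster(cx, cy, r, r, 0, mpp, nr, nc)

# Voronoi cell of seed i among seeds (k x 2), clipped to rect [0,W]x[0,H];
# only the `neigh` nearest other seeds are used as bisector constraints.
.voronoi_cell <- function(i, seeds, W, H, neigh = 40L) {
  p <- seeds[i, ]
  poly <- matrix(c(0, 0, W, 0, W, H, 0, H), ncol = 2, byrow = TRUE)
  d2 <- (seeds[, 1] - p[1])^2 + (seeds[, 2] - p[2])^2
  ord <- order(d2)
  ord <- ord[ord != i]
  for (j in utils::head(ord, neigh)) {
    q <- seeds[j, ]
    a <- q - p
    b <- sum(a * (p + q) / 2)
    poly <- .clip_halfplane(poly, a, b)
    if (nrow(poly) < 3) break
  }
  poly
}

# full tessellation with `iters` Lloyd relaxation steps
.voronoi_tessellate <- function(seeds, W, H, iters = 8L) {
  n <- nrow(seeds)
  for (k in seq_len(iters)) {
    polys <- lapply(seq_len(n), .voronoi_cell, seeds = seeds, W = W, H = H)
    seeds <- do.call(rbind, lapply(polys, .poly_centroid))
  }
  lapply(seq_len(n), .voronoi_cell, seeds = seeds, W = W, H = H)
}

# HSB (deg, pct, pct) -> RGB in [0, 255]
.hsb_to_rgb <- function(h, s, b) {
  s <- s / 100; v <- b / 100
  c <- v * s
  hp <- (h %% 360) / 60
  x <- c * (1 - abs(hp %% 2 - 1))
  rgb1 <- switch(floor(hp) %% 6 + 1,
                 c(c, x, 0), c(x, c, 0), c(0, c, x),
                 c(0, x, c), c(x, 0, c), c(c, 0, x))
  (rgb1 + (v - c)) * 255
}
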