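# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately naive (exhaustive scans, brute force) and share no code with
# the implementation paths they check.

# ---- brute-force Feret oracle: angular scan over hull/corner points ----
# pts: n x 2 matrix of (x, y) points (e.g. pixel corners)
feret_bruteforce <- function(pts, step_deg = 0.01) {
  if (nrow(pts) > 800) {
    # keep only directional extremes over a fine fan; the width error this
    # introduces is below (1 - cos(0.25 deg)) * radius, orders of magnitude
    # under the comparison tolerance
    fan <- seq(0, 2 * pi, length.out = 1441)
    proj <- pts %*% rbind(cos(fan), sin(fan))
    keep <- unique(as.vector(apply(proj, 2, which.max)))
    pts <- pts[keep, , drop = FALSE]
  }
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  # width in the direction perpendicular to angle th: project onto (cos, sin)
  w <- numeric(length(th))
  chunk <- 2000
  for (s in seq(1, length(th), by = chunk)) {
    ii <- s:min(s + chunk - 1, length(th))
    proj <- pts %*% rbind(cos(th[ii]), sin(th[ii]))
    w[ii] <- apply(proj, 2, max) - apply(proj, 2, min)
  }
  c(max = max(w), min = min(w))
}

# corner points of a pixel set given as (row, col) matrix, 0-based geometry
pixel_corners_of <- function(rc) {
  x <- rc[, 2] - 1; y <- rc[, 1] - 1
  cbind(c(x, x + 1, x, x + 1), c(y, y, y + 1, y + 1))
}

# ---- brute-force contact oracle: full all-pairs pixel distances ----
contacts_bruteforce <- function(cm_ids, cap_ids, labels, max_um, mpp) {
  out <- data.frame(cm_id = integer(0), n_contacts = integer(0))
  for (cm in cm_ids) {
    p1 <- which(labels == cm, arr.ind = TRUE)
    n <- 0L
    for (cap in cap_ids) {
      p2 <- which(labels == cap, arr.ind = TRUE)
      if (!nrow(p1) || !nrow(p2)) next
      d2 <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
      if (sqrt(min(d2)) * mpp <= max_um) n <- n + 1L
    }
    out <- rbind(out, data.frame(cm_id = cm, n_contacts = n))
  }
  out
}

# ---- exhaustive Otsu oracle: scan all 256 candidate thresholds ----
otsu_bruteforce <- function(x) {
  v <- as.vector(x)
  v <- (v - min(v)) / diff(range(v))
  bins <- pmin(255L, as.integer(v * 256))
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  mids <- (0:255 + 0.5) / 256
  best <- -1; bt <- 0
  for (t in 1:255) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:t] * mids[1:t]) / w0
    m1 <- sum(p[(t + 1):256] * mids[(t + 1):256]) / w1
    s <- w0 * w1 * (m0 - m1)^2
    if (s > best) { best <- s; bt <- mids[t] + 1 / 512 }
  }
  bt
}

# ---- plateau-aware steepest-descent watershed oracle -------------------
# Exhaustive simulation: every pixel follows the strictly lowest
# 4-neighbour (plateaus resolved by BFS to their lower exits) down to a
# regional minimum. Returns per-pixel basin label (0 where the reachable
# minimum is not unique), an ambiguity mask, and a taint mask marking
# pixels whose descent path runs through a pixel the watershed under test
# labelled as a line (there the two conventions legitimately differ).
descent_oracle <- function(relief, lines = NULL) {
  nr <- nrow(relief); nc <- ncol(relief); npx <- nr * nc
  v <- as.vector(relief)
  L <- if (is.null(lines)) logical(npx) else as.vector(lines)
  nbs <- function(i) {
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    out <- c()
    if (r > 1) out <- c(out, i - 1)
    if (r < nr) out <- c(out, i + 1)
    if (c > 1) out <- c(out, i - nr)
    if (c < nc) out <- c(out, i + nr)
    out
  }
  basins <- vector("list", npx); taint <- logical(npx)
  minid <- integer(npx); cur <- 0L; seen <- logical(npx)
  for (i in seq_len(npx)) {
    if (seen[i]) next
    zone <- i; stack <- i; seen[i] <- TRUE; is_min <- TRUE
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (q in nbs(p)) {
        if (v[q] == v[p] && !seen[q]) {
          seen[q] <- TRUE; zone <- c(zone, q); stack <- c(stack, q)
        }
        if (v[q] < v[p]) is_min <- FALSE
      }
    }
    if (is_min) { cur <- cur + 1L; minid[zone] <- cur }
  }
  resolve <- function(i) {
    if (!is.null(basins[[i]])) return(basins[[i]])
    if (minid[i] > 0) { basins[[i]] <<- minid[i]; return(minid[i]) }
    nb <- nbs(i); lower <- nb[v[nb] < v[i]]
    if (length(lower)) {
      steep <- lower[v[lower] == min(v[lower])]
    } else {
      stack <- i; vis <- c(i); exits <- c()
      while (length(stack)) {
        p <- stack[length(stack)]; stack <- stack[-length(stack)]
        for (q in nbs(p)) {
          if (v[q] == v[i] && !(q %in% vis)) {
            vis <- c(vis, q); stack <- c(stack, q)
          }
          if (v[q] < v[i]) exits <- c(exits, q)
        }
      }
      steep <- unique(exits)
    }
    res <- unique(unlist(lapply(steep, resolve)))
    basins[[i]] <<- res
    if (any(L[steep]) || any(taint[steep])) taint[i] <<- TRUE
    res
  }
  for (i in order(v)) resolve(i)
  lab <- integer(npx); amb <- logical(npx)
  for (i in seq_len(npx)) {
    b <- basins[[i]]
    if (length(b) == 1) lab[i] <- b else amb[i] <- TRUE
  }
  list(lab = matrix(lab, nr, nc), amb = matrix(amb, nr, nc),
       taint = matrix(taint, nr, nc), n_min = cur)
}

# multi-well integer relief: k separated quadratic wells on an n x n grid
multiwell_relief <- function(n, centers, scale = 3) {
  xs <- matrix(rep(1:n, n), n); ys <- t(xs)
  d2 <- sapply(seq_len(nrow(centers)), function(i)
    (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2)
  matrix(round(scale * apply(d2, 1, min)), n, n)
}

# ---- constructed label maps --------------------------------------------
# place a w x h pixel rectangle of label `id` into `labels` at (r0, c0)
put_rect <- function(labels, r0, c0, h, w, id) {
  labels[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- id
  labels
}

# random convex polygon (point cloud hull) with given radius, in um
random_convex_polygon <- function(radius, n_pts = 12) {
  ang <- sort(runif(n_pts, 0, 2 * pi))
  rad <- runif(n_pts, 0.4, 1) * radius
  cbind(rad * cos(ang), rad * sin(ang))
}

# rasterise a convex polygon (um coords) into a label matrix at mpp
rasterize_polygon <- function(poly, mpp, pad_px = 3) {
  poly[, 1] <- poly[, 1] - min(poly[, 1]) + pad_px * mpp
  poly[, 2] <- poly[, 2] - min(poly[, 2]) + pad_px * mpp
  nc <- ceiling(max(poly[, 1]) / mpp) + pad_px
  nr <- ceiling(max(poly[, 2]) / mpp) + pad_px
  lab <- matrix(0L, nr, nc)
  ctr <- colMeans(poly)
  h <- grDevices::chull(poly)
  hp <- poly[h, , drop = FALSE]
  m <- nrow(hp)
  for (r in 1:nr) for (cc in 1:nc) {
    x <- (cc - 1) * mpp; y <- (r - 1) * mpp
    inside <- TRUE
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      e <- hp[j, ] - hp[i, ]
      s <- e[1] * (y - hp[i, 2]) - e[2] * (x - hp[i, 1])
      ref <- e[1] * (ctr[2] - hp[i, 2]) - e[2] * (ctr[1] - hp[i, 1])
      if (s * ref < 0) { inside <- FALSE; break }
    }
    if (inside) lab[r, cc] <- 1L
  }
  lab
}

# rasterise a rotated a x b um rectangle (centred) at mpp, angle degrees
rasterize_rect <- function(a, b, angle_deg, mpp) {
  th <- angle_deg * pi / 180
  ext <- (abs(a * cos(th)) + abs(b * sin(th))) / 2 + 2 * mpp
  eyt <- (abs(a * sin(th)) + abs(b * cos(th))) / 2 + 2 * mpp
  nc <- ceiling(2 * ext / mpp); nr <- ceiling(2 * eyt / mpp)
  lab <- matrix(0L, nr, nc)
  cx <- (nc - 1) / 2 * mpp; cy <- (nr - 1) / 2 * mpp
  for (r in 1:nr) for (cc in 1:nc) {
    x <- (cc - 1) * mpp - cx; y <- (r - 1) * mpp - cy
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    if (abs(u) <= a / 2 && abs(v) <= b / 2) lab[r, cc] <- 1L
  }
  lab
}

# ---- cached synthetic fixtures (shared across test files) --------------
.fixture_cache <- new.env(parent = emptyenv())

cached_tissue <- function(key, spec) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_tissue(spec)
  .fixture_cache[[key]]
}

standard_tissue <- function() {
  cached_tissue("std", tissue_spec(seed = 11, noise_sd = 0,
                                   field_size_um = c(150, 110)))
}

edgecase_tissue <- function() {
  cached_tissue("edge", tissue_spec(seed = 5, noise_sd = 0,
                                    include_edge_cases = TRUE,
                                    field_size_um = c(200, 150)))
}

dense_tissue <- function() {
  cached_tissue("dense", tissue_spec(seed = 6, noise_sd = 0,
                                     dense_packing = TRUE,
                                     capillary_density = 0.3,
                                     field_size_um = c(150, 110)))
}

cached_analysis <- function(key, fun) {
  k <- paste0("an_", key)
  if (is.null(.fixture_cache[[k]])) .fixture_cache[[k]] <- fun()
  .fixture_cache[[k]]
}

# map ground-truth structures to pipeline basins by majority vote
majority_basin <- function(labels, truth_map, id) {
  bl <- labels[truth_map == id]
  bl <- bl[bl > 0]
  if (!length(bl)) return(NA_integer_)
  as.integer(names(sort(table(bl), decreasing = TRUE))[1])
}
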