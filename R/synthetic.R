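#' Specification of a synthetic cardiac tissue fixture
#'
#' Describes a simulated histology field: a Lloyd-relaxed Voronoi
#' tessellation emulating cross-sectioned cardiomyocytes, separated by a
#' pale reticular boundary network, with capillary lumens at cell junctions
#' and elliptical nuclei inside a subset of cells. Every structure carries
#' exact analytic ground truth (polygon/ellipse geometry, classes, contact
#' graph), which makes the whole analysis pipeline testable without any
#' real slide.
#'
#' @param field_size_um Field width and height in um.
#' @param microns_per_pixel Calibration of the rendered images.
#' @param n_cells Number of cells; `NULL` derives it from the field area and
#'   the diameter distribution (near-hexagonal packing).
#' @param cell_diameter_um `c(mean, sd)` of the target minimum Feret
#'   diameter (um) of interior cells. Targets are sampled from
#'   `diameter_dist`, truncated to `mean +/- 2.5 sd` and never below
#'   `min_cell_diameter_um`; a cell can only be shrunk towards its target,
#'   never grown beyond the space the tessellation gives it.
#' @param diameter_dist `"normal"` or `"lognormal"`.
#' @param min_cell_diameter_um Lower truncation of the diameter targets
#'   (default 11 um), which keeps every generated interior myocyte
#'   unambiguously above the 60 um^2 cardiomyocyte area threshold even
#'   after rasterisation and watershed-line losses.
#' @param capillary_density Probability that a cell junction hosts a
#'   capillary lumen (default 0.85, giving roughly 1.7 capillaries and
#'   3 capillary contacts per cell, matching healthy myocardium).
#' @param nucleus_fraction Fraction of eligible cardiomyocytes (interior,
#'   polygon area >= 140 um^2) given a visible nucleus (default 0.32; in
#'   cross sections most myocyte profiles miss the nucleus).
#' @param noise_sd Gaussian intensity noise, in 8-bit grey levels (scaled
#'   to the [0, 1] range for fluorescence renders). Default 2.
#' @param seed Integer; a fixed seed gives byte-identical geometry, ground
#'   truth and renders.
#' @param aspect_ratio Cell elongation factor along x (1 = isotropic cross
#'   sections; > 1 emulates longitudinally cut cells).
#' @param boundary_gap_um Width of the boundary network between adjacent
#'   cells (um); each cell is eroded by half this amount, so a cell's true
#'   MinFeret equals its target exactly whenever the target fits.
#' @param dense_packing Ignore the diameter targets and keep every cell at
#'   the full size its tessellation slot allows, so the boundary network is
#'   a uniform thin band. Used for expression fixtures, where a cell's
#'   watershed basin must coincide with its rendered footprint.
#' @param include_edge_cases Inject deliberate boundary-case structures
#'   (a below-threshold cell, unstained/pale/dim cells, an oversized and an
#'   undersized nucleus, an undersized capillary) used to exercise each
#'   classification filter on both sides of its boundary.
#' @param expression_fractions Per-cell marker-positive area fractions
#'   cycled over cardiomyocytes for expression-role fluorescence renders.
#' @return A `tissue_spec`.
#' @export
tissue_spec <- function(field_size_um = c(250, 180),
                        microns_per_pixel = 0.25,
                        n_cells = NULL,
                        cell_diameter_um = c(mean = 14, sd = 2),
                        diameter_dist = c("normal", "lognormal"),
                        min_cell_diameter_um = 11,
                        capillary_density = 0.85,
                        nucleus_fraction = 0.32,
                        noise_sd = 2,
                        seed = 1,
                        aspect_ratio = 1,
                        boundary_gap_um = 1.2,
                        dense_packing = FALSE,
                        include_edge_cases = FALSE,
                        expression_fractions = c(0, 0.25, 0.5, 1.0)) {
  diameter_dist <- match.arg(diameter_dist)
  stopifnot(length(field_size_um) == 2, all(field_size_um > 0),
            microns_per_pixel > 0, length(cell_diameter_um) == 2,
            cell_diameter_um[1] > 0, cell_diameter_um[2] >= 0,
            capillary_density >= 0, capillary_density <= 1,
            nucleus_fraction >= 0, nucleus_fraction <= 1,
            noise_sd >= 0, aspect_ratio >= 1, boundary_gap_um > 0)
  if (!is.null(n_cells)) {
    n_cells <- as.integer(n_cells)
    if (n_cells < 1) stop("n_cells must be at least 1")
    # near-hexagonal packing feasibility
    if (n_cells * 0.55 * cell_diameter_um[1]^2 > prod(field_size_um))
      stop("infeasible packing: too many cells for the field")
  }
  structure(list(
    field_size_um = as.numeric(field_size_um),
    microns_per_pixel = microns_per_pixel,
    n_cells = n_cells,
    cell_diameter_um = unname(as.numeric(cell_diameter_um)),
    diameter_dist = diameter_dist,
    min_cell_diameter_um = min_cell_diameter_um,
    capillary_density = capillary_density,
    nucleus_fraction = nucleus_fraction,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    aspect_ratio = aspect_ratio,
    boundary_gap_um = boundary_gap_um,
    dense_packing = isTRUE(dense_packing),
    include_edge_cases = isTRUE(include_edge_cases),
    expression_fractions = expression_fractions
  ), class = "tissue_spec")
}

# evaluate expr with a local RNG stream; the global stream is untouched
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# nearest point of a convex polygon to p, with its distance
.nearest_point <- function(p, poly) {
  n <- nrow(poly)
  best <- c(Inf, NA, NA)
  sgn <- sign(.poly_signed_area(poly))
  inside <- TRUE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    w <- p - poly[i, ]
    len2 <- sum(e^2)
    t <- if (len2 > 0) max(0, min(1, sum(w * e) / len2)) else 0
    q <- poly[i, ] + t * e
    d <- sqrt(sum((p - q)^2))
    if (d < best[1]) best <- c(d, q)
    if (sgn * (e[1] * w[2] - e[2] * w[1]) < 0) inside <- FALSE
  }
  list(dist = if (inside) 0 else best[1], point = best[2:3])
}

# inward offset that skips edges lying on the field rectangle, so border
# cells keep touching the image edge (they are excluded as partial cells)
.offset_skip_rect <- function(poly, r, W, H, tol = 1e-6) {
  n <- nrow(poly)
  cen <- .poly_centroid(poly)
  out <- poly
  on_rect <- function(a, b) {
    (abs(a[1]) < tol && abs(b[1]) < tol) |
    (abs(a[1] - W) < tol && abs(b[1] - W) < tol) |
    (abs(a[2]) < tol && abs(b[2]) < tol) |
    (abs(a[2] - H) < tol && abs(b[2] - H) < tol)
  }
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (on_rect(poly[i, ], poly[j, ])) next
    e <- poly[j, ] - poly[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-9) next
    nrm <- c(-e[2], e[1]) / len
    if (sum(nrm * (cen - poly[i, ])) < 0) nrm <- -nrm
    out <- .clip_halfplane(out, -nrm, -(sum(nrm * poly[i, ]) + r))
    if (nrow(out) < 3) return(out)
  }
  out
}

#' Generate a synthetic tissue with exact ground truth
#'
#' Seeds are placed uniformly, relaxed by 8 Lloyd iterations of the Voronoi
#' tessellation (computed exactly by half-plane intersection), and each
#' interior cell is scaled about its centroid towards a sampled MinFeret
#' target, then eroded by half the boundary gap -- erosion of a convex
#' polygon by a disk reduces its MinFeret by exactly the gap width, so the
#' realised true MinFeret equals the sampled target whenever the
#' tessellation leaves room. Border cells are not scaled and keep touching
#' the field edge. Capillary disks are placed at cell junctions; adjacent
#' cells are chord-clipped so that every disk-cell gap is either about
#' 1.2-1.5 um (an unambiguous contact under the 2 um rule, and wide
#' enough that rasterised disk and cell pixels never become 8-adjacent)
#' or at least 2.7 um (an unambiguous non-contact). Nuclei are ellipses fitted
#' inside eligible cells.
#'
#' @param spec A [tissue_spec()].
#' @return A `tissue` object: `$spec`, `$polygons` (final cell vertices),
#'   `$cells`, `$nuclei`, `$capillaries`, `$contacts` (ground-truth tables),
#'   `$label_map` (true instance raster: cells, then nuclei, then
#'   capillaries; the boundary network is background 0), `$width_px`,
#'   `$height_px`. Instance ids are shared between tables and label map.
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  .with_seed(spec$seed, .generate_tissue_impl(spec))
}

.generate_tissue_impl <- function(spec) {
  W <- spec$field_size_um[1]; H <- spec$field_size_um[2]
  mpp <- spec$microns_per_pixel
  gap <- spec$boundary_gap_um
  mu <- spec$cell_diameter_um[1]; sdv <- spec$cell_diameter_um[2]
  ar <- spec$aspect_ratio
  n <- spec$n_cells
  if (is.null(n)) {
    # density chosen so the raw tessellation leaves roughly two sd of
    # headroom over the requested mean: realised diameters are
    # min(target, available), so ample headroom keeps the realised mean on
    # target; 0.89 is the packing factor of relaxed Voronoi cells
    n <- max(1L, as.integer(round(W * H / (0.89 * (mu + 2 * sdv + gap)^2))))
  }

  # tessellate in a domain squeezed along x by the aspect ratio, then map
  # back, which elongates cells by `ar` along x
  Ws <- W / ar
  seeds <- cbind(runif(n, 0, Ws), runif(n, 0, H))
  polys0 <- if (n == 1) {
    list(matrix(c(0, 0, Ws, 0, Ws, H, 0, H), ncol = 2, byrow = TRUE))
  } else {
    .voronoi_tessellate(seeds, Ws, H, iters = 8L)
  }
  if (ar != 1) polys0 <- lapply(polys0, function(p) { p[, 1] <- p[, 1] * ar; p })

  border <- vapply(polys0, function(p) {
    any(p[, 1] < 1e-6 | p[, 1] > W - 1e-6 |
        p[, 2] < 1e-6 | p[, 2] > H - 1e-6)
  }, TRUE)

  # sample MinFeret targets
  lo <- max(spec$min_cell_diameter_um, mu - 2.5 * sdv)
  hi <- mu + 2.5 * sdv
  draw_target <- function(k) {
    if (sdv == 0) return(rep(mu, k))
    x <- if (spec$diameter_dist == "normal") {
      rnorm(k, mu, sdv)
    } else {
      sl2 <- log(1 + (sdv / mu)^2)
      exp(rnorm(k, log(mu) - sl2 / 2, sqrt(sl2)))
    }
    pmin(hi, pmax(lo, x))
  }
  targets <- draw_target(n)

  # rank-match targets to the space the tessellation makes available
  # (largest target to the roomiest interior cell): realised diameters are
  # min(target, available), so matching removes the truncation bias that
  # random assignment would put on the realised mean
  rawf <- vapply(polys0, function(p) .poly_feret(p)[2], 0)
  interior_idx <- which(!border)
  if (length(interior_idx) > 1) {
    avail_ord <- interior_idx[order(rawf[interior_idx])]
    targets[avail_ord] <- sort(targets[interior_idx])
  }

  # deliberate boundary-case cells: picked among interior cells nearest the
  # field centre (deterministic given the tessellation)
  style <- rep("normal", n)
  if (spec$include_edge_cases) {
    cen <- do.call(rbind, lapply(polys0, .poly_centroid))
    d2c <- (cen[, 1] - W / 2)^2 + (cen[, 2] - H / 2)^2
    cand <- order(d2c)
    cand <- cand[!border[cand]]
    picks <- utils::head(cand, 4)
    for (k in seq_along(picks)) {
      style[picks[k]] <- c("tiny", "pale", "dim", "lumen")[k]
    }
    targets[style == "tiny"] <- 6.5
  }

  # shrink interior cells to target + gap, then erode by gap/2
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    if (border[i]) {
      polys[[i]] <- .offset_skip_rect(polys0[[i]], gap / 2, W, H)
    } else {
      s <- if (spec$dense_packing) 1
           else min(1, (targets[i] + gap) / rawf[i])
      polys[[i]] <- .poly_offset_in(.poly_scale(polys0[[i]], s), gap / 2)
    }
  }

  # capillaries at interior junction vertices of the raw tessellation
  verts <- do.call(rbind, polys0)
  key <- paste(round(verts[, 1], 3), round(verts[, 2], 3))
  shared <- names(which(table(key) >= 2))
  vm <- do.call(rbind, lapply(strsplit(shared, " "), as.numeric))
  if (is.null(vm)) vm <- matrix(numeric(0), ncol = 2)
  if (nrow(vm)) {
    inter <- vm[, 1] > 2 & vm[, 1] < W - 2 & vm[, 2] > 2 & vm[, 2] < H - 2
    vm <- vm[inter, , drop = FALSE]
    vm <- vm[order(vm[, 2], vm[, 1]), , drop = FALSE]
  }
  caps <- data.frame(x_um = numeric(0), y_um = numeric(0), r_um = numeric(0),
                     kind = character(0))
  tiny_cap_placed <- FALSE
  for (k in seq_len(nrow(vm))) {
    u <- runif(1); r <- runif(1, 1.0, 1.8)
    if (u > spec$capillary_density) {
      # optionally reuse one skipped junction for the undersized capillary
      if (spec$include_edge_cases && !tiny_cap_placed) {
        caps <- rbind(caps, data.frame(x_um = vm[k, 1], y_um = vm[k, 2],
                                       r_um = 0.3, kind = "tiny"))
        tiny_cap_placed <- TRUE
      }
      next
    }
    if (nrow(caps) && any((caps$x_um - vm[k, 1])^2 +
                          (caps$y_um - vm[k, 2])^2 <
                          (caps$r_um + r + 1.0)^2)) next
    caps <- rbind(caps, data.frame(x_um = vm[k, 1], y_um = vm[k, 2],
                                   r_um = r, kind = "normal"))
  }

  # chord-clip cells so every disk-cell gap is unambiguous under the 2 um
  # contact rule: about 1.2-1.5 um (a contact, wide enough that rasterised
  # disk and cell pixels never become 8-adjacent, narrow enough that the
  # watershed still measures the pair within the bound) or >= 2.7 um
  # (non-contact); only cells whose circumradius can reach the disk need
  # checking
  cell_cen <- do.call(rbind, lapply(polys, function(p)
    if (nrow(p) >= 3) .poly_centroid(p) else c(NA_real_, NA_real_)))
  cell_rad <- vapply(seq_len(n), function(i) {
    p <- polys[[i]]
    if (nrow(p) < 3) return(0)
    sqrt(max((p[, 1] - cell_cen[i, 1])^2 + (p[, 2] - cell_cen[i, 2])^2))
  }, 0)
  near_cells <- function(v, reach) {
    which(!is.na(cell_cen[, 1]) &
          sqrt((cell_cen[, 1] - v[1])^2 + (cell_cen[, 2] - v[2])^2) <=
            reach + cell_rad)
  }
  if (nrow(caps)) {
    for (round_i in 1:3) {
      changed <- FALSE
      for (ci in seq_len(nrow(caps))) {
        v <- c(caps$x_um[ci], caps$y_um[ci]); r <- caps$r_um[ci]
        for (i in near_cells(v, r + 3)) {
          if (nrow(polys[[i]]) < 3) next
          np <- .nearest_point(v, polys[[i]])
          g <- np$dist - r
          if (g >= 2.7) next
          dirv <- np$point - v
          nd <- sqrt(sum(dirv^2))
          if (nd < 1e-9) next
          dirv <- dirv / nd
          cut <- if (g < 1.5) r + 1.2 else r + 2.9
          if (np$dist >= cut) next
          polys[[i]] <- .clip_halfplane(polys[[i]], -dirv,
                                        -(sum(dirv * v) + cut))
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  # ground-truth cell table from the final polygons
  nr <- as.integer(round(H / mpp)); nc <- as.integer(round(W / mpp))
  cells <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- polys[[i]]
    f <- if (nrow(p) >= 3) .poly_feret(p) else c(0, 0, 0)
    cenp <- if (nrow(p) >= 3) .poly_centroid(p) else c(NA, NA)
    data.frame(cell_id = i, style = style[i], border = border[i],
               area_um2 = .poly_area(p), feret_max_um = f[1],
               feret_min_um = f[2], centroid_x_um = cenp[1],
               centroid_y_um = cenp[2], target_minferet_um = targets[i])
  }))
  cells$class_brightfield <- ifelse(
    cells$border, "removed",
    ifelse(cells$style == "normal" & cells$area_um2 >= 90, "cardiomyocyte",
           "removed"))
  # fluorescence classification is size-only on watershed basins, and a
  # basin is the cell's influence zone (cell plus its share of the bright
  # boundary network, out to the midline towards its neighbours), which
  # with this generator's packing is always far above the 60 um^2 floor:
  # every interior cell is a fluorescence cardiomyocyte, whatever its
  # stain style; the below-floor side of the size rule is exercised by the
  # small capillary-lumen basins
  cells$class_fluorescence <- ifelse(cells$border, "removed",
                                     "cardiomyocyte")
  is_cm_bf <- cells$class_brightfield == "cardiomyocyte"

  # expression fractions cycled over fluorescence cardiomyocytes
  cells$expression_fraction <- 0
  idx_cm <- which(cells$class_fluorescence == "cardiomyocyte")
  if (length(idx_cm) && length(spec$expression_fractions))
    cells$expression_fraction[idx_cm] <-
      spec$expression_fractions[((seq_along(idx_cm) - 1) %%
                                 length(spec$expression_fractions)) + 1]

  # nuclei inside eligible cardiomyocytes (area >= 140 so the cell stays
  # above the CM threshold even with its nucleus carved out of the basin)
  eligible <- which(is_cm_bf & cells$area_um2 >= 140)
  nuclei <- data.frame()
  big_done <- FALSE; tiny_done <- FALSE
  if (spec$include_edge_cases && length(eligible) >= 3) {
    ord <- eligible[order(-cells$feret_min_um[eligible])]
    big_host <- ord[1]; tiny_host <- ord[2]
  } else big_host <- tiny_host <- NA
  for (i in eligible) {
    kind <- if (!is.na(big_host) && i == big_host) "big"
            else if (!is.na(tiny_host) && i == tiny_host) "tiny"
            else "normal"
    if (kind == "normal" && runif(1) > spec$nucleus_fraction) next
    if (kind == "big") {
      a <- 6.6; b <- 5.9           # ~122 um^2, above the 100 um^2 ceiling
    } else if (kind == "tiny") {
      a <- 1.1; b <- 0.9           # ~3.1 um^2, below the 6 um^2 floor
    } else {
      a <- runif(1, 2.0, 2.8); b <- runif(1, 1.5, 2.1)
    }
    theta <- runif(1, 0, pi)
    cen <- c(cells$centroid_x_um[i], cells$centroid_y_um[i])
    # shrink the ellipse until it fits 1.2 um inside the cell polygon
    fits <- function(a, b) {
      p <- polys[[i]]
      m <- nrow(p)
      ok <- TRUE
      for (e in seq_len(m)) {
        j <- if (e == m) 1L else e + 1L
        ed <- p[j, ] - p[e, ]
        len <- sqrt(sum(ed^2)); if (len < 1e-9) next
        nrm <- c(-ed[2], ed[1]) / len
        if (sum(nrm * (.poly_centroid(p) - p[e, ])) < 0) nrm <- -nrm
        # support of rotated ellipse in direction -nrm
        sup <- sqrt((a * cos(theta) * nrm[1] + a * sin(theta) * nrm[2])^2 +
                    (b * sin(theta) * nrm[1] - b * cos(theta) * nrm[2])^2)
        margin <- sum(nrm * (cen - p[e, ])) - sup
        if (margin < 1.2) { ok <- FALSE; break }
      }
      ok
    }
    sc <- 1
    while (sc > 0.4 && !fits(a * sc, b * sc)) sc <- sc - 0.1
    if (kind != "normal" && sc < 1) next   # boundary-case sizes are exact
    if (sc <= 0.4) next
    a <- a * sc; b <- b * sc
    if (pi * a * b < 8 && kind == "normal") next
    nuclei <- rbind(nuclei, data.frame(
      host_cell_id = i, cx_um = cen[1], cy_um = cen[2], a_um = a, b_um = b,
      theta = theta, area_um2 = pi * a * b, feret_max_um = 2 * a,
      feret_min_um = 2 * b, kind = kind,
      class = if (kind == "normal") "cm_nucleus" else "removed"))
    if (kind == "big") big_done <- TRUE
    if (kind == "tiny") tiny_done <- TRUE
  }

  # instance ids: cells 1..n, nuclei, then capillaries
  if (nrow(nuclei)) nuclei$nucleus_id <- n + seq_len(nrow(nuclei))
  cap_off <- n + nrow(nuclei)
  if (nrow(caps)) {
    caps$cap_id <- cap_off + seq_len(nrow(caps))
    caps$area_um2 <- pi * caps$r_um^2
    caps$class <- ifelse(caps$kind == "normal", "capillary", "removed")
  }

  # exact contact graph (disk edge to polygon, 2 um rule)
  contacts <- data.frame(cap_id = integer(0), cell_id = integer(0),
                         gap_um = numeric(0))
  for (ci in seq_len(nrow(caps))) {
    v <- c(caps$x_um[ci], caps$y_um[ci])
    for (i in near_cells(v, caps$r_um[ci] + 2.1)) {
      if (nrow(polys[[i]]) < 3) next
      g <- .point_poly_dist(v, polys[[i]]) - caps$r_um[ci]
      if (g <= 2) contacts <- rbind(contacts, data.frame(
        cap_id = caps$cap_id[ci], cell_id = i, gap_um = max(0, g)))
    }
  }

  # true instance raster
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(n)) {
    rc <- .poly_raster(polys[[i]], mpp, nr, nc)
    if (nrow(rc)) lab[cbind(rc[, 1], rc[, 2])] <- i
  }
  for (k in seq_len(nrow(nuclei))) {
    rc <- .ellipse_raster(nuclei$cx_um[k], nuclei$cy_um[k], nuclei$a_um[k],
                          nuclei$b_um[k], nuclei$theta[k], mpp, nr, nc)
    if (nrow(rc)) lab[cbind(rc[, 1], rc[, 2])] <- nuclei$nucleus_id[k]
  }
  for (k in seq_len(nrow(caps))) {
    rc <- .disk_raster(caps$x_um[k], caps$y_um[k], caps$r_um[k], mpp, nr, nc)
    if (nrow(rc)) lab[cbind(rc[, 1], rc[, 2])] <- caps$cap_id[k]
  }

  structure(list(spec = spec, polygons = polys, cells = cells,
                 nuclei = nuclei, capillaries = caps, contacts = contacts,
                 label_map = lab, width_px = nc, height_px = nr),
            class = "tissue")
}

#' @export
print.tissue <- function(x, ...) {
  cat("synthetic tissue:", nrow(x$cells), "cells,",
      nrow(x$nuclei), "nuclei,", nrow(x$capillaries), "capillaries on a ",
      x$width_px, "x", x$height_px, "px field\n")
  print(table(brightfield = x$cells$class_brightfield))
  invisible(x)
}

#' Render a synthetic Gomori silver brightfield image
#'
#' Cells are filled with in-range reddish tones (hue 280-340 deg,
#' saturation 45-90\%, brightness 60-90\%; one colour per cell), the
#' boundary network with a uniform pale low-saturation silver tone (a
#' single connected flat zone, so it segments as one background basin),
#' capillary lumens near-white, and nuclei a dark blue-grey that fails
#' the brightness floor of the colour window. Gaussian noise of sd `spec$noise_sd` grey levels
#' is added and the image is quantised to 8 bits. Deterministic given the
#' spec seed.
#'
#' Boundary-case styles: `pale` low saturation, `dim` low brightness,
#' `lumen` unstained white (all out of the colour window), `tiny` a normal
#' reddish fill on a below-threshold cell.
#'
#' @param tissue A `tissue` from [generate_tissue()].
#' @return A brightfield [calibrated_image()].
#' @export
render_brightfield <- function(tissue) {
  stopifnot(inherits(tissue, "tissue"))
  spec <- tissue$spec
  .with_seed(spec$seed + 1L, {
    nr <- tissue$height_px; nc <- tissue$width_px
    lab <- tissue$label_map
    n <- nrow(tissue$cells)
    # pale silver boundary network, with a slightly darker 1-px reticulin
    # sheath hugging every structure: the relief crest then falls on the
    # sheath, so watershed lines trace it and cell basins coincide with
    # the rendered cell rasters
    # uniform pale silver background (boundary network)
    arr <- array(0, dim = c(nr, nc, 3))
    base <- c(211, 207, 205)
    for (k in 1:3) arr[, , k] <- matrix(base[k], nr, nc)
    # per-cell reddish fills
    cols <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      cols[i, ] <- switch(tissue$cells$style[i],
        pale = .hsb_to_rgb(300, 15, 85),
        dim = .hsb_to_rgb(300, 60, 45),
        lumen = c(250, 250, 252),
        .hsb_to_rgb(runif(1, 280, 340), runif(1, 45, 90), runif(1, 60, 90)))
    }
    maxid <- max(lab)
    lut <- matrix(0, maxid, 3)
    lut[seq_len(n), ] <- cols
    if (nrow(tissue$nuclei))
      lut[tissue$nuclei$nucleus_id, ] <- matrix(c(40, 40, 70),
                                                nrow(tissue$nuclei), 3,
                                                byrow = TRUE)
    if (nrow(tissue$capillaries))
      lut[tissue$capillaries$cap_id, ] <- matrix(c(250, 250, 252),
                                                 nrow(tissue$capillaries), 3,
                                                 byrow = TRUE)
    fg <- lab > 0
    for (k in 1:3) {
      ch <- arr[, , k]
      ch[fg] <- lut[lab[fg], k]
      arr[, , k] <- ch
    }
    if (spec$noise_sd > 0)
      arr <- arr + array(rnorm(length(arr), 0, spec$noise_sd), dim = dim(arr))
    arr <- round(pmin(pmax(arr, 0), 255))
    calibrated_image(arr, spec$microns_per_pixel, "brightfield")
  })
}

#' Render synthetic fluorescence channels
#'
#' The membrane (WGA) channel is bright over the boundary network and dark
#' inside cells, nuclei and unstained capillary lumens, so its watershed
#' recovers one basin per cell plus one small basin per capillary lumen
#' (removed from the cardiomyocyte class by the size rule). The nuclei
#' (DAPI) channel shows bright ellipses. The marker channel depends on
#' `marker_role`: `"endothelium"` renders the capillary disks (CD31),
#' `"intracellular_expression"` fills a centred, concentric sub-polygon of
#' each cardiomyocyte whose area fraction equals the cell's ground-truth
#' `expression_fraction`. Channels are quantised to 16 bits; noise of
#' `spec$noise_sd / 255` is added on the [0, 1] scale. Deterministic given
#' the spec seed.
#'
#' @param tissue A `tissue` from [generate_tissue()].
#' @param marker_role `"endothelium"` or `"intracellular_expression"`.
#' @return A [channel_set()] with channels `membrane`, `nuclei`, `marker`.
#' @export
render_fluorescence <- function(tissue,
                                marker_role = c("endothelium",
                                                "intracellular_expression")) {
  marker_role <- match.arg(marker_role)
  stopifnot(inherits(tissue, "tissue"))
  spec <- tissue$spec
  .with_seed(spec$seed + 2L, {
    nr <- tissue$height_px; nc <- tissue$width_px
    lab <- tissue$label_map
    n <- nrow(tissue$cells)
    mpp <- spec$microns_per_pixel
    # membranes (and the boundary network) are bright; cell interiors,
    # nuclei and unstained capillary lumens are dark
    membrane <- matrix(0.90, nr, nc)
    membrane[lab > 0] <- 0.05
    nuclei_ch <- matrix(0.03, nr, nc)
    if (nrow(tissue$nuclei)) for (id in tissue$nuclei$nucleus_id)
      nuclei_ch[lab == id] <- 0.90
    marker <- matrix(0.02, nr, nc)
    if (marker_role == "endothelium") {
      if (nrow(tissue$capillaries)) for (id in tissue$capillaries$cap_id)
        marker[lab == id] <- 0.90
    } else {
      # the watershed basin of a cell extends to the middle of the
      # membrane band, so fills are scaled from the half-gap-expanded
      # polygon: a fraction-1 cell covers its whole basin
      for (i in which(tissue$cells$expression_fraction > 0)) {
        f <- tissue$cells$expression_fraction[i]
        ext <- .poly_offset_out(tissue$polygons[[i]],
                                spec$boundary_gap_um / 2)
        sub <- if (f >= 1) ext else .poly_scale(ext, sqrt(f))
        rc <- .poly_raster(sub, mpp, nr, nc)
        if (nrow(rc)) marker[cbind(rc[, 1], rc[, 2])] <- 0.80
      }
    }
    q16 <- function(m) {
      if (spec$noise_sd > 0)
        m <- m + matrix(rnorm(length(m), 0, spec$noise_sd / 255), nrow(m))
      matrix(round(pmin(pmax(m, 0), 1) * 65535) / 65535, nrow(m))
    }
    channel_set(q16(membrane), q16(nuclei_ch), q16(marker), marker_role,
                mpp)
  })
}

#' Write a fixture set to disk
#'
#' Writes the brightfield PNG, a 3-page fluorescence TIFF (membrane,
#' nuclei, marker as 16-bit pages), ground-truth CSV tables and a JSON echo
#' of the spec. All outputs are byte-identical across runs with the same
#' spec.
#'
#' @param tissue A `tissue`.
#' @param dir Output directory (created if needed).
#' @param marker_role Marker role for the fluorescence render.
#' @return Invisibly, a named vector of the files written.
#' @export
write_fixture <- function(tissue, dir, marker_role = "endothelium") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bf <- render_brightfield(tissue)
  fl <- render_fluorescence(tissue, marker_role)
  p_bf <- file.path(dir, "brightfield.png")
  write_rgb_png(bf$pixels, p_bf)
  p_fl <- file.path(dir, "fluorescence.tif")
  stack <- EBImage::Image(array(c(t(fl$membrane), t(fl$nuclei), t(fl$marker)),
                                dim = c(ncol(fl$membrane),
                                        nrow(fl$membrane), 3)))
  EBImage::writeImage(stack, p_fl, type = "tiff", bits.per.sample = 16L)
  paths <- c(brightfield = p_bf, fluorescence = p_fl)
  for (nm in c("cells", "nuclei", "capillaries", "contacts")) {
    f <- file.path(dir, paste0("truth_", nm, ".csv"))
    write.csv(tissue[[nm]], f, row.names = FALSE)
    paths[nm] <- f
  }
  f <- file.path(dir, "spec.json")
  jsonlite::write_json(unclass(tissue$spec), f, auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths["spec"] <- f
  invisible(paths)
}
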