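test_that("auto_threshold separates a bimodal image like the exhaustive scan", {
  set.seed(21)
  lowpx <- pmax(0, pmin(255, rnorm(3000, 30, 10)))
  hipx <- pmax(0, pmin(255, rnorm(1000, 220, 10)))
  ch <- matrix(sample(c(lowpx, hipx)), 50, 80)
  mask <- auto_threshold(ch, "otsu")
  th <- attr(mask, "threshold")
  expect_gt(th, 60); expect_lt(th, 190)
  # the exhaustive inter-class-variance scan yields the same foreground
  # (between well-separated modes the variance curve has a plateau of
  # equivalent thresholds, so masks are compared rather than thresholds)
  th_bf <- otsu_bruteforce(ch) * diff(range(ch)) + min(ch)
  expect_gt(th_bf, 60); expect_lt(th_bf, 190)
  expect_identical(as.vector(mask), as.vector(ch > th_bf))
  # foreground recovers the bright mode with at most 1% misassignment
  truth <- ch > 125
  expect_lt(mean(mask != truth), 0.01)

  # binary image: foreground exactly the bright pixels
  bw <- matrix(c(0, 255)[1 + (runif(400) > 0.6)], 20, 20)
  mb <- auto_threshold(bw)
  expect_identical(as.vector(mb), as.vector(bw == 255))

  expect_error(auto_threshold(matrix(3, 5, 5)), "no contrast")

  # isodata variant also splits the modes
  mi <- auto_threshold(ch, "isodata")
  expect_lt(mean(mi != truth), 0.01)
})

# constructed channel set at 0.5 um/px, 60 x 60 px, with hand-built labels
# so the containment rules are exercised against exact cell footprints
fluo_scene <- function() {
  nr <- 60; nc <- 60
  mem <- matrix(0.9, nr, nc)
  mem[5:34, 5:34] <- 0.05        # cell 1: 30x30 px = 225 um^2
  mem[40:49, 40:49] <- 0.05      # cell 2: 10x10 px = 25 um^2 (< 60)
  lab <- matrix(0L, nr, nc)
  lab <- put_rect(lab, 5, 5, 30, 30, 1L)
  lab <- put_rect(lab, 40, 40, 10, 10, 2L)
  nuc <- matrix(0.02, nr, nc)
  nuc[10:14, 10:14] <- 0.95      # inside cell 1: 6.25 um^2 nucleus
  nuc[31:40, 20:24] <- 0.95      # straddles cell 1 edge: 40% inside
  mk <- matrix(0.02, nr, nc)
  mk[52:54, 10:12] <- 0.9        # outside cells: capillary 2.25 um^2
  mk[20:22, 20:22] <- 0.9        # fully inside cell 1: must be zeroed
  list(channels = channel_set(mem, nuc, mk, "endothelium", 0.5),
       labels = lab)
}

test_that("classify_fluo uses size-only CMs and containment rules", {
  sc <- fluo_scene()
  out <- classify_fluo(sc$channels, sc$labels, analysis_config("mouse"))
  cls <- out$classification
  expect_equal(sum(cls$class == "cardiomyocyte"), 1)
  # the 25 um^2 instance is below the floor
  expect_true(any(cls$class == "removed" & grepl("below", cls$reason)))
  # nucleus inside the CM is kept; the straddling component (40% inside)
  # is excluded as a non-CM nucleus
  expect_equal(sum(cls$class == "cm_nucleus"), 1)
  expect_true(any(grepl("nucleus outside cardiomyocytes", cls$reason)))
  # the marker component inside the CM footprint was zeroed before
  # component extraction: only the outside capillary survives
  expect_equal(sum(cls$class == "capillary"), 1)
  cap_id <- cls$instance_id[cls$class == "capillary"]
  cap_px <- which(out$labels == cap_id, arr.ind = TRUE)
  expect_true(all(cap_px[, 1] >= 52)) # the outside component
  # capillary mask and CM footprints are pixel-disjoint
  fp <- heartmorph:::.cm_footprints(sc$labels,
    cls$instance_id[cls$class == "cardiomyocyte"])
  expect_equal(sum(out$masks$marker & fp > 0), 0)
})

test_that("fluorescence CM classification is invariant to monotone rescaling", {
  sc <- fluo_scene()
  ch <- sc$channels
  cfg <- analysis_config("mouse")
  base <- classify_fluo(ch, sc$labels, cfg)$classification
  # squaring intensities is monotone: the same label map arises from the
  # rescaled membrane, and size-only classification is unchanged
  ch2 <- channel_set(ch$membrane^2, ch$nuclei, ch$marker, "endothelium", 0.5)
  lab2 <- watershed_segment(ch2$membrane, 0.1)
  lab1 <- watershed_segment(ch$membrane, 0.1)
  expect_equal(n_labels(lab2), n_labels(lab1))
  out2 <- classify_fluo(ch2, sc$labels, cfg)$classification
  expect_equal(sum(out2$class == "cardiomyocyte"),
               sum(base$class == "cardiomyocyte"))
})

test_that("oversized nuclei are rejected by the 100 um^2 ceiling", {
  nr <- 80; nc <- 80
  mem <- matrix(0.9, nr, nc)
  mem[3:70, 3:70] <- 0.05                 # one large interior cell
  nuc <- matrix(0.02, nr, nc)
  nuc[10:31, 10:31] <- 0.95               # 22x22 px = 121 um^2 > 100
  ch <- channel_set(mem, nuc, NULL, microns_per_pixel = 0.5)
  lab <- put_rect(matrix(0L, nr, nc), 3, 3, 68, 68, 1L)
  cls <- classify_fluo(ch, lab, analysis_config("mouse"))$classification
  expect_equal(sum(cls$class == "cm_nucleus"), 0)
  expect_true(any(grepl("nucleus outside size window", cls$reason)))
})

test_that("nucleus pixel totals never exceed the DAPI foreground", {
  tis <- standard_tissue()
  ch <- render_fluorescence(tis, "endothelium")
  lab <- watershed_segment(ch$membrane, 0.2)
  out <- classify_fluo(ch, lab, analysis_config("mouse"))
  nuc_ids <- out$classification$instance_id[
    out$classification$class == "cm_nucleus"]
  npx <- sum(out$labels %in% nuc_ids)
  expect_lte(npx, sum(out$masks$nuclei))
})

test_that("fluorescence counts match ground truth on a clean fixture", {
  tis <- standard_tissue()
  ch <- render_fluorescence(tis, "endothelium")
  an <- cached_analysis("std_fl", function()
    analyze_fluo(ch, analysis_config("mouse", watershed_tolerance = 0.2)))
  got <- table(factor(an$classification$class,
                      levels = c("cardiomyocyte", "cm_nucleus", "capillary")))
  expect_equal(unname(got["cardiomyocyte"]),
               sum(tis$cells$class_fluorescence == "cardiomyocyte"))
  expect_equal(unname(got["cm_nucleus"]), sum(tis$nuclei$class == "cm_nucleus"))
  expect_equal(unname(got["capillary"]),
               sum(tis$capillaries$class == "capillary"))
})
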