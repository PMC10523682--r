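test_that("rgb_to_hsb is the standard hexcone conversion", {
  expect_equal(unlist(rgb_to_hsb(255, 0, 0)), c(hue = 0, saturation = 100,
                                                brightness = 100))
  g <- rgb_to_hsb(128, 128, 128)
  expect_equal(g$hue, 0)
  expect_equal(g$saturation, 0)
  expect_equal(g$brightness, 128 / 255 * 100, tolerance = 1e-6)
  m <- rgb_to_hsb(255, 0, 255)
  expect_equal(m$hue, 300)
  expect_equal(m$saturation, 100)
  expect_error(rgb_to_hsb(256, 0, 0), "0, 255")
})

# build a brightfield image whose single instance has the given fill
fill_image <- function(rgb, nr = 20, nc = 20) {
  arr <- array(0, dim = c(nr, nc, 3))
  for (k in 1:3) arr[, , k] <- rgb[k]
  list(image = calibrated_image(arr, 0.5, "brightfield"),
       labels = put_rect(matrix(0L, nr, nc), 5, 5, 10, 10, 1L))
}

test_that("instance colour match uses per-channel medians in the window", {
  rng <- c(240, 360, 32, 100, 54, 100)
  # reddish-purple synthetic fill: H 320, S 70, B 78
  f <- fill_image(heartmorph:::.hsb_to_rgb(320, 70, 78))
  expect_true(instance_color_match(f$image, f$labels, 1, rng))
  # green fails the hue window
  f2 <- fill_image(heartmorph:::.hsb_to_rgb(120, 80, 80))
  expect_false(instance_color_match(f2$image, f2$labels, 1, rng))
  # pale instance fails the 54% brightness floor
  f3 <- fill_image(heartmorph:::.hsb_to_rgb(300, 70, 40))
  expect_false(instance_color_match(f3$image, f3$labels, 1, rng))
  # hue window does not wrap: pure red (hue 0) does not match
  f4 <- fill_image(c(255, 10, 10))
  expect_false(instance_color_match(f4$image, f4$labels, 1, rng))
  expect_error(instance_color_match(f$image, f$labels, 9, rng), "empty")
})

# A hand-built scene at 0.5 um/px (60 x 60 px = 30 x 30 um):
#  - label 1: reddish 18x18 px (81 um^2) interior -> cardiomyocyte
#  - label 2: reddish 20x11 px (55 um^2) -> below mouse floor, above human
#  - label 3: pale 3x3 px (2.25 um^2) outside CMs -> capillary
#  - label 4: dark 3x3 px inside label 1's footprint -> nucleus (2.25 um^2
#    is below the 6 um^2 floor, so use 5x5=6.25 um^2) -> cm_nucleus
#  - label 5: pale 2x1 px (0.5 um^2) -> artefact, below capillary floor
#  - label 6: reddish 18x18 on the border -> removed
gomori_scene <- function() {
  nr <- 60; nc <- 60
  arr <- array(0, dim = c(nr, nc, 3))
  base <- c(210, 206, 204)
  for (k in 1:3) arr[, , k] <- base[k]
  lab <- matrix(0L, nr, nc)
  red <- heartmorph:::.hsb_to_rgb(310, 70, 75)
  pale <- c(250, 250, 252)
  dark <- c(40, 40, 70)
  paint <- function(arr, r0, c0, h, w, col) {
    for (k in 1:3) arr[r0:(r0 + h - 1), c0:(c0 + w - 1), k] <- col[k]
    arr
  }
  lab <- put_rect(lab, 5, 5, 18, 18, 1L);  arr <- paint(arr, 5, 5, 18, 18, red)
  lab <- put_rect(lab, 5, 35, 11, 20, 2L); arr <- paint(arr, 5, 35, 11, 20, red)
  lab <- put_rect(lab, 40, 40, 3, 3, 3L);  arr <- paint(arr, 40, 40, 3, 3, pale)
  lab <- put_rect(lab, 10, 10, 5, 5, 4L);  arr <- paint(arr, 10, 10, 5, 5, dark)
  lab <- put_rect(lab, 30, 50, 1, 2, 5L);  arr <- paint(arr, 30, 50, 1, 2, pale)
  lab <- put_rect(lab, 43, 1, 18, 18, 6L); arr <- paint(arr, 43, 1, 18, 18, red)
  # relabel 4 inside 1: carve the nucleus out of the CM instance
  list(image = calibrated_image(arr, 0.5, "brightfield"), labels = lab)
}

test_that("classify_gomori applies colour, size, containment and border rules", {
  sc <- gomori_scene()
  cls <- classify_gomori(sc$image, sc$labels, analysis_config("mouse"))
  got <- setNames(cls$class, cls$instance_id)
  expect_equal(unname(got["1"]), "cardiomyocyte")
  expect_equal(unname(got["2"]), "removed") # 55 um^2 < 60 mouse floor
  expect_equal(unname(got["3"]), "capillary")
  expect_equal(unname(got["4"]), "cm_nucleus")
  expect_equal(unname(got["5"]), "removed") # 0.5 um^2 artefact
  expect_equal(unname(got["6"]), "removed") # partial cell at the border
  expect_true(all(nzchar(cls$reason[cls$class == "removed"])))

  # the same 55 um^2 instance is a cardiomyocyte under the human preset
  cls_h <- classify_gomori(sc$image, sc$labels, analysis_config("human"))
  expect_equal(cls_h$class[cls_h$instance_id == 2], "cardiomyocyte")

  # border exclusion can be disabled
  cfg_nb <- analysis_config("mouse", exclude_border_cm = FALSE)
  cls_nb <- classify_gomori(sc$image, sc$labels, cfg_nb)
  expect_equal(cls_nb$class[cls_nb$instance_id == 6], "cardiomyocyte")
})

test_that("classification is a deterministic partition, monotone in the CM floor", {
  sc <- gomori_scene()
  cfg <- analysis_config("mouse")
  cls <- classify_gomori(sc$image, sc$labels, cfg)
  expect_equal(nrow(cls), length(setdiff(unique(as.vector(sc$labels)), 0L)))
  expect_equal(anyDuplicated(cls$instance_id), 0)
  expect_identical(cls, classify_gomori(sc$image, sc$labels, cfg))
  n_cm <- function(minarea) {
    cfg2 <- analysis_config("custom", cm_min_area_um2 = minarea)
    sum(classify_gomori(sc$image, sc$labels, cfg2)$class == "cardiomyocyte")
  }
  counts <- vapply(c(20, 50, 60, 80, 100), n_cm, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("classification matches ground truth exactly on a clean fixture", {
  tis <- standard_tissue()
  bf <- render_brightfield(tis)
  an <- cached_analysis("std_bf", function()
    analyze_gomori(bf, analysis_config("mouse", watershed_tolerance = 10)))
  got <- table(factor(an$classification$class,
                      levels = c("cardiomyocyte", "cm_nucleus", "capillary")))
  expect_equal(unname(got["cardiomyocyte"]),
               sum(tis$cells$class_brightfield == "cardiomyocyte"))
  expect_equal(unname(got["cm_nucleus"]),
               sum(tis$nuclei$class == "cm_nucleus"))
  expect_equal(unname(got["capillary"]),
               sum(tis$capillaries$class == "capillary"))
  # partition: every watershed instance got exactly one class
  expect_equal(nrow(an$classification), n_labels(an$labels))
})
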