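test_that("a fixed seed gives identical geometry and byte-identical files", {
  spec <- tissue_spec(seed = 7, noise_sd = 1, field_size_um = c(80, 60))
  t1 <- generate_tissue(spec)
  t2 <- generate_tissue(spec)
  expect_identical(t1, t2)
  expect_identical(render_brightfield(t1), render_brightfield(t2))
  expect_identical(render_fluorescence(t1, "endothelium"),
                   render_fluorescence(t2, "endothelium"))
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  write_fixture(t1, td1); write_fixture(t2, td2)
  for (f in c("brightfield.png", "fluorescence.tif", "truth_cells.csv")) {
    expect_identical(readBin(file.path(td1, f), "raw", 9e6),
                     readBin(file.path(td2, f), "raw", 9e6))
  }
  # the generator does not disturb the session RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_tissue(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("degenerate and infeasible specs are handled", {
  t1 <- generate_tissue(tissue_spec(seed = 1, n_cells = 1, noise_sd = 0,
                                    field_size_um = c(40, 30)))
  expect_equal(nrow(t1$cells), 1)
  expect_true(t1$cells$border[1]) # a single cell fills the field
  expect_equal(nrow(t1$capillaries), 0)
  expect_error(tissue_spec(n_cells = 0), "at least 1")
  expect_error(tissue_spec(n_cells = 500, field_size_um = c(50, 50)),
               "infeasible")
})

test_that("generated structures respect the size windows by construction", {
  tis <- standard_tissue()
  nuc <- tis$nuclei[tis$nuclei$class == "cm_nucleus", ]
  expect_true(all(nuc$area_um2 > 6 & nuc$area_um2 < 100))
  cap <- tis$capillaries[tis$capillaries$class == "capillary", ]
  expect_true(all(cap$area_um2 > 1.5 & cap$area_um2 < 100))
  cm <- tis$cells[tis$cells$class_brightfield == "cardiomyocyte", ]
  expect_true(all(cm$area_um2 > 60))
  expect_true(all(!cm$border))
  # ground-truth contact gaps obey the generating 2 um rule
  expect_true(all(tis$contacts$gap_um <= 2))
})

test_that("diameter targets are recovered in the realised tessellation", {
  # Monte-Carlo: across several seeds, the realised mean true MinFeret of
  # interior cells tracks the requested mean within 3 standard errors
  mf <- c()
  for (s in 41:44) {
    tis <- generate_tissue(tissue_spec(seed = s, noise_sd = 0,
                                       field_size_um = c(200, 150),
                                       cell_diameter_um = c(14, 2)))
    cm <- tis$cells[!tis$cells$border, ]
    mf <- c(mf, cm$feret_min_um)
  }
  se <- sd(mf) / sqrt(length(mf))
  expect_lt(abs(mean(mf) - 14), 3 * se + 0.35)
})

test_that("noise-free brightfield renders honour the colour conventions", {
  tis <- standard_tissue()
  bf <- render_brightfield(tis)
  rng <- analysis_config("mouse")$hsb_range
  lab <- tis$label_map
  cm <- tis$cells$cell_id[tis$cells$class_brightfield == "cardiomyocyte"]
  for (i in cm[1:10]) # every cell-interior fill passes the colour window
    expect_true(instance_color_match(bf, lab, i, rng))
  # capillary lumens fail the match (low saturation)
  caps <- tis$capillaries$cap_id[tis$capillaries$class == "capillary"]
  for (i in caps[1:5])
    expect_false(instance_color_match(bf, lab, i, rng))
})

test_that("membrane watershed recovers every cell and lumen", {
  tis <- standard_tissue()
  ch <- render_fluorescence(tis, "endothelium")
  lab <- watershed_segment(ch$membrane, 0.2)
  expect_equal(n_labels(lab), nrow(tis$cells) + nrow(tis$capillaries))
})

test_that("true MinFeret agrees with the measured MinFeret at pixel scale", {
  # per-cell agreement between the analytic polygon MinFeret and the
  # pipeline measurement: the watershed line and the unit-square corner
  # model each contribute up to a pixel, so agreement is checked at one
  # and at two pixel-equivalents
  tot <- 0; ok1 <- 0; ok2 <- 0
  for (s in c(11, 12, 13)) {
    tis <- generate_tissue(tissue_spec(seed = s, noise_sd = 0,
                                       field_size_um = c(150, 110)))
    an <- analyze_gomori(render_brightfield(tis),
                         analysis_config("mouse", watershed_tolerance = 10))
    cm <- tis$cells[tis$cells$class_brightfield == "cardiomyocyte", ]
    mpp <- tis$spec$microns_per_pixel
    for (i in cm$cell_id) {
      b <- majority_basin(an$labels, tis$label_map, i)
      if (is.na(b)) next
      meas <- an$report$records$feret_min_um[
        an$report$records$instance_id == b]
      if (!length(meas)) next
      err <- abs(meas - cm$feret_min_um[cm$cell_id == i])
      tot <- tot + 1
      if (err <= mpp) ok1 <- ok1 + 1
      if (err <= 2 * mpp) ok2 <- ok2 + 1
    }
  }
  expect_gte(ok1 / tot, 0.90)
  expect_equal(ok2 / tot, 1)
})

test_that("expression renders recover the designated per-cell fractions", {
  tis <- dense_tissue()
  ch <- render_fluorescence(tis, "intracellular_expression")
  an <- cached_analysis("dense_ex", function()
    analyze_fluo(ch, analysis_config("mouse", watershed_tolerance = 0.2)))
  ex <- an$report$relations$expressions
  n <- nrow(tis$cells)
  err_by_f <- list()
  for (b in ex$cm_id) {
    px <- which(an$labels == b)
    cellpx <- tis$label_map[px]
    cellpx <- cellpx[cellpx > 0 & cellpx <= n]
    tcell <- as.integer(names(sort(table(cellpx), decreasing = TRUE))[1])
    f <- tis$cells$expression_fraction[tcell] * 100
    key <- as.character(f)
    err_by_f[[key]] <- c(err_by_f[[key]],
                         ex$positive_pct[ex$cm_id == b] - f)
  }
  for (key in names(err_by_f))
    expect_lt(abs(mean(err_by_f[[key]])), 2)
})

test_that("anisotropic tessellations elongate cells along x", {
  tis <- generate_tissue(tissue_spec(seed = 9, noise_sd = 0,
                                     field_size_um = c(160, 80),
                                     aspect_ratio = 2.5))
  cm <- tis$cells[!tis$cells$border, ]
  # elongated sections: max Feret well above min Feret on average
  expect_gt(mean(cm$feret_max_um / cm$feret_min_um), 1.6)
})
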