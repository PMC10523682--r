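test_that("capillary contacts respect the 2 um bound", {
  # capillary separated from the CM by a single 1-px line at 0.5 um/px
  lab <- matrix(0L, 20, 20)
  lab <- put_rect(lab, 3, 3, 10, 6, 1L)   # CM, cols 3:8
  lab <- put_rect(lab, 3, 10, 4, 2, 2L)   # capillary, col gap of 1 px
  cc <- count_capillary_contacts(1L, 2L, lab, 2, 0.5)
  expect_equal(cc$n_contacts, 1L)
  expect_equal(cc$cc_per_area, 1 / (60 * 0.25))
  # cc_per_area times the CM area reproduces the count exactly
  expect_equal(cc$cc_per_area * 60 * 0.25, cc$n_contacts)

  # capillary at a 3 um minimum gap: no contact
  lab2 <- matrix(0L, 30, 30)
  lab2 <- put_rect(lab2, 3, 3, 10, 6, 1L)   # CM ends at col 8
  lab2 <- put_rect(lab2, 3, 16, 4, 2, 2L)   # center gap 8 px = 4 um, edge 3.5
  cc2 <- count_capillary_contacts(1L, 2L, lab2, 2, 0.5)
  expect_equal(cc2$n_contacts, 0L)

  # no capillaries: zero contacts and zero density for every CM
  cc3 <- count_capillary_contacts(1L, integer(0), lab, 2, 0.5)
  expect_equal(cc3$n_contacts, 0L)
  expect_equal(cc3$cc_per_area, 0)

  expect_error(count_capillary_contacts(1L, 2L, lab, -1, 0.5), "positive")
})

test_that("a central CM ringed by capillaries counts only those in range", {
  # hexagon-like CM with 3 capillaries within 2 um and 1 outside
  lab <- matrix(0L, 60, 60)
  lab <- put_rect(lab, 25, 25, 12, 12, 1L)     # CM block
  lab <- put_rect(lab, 20, 28, 3, 3, 2L)       # 2 px above -> 1 um gap
  lab <- put_rect(lab, 39, 28, 3, 3, 3L)       # 2 px below -> 1 um gap
  lab <- put_rect(lab, 28, 39, 3, 3, 4L)       # 2 px right -> 1 um gap
  lab <- put_rect(lab, 28, 3, 3, 3, 5L)        # 19 px left -> ~10 um gap
  cc <- count_capillary_contacts(1L, 2:5, lab, 2, 0.5)
  expect_equal(cc$n_contacts, 3L)
  bf <- contacts_bruteforce(1L, 2:5, lab, 2, 0.5)
  expect_equal(cc$n_contacts, bf$n_contacts)
})

test_that("contact counts equal brute force on random scenes and are monotone", {
  set.seed(61)
  for (trial in 1:6) {
    n <- 100
    lab <- matrix(0L, n, n)
    # a few CM blocks
    cm_ids <- 1:3
    for (id in cm_ids) {
      repeat {
        r0 <- sample(5:(n - 25), 1); c0 <- sample(5:(n - 25), 1)
        h <- sample(12:20, 1); w <- sample(12:20, 1)
        if (all(lab[r0:(r0 + h - 1), c0:(c0 + w - 1)] == 0)) break
      }
      lab <- put_rect(lab, r0, c0, h, w, id)
    }
    # scatter capillaries
    cap_ids <- 4:11
    for (id in cap_ids) {
      r0 <- sample(2:(n - 4), 1); c0 <- sample(2:(n - 4), 1)
      sub <- lab[r0:(r0 + 2), c0:(c0 + 2)]
      if (any(sub != 0)) next
      lab <- put_rect(lab, r0, c0, 3, 3, id)
    }
    cap_ids <- intersect(cap_ids, unique(as.vector(lab)))
    cc <- count_capillary_contacts(cm_ids, cap_ids, lab, 2, 0.5)
    bf <- contacts_bruteforce(cm_ids, cap_ids, lab, 2, 0.5)
    expect_equal(cc$n_contacts, bf$n_contacts)
    # monotone in the distance bound
    prev <- rep(0L, 3)
    for (d in c(0.5, 1, 2, 4, 8)) {
      cur <- count_capillary_contacts(cm_ids, cap_ids, lab, d, 0.5)$n_contacts
      expect_true(all(cur >= prev))
      prev <- cur
    }
  }
})

test_that("expression percentages are exact on binary masks", {
  lab <- matrix(0L, 20, 20)
  lab <- put_rect(lab, 3, 3, 10, 10, 1L)
  mask <- matrix(FALSE, 20, 20)
  mask[3:12, 3:7] <- TRUE # left half of the CM
  ex <- expression_per_cm(1L, lab, mask)
  expect_equal(ex$positive_pct, 50)
  expect_equal(expression_per_cm(1L, lab, matrix(FALSE, 20, 20))$positive_pct, 0)
  expect_equal(expression_per_cm(1L, lab, matrix(TRUE, 20, 20))$positive_pct, 100)
  expect_error(expression_per_cm(1L, lab, matrix(TRUE, 5, 5)), "dimensions")
  # invariant under relabeling
  lab2 <- lab; lab2[lab == 1L] <- 7L
  expect_equal(expression_per_cm(7L, lab2, mask)$positive_pct, 50)
})

test_that("summaries use the n-1 SD convention and per-CM averaging", {
  rec <- data.frame(instance_id = 1:2, class = "cardiomyocyte",
                    area_um2 = c(100, 300), feret_min_um = c(10, 14))
  s <- summarize_image(rec)$class_summaries
  cm <- s[s$class == "cardiomyocyte", ]
  expect_equal(cm$mean_area_um2, 200)
  expect_equal(cm$sd_area_um2, sqrt(20000))
  # single instance: SD reported as NA, not zero
  s1 <- summarize_image(rec[1, ])$class_summaries
  expect_true(is.na(s1$sd_area_um2[s1$class == "cardiomyocyte"]))
  # empty classes appear with n = 0
  expect_equal(s[s$class == "capillary", "n"], 0)

  # contacts {3,3,4} over areas {200,200,250}: per-CM ratios averaged
  rec3 <- data.frame(instance_id = 1:3, class = "cardiomyocyte",
                     area_um2 = c(200, 200, 250), feret_min_um = 12)
  ct <- data.frame(cm_id = 1:3, n_contacts = c(3L, 3L, 4L),
                   cc_per_area = c(3, 3, 4) / c(200, 200, 250))
  s3 <- summarize_image(rec3, contacts = ct)$class_summaries
  cm3 <- s3[s3$class == "cardiomyocyte", ]
  expect_equal(cm3$mean_capillary_contacts, 10 / 3, tolerance = 1e-9)
  expect_equal(cm3$mean_cc_per_area_um2, mean(c(0.015, 0.015, 0.016)),
               tolerance = 1e-9)

  # relations must reference existing CM records
  bad <- data.frame(cm_id = 9L, n_contacts = 1L, cc_per_area = 0.01)
  expect_error(summarize_image(rec3, contacts = bad))
})
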