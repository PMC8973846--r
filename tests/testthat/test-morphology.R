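# Concentric-layer ring classification and FormFactor circularity.

test_that("a disk partitions into four shells with a quartile core", {
  mask <- disk_mask(20)
  lay <- concentric_layers(mask, 4)
  expect_setequal(unique(lay[mask]), 1:4)
  expect_equal(sum(tabulate(lay[mask], 4)), sum(mask))
  # core shell is the deepest quartile: compare to the brute-force map
  ed <- bf_interior_distance(mask)
  expect_identical(lay == 4L, ed > 0.75 * max(ed))
  # core is approximately a disk of radius 5 (quartile of max depth 20)
  expect_lt(abs(sqrt(sum(lay == 4L) / pi) - 5), 1)
})

test_that("one layer is the identity partition and unions always cover", {
  mask <- disk_mask(12)
  expect_identical(concentric_layers(mask, 1) > 0L, mask)
  # partition property across assorted shapes
  shapes <- list(disk_mask(9), disk_mask(15.5, cy = 18.3, cx = 20.7),
                 exact_area_mask(300))
  for (m in shapes) {
    lay <- concentric_layers(m, 4)
    expect_identical(lay > 0L, m)
    expect_true(all(tabulate(lay[m], 4) > 0))
  }
})

test_that("degenerate inputs raise typed errors", {
  expect_error(concentric_layers(matrix(FALSE, 5, 5)),
               class = "nucleoshape_input_error")
  two <- matrix(FALSE, 9, 9); two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(concentric_layers(two), class = "nucleoshape_input_error")
  thin <- matrix(FALSE, 9, 20); thin[4:5, 3:18] <- TRUE
  expect_error(concentric_layers(thin, 4),
               class = "nucleoshape_degenerate_error")
})

test_that("ring classification matches exact constructions and is strict at 1.4", {
  cfg <- morphology_config()
  # uniform disk: ratio exactly 1, negative
  mask <- disk_mask(20)
  lay <- concentric_layers(mask, cfg$n_layers)
  uni <- matrix(0, nrow(mask), ncol(mask)); uni[mask] <- 100
  rc <- ring_classify(uni, lay, cfg)
  expect_equal(rc$ring_ratio, 1)
  expect_false(rc$ring_positive)
  # generator patch with contrast 2: ratio 2, positive
  p <- make_nucleolus_patch(20, ring_contrast = 2)
  lay2 <- concentric_layers(p$mask, cfg$n_layers)
  rc2 <- ring_classify(p$intensity, lay2, cfg)
  expect_equal(rc2$ring_ratio, 2)
  expect_true(rc2$ring_positive)
  # rim/core ratio exactly 1.4: strict > leaves it negative
  exact <- matrix(0, nrow(mask), ncol(mask))
  exact[mask] <- 100
  exact[lay == 1L] <- 140
  rc3 <- ring_classify(exact, lay, cfg)
  expect_equal(rc3$ring_ratio, 1.4)
  expect_false(rc3$ring_positive)
  exact[lay == 1L] <- 141
  expect_true(ring_classify(exact, lay, cfg)$ring_positive)
  # zero innermost mean is a typed error
  hollow <- matrix(0, nrow(mask), ncol(mask))
  hollow[lay == 1L] <- 10
  expect_error(ring_classify(hollow, lay, cfg),
               class = "nucleoshape_ratio_error")
})

test_that("ring ratio is invariant to intensity scaling, translation and rotation", {
  p <- make_nucleolus_patch(15, ring_contrast = 2.5, noise_sd = 3, seed = 2)
  lay <- concentric_layers(p$mask, 4)
  r0 <- ring_classify(p$intensity, lay)$ring_ratio
  expect_equal(ring_classify(7.3 * p$intensity, lay)$ring_ratio, r0)
  rot_i <- t(p$intensity)[ncol(p$intensity):1, ]
  rot_m <- t(p$mask)[ncol(p$mask):1, ]
  expect_equal(ring_classify(rot_i, concentric_layers(rot_m, 4))$ring_ratio,
               r0)
  ff0 <- form_factor(p$mask)$form_factor
  expect_equal(form_factor(rot_m)$form_factor, ff0)
  shifted <- cbind(matrix(FALSE, nrow(p$mask), 4), p$mask)
  expect_equal(form_factor(shifted)$form_factor, ff0)
})

test_that("measured ring ratio is monotone in generator contrast", {
  ratios <- vapply(c(1, 1.2, 1.5, 2, 3, 5), function(cc) {
    p <- make_nucleolus_patch(18, ring_contrast = cc)
    ring_classify(p$intensity, concentric_layers(p$mask, 4))$ring_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("FormFactor matches the isoperimetric expectations", {
  ffd <- form_factor(disk_mask(50))
  expect_gte(ffd$form_factor, 0.95)
  expect_lte(ffd$form_factor, 1.0)
  sq <- matrix(FALSE, 50, 50); sq[6:45, 6:45] <- TRUE
  ffs <- form_factor(sq)
  expect_equal(ffs$form_factor, 4 * pi * 1600 / ffs$perimeter^2)
  # same-area disk is rounder than the square, and than assorted shapes
  same_disk <- exact_area_mask(1600)
  expect_lt(ffs$form_factor, form_factor(same_disk)$form_factor)
  for (m in list(disk_mask(12), exact_area_mask(500),
                 rbind(sq, sq)[1:60, ])) {
    disk_same <- exact_area_mask(sum(m), n = 61L)
    expect_lte(form_factor(m)$form_factor,
               form_factor(disk_same)$form_factor + 1e-9)
  }
})

test_that("small and above-unity FormFactor values are marked excluded", {
  expect_true(form_factor(exact_area_mask(99))$excluded)
  expect_equal(form_factor(exact_area_mask(99))$reason, "small_area")
  expect_false(form_factor(exact_area_mask(100))$excluded)
  cfg_tight <- morphology_config(form_factor_max_valid = 0.5)
  ff <- form_factor(disk_mask(20), cfg_tight)
  expect_true(ff$excluded)
  expect_equal(ff$reason, "above_max")
  expect_error(form_factor(matrix(FALSE, 3, 3)),
               class = "nucleoshape_input_error")
})

test_that("population scoring recovers planted fractions and feeds chi-squared", {
  # all-uniform population: no ring-positive calls
  sc0 <- make_cell_scene(scene_spec(n_nuclei = 4, ring_fraction = 0,
                                    ring_contrast = 1, seed = 3))
  res0 <- score_population(sc0$true_masks$nucleoli,
                           get_channel(sc0$stack, "B23"))
  expect_equal(sum(res0$counts[, "RingShape_pos"]), 0L)
  # two groups with planted proportions 0.1 vs 0.6 separate at p < 0.001
  tally <- matrix(0L, 2, 2,
                  dimnames = list(c("neg", "pos"),
                                  c("RingShape_pos", "RingShape_neg")))
  for (seed in 1:6) {
    for (grp in c("neg", "pos")) {
      frac <- if (grp == "neg") 0.1 else 0.6
      sc <- make_cell_scene(scene_spec(n_nuclei = 5, ring_fraction = frac,
                                       ring_contrast = 3, snr = 10,
                                       seed = 400 + seed * 2 +
                                         (grp == "pos")))
      nuc_ids <- sc$truth$nuclei$nucleus_id
      groups <- setNames(rep(grp, length(nuc_ids)), nuc_ids)
      res <- score_population(sc$true_masks$nucleoli,
                              get_channel(sc$stack, "B23"),
                              group_labels = groups)
      tally[grp, ] <- tally[grp, ] + res$counts[grp, ]
    }
  }
  out <- chi_square_tests(tally, adjust = "none")
  expect_lt(out$p_value, 0.001)
})

test_that("3D nucleolus masks are scored on their largest plane", {
  fs <- make_fish_scene_3d(small_fish_spec(3))
  res <- score_population(fs$true_masks$nucleoli,
                          get_channel(fs$stack, "B23"))
  scored <- res$records[!res$records$skipped, ]
  # filled spheres: near-uniform ratio, high circularity
  expect_true(all(abs(scored$ring_ratio - 1) < 0.2))
  expect_true(all(scored$form_factor > 0.9))
})
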