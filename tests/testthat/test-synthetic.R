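# Synthetic scene generator: exact constructions, determinism, planted
# statistics, and the noise model.

test_that("nucleolus patch renders exact rim and interior intensities", {
  # contrast 1: uniform disk
  p <- make_nucleolus_patch(20, ring_contrast = 1, interior_level = 100)
  expect_equal(unique(p$intensity[p$mask]), 100)
  ed <- bf_interior_distance(p$mask)
  ndist <- ed / max(ed)
  # contrast 2: outer quarter-depth band at 200, innermost core at 100
  p2 <- make_nucleolus_patch(20, ring_contrast = 2, interior_level = 100)
  rim <- p2$mask & ndist <= 0.25
  core <- p2$mask & ndist > 0.75
  expect_equal(mean(p2$intensity[rim]), 200)
  expect_equal(mean(p2$intensity[core]), 100)
  expect_false(any(p2$intensity[!p2$mask] != 0))
})

test_that("noisy patch rim/core ratio concentrates at the contrast", {
  p <- make_nucleolus_patch(20, ring_contrast = 2, interior_level = 100,
                            noise_sd = 5, seed = 7)
  ed <- bf_interior_distance(p$mask)
  ndist <- ed / max(ed)
  rim <- p$mask & ndist <= 0.25
  core <- p$mask & ndist > 0.75
  ratio <- mean(p$intensity[rim]) / mean(p$intensity[core])
  # delta-method SEM of the ratio under the generator's own noise model
  sem <- 2 * 5 * sqrt(1 / (sum(rim) * 200^2) + 1 / (sum(core) * 100^2)) * 100
  expect_lt(abs(ratio - 2), 3 * max(sem, 2 * 5 *
              sqrt(1 / sum(rim) + 1 / sum(core)) / 100))
})

test_that("invalid patch parameters are rejected", {
  expect_error(make_nucleolus_patch(1), class = "nucleoshape_parameter_error")
  expect_error(make_nucleolus_patch(10, ring_contrast = 0.9),
               class = "nucleoshape_parameter_error")
  expect_error(make_nucleolus_patch(10, interior_level = 0),
               class = "nucleoshape_parameter_error")
})

test_that("empty scene gives background-only channels and empty truth", {
  spec <- scene_spec(n_nuclei = 0, snr = Inf, seed = 1)
  sc <- make_cell_scene(spec)
  expect_equal(nrow(sc$truth$nuclei), 0)
  expect_equal(nrow(sc$truth$nucleoli), 0)
  expect_equal(unique(as.vector(sc$stack$channels$DAPI)), spec$bg_level)
  expect_equal(max(sc$true_masks$nuclei$labels), 0L)
})

test_that("ring_fraction 1 marks every nucleolus ring-like", {
  sc <- make_cell_scene(scene_spec(n_nuclei = 5, ring_fraction = 1,
                                   seed = 3))
  expect_true(all(sc$truth$nucleoli$ring))
})

test_that("scenes are bit-identical for identical specs", {
  spec <- scene_spec(n_nuclei = 4, seed = 9)
  a <- make_cell_scene(spec)
  b <- make_cell_scene(spec)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth, b$truth)
  f1 <- make_fish_scene_3d(small_fish_spec(5))
  f2 <- make_fish_scene_3d(small_fish_spec(5))
  expect_identical(f1$stack$channels, f2$stack$channels)
  expect_identical(f1$truth, f2$truth)
})

test_that("planted ring fraction falls in its exact binomial 99% interval", {
  sc <- make_cell_scene(scene_spec(image_shape = c(1024L, 1024L),
                                   n_nuclei = 50, ring_fraction = 0.3,
                                   nucleus_radius_px = c(35, 3),
                                   seed = 1))
  n <- nrow(sc$truth$nucleoli)
  k <- sum(sc$truth$nucleoli$ring)
  expect_gte(k, qbinom(0.005, n, 0.3))
  expect_lte(k, qbinom(0.995, n, 0.3))
})

test_that("nucleus placement fails loudly when the image is too small", {
  expect_error(
    make_cell_scene(scene_spec(image_shape = c(128L, 128L), n_nuclei = 10,
                               nucleus_radius_px = c(45, 2), seed = 1)),
    class = "nucleoshape_placement_error")
})

test_that("3D ground truth distances are exact and compartments honour tolerances", {
  fs <- make_fish_scene_3d(small_fish_spec(2))
  tr <- fs$truth
  expect_true(all(tr$spots$dist_nucleolus_um >= 0, na.rm = TRUE))
  expect_true(all(tr$spots$dist_border_um >= 0))
  # recompute truth distances analytically from stored centres/radii
  for (k in seq_len(nrow(tr$spots))) {
    s <- tr$spots[k, ]
    nuc <- tr$nuclei[tr$nuclei$nucleus_id == s$nucleus_id, ]
    p <- c(s$z_um, s$y_um, s$x_um)
    db <- nuc$radius_um - sqrt(sum((p - c(nuc$centroid_z_um,
                                          nuc$centroid_y_um,
                                          nuc$centroid_x_um))^2))
    expect_lt(abs(db - s$dist_border_um), 1e-9)
    ncl <- tr$nucleoli[tr$nucleoli$nucleus_id == s$nucleus_id, ]
    if (nrow(ncl)) {
      dn <- min(pmax(0, sqrt((ncl$centroid_z_um - p[1])^2 +
                             (ncl$centroid_y_um - p[2])^2 +
                             (ncl$centroid_x_um - p[3])^2) - ncl$radius_um))
      expect_lt(abs(dn - s$dist_nucleolus_um), 1e-9)
    }
  }
  # compartment labels respect the generation tolerances
  spec <- small_fish_spec(2)
  nucl <- tr$spots$compartment == "nucleolar"
  expect_true(all(tr$spots$dist_nucleolus_um[nucl] <= spec$assoc_tol))
  lam <- tr$spots$compartment == "lamina_proximal"
  expect_true(all(tr$spots$dist_border_um[lam] <= spec$lamina_tol))
})

test_that("degenerate compartment probabilities force a single category", {
  fs <- make_fish_scene_3d(small_fish_spec(
    4, spot_compartment_probs = c(1, 0, 0),
    spots_per_nucleus = c(1L, 1L)))
  expect_true(all(fs$truth$spots$compartment == "nucleolar"))
  expect_true(all(fs$truth$spots$dist_nucleolus_um == 0))
})

test_that("planted compartment counts satisfy multinomial 99% bounds", {
  scenes <- generate_fish_scenes(9, base_seed = 30,
                                 spots_per_nucleus = c(8L, 8L),
                                 spot_min_sep_um = 0.6)
  comp <- unlist(lapply(scenes, function(s) s$truth$spots$compartment))
  n <- length(comp)
  probs <- c(nucleolar = 0.5, nucleoplasmic = 0.4, lamina_proximal = 0.1)
  # simultaneous 99% bounds: Bonferroni over the three categories
  for (cat in names(probs)) {
    k <- sum(comp == cat)
    expect_gte(k, qbinom(0.005 / 3, n, probs[[cat]]))
    expect_lte(k, qbinom(1 - 0.005 / 3, n, probs[[cat]]))
  }
})

test_that("noise model: peak over background SD concentrates at snr", {
  scenes <- generate_fish_scenes(4, base_seed = 50)
  ratios <- unlist(lapply(scenes, function(fs) {
    spec <- small_fish_spec(1)
    img <- get_channel(fs$stack, "FISH")
    bg <- img[fs$true_masks$nuclei$labels == 0L]
    sapply(seq_len(nrow(fs$truth$spots)), function(k) {
      s <- fs$truth$spots[k, ]
      vox <- round(c(s$z_um, s$y_um, s$x_um) / fs$stack$spacing) + 1
      win <- img[max(1, vox[1] - 1):(vox[1] + 1),
                 max(1, vox[2] - 1):(vox[2] + 1),
                 max(1, vox[3] - 1):(vox[3] + 1)]
      (max(win) - mean(bg)) / sd(bg)
    })
  }))
  expect_lt(abs(mean(ratios) - 10) / 10, 0.25)
})

test_that("screen plate generator honours exact noiseless constructions", {
  p0 <- make_screen_plate(gene_effects = c(a = 0, b = 0), baseline = 5,
                          well_sd = 0, seed = 1)
  expect_true(all(p0$wells$percent_positive == 5))
  p1 <- make_screen_plate(gene_effects = c(hit = 10, null = 0),
                          baseline = 5, well_sd = 0, seed = 1)
  hit_vals <- p1$wells$percent_positive[p1$wells$gene == "hit"]
  ctrl_vals <- p1$wells$percent_positive[p1$wells$gene == "siControl"]
  expect_true(all(hit_vals - mean(ctrl_vals) == 10))
  expect_error(make_screen_plate(gene_effects = c(a = 150), baseline = 1),
               class = "nucleoshape_parameter_error")
  expect_error(make_screen_plate(gene_effects = c(a = 1), baseline = 1,
                                 replicates = 0),
               class = "nucleoshape_parameter_error")
})

test_that("scene_spec validates its invariants", {
  expect_error(scene_spec(ring_fraction = 1.2))
  expect_error(scene_spec(spot_compartment_probs = c(0.5, 0.4, 0.2)))
  expect_error(scene_spec(snr = 0))
  expect_error(scene_spec(ring_contrast = 0.5))
})
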