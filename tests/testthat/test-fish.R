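# FISH spot detection, distance measurement and compartment scoring.

test_that("spot-free scenes give an empty spot table", {
  fs <- make_fish_scene_3d(small_fish_spec(1, spots_per_nucleus = c(0L, 0L)))
  nuc <- segment_nuclei(fs$stack, "DAPI", min_size = 2000,
                        smoothing_sigma = 1)
  sp <- detect_spots(fs$stack, "FISH", nuc)
  expect_equal(nrow(sp), 0L)
})

test_that("noiseless localisation error is below one voxel diagonal", {
  fs <- make_fish_scene_3d(small_fish_spec(2, snr = Inf,
                                           spots_per_nucleus = c(1L, 1L)))
  nuc <- segment_nuclei(fs$stack, "DAPI", min_size = 2000,
                        smoothing_sigma = 1)
  sp <- detect_spots(fs$stack, "FISH", nuc)
  m <- match_spots(sp, fs$truth$spots)
  vd <- sqrt(sum(fs$stack$spacing^2))
  expect_equal(m$recall, 1)
  expect_true(all(m$matches$dist <= vd))
})

test_that("detection at snr 10 reaches recall and precision 0.95", {
  scenes <- generate_fish_scenes(3, base_seed = 70)
  rec <- prec <- numeric(0)
  for (fs in scenes) {
    nuc <- segment_nuclei(fs$stack, "DAPI", min_size = 2000,
                          smoothing_sigma = 1)
    sp <- detect_spots(fs$stack, "FISH", nuc)
    m <- match_spots(sp, fs$truth$spots)
    rec <- c(rec, m$recall); prec <- c(prec, m$precision)
  }
  expect_gte(mean(rec), 0.95)
  expect_gte(mean(prec), 0.95)
})

test_that("stacks without spacing metadata are refused", {
  path <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:4, function(i) matrix(runif(64), 8, 8)), path)
  stk <- suppressWarnings(read_stack(path))
  nuc <- label_mask(array(1L, dim(stk$channels[[1]])), stk$spacing)
  expect_error(detect_spots(stk, names(stk$channels)[1], nuc),
               class = "nucleoshape_geometry_error")
})

test_that("distances follow analytic sphere geometry", {
  # hand-built nucleus and nucleolus spheres with known geometry
  d <- c(40L, 96L, 96L)
  sp <- c(0.25, 0.12, 0.12)
  zc <- (seq_len(d[1]) - 1) * sp[1]
  yc <- (seq_len(d[2]) - 1) * sp[2]
  xc <- (seq_len(d[3]) - 1) * sp[3]
  c_nuc <- c(5, 5.7, 5.7); r_nuc <- 4.5
  c_ncl <- c(5, 5.7, 5.7); r_ncl <- 1.2
  dist3 <- function(c0) outer(outer((zc - c0[1])^2, (yc - c0[2])^2, `+`),
                              (xc - c0[3])^2, `+`)
  nuc <- label_mask(array(as.integer(dist3(c_nuc) <= r_nuc^2), d), sp)
  ncl_arr <- array(as.integer(dist3(c_ncl) <= r_ncl^2), d)
  ncl <- label_mask(ncl_arr, sp)
  attr(ncl, "parents") <- c("1" = 1L)
  vd <- sqrt(sum(sp^2))
  # spot exactly 2 um from the nucleolus surface, along +x
  spots <- data.frame(spot_id = 1:2, nucleus_id = 1L,
                      z_um = c(5, 5), y_um = c(5.7, 5.7),
                      x_um = c(5.7 + r_ncl + 2, 5.7))
  md <- measure_distances(spots, nuc, ncl)
  expect_lt(abs(md$dist_nucleolus_um[1] - 2), vd)
  # spot at the nucleolus centroid: distance 0
  expect_equal(md$dist_nucleolus_um[2], 0)
  # border distance matches R_nuc - |p - c|
  expect_lt(abs(md$dist_border_um[1] - (r_nuc - r_ncl - 2)), vd)
  expect_lt(abs(md$dist_border_um[2] - r_nuc), vd)
})

test_that("ground-truth coordinates reproduce ground-truth distances", {
  fs <- make_fish_scene_3d(small_fish_spec(6))
  md <- measure_distances(fs$truth$spots, fs$true_masks$nuclei,
                          fs$true_masks$nucleoli)
  vd <- sqrt(sum(fs$stack$spacing^2))
  expect_true(all(abs(md$dist_nucleolus_um -
                        fs$truth$spots$dist_nucleolus_um) <= vd,
                  na.rm = TRUE))
  expect_true(all(abs(md$dist_border_um -
                        fs$truth$spots$dist_border_um) <= vd))
})

test_that("spots in nuclei without nucleoli are flagged, not dropped", {
  fs <- make_fish_scene_3d(small_fish_spec(
    3, nucleoli_per_nucleus = c(0L, 0L),
    spot_compartment_probs = c(0, 0.9, 0.1)))
  expect_message(
    md <- measure_distances(fs$truth$spots, fs$true_masks$nuclei,
                            fs$true_masks$nucleoli),
    "without nucleoli")
  expect_true(all(is.na(md$dist_nucleolus_um)))
  expect_true(all(md$no_nucleolus))
  cl <- assign_compartment(md)
  expect_true(all(cl$compartment_flagged))
  expect_true(all(cl$compartment %in% c("nucleoplasmic", "lamina_proximal")))
})

test_that("compartment assignment applies precedence and inclusive bounds", {
  spots <- data.frame(dist_nucleolus_um = c(0, 0.25, 0.26, 1, NA),
                      dist_border_um = c(0.1, 0.5, 0.5, 2, 0.3))
  out <- assign_compartment(spots, assoc_tol = 0.25, lamina_tol = 0.5)
  expect_equal(out$compartment,
               c("nucleolar",        # inside: nucleolar despite border 0.1
                 "nucleolar",        # exactly at assoc_tol: inclusive
                 "lamina_proximal",  # just outside assoc_tol
                 "nucleoplasmic",
                 "lamina_proximal")) # missing nucleolar distance: border rule
  expect_equal(out$compartment_flagged, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # the three categories partition the spots
  expect_equal(sum(table(out$compartment)), nrow(spots))
})

test_that("recovered compartment fractions satisfy multinomial 99% bounds", {
  scenes <- generate_fish_scenes(6, base_seed = 90,
                                 spots_per_nucleus = c(3L, 3L))
  comp <- character(0)
  for (fs in scenes) {
    nuc <- segment_nuclei(fs$stack, "DAPI", min_size = 2000,
                          smoothing_sigma = 1)
    ncl <- segment_nucleoli(fs$stack, "B23", nuc, min_size = 100)
    sp <- detect_spots(fs$stack, "FISH", nuc)
    sp <- assign_compartment(measure_distances(sp, nuc, ncl))
    comp <- c(comp, sp$compartment)
  }
  n <- length(comp)
  probs <- c(nucleolar = 0.5, nucleoplasmic = 0.4, lamina_proximal = 0.1)
  for (cat in names(probs)) {
    k <- sum(comp == cat)
    expect_gte(k, qbinom(0.005 / 3, n, probs[[cat]]))
    expect_lte(k, qbinom(1 - 0.005 / 3, n, probs[[cat]]))
  }
})

test_that("nascent focus selection follows the two-brightest rule", {
  spots <- data.frame(
    nucleus_id = c(1, 2, 2, 3, 3, 3, 3, 3, 4, 4, 4),
    intensity = c(9, 5, 6, 10, 20, 30, 40, 50, 7, 7, 7),
    z_um = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 3, 2),
    y_um = 0, x_um = 0)
  out <- select_nascent_foci(spots)
  # single focus: flagged; two foci: both flagged
  expect_true(out$nascent_candidate[1])
  expect_true(all(out$nascent_candidate[2:3]))
  # five foci: exactly the two brightest (50 and 40)
  sel3 <- out[out$nucleus_id == 3, ]
  expect_equal(sort(sel3$intensity[sel3$nascent_candidate]), c(40, 50))
  # all-tied intensities: exactly two flagged, lexicographic tie-break
  sel4 <- out[out$nucleus_id == 4, ]
  expect_equal(sum(sel4$nascent_candidate), 2L)
  expect_equal(sort(sel4$z_um[sel4$nascent_candidate]), c(1, 2))
})

test_that("halving voxel size leaves physical distances nearly unchanged", {
  build <- function(f) {
    d <- c(16L * f, 48L * f, 48L * f)
    sp <- c(0.5, 0.25, 0.25) / f
    zc <- (seq_len(d[1]) - 1) * sp[1]
    yc <- (seq_len(d[2]) - 1) * sp[2]
    xc <- (seq_len(d[3]) - 1) * sp[3]
    c_n <- c(3.5, 5.5, 5.5)
    dist3 <- outer(outer((zc - c_n[1])^2, (yc - c_n[2])^2, `+`),
                   (xc - c_n[3])^2, `+`)
    nuc <- label_mask(array(as.integer(dist3 <= 3^2), d), sp)
    ncl <- label_mask(array(as.integer(dist3 <= 1^2), d), sp)
    attr(ncl, "parents") <- c("1" = 1L)
    spots <- data.frame(spot_id = 1L, nucleus_id = 1L,
                        z_um = 3.5, y_um = 5.5, x_um = 7.5)
    measure_distances(spots, nuc, ncl)
  }
  coarse <- build(1L)
  fine <- build(2L)
  vd <- sqrt(sum((c(0.5, 0.25, 0.25))^2))
  expect_lt(abs(coarse$dist_nucleolus_um - fine$dist_nucleolus_um), vd)
  expect_lt(abs(coarse$dist_border_um - fine$dist_border_um), vd)
})
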