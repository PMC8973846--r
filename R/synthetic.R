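# Ground-truthed synthetic microscopy scenes.
#
# Scenes emulate confocal acquisitions of ESC nuclei: DAPI-stained nuclei
# containing 1-4 B23-stained nucleoli that are either granular ("filled")
# or ring-like (bright rim over the outer quarter of radial depth, dim
# interior), plus diffraction-limited FISH foci placed at controlled
# distances from the nucleolar surface and the nuclear border in
# anisotropic z-stacks. Nuclei and nucleoli are rendered as exact digital
# disks (2D) or spheres (3D physical coordinates) so that every ground
# truth quantity is analytic.
#
# Noise model: the clean signal S (peak level `level`) receives Poisson
# shot noise at `photons_per_unit` photons per intensity unit, then a
# constant background `bg_level` plus Gaussian read noise of SD
# `level / snr` is added. The background therefore has SD level/snr
# exactly, so (peak - background mean) / background SD concentrates at
# `snr`. `snr = Inf` yields the noiseless clean image.

.compartments <- c("nucleolar", "nucleoplasmic", "lamina_proximal")

#' Specify a synthetic microscopy scene
#'
#' Collects every generator parameter with validation. Defaults emulate a
#' 63x oil-immersion confocal snapshot (2D) or a 0.25 µm z-stack (3D) of
#' mouse ESC nuclei.
#'
#' @param image_shape Voxel counts per axis: `(y, x)` for 2D scenes,
#'   `(z, y, x)` for 3D.
#' @param spacing Physical voxel size in µm per axis (same order).
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_radius_px Mean and spread (SD) of the nucleus radius in
#'   xy pixels, `c(mean, sd)`.
#' @param nucleoli_per_nucleus Inclusive count range `c(min, max)`.
#' @param nucleolus_radius_frac Nucleolus radius range as a fraction of
#'   its nucleus radius, `c(min, max)`.
#' @param ring_fraction Proportion of nucleoli rendered ring-like, in
#'   `[0, 1]`.
#' @param ring_contrast Rim/interior mean-intensity ratio (>= 1) for
#'   ring-like nucleoli.
#' @param spots_per_nucleus Inclusive FISH focus count range per nucleus.
#' @param spot_compartment_probs Probabilities over the compartments
#'   nucleolar, nucleoplasmic and lamina-proximal; must sum to 1.
#' @param snr Peak signal over background-noise SD; `Inf` disables noise.
#' @param bg_level Constant background offset (intensity units).
#' @param level Peak signal level for every structure (intensity units).
#' @param photons_per_unit Photon gain of the Poisson shot-noise stage.
#' @param gfp_fraction Proportion of nuclei carrying the GFP reporter
#'   channel signal (0 omits the channel).
#' @param spot_sigma_um Gaussian spot SD in µm, `c(axial, lateral)`.
#' @param spot_min_sep_um Minimum pairwise distance (µm) between planted
#'   spots of one nucleus, keeping foci individually resolvable.
#' @param assoc_tol,lamina_tol Generation tolerances (µm) defining the
#'   nucleolar and lamina-proximal compartments of planted spots.
#' @param margin_um Safety margin (µm) keeping planted spots away from
#'   compartment boundaries so voxelisation cannot flip their true class.
#' @param seed Integer seed; identical specs give bit-identical scenes.
#' @return A validated `SceneSpec` object.
#' @export
scene_spec <- function(image_shape = c(512L, 512L),
                       spacing = c(0.1, 0.1),
                       n_nuclei = 10L,
                       nucleus_radius_px = c(45, 5),
                       nucleoli_per_nucleus = c(1L, 4L),
                       nucleolus_radius_frac = c(0.18, 0.30),
                       ring_fraction = 0.3,
                       ring_contrast = 2,
                       spots_per_nucleus = c(2L, 2L),
                       spot_compartment_probs = c(nucleolar = 0.55,
                                                  nucleoplasmic = 0.35,
                                                  lamina_proximal = 0.10),
                       snr = 10,
                       bg_level = 10,
                       level = 100,
                       photons_per_unit = 5,
                       gfp_fraction = 0,
                       spot_sigma_um = c(0.5, 0.25),
                       spot_min_sep_um = 1,
                       assoc_tol = 0.25,
                       lamina_tol = 0.5,
                       margin_um = NULL,
                       seed = 1L) {
  nd <- length(image_shape)
  .assert(nd %in% c(2L, 3L), "image_shape must have 2 (y,x) or 3 (z,y,x) axes")
  .assert(length(spacing) == nd && all(spacing > 0),
          "spacing must be positive, one entry per axis")
  .assert(n_nuclei >= 0, "n_nuclei must be non-negative")
  .assert(length(nucleus_radius_px) == 2L && nucleus_radius_px[1L] > 0 &&
            nucleus_radius_px[2L] >= 0, "nucleus_radius_px must be c(mean, sd)")
  .assert(all(nucleoli_per_nucleus >= 0) &&
            nucleoli_per_nucleus[1L] <= nucleoli_per_nucleus[2L],
          "nucleoli_per_nucleus must be an increasing count range")
  .assert(ring_fraction >= 0 && ring_fraction <= 1,
          "ring_fraction must lie in [0, 1]")
  .assert(ring_contrast >= 1, "ring_contrast must be >= 1")
  .assert(all(spots_per_nucleus >= 0) &&
            spots_per_nucleus[1L] <= spots_per_nucleus[2L],
          "spots_per_nucleus must be an increasing count range")
  .assert(length(spot_compartment_probs) == 3L &&
            all(spot_compartment_probs >= 0) &&
            abs(sum(spot_compartment_probs) - 1) <= 1e-9,
          "spot_compartment_probs must be 3 probabilities summing to 1")
  names(spot_compartment_probs) <- .compartments
  .assert(snr > 0, "snr must be positive")
  .assert(level > 0 && bg_level >= 0, "levels must be non-negative")
  if (is.null(margin_um)) margin_um <- spacing[nd]  # one lateral pixel
  spec <- list(image_shape = as.integer(image_shape),
               spacing = as.numeric(spacing),
               n_nuclei = as.integer(n_nuclei),
               nucleus_radius_px = as.numeric(nucleus_radius_px),
               nucleoli_per_nucleus = as.integer(nucleoli_per_nucleus),
               nucleolus_radius_frac = as.numeric(nucleolus_radius_frac),
               ring_fraction = ring_fraction,
               ring_contrast = ring_contrast,
               spots_per_nucleus = as.integer(spots_per_nucleus),
               spot_compartment_probs = spot_compartment_probs,
               snr = snr, bg_level = bg_level, level = level,
               photons_per_unit = photons_per_unit,
               gfp_fraction = gfp_fraction,
               spot_sigma_um = as.numeric(spot_sigma_um),
               spot_min_sep_um = spot_min_sep_um,
               assoc_tol = assoc_tol, lamina_tol = lamina_tol,
               margin_um = margin_um,
               seed = as.integer(seed))
  class(spec) <- "SceneSpec"
  spec
}

#' @export
print.SceneSpec <- function(x, ...) {
  cat("SceneSpec:", paste(x$image_shape, collapse = " x "),
      "voxels,", x$n_nuclei, "nuclei, seed", x$seed, "\n")
  invisible(x)
}

# Apply the shot + read noise model to a clean signal array.
.apply_noise <- function(clean_signal, spec, seed) {
  if (is.infinite(spec$snr)) {
    return(clean_signal + spec$bg_level)
  }
  .with_seed(seed, {
    ppu <- spec$photons_per_unit
    shot <- array(stats::rpois(length(clean_signal),
                               pmax(clean_signal, 0) * ppu) / ppu,
                  dim(clean_signal))
    read_sd <- spec$level / spec$snr
    shot + spec$bg_level +
      array(stats::rnorm(length(clean_signal), 0, read_sd),
            dim(clean_signal))
  })
}

#' Render a single synthetic nucleolus patch
#'
#' A square 2D patch containing one digital disk. For `ring_contrast > 1`
#' the outer quarter of the disk's radial depth (normalised interior
#' distance <= 0.25, the same convention the four-layer classifier uses
#' for its outermost layer) is rendered at `ring_contrast * interior_level`
#' and the rest at `interior_level`, so the noiseless rim/core mean ratio
#' equals `ring_contrast` exactly.
#'
#' @param radius_px Disk radius in pixels (>= 2).
#' @param ring_contrast Rim over interior mean-intensity ratio (>= 1);
#'   1 gives a uniform disk.
#' @param interior_level Interior intensity (> 0).
#' @param noise_sd SD of additive Gaussian noise (0 = noiseless).
#' @param seed Seed for the noise draw.
#' @return A list with `intensity` (numeric matrix) and `mask` (logical
#'   matrix marking the full disk).
#' @examples
#' p <- make_nucleolus_patch(20, ring_contrast = 2)
#' mean(p$intensity[p$mask])
#' @export
make_nucleolus_patch <- function(radius_px, ring_contrast = 1,
                                 interior_level = 100, noise_sd = 0,
                                 seed = 1L) {
  .assert(radius_px >= 2, "radius_px must be >= 2",
          class = "nucleoshape_parameter_error")
  .assert(ring_contrast >= 1, "ring_contrast must be >= 1",
          class = "nucleoshape_parameter_error")
  .assert(interior_level > 0, "interior_level must be positive",
          class = "nucleoshape_parameter_error")
  n <- as.integer(2 * ceiling(radius_px) + 5)
  c0 <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  mask <- (yy - c0)^2 + (xx - c0)^2 <= radius_px^2
  ed <- sqrt(.edt_sq(mask, dim(mask), c(1, 1)))
  nd <- ed / max(ed)
  rim <- mask & nd <= 0.25
  intensity <- matrix(0, n, n)
  intensity[mask] <- interior_level
  intensity[rim] <- ring_contrast * interior_level
  if (noise_sd > 0) {
    intensity <- intensity +
      .with_seed(seed, matrix(stats::rnorm(n * n, 0, noise_sd), n, n))
  }
  list(intensity = intensity, mask = mask)
}

# Rejection-sample non-overlapping circle/sphere centres. `lims` is a
# matrix with one row per axis giving the allowed centre range; distances
# use `spacing_weights` (all 1 for pixel-unit 2D scenes). Errors after
# `max_attempts` placements fail.
.place_centers <- function(n, radii, lims, min_gap, max_attempts = 200L) {
  nd <- nrow(lims)
  centers <- matrix(NA_real_, n, nd)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- stats::runif(nd, lims[, 1L], lims[, 2L])
      ok <- TRUE
      if (i > 1L) {
        d <- sqrt(colSums((t(centers[seq_len(i - 1L), , drop = FALSE]) - p)^2))
        ok <- all(d > radii[seq_len(i - 1L)] + radii[i] + min_gap)
      }
      if (ok) { centers[i, ] <- p; placed <- TRUE; break }
    }
    if (!placed) {
      stop(structure(class = c("nucleoshape_placement_error", "error",
                               "condition"),
                     list(message = sprintf(
                       paste0("could not place nucleus %d of %d without ",
                              "overlap after %d attempts; reduce n_nuclei ",
                              "or radii in the SceneSpec"),
                       i, n, max_attempts), call = NULL)))
    }
  }
  centers
}

#' Generate a 2D multi-channel cell scene with ground truth
#'
#' Renders `spec$n_nuclei` non-overlapping digital-disk nuclei (DAPI
#' channel), each containing 1-4 nucleoli (B23 channel) rendered filled
#' or ring-like according to `ring_fraction`/`ring_contrast`, plus an
#' optional GFP reporter channel. Identical specs (including seed) give
#' bit-identical scenes.
#'
#' @param spec A 2D [scene_spec()].
#' @return A list with `stack` ([image_stack()]), `truth` (data frames
#'   `nuclei` and `nucleoli`), and `true_masks` (ground-truth
#'   [label_mask()]s `nuclei` and `nucleoli`).
#' @export
make_cell_scene <- function(spec) {
  .assert(inherits(spec, "SceneSpec"), "spec must be a SceneSpec")
  .assert(length(spec$image_shape) == 2L,
          "make_cell_scene needs a 2D (y,x) SceneSpec")
  d <- spec$image_shape
  .with_seed(spec$seed, {
    n <- spec$n_nuclei
    radii <- if (n > 0)
      pmax(8, stats::rnorm(n, spec$nucleus_radius_px[1L],
                           spec$nucleus_radius_px[2L])) else numeric(0)
    dapi <- array(0, d)
    b23 <- array(0, d)
    gfp <- array(0, d)
    nuc_lab <- array(0L, d)
    nucleo_lab <- array(0L, d)
    nuclei_rows <- list()
    nucleoli_rows <- list()
    if (n > 0) {
      rmax <- max(radii)
      lims <- rbind(c(1 + rmax + 2, d[1L] - rmax - 2),
                    c(1 + rmax + 2, d[2L] - rmax - 2))
      .assert(all(lims[, 2L] > lims[, 1L]),
              "image too small for the requested nucleus radii",
              class = "nucleoshape_placement_error")
      centers <- .place_centers(n, radii, lims, min_gap = 3)
      gfp_pos <- stats::runif(n) < spec$gfp_fraction
      nucleolus_id <- 0L
      yy <- matrix(seq_len(d[1L]), d[1L], d[2L])
      xx <- matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE)
      for (i in seq_len(n)) {
        cy <- centers[i, 1L]; cx <- centers[i, 2L]; r <- radii[i]
        box_y <- max(1L, floor(cy - r - 1)):min(d[1L], ceiling(cy + r + 1))
        box_x <- max(1L, floor(cx - r - 1)):min(d[2L], ceiling(cx + r + 1))
        sub <- (yy[box_y, box_x] - cy)^2 + (xx[box_y, box_x] - cx)^2 <= r^2
        dapi[box_y, box_x][sub] <- spec$level
        nuc_lab[box_y, box_x][sub] <- i
        if (gfp_pos[i]) gfp[box_y, box_x][sub] <- spec$level
        k <- if (spec$nucleoli_per_nucleus[2L] == 0L) 0L else
          sample(spec$nucleoli_per_nucleus[1L]:spec$nucleoli_per_nucleus[2L],
                 1L)
        placed_c <- matrix(numeric(0), 0, 2)
        placed_r <- numeric(0)
        for (j in seq_len(k)) {
          rn <- stats::runif(1, spec$nucleolus_radius_frac[1L],
                             spec$nucleolus_radius_frac[2L]) * r
          rn <- max(rn, 4)
          ok <- FALSE
          for (a in seq_len(100L)) {
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- sqrt(stats::runif(1)) * max(r - rn - 2, 0)
            p <- c(cy + rad * sin(ang), cx + rad * cos(ang))
            if (nrow(placed_c) > 0) {
              dd <- sqrt(colSums((t(placed_c) - p)^2))
              if (any(dd <= placed_r + rn + 2)) next
            }
            ok <- TRUE
            break
          }
          if (!ok) next  # nucleus too crowded: generate fewer nucleoli
          placed_c <- rbind(placed_c, p)
          placed_r <- c(placed_r, rn)
          nucleolus_id <- nucleolus_id + 1L
          is_ring <- stats::runif(1) < spec$ring_fraction
          nb_y <- max(1L, floor(p[1L] - rn - 1)):min(d[1L], ceiling(p[1L] + rn + 1))
          nb_x <- max(1L, floor(p[2L] - rn - 1)):min(d[2L], ceiling(p[2L] + rn + 1))
          subm <- (yy[nb_y, nb_x] - p[1L])^2 + (xx[nb_y, nb_x] - p[2L])^2 <= rn^2
          vals <- matrix(0, length(nb_y), length(nb_x))
          vals[subm] <- spec$level
          if (is_ring && spec$ring_contrast > 1) {
            ed <- sqrt(.edt_sq(subm, dim(subm), c(1, 1)))
            ndist <- ed / max(ed)
            vals[subm & ndist <= 0.25] <- spec$level * spec$ring_contrast
          }
          b23[nb_y, nb_x] <- pmax(b23[nb_y, nb_x], vals)
          nucleo_lab[nb_y, nb_x][subm] <- nucleolus_id
          nucleoli_rows[[nucleolus_id]] <- data.frame(
            nucleolus_id = nucleolus_id, nucleus_id = i,
            centroid_y_px = p[1L], centroid_x_px = p[2L],
            radius_px = rn, area_px = sum(subm),
            ring = is_ring,
            ring_contrast = if (is_ring) spec$ring_contrast else 1)
        }
        nuclei_rows[[i]] <- data.frame(
          nucleus_id = i,
          centroid_y_um = (cy - 1) * spec$spacing[1L],
          centroid_x_um = (cx - 1) * spec$spacing[2L],
          centroid_y_px = cy, centroid_x_px = cx,
          radius_px = r, gfp_positive = gfp_pos[i])
      }
    }
    channels <- list(
      DAPI = .apply_noise(dapi, spec, .sub_seed(spec$seed, 1L)),
      B23 = .apply_noise(b23, spec, .sub_seed(spec$seed, 2L)))
    if (spec$gfp_fraction > 0) {
      channels$GFP <- .apply_noise(gfp, spec, .sub_seed(spec$seed, 3L))
    }
    nucleoli_df <- if (length(nucleoli_rows)) do.call(rbind, nucleoli_rows)
                   else data.frame()
    ncl_mask <- label_mask(nucleo_lab, spec$spacing)
    if (nrow(nucleoli_df)) {
      attr(ncl_mask, "parents") <- stats::setNames(
        as.integer(nucleoli_df$nucleus_id), nucleoli_df$nucleolus_id)
    } else {
      attr(ncl_mask, "parents") <- integer(0)
    }
    list(stack = image_stack(channels, spec$spacing),
         truth = list(
           nuclei = if (length(nuclei_rows)) do.call(rbind, nuclei_rows)
                    else data.frame(),
           nucleoli = nucleoli_df),
         true_masks = list(
           nuclei = label_mask(nuc_lab, spec$spacing),
           nucleoli = ncl_mask))
  })
}

# Uniform point in a ball of radius r around centre c (physical coords).
.runif_ball <- function(c0, r) {
  repeat {
    p <- stats::runif(length(c0), -r, r)
    if (sum(p^2) <= r^2) return(c0 + p)
  }
}

#' Generate a 3D FISH scene with ground truth
#'
#' Places spherical nuclei and nucleoli in an anisotropic z-stack and
#' plants Gaussian-profile FISH foci whose true compartment follows
#' `spec$spot_compartment_probs`. Ground truth records exact continuous
#' physical coordinates and exact Euclidean distances (µm) to the nearest
#' nucleolus surface and to the nucleus border. Planted positions keep a
#' `spec$margin_um` margin from the compartment boundaries defined by
#' `assoc_tol`/`lamina_tol`, so voxelisation cannot flip a true class.
#'
#' @param spec A 3D [scene_spec()].
#' @return A list with `stack` (channels DAPI, B23, FISH), `truth`
#'   (data frames `nuclei`, `nucleoli`, `spots`), and `true_masks`.
#' @export
make_fish_scene_3d <- function(spec) {
  .assert(inherits(spec, "SceneSpec"), "spec must be a SceneSpec")
  .assert(length(spec$image_shape) == 3L,
          "make_fish_scene_3d needs a 3D (z,y,x) SceneSpec")
  d <- spec$image_shape
  sp <- spec$spacing
  ext <- (d - 1) * sp  # physical extent per axis
  .with_seed(spec$seed, {
    n <- spec$n_nuclei
    r_um <- if (n > 0)
      pmax(8, stats::rnorm(n, spec$nucleus_radius_px[1L],
                           spec$nucleus_radius_px[2L])) * sp[3L] else numeric(0)
    if (n > 0) {
      lim_mat <- rbind(c(max(r_um) + sp[1L], ext[1L] - max(r_um) - sp[1L]),
                       c(max(r_um) + sp[2L], ext[2L] - max(r_um) - sp[2L]),
                       c(max(r_um) + sp[3L], ext[3L] - max(r_um) - sp[3L]))
      .assert(all(lim_mat[, 2L] > lim_mat[, 1L]),
              "stack too small for the requested nucleus radii",
              class = "nucleoshape_placement_error")
      centers <- .place_centers(n, r_um, lim_mat, min_gap = 3 * sp[3L])
    } else {
      centers <- matrix(numeric(0), 0, 3)
    }
    # voxel centre physical coordinates
    zc <- (seq_len(d[1L]) - 1) * sp[1L]
    yc <- (seq_len(d[2L]) - 1) * sp[2L]
    xc <- (seq_len(d[3L]) - 1) * sp[3L]
    dapi <- array(0, d); b23 <- array(0, d); fish <- array(0, d)
    nuc_lab <- array(0L, d); nucleo_lab <- array(0L, d)
    nuclei_rows <- list(); nucleoli_rows <- list(); spot_rows <- list()
    nucleolus_id <- 0L; spot_id <- 0L
    sphere_box <- function(c0, r) {
      lapply(1:3, function(a) {
        v <- list(zc, yc, xc)[[a]]
        which(v >= c0[a] - r - sp[a] & v <= c0[a] + r + sp[a])
      })
    }
    fill_sphere <- function(arr, c0, r, value, lab = NULL, labarr = NULL) {
      bx <- sphere_box(c0, r)
      dz <- (zc[bx[[1L]]] - c0[1L])^2
      dy <- (yc[bx[[2L]]] - c0[2L])^2
      dx <- (xc[bx[[3L]]] - c0[3L])^2
      sub <- outer(outer(dz, dy, `+`), dx, `+`) <= r^2
      a <- arr[bx[[1L]], bx[[2L]], bx[[3L]], drop = FALSE]
      a[sub] <- value
      arr[bx[[1L]], bx[[2L]], bx[[3L]]] <- a
      if (!is.null(labarr)) {
        la <- labarr[bx[[1L]], bx[[2L]], bx[[3L]], drop = FALSE]
        la[sub] <- lab
        labarr[bx[[1L]], bx[[2L]], bx[[3L]]] <- la
        return(list(arr = arr, labarr = labarr, n = sum(sub)))
      }
      list(arr = arr, n = sum(sub))
    }
    for (i in seq_len(n)) {
      c0 <- centers[i, ]; R <- r_um[i]
      res <- fill_sphere(dapi, c0, R, spec$level, i, nuc_lab)
      dapi <- res$arr; nuc_lab <- res$labarr
      nuclei_rows[[i]] <- data.frame(
        nucleus_id = i, centroid_z_um = c0[1L], centroid_y_um = c0[2L],
        centroid_x_um = c0[3L], radius_um = R)
      # nucleoli
      k <- if (spec$nucleoli_per_nucleus[2L] == 0L) 0L else
        sample(spec$nucleoli_per_nucleus[1L]:spec$nucleoli_per_nucleus[2L], 1L)
      placed_c <- matrix(numeric(0), 0, 3); placed_r <- numeric(0)
      for (j in seq_len(k)) {
        rn <- stats::runif(1, spec$nucleolus_radius_frac[1L],
                           spec$nucleolus_radius_frac[2L]) * R
        rn <- max(rn, 3 * sp[3L])
        ok <- FALSE
        for (a in seq_len(100L)) {
          p <- .runif_ball(c0, max(R - rn - 2 * sp[1L], 0))
          if (nrow(placed_c) > 0) {
            dd <- sqrt(colSums((t(placed_c) - p)^2))
            if (any(dd <= placed_r + rn + 2 * sp[3L])) next
          }
          ok <- TRUE
          break
        }
        if (!ok) next
        placed_c <- rbind(placed_c, p); placed_r <- c(placed_r, rn)
        nucleolus_id <- nucleolus_id + 1L
        res <- fill_sphere(b23, p, rn, spec$level, nucleolus_id, nucleo_lab)
        b23 <- res$arr; nucleo_lab <- res$labarr
        nucleoli_rows[[nucleolus_id]] <- data.frame(
          nucleolus_id = nucleolus_id, nucleus_id = i,
          centroid_z_um = p[1L], centroid_y_um = p[2L],
          centroid_x_um = p[3L], radius_um = rn, volume_vox = res$n,
          ring = FALSE, ring_contrast = 1)
      }
      if (nrow(placed_c) == 0L && spec$nucleoli_per_nucleus[2L] > 0L &&
          k > 0L) {
        # should not happen with default geometry; nucleus kept without
        # nucleoli and downstream distance measurement flags the spots
        placed_r <- numeric(0)
      }
      # spots
      ns <- if (spec$spots_per_nucleus[2L] == 0L) 0L else
        sample(spec$spots_per_nucleus[1L]:spec$spots_per_nucleus[2L], 1L)
      if (ns > 0L) {
        comp <- sample(.compartments, ns, replace = TRUE,
                       prob = spec$spot_compartment_probs)
        placed_spots <- matrix(numeric(0), 0, 3)
        for (s in seq_len(ns)) {
          pos <- .sample_spot_position(comp[s], c0, R, placed_c, placed_r,
                                       spec, placed_spots)
          placed_spots <- rbind(placed_spots, pos)
          spot_id <- spot_id + 1L
          dn <- if (nrow(placed_c) > 0)
            min(pmax(0, sqrt(colSums((t(placed_c) - pos)^2)) - placed_r))
            else NA_real_
          db <- R - sqrt(sum((pos - c0)^2))
          spot_rows[[spot_id]] <- data.frame(
            spot_id = spot_id, nucleus_id = i,
            z_um = pos[1L], y_um = pos[2L], x_um = pos[3L],
            compartment = comp[s],
            dist_nucleolus_um = dn, dist_border_um = db,
            amplitude = spec$level)
          # render Gaussian spot over a +-4 sigma box
          sig <- c(spec$spot_sigma_um[1L], spec$spot_sigma_um[2L],
                   spec$spot_sigma_um[2L])
          bx <- lapply(1:3, function(a) {
            v <- list(zc, yc, xc)[[a]]
            which(v >= pos[a] - 4 * sig[a] & v <= pos[a] + 4 * sig[a])
          })
          gz <- exp(-0.5 * ((zc[bx[[1L]]] - pos[1L]) / sig[1L])^2)
          gy <- exp(-0.5 * ((yc[bx[[2L]]] - pos[2L]) / sig[2L])^2)
          gx <- exp(-0.5 * ((xc[bx[[3L]]] - pos[3L]) / sig[3L])^2)
          g <- outer(outer(gz, gy), gx) * spec$level
          fish[bx[[1L]], bx[[2L]], bx[[3L]]] <-
            fish[bx[[1L]], bx[[2L]], bx[[3L]]] + g
        }
      }
    }
    channels <- list(
      DAPI = .apply_noise(dapi, spec, .sub_seed(spec$seed, 11L)),
      B23 = .apply_noise(b23, spec, .sub_seed(spec$seed, 12L)),
      FISH = .apply_noise(fish, spec, .sub_seed(spec$seed, 13L)))
    nucleoli_df <- if (length(nucleoli_rows)) do.call(rbind, nucleoli_rows)
                   else data.frame()
    ncl_mask <- label_mask(nucleo_lab, sp)
    attr(ncl_mask, "parents") <- if (nrow(nucleoli_df))
      stats::setNames(as.integer(nucleoli_df$nucleus_id),
                      nucleoli_df$nucleolus_id) else integer(0)
    list(stack = image_stack(channels, sp),
         truth = list(
           nuclei = if (length(nuclei_rows)) do.call(rbind, nuclei_rows)
                    else data.frame(),
           nucleoli = nucleoli_df,
           spots = if (length(spot_rows)) do.call(rbind, spot_rows)
                   else data.frame()),
         true_masks = list(nuclei = label_mask(nuc_lab, sp),
                           nucleoli = ncl_mask))
  })
}

# Rejection-sample one spot position of a given true compartment inside a
# nucleus (sphere centre c0, radius R) containing nucleoli at `ncl_c`
# (rows) with radii `ncl_r`. Margins keep the true class robust to
# voxelisation.
.sample_spot_position <- function(compartment, c0, R, ncl_c, ncl_r, spec,
                                  placed_spots = matrix(numeric(0), 0, 3)) {
  m <- spec$margin_um
  at <- spec$assoc_tol
  lt <- spec$lamina_tol
  ncl_dist <- function(p) {
    if (nrow(ncl_c) == 0) return(Inf)
    min(pmax(0, sqrt(colSums((t(ncl_c) - p)^2)) - ncl_r))
  }
  for (a in seq_len(2000L)) {
    p <- switch(compartment,
      nucleolar = {
        if (nrow(ncl_c) == 0) break
        j <- sample.int(nrow(ncl_c), 1L)
        .runif_ball(ncl_c[j, ], max(ncl_r[j] - m, 0.5 * m))
      },
      lamina_proximal = {
        u <- stats::runif(3, -1, 1)
        u <- u / sqrt(sum(u^2))
        rr <- stats::runif(1, max(R - lt + m, 0), R - m)
        c0 + u * rr
      },
      nucleoplasmic = .runif_ball(c0, R - lt - m))
    db <- R - sqrt(sum((p - c0)^2))
    dn <- ncl_dist(p)
    ok <- switch(compartment,
      nucleolar = dn == 0,
      lamina_proximal = db >= m && db <= lt - m && dn > at + m,
      nucleoplasmic = db > lt + m && dn > at + m)
    if (ok && nrow(placed_spots) > 0) {
      ok <- min(sqrt(colSums((t(placed_spots) - p)^2))) >=
        spec$spot_min_sep_um
    }
    if (ok) return(p)
  }
  stop(structure(class = c("nucleoshape_placement_error", "error",
                           "condition"),
                 list(message = sprintf(
                   "could not place a %s spot in a nucleus of radius %.2f um",
                   compartment, R), call = NULL)))
}

#' Simulate an siRNA screen plate
#'
#' Well-level percent reporter-positive values are
#' `baseline + gene effect + Gaussian noise`, clipped to `[0, 100]`, with
#' `replicates` wells per gene plus `n_control_wells` control wells
#' (gene `"siControl"`, zero effect), emulating a triplicate-well 96-well
#' miniscreen read out by flow cytometry.
#'
#' @param gene_effects Named numeric vector: mean shift of percent
#'   reporter-positive per gene knockdown.
#' @param n_control_wells Number of control wells.
#' @param baseline Baseline percent reporter-positive of control wells.
#' @param well_sd SD of well-level Gaussian noise (percentage points).
#' @param replicates Wells per gene (>= 1).
#' @param seed Integer seed.
#' @param plate_id Plate identifier string.
#' @return A [screen_plate()] object.
#' @export
make_screen_plate <- function(gene_effects, n_control_wells = 3L,
                              baseline = 1, well_sd = 0.5,
                              replicates = 3L, seed = 1L,
                              plate_id = "plate1") {
  .assert(replicates >= 1L, "replicates must be >= 1",
          class = "nucleoshape_parameter_error")
  .assert(well_sd >= 0, "well_sd must be >= 0",
          class = "nucleoshape_parameter_error")
  .assert(baseline >= 0 && baseline <= 100,
          "baseline must be a percentage in [0, 100]",
          class = "nucleoshape_parameter_error")
  .assert(!is.null(names(gene_effects)) || length(gene_effects) == 0,
          "gene_effects must be a named vector")
  means <- baseline + gene_effects
  .assert(all(means >= 0 & means <= 100),
          "a gene effect drives its wells outside [0, 100]",
          class = "nucleoshape_parameter_error")
  genes <- c(rep("siControl", n_control_wells),
             rep(names(gene_effects), each = replicates))
  mu <- c(rep(baseline, n_control_wells), rep(means, each = replicates))
  vals <- .with_seed(seed, mu + stats::rnorm(length(mu), 0, well_sd))
  vals <- pmin(100, pmax(0, vals))
  wells <- data.frame(
    well_id = sprintf("%s%02d", rep(LETTERS[1:8], length.out = length(mu)),
                      ((seq_along(mu) - 1L) %/% 8L) + 1L),
    gene = genes, percent_positive = vals,
    stringsAsFactors = FALSE)
  screen_plate(wells, plate_id = plate_id)
}
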