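# Nucleolar shape statistics: concentric-layer ring classification and
# FormFactor circularity.
#
# A nucleolus is partitioned into n concentric layers of equal normalised
# radial depth (interior distance transform scaled to [0, 1] per object;
# quartiles for the default n = 4, matching the scaled radial bins of
# object intensity-distribution profiling). The ratio of the outer
# layer's mean intensity over the innermost layer's classifies the object
# as ring-shaped when it strictly exceeds the threshold (default 1.4).
# FormFactor is 4*pi*area/perimeter^2 with a Crofton multi-directional
# perimeter estimator; objects below the minimum area (default 100 px)
# or with FormFactor above the validity bound (default 1) are marked
# excluded rather than scored.

#' Morphology scoring configuration
#'
#' @param n_layers Number of concentric layers (>= 2; default 4).
#' @param ring_ratio_threshold Outer/innermost mean-intensity ratio above
#'   which (strictly) a nucleolus is called ring-shaped. Default 1.4.
#' @param min_area_px Minimum area in pixels for a valid FormFactor;
#'   smaller nucleoli are marked excluded. Default 100.
#' @param form_factor_max_valid FormFactor values above this bound are
#'   marked excluded as unreliable. Default 1.
#' @return A `MorphologyConfig` list.
#' @export
morphology_config <- function(n_layers = 4L, ring_ratio_threshold = 1.4,
                              min_area_px = 100, form_factor_max_valid = 1) {
  .assert(n_layers >= 2L, "n_layers must be >= 2",
          class = "nucleoshape_parameter_error")
  .assert(ring_ratio_threshold > 0, "ring_ratio_threshold must be > 0",
          class = "nucleoshape_parameter_error")
  .assert(min_area_px >= 0, "min_area_px must be >= 0",
          class = "nucleoshape_parameter_error")
  structure(list(n_layers = as.integer(n_layers),
                 ring_ratio_threshold = ring_ratio_threshold,
                 min_area_px = min_area_px,
                 form_factor_max_valid = form_factor_max_valid),
            class = "MorphologyConfig")
}

#' Partition a nucleolus mask into concentric layers
#'
#' Shells of equal normalised radial depth, computed from the interior
#' distance transform scaled to `[0, 1]` per object. Layer 1 is the
#' outermost shell (touching the boundary), layer `n_layers` the core.
#' The shells are disjoint and their union is exactly the input mask.
#'
#' @param mask Logical matrix: a single-nucleolus binary mask (one
#'   connected component).
#' @param n_layers Number of shells.
#' @return Integer matrix of the same shape: 0 outside the mask, layer
#'   index 1..`n_layers` inside (1 = outermost).
#' @export
concentric_layers <- function(mask, n_layers = 4L) {
  .assert(is.logical(mask) && length(dim(mask)) == 2L,
          "mask must be a logical matrix",
          class = "nucleoshape_input_error")
  .assert(any(mask), "mask is empty", class = "nucleoshape_input_error")
  ncc <- max(.cc_label(mask, dim(mask)))
  .assert(ncc == 1L, "mask must contain exactly one connected component",
          class = "nucleoshape_input_error")
  n_layers <- as.integer(n_layers)
  .assert(n_layers >= 1L, "n_layers must be >= 1",
          class = "nucleoshape_parameter_error")
  ed <- sqrt(.edt_sq(mask, dim(mask), c(1, 1)))
  maxd <- max(ed)
  if (maxd < n_layers) {
    stop(structure(class = c("nucleoshape_degenerate_error", "error",
                             "condition"),
                   list(message = sprintf(
                     paste0("object radial depth %.1f px is below the ",
                            "layer count %d; object skipped"),
                     maxd, n_layers), call = NULL)))
  }
  layers <- array(0L, dim(mask))
  nd <- ed[mask] / maxd
  layers[mask] <- pmin(n_layers, as.integer(ceiling(nd * n_layers)))
  .assert(all(tabulate(layers[mask], n_layers) > 0L),
          "a concentric layer came out empty; object skipped",
          class = "nucleoshape_degenerate_error")
  layers
}

#' Ring-shape classification from concentric layers
#'
#' The mean intensity of the outermost layer divided by the mean
#' intensity of the innermost layer; the nucleolus is ring-positive when
#' the ratio strictly exceeds `cfg$ring_ratio_threshold`.
#'
#' @param intensity Numeric matrix of intensities, same geometry as
#'   `layers`.
#' @param layers Layer mask from [concentric_layers()].
#' @param cfg A [morphology_config()].
#' @return A list with `ring_ratio` and `ring_positive`.
#' @export
ring_classify <- function(intensity, layers, cfg = morphology_config()) {
  .assert(identical(dim(intensity), dim(layers)),
          "intensity and layers must share one geometry",
          class = "nucleoshape_geometry_error")
  n <- max(layers)
  .assert(n >= 1L, "layers contains no object",
          class = "nucleoshape_input_error")
  outer_mean <- mean(intensity[layers == 1L])
  inner_mean <- mean(intensity[layers == n])
  if (inner_mean == 0) {
    stop(structure(class = c("nucleoshape_ratio_error", "error",
                             "condition"),
                   list(message = "innermost layer mean is zero: ring ratio undefined",
                        call = NULL)))
  }
  ratio <- outer_mean / inner_mean
  list(ring_ratio = ratio,
       ring_positive = ratio > cfg$ring_ratio_threshold)
}

# Crofton 4-direction perimeter estimate: pi * mean over directions of
# (number of foreground runs along the direction's scan lines times the
# spacing between adjacent parallel lines: 1 for axis directions,
# 1/sqrt(2) for diagonals). Exact in expectation for disks.
.crofton_perimeter <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(m, dy, dx) {
    out <- matrix(FALSE, nr, nc)
    ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
    ok_y <- ys >= 1L & ys <= nr; ok_x <- xs >= 1L & xs <= nc
    out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
    out
  }
  runs <- function(dy, dx) sum(m & !shift(m, dy, dx))
  r0 <- runs(0L, 1L)     # horizontal runs
  r90 <- runs(1L, 0L)    # vertical runs
  r45 <- runs(1L, 1L)
  r135 <- runs(1L, -1L)
  pi * (r0 + r90 + (r45 + r135) / sqrt(2)) / 4
}

#' FormFactor circularity of a nucleolus mask
#'
#' `4 * pi * area / perimeter^2`, with area the pixel count and perimeter
#' the Crofton multi-directional estimate. A perfect disk scores close to
#' 1. The value is marked excluded (not valid for downstream comparison)
#' when the area is below `cfg$min_area_px` or the value exceeds
#' `cfg$form_factor_max_valid`.
#'
#' @param mask Logical matrix: single-nucleolus binary mask.
#' @param cfg A [morphology_config()].
#' @return A list with `form_factor` (the computed value), `excluded`
#'   (logical) and `reason` (`NA`, `"small_area"` or `"above_max"`).
#' @export
form_factor <- function(mask, cfg = morphology_config()) {
  .assert(is.logical(mask) && length(dim(mask)) == 2L && any(mask),
          "mask must be a non-empty logical matrix",
          class = "nucleoshape_input_error")
  area <- sum(mask)
  perim <- .crofton_perimeter(mask)
  ff <- 4 * pi * area / perim^2
  excluded <- FALSE
  reason <- NA_character_
  if (area < cfg$min_area_px) {
    excluded <- TRUE; reason <- "small_area"
  } else if (ff > cfg$form_factor_max_valid) {
    excluded <- TRUE; reason <- "above_max"
  }
  list(form_factor = ff, area = area, perimeter = perim,
       excluded = excluded, reason = reason)
}

# Largest-area z-plane of a 3D object mask (morphology is scored on 2D
# sections; 3D masks are reduced to their largest plane).
.largest_plane <- function(mask3d) {
  areas <- apply(mask3d, 1L, sum)
  z <- which.max(areas)
  mask3d[z, , ]
}

#' Score a nucleolus population
#'
#' Applies [concentric_layers()], [ring_classify()] and [form_factor()]
#' to every labelled nucleolus and tabulates ring-positive counts per
#' group, ready for chi-squared testing. 3D masks are scored on each
#' object's largest-area z-plane. Objects too thin for the layer count or
#' with an undefined ratio are recorded as skipped, not scored.
#'
#' @param nucleoli A [label_mask()] from [segment_nucleoli()] (or ground
#'   truth), 2D or 3D.
#' @param intensity Intensity array aligned with `nucleoli` (the
#'   nucleolar marker channel).
#' @param group_labels Named vector mapping nucleus id to group label;
#'   `NULL` puts every object in group `"all"`.
#' @param cfg A [morphology_config()].
#' @param parents Optional named integer vector mapping nucleolus label
#'   to parent nucleus; defaults to the mask's `parents` attribute.
#' @return A list with `records` (one row per nucleolus) and `counts`
#'   (group x RingShape+/- contingency matrix).
#' @export
score_population <- function(nucleoli, intensity,
                             group_labels = NULL,
                             cfg = morphology_config(),
                             parents = attr(nucleoli, "parents")) {
  .assert(inherits(nucleoli, "LabelMask"), "nucleoli must be a LabelMask")
  .assert(identical(dim(intensity), dim(nucleoli$labels)),
          "intensity and mask must share one geometry",
          class = "nucleoshape_geometry_error")
  lab <- nucleoli$labels
  nd <- length(dim(lab))
  labs <- sort(setdiff(unique(as.vector(lab)), 0L))
  rows <- vector("list", length(labs))
  for (k in seq_along(labs)) {
    l <- labs[k]
    obj <- lab == l
    # bounding box crop
    idx <- which(obj, arr.ind = TRUE)
    rng <- apply(idx, 2L, range)
    if (nd == 2L) {
      sub <- obj[rng[1L, 1L]:rng[2L, 1L], rng[1L, 2L]:rng[2L, 2L],
                 drop = FALSE]
      ints <- intensity[rng[1L, 1L]:rng[2L, 1L], rng[1L, 2L]:rng[2L, 2L],
                        drop = FALSE]
    } else {
      m3 <- obj[rng[1L, 1L]:rng[2L, 1L], rng[1L, 2L]:rng[2L, 2L],
                rng[1L, 3L]:rng[2L, 3L], drop = FALSE]
      i3 <- intensity[rng[1L, 1L]:rng[2L, 1L], rng[1L, 2L]:rng[2L, 2L],
                      rng[1L, 3L]:rng[2L, 3L], drop = FALSE]
      areas <- apply(m3, 1L, sum)
      z <- which.max(areas)
      sub <- m3[z, , ]
      ints <- i3[z, , ]
    }
    # pad one pixel so boundary pixels have an exterior neighbour
    sub_p <- rbind(FALSE, cbind(FALSE, sub, FALSE), FALSE)
    int_p <- rbind(0, cbind(0, ints, 0), 0)
    parent <- if (!is.null(parents) && as.character(l) %in% names(parents))
      parents[[as.character(l)]] else NA_integer_
    group <- if (!is.null(group_labels) && !is.na(parent) &&
                 as.character(parent) %in% names(group_labels))
      group_labels[[as.character(parent)]] else "all"
    row <- data.frame(nucleolus_id = l, nucleus_id = parent, group = group,
                      area_px = sum(sub), perimeter_px = NA_real_,
                      form_factor = NA_real_,
                      form_factor_excluded = NA,
                      ring_ratio = NA_real_, ring_positive = NA,
                      skipped = FALSE, skip_reason = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      layers <- concentric_layers(sub_p, cfg$n_layers)
      rc <- ring_classify(int_p, layers, cfg)
      lm <- vapply(seq_len(cfg$n_layers),
                   function(j) mean(int_p[layers == j]), numeric(1))
      list(rc = rc, lm = lm)
    }, nucleoshape_degenerate_error = function(e) e,
       nucleoshape_ratio_error = function(e) e)
    ff <- form_factor(sub_p, cfg)
    row$perimeter_px <- ff$perimeter
    row$form_factor <- ff$form_factor
    row$form_factor_excluded <- ff$excluded
    if (inherits(res, "condition")) {
      row$skipped <- TRUE
      row$skip_reason <- conditionMessage(res)
    } else {
      row$ring_ratio <- res$rc$ring_ratio
      row$ring_positive <- res$rc$ring_positive
      for (j in seq_len(cfg$n_layers)) {
        row[[paste0("layer_mean_", j)]] <- res$lm[j]
      }
    }
    rows[[k]] <- row
  }
  records <- if (length(rows)) {
    cols <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
      for (cn in setdiff(cols, names(r))) r[[cn]] <- NA_real_
      r[cols]
    })
    do.call(rbind, rows)
  } else data.frame()
  scored <- records[!is.na(records$ring_positive) & !records$skipped, ,
                    drop = FALSE]
  groups <- if (is.null(group_labels)) "all" else
    unique(c(unlist(group_labels)))
  counts <- matrix(0L, nrow = length(groups), ncol = 2L,
                   dimnames = list(groups,
                                   c("RingShape_pos", "RingShape_neg")))
  if (nrow(scored)) {
    for (g in groups) {
      sel <- scored$group == g
      counts[g, 1L] <- sum(scored$ring_positive[sel])
      counts[g, 2L] <- sum(!scored$ring_positive[sel])
    }
  }
  for (g in groups) {
    if (sum(counts[g, ]) == 0L) {
      warning(sprintf("group '%s' has no scorable nucleoli", g),
              call. = FALSE)
    }
  }
  list(records = records, counts = counts)
}
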