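# FISH focus detection and compartment scoring in 3D.
#
# Foci are detected by multiscale Laplacian-of-Gaussian filtering with
# scales given in physical units (anisotropy-aware: the per-axis voxel
# sigma is scale/spacing), followed by plateau-stable local maxima and
# sub-voxel centre-of-mass refinement. Distances from each focus to the
# nearest nucleolus surface and to the parent nucleus border are
# anisotropic Euclidean distances (µm) to the object surface voxels.

# Boundary voxels of `which_labels` objects (face-connected neighbour
# with a different value), returned as physical coordinates. With
# `side = "out"`, returns instead the background voxels adjacent to the
# objects. The true object boundary lies between the two voxel-centre
# shells, so averaging nearest-neighbour distances to both sides gives a
# boundary-distance estimate free of the half-voxel bias either shell
# alone would carry.
.surface_coords <- function(lab, spacing, which_labels = NULL,
                            side = c("in", "out")) {
  side <- match.arg(side)
  d <- dim(lab)
  nd <- length(d)
  fg <- if (is.null(which_labels)) lab > 0L else
    array(lab %in% which_labels, d)
  if (side == "out") fg <- !fg
  surf <- array(FALSE, d)
  for (a in seq_len(nd)) {
    for (s in c(-1L, 1L)) {
      shifted <- array(FALSE, d)
      n <- d[a]
      src <- if (s == 1L) 1L:(n - 1L) else 2L:n
      dst <- if (s == 1L) 2L:n else 1L:(n - 1L)
      if (nd == 2L) {
        if (a == 1L) shifted[dst, ] <- fg[src, ] else
          shifted[, dst] <- fg[, src]
      } else {
        if (a == 1L) shifted[dst, , ] <- fg[src, , ] else
        if (a == 2L) shifted[, dst, ] <- fg[, src, ] else
          shifted[, , dst] <- fg[, , src]
      }
      # a foreground voxel whose neighbour in this direction is background
      # (or outside the array) is a surface voxel
      edge <- array(FALSE, d)
      if (nd == 2L) {
        if (a == 1L) edge[if (s == 1L) 1L else n, ] <- TRUE else
          edge[, if (s == 1L) 1L else n] <- TRUE
      } else {
        if (a == 1L) edge[if (s == 1L) 1L else n, , ] <- TRUE else
        if (a == 2L) edge[, if (s == 1L) 1L else n, ] <- TRUE else
          edge[, , if (s == 1L) 1L else n] <- TRUE
      }
      at_edge <- if (side == "in") edge else array(FALSE, d)
      surf <- surf | (fg & ((!shifted & !edge) | at_edge))
    }
  }
  idx <- which(surf)
  .phys_coords(arrayInd(idx, d), spacing)
}

# Discrete Laplacian in physical units (second differences / h^2 per
# axis, replicated boundaries).
.laplacian <- function(img, spacing) {
  d <- dim(img)
  nd <- length(d)
  out <- array(0, d)
  for (a in seq_len(nd)) {
    n <- d[a]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    if (nd == 2L) {
      up <- if (a == 1L) img[ip, ] else img[, ip]
      dn <- if (a == 1L) img[im, ] else img[, im]
    } else {
      up <- switch(a, img[ip, , ], img[, ip, ], img[, , ip])
      dn <- switch(a, img[im, , ], img[, im, ], img[, , im])
    }
    out <- out + (up + dn - 2 * img) / spacing[a]^2
  }
  out
}

#' Detect FISH foci by multiscale Laplacian-of-Gaussian filtering
#'
#' @param stack A 3D [image_stack()] with physical spacing; stacks whose
#'   spacing was inferred (no metadata) are refused, since distances in
#'   µm would be meaningless.
#' @param channel FISH channel name.
#' @param nuclei Nucleus [label_mask()]; foci outside any nucleus are
#'   discarded.
#' @param min_sigma,max_sigma Blob scale range in µm.
#' @param n_scales Number of log-spaced scales.
#' @param threshold Detection threshold in units of the robust background
#'   SD (MAD) of the scale-normalised LoG response.
#' @return A data frame of spots: `spot_id`, `nucleus_id`, physical
#'   coordinates `z_um`/`y_um`/`x_um` (sub-voxel, centre-of-mass
#'   refined), `intensity` (peak raw intensity), `sigma_um` (best scale)
#'   and `response`.
#' @export
detect_spots <- function(stack, channel, nuclei,
                         min_sigma = 0.2, max_sigma = 0.45,
                         n_scales = 3L, threshold = 10) {
  .assert(inherits(stack, "ImageStack"), "stack must be an ImageStack")
  .assert(!isTRUE(stack$spacing_inferred),
          "stack has no spacing metadata: physical distances would be meaningless",
          class = "nucleoshape_geometry_error")
  img <- get_channel(stack, channel)
  d <- dim(img)
  .assert(length(d) == 3L, "detect_spots needs a 3D (z,y,x) stack",
          class = "nucleoshape_geometry_error")
  .check_aligned(stack, nuclei)
  sp <- stack$spacing
  sigmas <- exp(seq(log(min_sigma), log(max_sigma),
                    length.out = max(1L, n_scales)))
  best <- array(-Inf, d)
  best_sigma <- array(sigmas[1L], d)
  for (s in sigmas) {
    sm <- .gauss_sep(img, d, s / sp)
    resp <- -s^2 * .laplacian(sm, sp)   # positive for bright blobs
    upd <- resp > best
    best[upd] <- resp[upd]
    best_sigma[upd] <- s
  }
  noise <- stats::mad(best)
  floor_resp <- max(noise, 1e-9 * max(abs(best)))
  cand <- which(.local_maxima(best, d) & best > threshold * floor_resp)
  if (length(cand) == 0L) return(.empty_spots())
  rows <- list()
  sid <- 0L
  for (i in cand[order(-best[cand], cand)]) {
    ci <- arrayInd(i, d)
    nl <- nuclei$labels[ci]
    if (nl == 0L) next
    # sub-voxel centre of mass over a 3x3x3 raw-intensity window
    w <- lapply(seq_len(3L), function(a)
      max(1L, ci[a] - 1L):min(d[a], ci[a] + 1L))
    win <- img[w[[1L]], w[[2L]], w[[3L]], drop = FALSE]
    wpos <- as.matrix(expand.grid(w[[1L]], w[[2L]], w[[3L]]))
    # expand.grid varies the first factor fastest: matches array order
    wt <- pmax(as.vector(win) - min(win), 0)
    com <- if (sum(wt) > 0) colSums(wpos * wt) / sum(wt) else as.numeric(ci)
    sid <- sid + 1L
    rows[[sid]] <- data.frame(
      spot_id = sid, nucleus_id = nl,
      z_um = (com[1L] - 1) * sp[1L],
      y_um = (com[2L] - 1) * sp[2L],
      x_um = (com[3L] - 1) * sp[3L],
      intensity = max(win), sigma_um = best_sigma[i], response = best[i])
  }
  if (length(rows) == 0L) return(.empty_spots())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_spots <- function() {
  data.frame(spot_id = integer(0), nucleus_id = integer(0),
             z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
             intensity = numeric(0), sigma_um = numeric(0),
             response = numeric(0))
}

#' Measure spot distances to nucleolus surface and nucleus border
#'
#' Anisotropic Euclidean distances in µm: `dist_nucleolus_um` to the
#' nearest surface voxel of any nucleolus inside the parent nucleus
#' (0 when the spot lies inside a nucleolus), and `dist_border_um` to the
#' parent nucleus's boundary. Spots in a nucleus without nucleoli get
#' `NA` nucleolar distance and are flagged.
#'
#' @param spots Spot data frame from [detect_spots()] (or ground-truth
#'   coordinates with columns `nucleus_id`, `z_um`, `y_um`, `x_um`).
#' @param nuclei Nucleus [label_mask()].
#' @param nucleoli Nucleolus [label_mask()] with a `parents` attribute.
#' @return `spots` with `dist_nucleolus_um`, `dist_border_um` and
#'   `no_nucleolus` columns added.
#' @export
measure_distances <- function(spots, nuclei, nucleoli) {
  .check_aligned(nuclei, nucleoli)
  sp <- nuclei$spacing
  d <- dim(nuclei$labels)
  parents <- attr(nucleoli, "parents")
  if (is.null(parents)) {
    # derive parents by majority overlap
    labs <- setdiff(unique(as.vector(nucleoli$labels)), 0L)
    parents <- vapply(labs, function(l) {
      par <- nuclei$labels[nucleoli$labels == l]
      par <- par[par > 0L]
      if (length(par)) as.integer(names(which.max(table(par)))) else 0L
    }, integer(1))
    names(parents) <- labs
  }
  spots$dist_nucleolus_um <- NA_real_
  spots$dist_border_um <- NA_real_
  spots$no_nucleolus <- FALSE
  if (nrow(spots) == 0L) return(spots)
  coord_cols <- intersect(c("z_um", "y_um", "x_um"), names(spots))
  nn_dist <- function(coords, p) {
    if (nrow(coords) == 0L) return(NA_real_)
    sqrt(min(rowSums(sweep(coords, 2L, p)^2)))
  }
  for (nl in unique(spots$nucleus_id)) {
    sel <- which(spots$nucleus_id == nl)
    pts <- as.matrix(spots[sel, coord_cols, drop = FALSE])
    nuc_in <- .surface_coords(nuclei$labels, sp, nl, side = "in")
    nuc_out <- .surface_coords(nuclei$labels, sp, nl, side = "out")
    ncl_labs <- as.integer(names(parents)[parents == nl])
    if (length(ncl_labs) == 0L) {
      spots$no_nucleolus[sel] <- TRUE
    } else {
      ncl_in <- .surface_coords(nucleoli$labels, sp, ncl_labs, side = "in")
      ncl_out <- .surface_coords(nucleoli$labels, sp, ncl_labs,
                                 side = "out")
      for (j in seq_along(sel)) {
        p <- pts[j, ]
        vox <- pmin(pmax(round(p / sp) + 1, 1), d)
        inside <- nucleoli$labels[matrix(vox, 1L)] %in% ncl_labs
        spots$dist_nucleolus_um[sel[j]] <- if (inside) 0 else
          (nn_dist(ncl_in, p) + nn_dist(ncl_out, p)) / 2
      }
    }
    for (j in seq_along(sel)) {
      spots$dist_border_um[sel[j]] <-
        (nn_dist(nuc_in, pts[j, ]) + nn_dist(nuc_out, pts[j, ])) / 2
    }
  }
  if (any(spots$no_nucleolus)) {
    message(sprintf("%d spot(s) lie in nuclei without nucleoli; nucleolar distance set to NA",
                    sum(spots$no_nucleolus)))
  }
  spots
}

#' Assign nuclear compartments to measured spots
#'
#' `nucleolar` when the nucleolar distance is within `assoc_tol`
#' (inclusive), otherwise `lamina_proximal` when the border distance is
#' within `lamina_tol` (inclusive), otherwise `nucleoplasmic`; the
#' nucleolar call takes precedence. Spots with missing nucleolar distance
#' are classified from the border distance only and flagged.
#'
#' @param spots Data frame from [measure_distances()].
#' @param assoc_tol Nucleolar association tolerance in µm (default 0.25,
#'   about the confocal lateral resolution).
#' @param lamina_tol Lamina proximity tolerance in µm (default 0.5).
#' @return `spots` with `compartment` and `compartment_flagged` columns.
#' @export
assign_compartment <- function(spots, assoc_tol = 0.25, lamina_tol = 0.5) {
  .assert(all(c("dist_nucleolus_um", "dist_border_um") %in% names(spots)),
          "spots must carry measured distances",
          class = "nucleoshape_input_error")
  dn <- spots$dist_nucleolus_um
  db <- spots$dist_border_um
  comp <- ifelse(!is.na(dn) & dn <= assoc_tol, "nucleolar",
                 ifelse(db <= lamina_tol, "lamina_proximal",
                        "nucleoplasmic"))
  spots$compartment <- comp
  spots$compartment_flagged <- is.na(dn)
  spots
}

#' Select nascent-transcription candidate foci
#'
#' Nuclei with two or fewer foci have all foci flagged; nuclei with more
#' have exactly their two brightest foci flagged. Intensity ties are
#' broken by coordinate lexicographic order (z, then y, then x).
#'
#' @param spots Spot data frame with `nucleus_id` and `intensity` (and
#'   coordinate columns for tie-breaking).
#' @return `spots` with a logical `nascent_candidate` column.
#' @export
select_nascent_foci <- function(spots) {
  spots$nascent_candidate <- FALSE
  if (nrow(spots) == 0L) return(spots)
  zc <- spots$z_um %||% rep(0, nrow(spots))
  yc <- spots$y_um %||% rep(0, nrow(spots))
  xc <- spots$x_um %||% rep(0, nrow(spots))
  for (nl in unique(spots$nucleus_id)) {
    sel <- which(spots$nucleus_id == nl)
    if (length(sel) <= 2L) {
      spots$nascent_candidate[sel] <- TRUE
    } else {
      ord <- sel[order(-spots$intensity[sel], zc[sel], yc[sel], xc[sel])]
      spots$nascent_candidate[ord[1:2]] <- TRUE
    }
  }
  spots
}

#' Match detected spots to ground-truth spots
#'
#' Greedy nearest-neighbour matching with a distance gate, for evaluating
#' detection against a generated scene.
#'
#' @param detected,truth Data frames with physical coordinate columns
#'   `z_um`, `y_um`, `x_um`.
#' @param gate Maximum match distance in µm (default 0.5).
#' @return A list with `matches` (data frame of detected/truth index
#'   pairs and distances), `recall`, `precision` and `rmse` (µm, over
#'   matched pairs).
#' @export
match_spots <- function(detected, truth, gate = 0.5) {
  cc <- c("z_um", "y_um", "x_um")
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L) {
    return(list(matches = data.frame(), recall = 0, precision = 0,
                rmse = NA_real_))
  }
  dm <- as.matrix(stats::dist(rbind(as.matrix(detected[, cc]),
                                    as.matrix(truth[, cc]))))
  dm <- dm[seq_len(nd), nd + seq_len(nt), drop = FALSE]
  pairs <- list()
  used_d <- logical(nd); used_t <- logical(nt)
  repeat {
    if (all(used_d) || all(used_t)) break
    m <- min(dm[!used_d, !used_t, drop = FALSE])
    if (!is.finite(m) || m > gate) break
    w <- which(dm == m & outer(!used_d, !used_t), arr.ind = TRUE)[1L, ]
    pairs[[length(pairs) + 1L]] <- data.frame(detected = w[1L],
                                              truth = w[2L], dist = m)
    used_d[w[1L]] <- TRUE
    used_t[w[2L]] <- TRUE
    if (all(used_d) || all(used_t)) break
  }
  matches <- if (length(pairs)) do.call(rbind, pairs) else data.frame()
  k <- nrow(matches)
  list(matches = matches,
       recall = k / nt,
       precision = k / nd,
       rmse = if (k) sqrt(mean(matches$dist^2)) else NA_real_)
}
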