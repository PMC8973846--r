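# Nucleus and nucleolus segmentation, 2D and 3D.
#
# Nuclei: Gaussian smoothing (isotropic in physical units), global Otsu
# threshold, hole filling, distance-transform watershed to split touching
# objects, small-object removal, canonical relabelling. Nucleoli: Otsu
# per nucleus footprint, restricted to the nucleus, holes filled so
# ring-like (hollow) nucleoli yield their full disk. Connectivity is
# 8-neighbourhood in 2D and 26-neighbourhood in 3D throughout.

#' Segment nuclei from a nuclear-stain channel
#'
#' @param stack An [image_stack()] (2D or 3D).
#' @param channel Name of the nuclear channel (e.g. `"DAPI"`).
#' @param min_size Minimum object size in pixels/voxels; smaller objects
#'   are removed.
#' @param smoothing_sigma Gaussian pre-smoothing SD in lateral pixels.
#'   the axial sigma is scaled by the spacing ratio so smoothing is
#'   isotropic in physical units.
#' @param min_separation Minimum physical distance (µm) between watershed
#'   seeds; defaults to half the largest object radius found in the
#'   distance transform (roughly half the expected nucleus radius).
#' @return A [label_mask()]; labels are sorted by centroid lexicographic
#'   order, and the attribute `border_labels` lists labels touching the
#'   image border (retained but flagged).
#' @export
segment_nuclei <- function(stack, channel, min_size = 200,
                           smoothing_sigma = 2, min_separation = NULL) {
  .assert(inherits(stack, "ImageStack"), "stack must be an ImageStack")
  .assert(min_size >= 0, "min_size must be >= 0")
  img <- get_channel(stack, channel)
  d <- dim(img)
  nd <- length(d)
  sp <- stack$spacing
  sigma_vox <- smoothing_sigma * sp[nd] / sp
  sm <- .gauss_sep(img, d, sigma_vox)
  thr <- .otsu(sm)
  mask <- array(sm > thr, d)
  if (!any(mask)) {
    warning("thresholding found no foreground; returning an empty mask",
            call. = FALSE)
    return(label_mask(array(0L, d), sp))
  }
  mask <- .fill_holes(mask)
  ed <- sqrt(.edt_sq(mask, d, sp))
  if (is.null(min_separation)) min_separation <- 0.5 * max(ed)
  # watershed seeds: distance-transform maxima with minimum separation
  cand <- which(.local_maxima(ed, d) & mask)
  cand <- cand[order(-ed[cand], cand)]
  keep <- integer(0)
  keep_xy <- matrix(numeric(0), 0, nd)
  for (i in cand) {
    p <- (arrayInd(i, d) - 1) * sp
    if (nrow(keep_xy) == 0 ||
        all(sqrt(rowSums(sweep(keep_xy, 2L, as.numeric(p))^2)) >=
              min_separation)) {
      keep <- c(keep, i)
      keep_xy <- rbind(keep_xy, as.numeric(p))
    }
  }
  seeds <- array(0L, d)
  seeds[keep] <- seq_along(keep)
  lab <- .flood_watershed(ed, seeds, mask, d)
  lab <- .filter_small(lab, min_size)
  lab <- .canonical_relabel(lab)
  out <- label_mask(lab, sp)
  attr(out, "border_labels") <- .border_labels(lab)
  out
}

.filter_small <- function(lab, min_size) {
  if (min_size <= 0) return(lab)
  sz <- tabulate(lab[lab > 0L])
  drop <- which(sz > 0L & sz < min_size)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

.border_labels <- function(lab) {
  d <- dim(lab)
  nd <- length(d)
  border <- array(FALSE, d)
  if (nd == 2L) {
    border[c(1L, d[1L]), ] <- TRUE
    border[, c(1L, d[2L])] <- TRUE
  } else {
    border[c(1L, d[1L]), , ] <- TRUE
    border[, c(1L, d[2L]), ] <- TRUE
    border[, , c(1L, d[3L])] <- TRUE
  }
  sort(setdiff(unique(lab[border]), 0L))
}

#' Segment nucleoli within segmented nuclei
#'
#' Applies an Otsu threshold to the nucleolar channel separately within
#' each nucleus footprint (local thresholding), discards nucleolar pixels
#' outside any nucleus, fills holes so ring-like nucleoli give their full
#' disk, removes small objects, and assigns each nucleolus its parent
#' nucleus.
#'
#' Ring-like nucleoli have three intensity classes inside a nucleus
#' (nucleoplasm, nucleolar interior, bright rim), so the local threshold
#' is the lower cut of a three-class Otsu, keeping the middle and upper
#' classes as nucleolar signal. A bimodality guard (foreground mean must
#' exceed the background mean by 3 background SDs) leaves nuclei without
#' nucleolar signal empty instead of thresholding their noise.
#'
#' @param stack An [image_stack()].
#' @param channel Nucleolar marker channel name (e.g. `"B23"`).
#' @param nuclei Nucleus [label_mask()] aligned with `stack`.
#' @param min_size Minimum nucleolus size in pixels/voxels.
#' @param smoothing_sigma Gaussian pre-smoothing SD in lateral pixels.
#' @return A [label_mask()] with attribute `parents`: an integer vector
#'   mapping each nucleolus label to its parent nucleus label.
#' @export
segment_nucleoli <- function(stack, channel, nuclei, min_size = 20,
                             smoothing_sigma = 0.5) {
  .assert(inherits(nuclei, "LabelMask"), "nuclei must be a LabelMask")
  .check_aligned(stack, nuclei)
  img <- get_channel(stack, channel)
  d <- dim(img)
  nd <- length(d)
  sp <- stack$spacing
  if (smoothing_sigma > 0) {
    img <- .gauss_sep(img, d, smoothing_sigma * sp[nd] / sp)
  }
  mask <- array(FALSE, d)
  for (nl in setdiff(unique(as.vector(nuclei$labels)), 0L)) {
    inside <- nuclei$labels == nl
    vals <- img[inside]
    thr2 <- .otsu3(vals)
    if (!is.finite(thr2[1L])) next
    # use the lower cut only when the middle class is signal-like
    # (well above the lower class); otherwise the middle class is
    # background noise and the upper cut is the nucleolar threshold
    m0 <- mean(vals[vals <= thr2[1L]])
    s0 <- stats::sd(vals[vals <= thr2[1L]])
    if (!is.finite(s0) || s0 == 0) s0 <- .Machine$double.eps
    mid <- vals[vals > thr2[1L] & vals <= thr2[2L]]
    thr <- if (length(mid) && mean(mid) - m0 > 3 * s0) thr2[1L] else
      thr2[2L]
    fg <- vals > thr
    if (!any(fg) || all(fg)) next
    mu_bg <- mean(vals[!fg])
    sd_bg <- stats::sd(vals[!fg])
    if (!is.finite(sd_bg) || sd_bg == 0) sd_bg <- .Machine$double.eps
    if (mean(vals[fg]) - mu_bg <= 3 * sd_bg) next
    mask[inside][fg] <- TRUE
  }
  if (!any(mask)) {
    out <- label_mask(array(0L, d), stack$spacing)
    attr(out, "parents") <- integer(0)
    return(out)
  }
  mask <- .fill_holes(mask)
  mask <- mask & nuclei$labels > 0L      # holes filled, then re-clipped
  lab <- .cc_label(mask, d)
  lab <- .filter_small(lab, min_size)
  lab <- .canonical_relabel(lab)
  labs <- setdiff(unique(as.vector(lab)), 0L)
  parents <- integer(length(labs))
  for (k in seq_along(labs)) {
    par <- nuclei$labels[lab == labs[k]]
    par <- par[par > 0L]
    parents[k] <- if (length(par)) as.integer(names(which.max(table(par))))
                  else 0L
  }
  names(parents) <- labs
  out <- label_mask(lab, stack$spacing)
  attr(out, "parents") <- parents
  out
}

#' Per-nucleus intensity and content table
#'
#' One record per nucleus: physical centroid, size, arithmetic mean
#' intensity of every channel over the nucleus mask, and the contained
#' nucleolus labels.
#'
#' @param stack An [image_stack()].
#' @param nuclei Nucleus [label_mask()].
#' @param nucleoli Optional nucleolus [label_mask()] from
#'   [segment_nucleoli()].
#' @return A data frame with columns `nucleus_id`, one centroid column
#'   per axis (µm), `size_px` (pixel/voxel count), `mean_<channel>` per
#'   channel, `n_nucleoli` and `nucleolus_ids` (comma-separated).
#' @export
build_nucleus_table <- function(stack, nuclei, nucleoli = NULL) {
  .check_aligned(stack, nuclei)
  if (!is.null(nucleoli)) .check_aligned(stack, nucleoli)
  lab <- nuclei$labels
  d <- dim(lab)
  nd <- length(d)
  labs <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(labs) == 0L) return(data.frame())
  idx <- which(lab > 0L)
  li <- lab[idx]
  coords <- .phys_coords(arrayInd(idx, d), nuclei$spacing)
  cent <- rowsum(coords, li) / as.vector(table(li))
  axis_names <- if (nd == 2L) c("y", "x") else c("z", "y", "x")
  out <- data.frame(nucleus_id = labs,
                    size_px = as.vector(table(li)))
  for (a in seq_len(nd)) {
    out[[paste0("centroid_", axis_names[a], "_um")]] <- cent[, a]
  }
  for (nm in names(stack$channels)) {
    v <- stack$channels[[nm]][idx]
    out[[paste0("mean_", nm)]] <- as.vector(rowsum(v, li)) /
      as.vector(table(li))
  }
  if (!is.null(nucleoli)) {
    parents <- attr(nucleoli, "parents")
    ids <- vapply(labs, function(nl) {
      ks <- names(parents)[parents == nl]
      paste(ks, collapse = ";")
    }, character(1))
    out$n_nucleoli <- vapply(labs, function(nl) sum(parents == nl),
                             integer(1))
    out$nucleolus_ids <- ids
  }
  rownames(out) <- NULL
  out
}
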