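# Brute-force oracles, independent of the package's compiled primitives,
# plus small fixture builders used across the test files.

# Exhaustive Euclidean distance from every foreground pixel to the
# nearest background pixel (O(n_fg * n_bg); fine for small patches).
bf_interior_distance <- function(mask) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, d[1L], d[2L])
  for (k in seq_len(nrow(fg))) {
    dd <- sqrt((bg[, 1L] - fg[k, 1L])^2 + (bg[, 2L] - fg[k, 2L])^2)
    out[fg[k, 1L], fg[k, 2L]] <- min(dd)
  }
  out
}

# Ring ratio recomputed directly from raw pixels via the brute-force
# distance map and quartile shells.
bf_ring_ratio <- function(intensity, mask, n_layers = 4L) {
  ed <- bf_interior_distance(mask)
  nd <- ed / max(ed)
  lay <- matrix(0L, nrow(mask), ncol(mask))
  lay[mask] <- pmin(n_layers, ceiling(nd[mask] * n_layers))
  mean(intensity[lay == 1L]) / mean(intensity[lay == n_layers])
}

# Crofton perimeter recomputed with rle() run counting per scan line.
bf_crofton_perimeter <- function(mask) {
  count_runs <- function(v) {
    r <- rle(v)
    sum(r$values)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- sum(apply(mask, 1L, count_runs))
  r90 <- sum(apply(mask, 2L, count_runs))
  diag_runs <- function(m) {
    tot <- 0
    for (k in (-(nrow(m) - 1L)):(ncol(m) - 1L)) {
      v <- m[row(m) + k == col(m)]
      if (length(v)) tot <- tot + count_runs(v)
    }
    tot
  }
  r45 <- diag_runs(mask)
  r135 <- diag_runs(mask[nrow(mask):1L, , drop = FALSE])
  pi * (r0 + r90 + (r45 + r135) / sqrt(2)) / 4
}

bf_form_factor <- function(mask) {
  4 * pi * sum(mask) / bf_crofton_perimeter(mask)^2
}

bf_zscores <- function(values, genes) {
  mu <- sum(values) / length(values)
  sdv <- sqrt(sum((values - mu)^2) / (length(values) - 1))
  vapply(unique(genes), function(g) {
    gv <- values[genes == g]
    (sum(gv) / length(gv) - mu) / sdv
  }, numeric(1))
}

bf_chisq <- function(tb) {
  E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  stat <- sum((tb - E)^2 / E)
  df <- (nrow(tb) - 1) * (ncol(tb) - 1)
  list(statistic = stat, p = pchisq(stat, df, lower.tail = FALSE))
}

# Digital disk mask of radius r, optionally centred off-grid.
disk_mask <- function(r, pad = 3, cy = NULL, cx = NULL) {
  n <- as.integer(2 * ceiling(r) + 2 * pad + 1)
  if (is.null(cy)) cy <- (n + 1) / 2
  if (is.null(cx)) cx <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n)
  (yy - cy)^2 + (t(yy) - cx)^2 <= r^2
}

# Compact connected mask of an exact pixel count: the `area` pixels of a
# large disk closest to its centre.
exact_area_mask <- function(area, n = 41L) {
  c0 <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n)
  dd <- (yy - c0)^2 + (t(yy) - c0)^2
  ord <- order(dd, seq_along(dd))
  m <- matrix(FALSE, n, n)
  m[ord[seq_len(area)]] <- TRUE
  m
}

# Compact elongated mask of exact pixel count (elliptical fill order);
# clearly non-circular, so its FormFactor stays below 1 at every size.
ellipse_area_mask <- function(area, n = 41L, aspect = 1.6) {
  c0 <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n)
  dd <- ((yy - c0) * aspect)^2 + ((t(yy) - c0) / aspect)^2
  ord <- order(dd, seq_along(dd))
  m <- matrix(FALSE, n, n)
  m[ord[seq_len(area)]] <- TRUE
  m
}

# Small 3D FISH scene spec used by several tests; generation is cheap
# (about half a second) and segmentation-friendly.
small_fish_spec <- function(seed, ...) {
  args <- list(image_shape = c(32L, 160L, 160L),
               spacing = c(0.25, 0.12, 0.12),
               n_nuclei = 3L, nucleus_radius_px = c(25, 2),
               nucleoli_per_nucleus = c(1L, 2L),
               spots_per_nucleus = c(2L, 2L),
               spot_compartment_probs = c(0.5, 0.4, 0.1),
               snr = 10, seed = seed)
  do.call(scene_spec, utils::modifyList(args, list(...)))
}

# Generate 3D scenes, transparently re-drawing the rare specs whose
# randomly drawn geometry cannot host all requested spots.
generate_fish_scenes <- function(n, base_seed, spec_fun = small_fish_spec,
                                 ...) {
  out <- vector("list", n)
  got <- 0L
  try_seed <- base_seed
  while (got < n) {
    sc <- tryCatch(make_fish_scene_3d(spec_fun(seed = try_seed, ...)),
                   nucleoshape_placement_error = function(e) NULL)
    if (!is.null(sc)) {
      got <- got + 1L
      out[[got]] <- sc
    }
    try_seed <- try_seed + 1L
  }
  out
}
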