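# Internal helpers shared across modules.

#' @useDynLib nucleoshape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.assert <- function(cond, msg, class = "nucleoshape_error") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-stream seed for object `i` under master seed `seed`;
# kept inside the 32-bit signed integer range.
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

# Otsu threshold of an intensity array. Otsu's criterion depends only on
# the histogram, so arrays of any dimensionality are wrapped as a flat
# EBImage image; values are rescaled to [0, 1] for the 256-bin histogram
# and the threshold is mapped back to the original scale.
.otsu <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo) return(Inf)  # constant image: nothing above threshold
  u <- (v - lo) / (hi - lo)
  thr <- EBImage::otsu(EBImage::Image(u, dim = c(length(u), 1L)),
                       range = c(0, 1), levels = 256L)
  lo + as.numeric(thr) * (hi - lo)
}

# Three-class Otsu: the pair of thresholds maximising between-class
# variance over a 128-bin histogram. Used for nucleolar thresholding,
# where ring-like rims, filled nucleoli and nucleoplasm form three
# intensity classes; the lower threshold separates nucleoplasm from all
# nucleolar signal (middle + upper classes kept as foreground).
.otsu3 <- function(v) {
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(c(Inf, Inf))
  nb <- 128L
  b <- pmin(nb, 1L + floor((v - lo) / (hi - lo) * nb))
  h <- tabulate(b, nb) / length(v)
  mids <- lo + (seq_len(nb) - 0.5) * (hi - lo) / nb
  cw <- cumsum(h)
  cm <- cumsum(h * mids)
  best <- -Inf; t1 <- 1L; t2 <- 2L
  for (i in 1L:(nb - 2L)) {
    w0 <- cw[i]
    if (w0 <= 0) next
    m0 <- cm[i] / w0
    for (j in (i + 1L):(nb - 1L)) {
      w1 <- cw[j] - cw[i]
      w2 <- 1 - cw[j]
      if (w1 <= 0 || w2 <= 0) next
      m1 <- (cm[j] - cm[i]) / w1
      m2 <- (cm[nb] - cm[j]) / w2
      mt <- cm[nb]
      v_b <- w0 * (m0 - mt)^2 + w1 * (m1 - mt)^2 + w2 * (m2 - mt)^2
      if (v_b > best) { best <- v_b; t1 <- i; t2 <- j }
    }
  }
  lo + c(t1, t2) * (hi - lo) / nb
}

# Fill interior holes of a binary mask (2D or 3D): background components
# not connected to the array border are converted to foreground.
.fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- .cc_label(!mask, d)
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
  outside <- unique(bg[border & bg > 0L])
  mask | (bg > 0L & !(bg %in% outside))
}

# Centroid (1-based array index units) of each positive label; returns a
# matrix with one row per label, ordered by label value.
.label_centroids <- function(labels) {
  d <- dim(labels)
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(matrix(numeric(0), ncol = length(d) + 1L))
  }
  lab <- labels[idx]
  coords <- arrayInd(idx, d)
  out <- rowsum(cbind(coords, 1), lab)
  labs <- as.integer(rownames(out))
  cent <- out[, seq_along(d), drop = FALSE] / out[, length(d) + 1L]
  cbind(label = labs, cent)
}

# Relabel objects canonically: labels sorted by centroid lexicographic
# order along array axes, 1..k. Keeps output independent of discovery
# order.
.canonical_relabel <- function(labels) {
  cent <- .label_centroids(labels)
  if (nrow(cent) == 0L) return(labels)
  ord <- do.call(order, lapply(seq_len(ncol(cent) - 1L) + 1L,
                               function(j) cent[, j]))
  old <- cent[ord, 1L]
  map <- integer(max(old))
  map[old] <- seq_along(old)
  out <- labels
  pos <- labels > 0L
  out[pos] <- map[labels[pos]]
  out
}

# Physical coordinates (µm) of 1-based voxel indices: coordinate of voxel
# i along an axis is (i - 1) * spacing.
.phys_coords <- function(index_matrix, spacing) {
  sweep(index_matrix - 1, 2L, spacing, `*`)
}

.voxel_diag <- function(spacing) sqrt(sum(spacing^2))
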