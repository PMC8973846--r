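#' Multi-channel image stack
#'
#' The universal raster container: a named set of 2D `(y, x)` or 3D
#' `(z, y, x)` intensity arrays sharing one geometry, with physical voxel
#' spacing in micrometres per axis. Physical coordinates follow the
#' convention `coordinate = (index - 1) * spacing`, i.e. 0-based voxel
#' indices scaled by spacing.
#'
#' @param channels Named list of numeric arrays, all with identical `dim`.
#' @param spacing Numeric vector of voxel spacing in µm, one entry per
#'   array axis (`(y, x)` for 2D, `(z, y, x)` for 3D). All entries must
#'   be positive.
#' @return An object of class `ImageStack`.
#' @examples
#' img <- array(runif(32 * 32), c(32, 32))
#' stk <- image_stack(list(DAPI = img), spacing = c(0.1, 0.1))
#' stk
#' @export
image_stack <- function(channels, spacing) {
  .assert(is.list(channels) && length(channels) >= 1L,
          "channels must be a non-empty list of arrays")
  nms <- names(channels)
  .assert(!is.null(nms) && !anyNA(nms) && all(nzchar(nms)) &&
            !anyDuplicated(nms),
          "channel names must be unique non-empty strings")
  dims <- lapply(channels, function(x) dim(x) %||% length(x))
  .assert(all(vapply(dims, identical, logical(1), dims[[1L]])),
          "all channels must share one shape")
  nd <- length(dims[[1L]])
  .assert(nd %in% c(2L, 3L), "channels must be 2D (y,x) or 3D (z,y,x)")
  spacing <- as.numeric(spacing)
  .assert(length(spacing) == nd && all(is.finite(spacing)) &&
            all(spacing > 0),
          "spacing must be positive, one entry per axis")
  channels <- lapply(channels, function(x) {
    storage.mode(x) <- "double"
    x
  })
  structure(list(channels = channels, spacing = spacing),
            class = "ImageStack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat("ImageStack:", paste(d, collapse = " x "),
      sprintf("(%s)", if (length(d) == 2L) "y,x" else "z,y,x"), "\n")
  cat("  spacing (um):", paste(format(x$spacing), collapse = ", "), "\n")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$channels[[1L]])

#' Extract one channel of an ImageStack
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @return The intensity array for that channel.
#' @export
get_channel <- function(stack, channel) {
  .assert(inherits(stack, "ImageStack"), "stack must be an ImageStack")
  .assert(channel %in% names(stack$channels),
          sprintf("channel '%s' not present (have: %s)", channel,
                  paste(names(stack$channels), collapse = ", ")),
          class = "nucleoshape_channel_error")
  stack$channels[[channel]]
}

#' Integer label mask
#'
#' A segmentation result sharing an [image_stack()]'s geometry: an
#' integer array where 0 is background and positive integers identify
#' objects (gaps in the label set are allowed).
#'
#' @param labels Integer array (2D or 3D) of non-negative labels.
#' @param spacing Physical voxel spacing in µm per axis.
#' @return An object of class `LabelMask`.
#' @export
label_mask <- function(labels, spacing) {
  .assert(!is.null(dim(labels)) && length(dim(labels)) %in% c(2L, 3L),
          "labels must be a 2D or 3D array")
  storage.mode(labels) <- "integer"
  .assert(!anyNA(labels) && all(labels >= 0L),
          "labels must be non-negative integers")
  spacing <- as.numeric(spacing)
  .assert(length(spacing) == length(dim(labels)) && all(spacing > 0),
          "spacing must be positive, one entry per axis")
  structure(list(labels = labels, spacing = spacing), class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  d <- dim(x$labels)
  labs <- setdiff(unique(as.vector(x$labels)), 0L)
  cat("LabelMask:", paste(d, collapse = " x "), "-", length(labs),
      "object(s)\n")
  invisible(x)
}

#' @export
dim.LabelMask <- function(x) dim(x$labels)

.check_aligned <- function(a, b) {
  da <- if (inherits(a, "ImageStack")) dim(a$channels[[1L]]) else dim(a$labels)
  db <- if (inherits(b, "ImageStack")) dim(b$channels[[1L]]) else dim(b$labels)
  .assert(identical(da, db) &&
            isTRUE(all.equal(a$spacing, b$spacing)),
          "geometry mismatch: shapes/spacings differ",
          class = "nucleoshape_geometry_error")
}
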