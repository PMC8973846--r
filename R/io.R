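# TIFF and CSV I/O.
#
# Stacks are written as multi-page TIFF with one run of pages per channel
# (channel-major, z within channel), never interleaved planes. The TIFF
# baseline stores samples in [0, 1], so each channel is affinely rescaled
# on write and the scale, spacing, shape and channel names are recorded in
# a JSON sidecar (`<path>.json`) read back by [read_stack()]. Integer
# channels with values in 0..65535 are stored as 16-bit pages and
# round-trip exactly; other channels are stored as 32-bit float pages and
# round-trip to single precision.

.sidecar_path <- function(path) paste0(path, ".json")

#' Write an ImageStack to a multi-page TIFF
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; a JSON sidecar `<path>.json` carrying
#'   spacing, shape and channel metadata is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  .assert(inherits(stack, "ImageStack"), "stack must be an ImageStack")
  d <- dim(stack$channels[[1L]])
  nd <- length(d)
  pages <- list()
  meta_ch <- list()
  for (nm in names(stack$channels)) {
    x <- stack$channels[[nm]]
    v <- as.vector(x)
    is_int <- all(v == round(v)) && min(v) >= 0 && max(v) <= 65535
    if (is_int) {
      lo <- 0; hi <- 65535; bits <- 16L
    } else {
      lo <- min(v); hi <- max(v)
      if (hi <= lo) hi <- lo + 1
      bits <- 32L
    }
    scaled <- (x - lo) / (hi - lo)
    meta_ch[[nm]] <- list(offset = lo, scale = hi - lo, bits = bits)
    if (nd == 2L) {
      pages <- c(pages, list(structure(scaled, bits = bits)))
    } else {
      for (z in seq_len(d[1L])) {
        pages <- c(pages, list(structure(scaled[z, , ], dim = d[2:3],
                                         bits = bits)))
      }
    }
  }
  bits_per_page <- vapply(pages, function(p) attr(p, "bits"), integer(1))
  pages <- lapply(pages, function(p) { attributes(p)$bits <- NULL; p })
  # tiff::writeTIFF takes one bits.per.sample for the whole file
  bits_all <- if (all(bits_per_page == 16L)) 16L else 32L
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits_all,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  .assert(!inherits(ok, "try-error"),
          sprintf("cannot write TIFF '%s'", path),
          class = "nucleoshape_io_error")
  meta <- list(shape = as.integer(d),
               axes = if (nd == 2L) "yx" else "zyx",
               spacing_um = stack$spacing,
               channel_names = names(stack$channels),
               channels = meta_ch,
               bits_per_sample = bits_all)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ImageStack from a multi-page TIFF
#'
#' With the JSON sidecar written by [write_stack()] present, arrays,
#' spacing and channel names are restored (exactly for integer channels).
#' Without it, all pages are stacked into a single channel, spacing falls
#' back to 1 µm per axis, and a warning is emitted.
#'
#' @param path TIFF file path.
#' @param channel_names Optional channel names overriding (and checked
#'   against) the stored ones.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_names = NULL) {
  .assert(file.exists(path), sprintf("file not found: '%s'", path),
          class = "nucleoshape_io_error")
  pages <- try(tiff::readTIFF(path, all = TRUE, info = FALSE),
               silent = TRUE)
  .assert(!inherits(pages, "try-error"),
          sprintf("'%s' is not a readable TIFF", path),
          class = "nucleoshape_format_error")
  if (!is.list(pages)) pages <- list(pages)
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    d <- as.integer(meta$shape)
    nd <- length(d)
    nms <- meta$channel_names
    if (!is.null(channel_names)) {
      .assert(length(channel_names) == length(nms),
              "channel count mismatch with provided names",
              class = "nucleoshape_channel_error")
      nms <- channel_names
    }
    nz <- if (nd == 2L) 1L else d[1L]
    .assert(length(pages) == length(nms) * nz,
            "page count inconsistent with sidecar metadata",
            class = "nucleoshape_format_error")
    channels <- list()
    for (ci in seq_along(nms)) {
      m <- meta$channels[[ci]]
      pg <- pages[(ci - 1L) * nz + seq_len(nz)]
      arr <- if (nd == 2L) pg[[1L]] else {
        a <- array(0, d)
        for (z in seq_len(nz)) a[z, , ] <- pg[[z]]
        a
      }
      arr <- arr * m$scale + m$offset
      if (m$bits == 16L) arr <- round(arr)
      channels[[nms[ci]]] <- arr
    }
    return(image_stack(channels, as.numeric(meta$spacing_um)))
  }
  # No metadata: single channel, unit spacing, warn.
  nz <- length(pages)
  d2 <- dim(pages[[1L]])
  arr <- if (nz == 1L) pages[[1L]] else {
    a <- array(0, c(nz, d2))
    for (z in seq_len(nz)) a[z, , ] <- pages[[z]]
    a
  }
  nd <- length(dim(arr))
  warning(sprintf(
    "'%s' carries no spacing metadata; assuming %s um voxels", path,
    paste(rep(1, nd), collapse = "x")), call. = FALSE)
  nm <- if (is.null(channel_names)) "ch1" else {
    .assert(length(channel_names) == 1L,
            "channel count mismatch with provided names",
            class = "nucleoshape_channel_error")
    channel_names
  }
  out <- image_stack(stats::setNames(list(arr), nm), spacing = rep(1, nd))
  out$spacing_inferred <- TRUE
  out
}

#' Write a LabelMask as an integer TIFF
#'
#' Labels up to 65535 are stored losslessly as 16-bit pages with the same
#' sidecar scheme as [write_stack()].
#'
#' @param mask A [label_mask()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  .assert(inherits(mask, "LabelMask"), "mask must be a LabelMask")
  .assert(max(mask$labels) <= 65535L,
          "labels above 65535 are not supported by the 16-bit writer",
          class = "nucleoshape_io_error")
  stk <- image_stack(list(labels = mask$labels + 0), mask$spacing)
  write_stack(stk, path)
}

#' Read a LabelMask written by [write_mask()]
#'
#' @param path TIFF file path.
#' @return A [label_mask()].
#' @export
read_mask <- function(path) {
  stk <- read_stack(path)
  label_mask(array(as.integer(round(stk$channels[[1L]])),
                   dim(stk$channels[[1L]])),
             stk$spacing)
}

#' Write a record table to CSV
#'
#' Comma-separated, UTF-8, `.` decimal, mandatory header row. Numeric
#' columns are printed with the C `%.17g` format so re-reading reproduces
#' doubles bit-exactly. Optional provenance lines are written as leading
#' `#` comments (skipped by [read_tables()]).
#'
#' @param records A data frame (possibly with zero rows).
#' @param path Output CSV path.
#' @param header_lines Optional character vector of provenance lines,
#'   written as `# `-prefixed comments before the header.
#' @return `path`, invisibly.
#' @export
write_tables <- function(records, path, header_lines = NULL) {
  .assert(is.data.frame(records), "records must be a data frame")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- sprintf("%.17g", out[[j]])
      out[[j]][out[[j]] == "NA"] <- NA
    }
  }
  con <- try(file(path, open = "wt", encoding = "UTF-8"), silent = TRUE)
  .assert(!inherits(con, "try-error"),
          sprintf("cannot open '%s' for writing", path),
          class = "nucleoshape_io_error")
  on.exit(close(con))
  if (!is.null(header_lines) && length(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  utils::write.table(out, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", na = "NA")
  invisible(path)
}

#' Read a record table written by [write_tables()]
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_tables <- function(path) {
  .assert(file.exists(path), sprintf("file not found: '%s'", path),
          class = "nucleoshape_io_error")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
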