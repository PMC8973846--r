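# Screen Z-score statistics and the categorical/group tests used to
# compare cell populations.

#' Construct a screen plate
#'
#' @param wells Data frame with columns `well_id`, `gene` and
#'   `percent_positive` (percent reporter-positive cells, in `[0, 100]`).
#' @param plate_id Plate identifier.
#' @return A `ScreenPlate` object.
#' @export
screen_plate <- function(wells, plate_id = "plate1") {
  .assert(is.data.frame(wells) &&
            all(c("well_id", "gene", "percent_positive") %in% names(wells)),
          "wells must have columns well_id, gene, percent_positive")
  .assert(nrow(wells) >= 2L, "a plate needs at least 2 wells (SD must exist)")
  .assert(all(wells$percent_positive >= 0 & wells$percent_positive <= 100),
          "percent_positive must lie in [0, 100]")
  structure(list(wells = wells, plate_id = plate_id),
            class = "ScreenPlate")
}

#' @export
print.ScreenPlate <- function(x, ...) {
  cat("ScreenPlate", x$plate_id, "-", nrow(x$wells), "wells,",
      length(unique(x$wells$gene)), "gene targets\n")
  invisible(x)
}

#' Plate-normalised Z-scores per gene
#'
#' Each gene's value is the mean percent reporter-positive over its
#' wells; its Z-score is that value minus the mean over all well values
#' of the entire plate (controls included), divided by the plate sample
#' standard deviation (n - 1) over all well values.
#'
#' @param plate A [screen_plate()].
#' @return A `ZScoreResult` data frame with columns `gene`,
#'   `mean_percent_positive`, `z_score` and `n_wells`; plate mean and SD
#'   are attached as attributes.
#' @export
plate_zscores <- function(plate) {
  .assert(inherits(plate, "ScreenPlate"), "plate must be a ScreenPlate")
  v <- plate$wells$percent_positive
  mu <- mean(v)
  sd_ <- stats::sd(v)
  if (!is.finite(sd_) || sd_ == 0) {
    stop(structure(class = c("nucleoshape_degenerate_plate_error", "error",
                             "condition"),
                   list(message = "plate SD is zero: Z-scores undefined",
                        call = NULL)))
  }
  genes <- unique(plate$wells$gene)
  means <- vapply(genes, function(g)
    mean(v[plate$wells$gene == g]), numeric(1))
  nw <- vapply(genes, function(g) sum(plate$wells$gene == g), integer(1))
  out <- data.frame(gene = genes, mean_percent_positive = as.numeric(means),
                    z_score = (as.numeric(means) - mu) / sd_,
                    n_wells = nw, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "plate_mean") <- mu
  attr(out, "plate_sd") <- sd_
  attr(out, "plate_id") <- plate$plate_id
  class(out) <- c("ZScoreResult", "data.frame")
  out
}

#' Call screen hits from Z-scores
#'
#' A gene is a hit when its Z-score strictly exceeds the cutoff
#' (default 1).
#'
#' @param result A [plate_zscores()] result.
#' @param cutoff Z-score cutoff (strict `>`).
#' @return `result` with a logical `hit` column.
#' @export
call_hits <- function(result, cutoff = 1) {
  .assert("z_score" %in% names(result), "result must carry z_score")
  result$hit <- result$z_score > cutoff
  result
}

#' Pearson chi-squared tests with Bonferroni adjustment
#'
#' Plain Pearson chi-squared without continuity correction on each
#' contingency table; the Bonferroni-adjusted p-value is
#' `min(1, m * p)` over the `m` tables supplied together.
#'
#' @param tables A contingency matrix (at least 2x2, non-negative
#'   counts) or a list of them.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return A data frame with one row per table: `statistic`, `df`,
#'   `p_value`, `p_adjusted`.
#' @export
chi_square_tests <- function(tables, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (is.matrix(tables)) tables <- list(tables)
  .assert(is.list(tables) && length(tables) >= 1L,
          "tables must be a matrix or list of matrices")
  for (tb in tables) {
    .assert(is.matrix(tb) && nrow(tb) >= 2L && ncol(tb) >= 2L,
            "each table must be at least 2x2",
            class = "nucleoshape_input_error")
    .assert(all(tb >= 0), "counts must be non-negative",
            class = "nucleoshape_input_error")
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
      stop(structure(class = c("nucleoshape_degenerate_table_error",
                               "error", "condition"),
                     list(message = "a table has a zero row or column sum",
                          call = NULL)))
    }
  }
  res <- lapply(tables, function(tb)
    suppressWarnings(stats::chisq.test(tb, correct = FALSE)))
  p <- vapply(res, function(r) r$p.value, numeric(1))
  out <- data.frame(
    table = if (!is.null(names(tables))) names(tables)
            else as.character(seq_along(tables)),
    statistic = vapply(res, function(r) unname(r$statistic), numeric(1)),
    df = vapply(res, function(r) unname(r$parameter), numeric(1)),
    p_value = p,
    p_adjusted = if (adjust == "bonferroni")
      stats::p.adjust(p, method = "bonferroni") else p,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-group comparison with automatic Welch correction
#'
#' Two-tailed t-test; the Welch (unequal-variance) variant is used when
#' the ratio of the larger to the smaller group variance exceeds
#' `var_ratio_trigger`, and the variant used is reported.
#'
#' @param values_a,values_b Per-cell measurements (each n >= 2).
#' @param var_ratio_trigger Variance-ratio criterion switching to the
#'   Welch variant (default 4).
#' @return A list with `statistic`, `p_value`, `df`, `variant`
#'   (`"student"` or `"welch"`), and the group means.
#' @export
group_difference <- function(values_a, values_b, var_ratio_trigger = 4) {
  .assert(length(values_a) >= 2L && length(values_b) >= 2L,
          "each group needs at least 2 values",
          class = "nucleoshape_insufficient_data_error")
  va <- stats::var(values_a)
  vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    same <- mean(values_a) == mean(values_b)
    return(list(statistic = if (same) 0 else
                  sign(mean(values_a) - mean(values_b)) * Inf,
                p_value = if (same) 1 else 0,
                df = length(values_a) + length(values_b) - 2,
                variant = "student",
                mean_a = mean(values_a), mean_b = mean(values_b),
                variance_ratio = 1))
  }
  ratio <- max(va, vb) / max(min(va, vb), .Machine$double.xmin)
  welch <- ratio > var_ratio_trigger
  tt <- stats::t.test(values_a, values_b, var.equal = !welch,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic),
       p_value = tt$p.value,
       df = unname(tt$parameter),
       variant = if (welch) "welch" else "student",
       mean_a = mean(values_a), mean_b = mean(values_b),
       variance_ratio = ratio)
}
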