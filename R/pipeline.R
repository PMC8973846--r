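# End-to-end orchestration: scene generation -> segmentation ->
# morphology -> FISH scoring -> screen statistics from one validated
# config, with per-stage outputs persisted for audit and a run report.

#' Build a validated pipeline run configuration
#'
#' Exactly one input source is allowed: either the `"simulate"` stage
#' with a `scene` specification, or an `input_stack` TIFF path.
#'
#' @param output_dir Directory for all outputs (created if needed).
#' @param seed Integer seed injected into every stochastic stage.
#' @param stages Character vector of enabled stages, a subset of
#'   `"simulate"`, `"segment"`, `"morphology"`, `"fish"`, `"screen"`.
#' @param scene Named list of [scene_spec()] arguments for the 2D scene
#'   (seed is supplied from `seed`).
#' @param fish_scene Named list of [scene_spec()] arguments for the 3D
#'   FISH scene; required when the `"fish"` stage is enabled with
#'   simulation.
#' @param input_stack Optional TIFF path used instead of simulation.
#' @param channels Named list mapping roles (`nucleus`, `nucleolus`,
#'   `fish`) to channel names.
#' @param segmentation Named list: `min_size`, `smoothing_sigma`,
#'   `nucleolus_min_size`.
#' @param morphology Named list of [morphology_config()] arguments.
#' @param fish Named list: `threshold`, `min_sigma`, `max_sigma`,
#'   `assoc_tol`, `lamina_tol`.
#' @param screen Named list of [make_screen_plate()] arguments, or
#'   `list(plate_csv = path)` to score an existing plate table.
#' @return A validated `RunConfig` object.
#' @export
run_config <- function(output_dir,
                       seed = 1L,
                       stages = c("simulate", "segment", "morphology"),
                       scene = list(),
                       fish_scene = NULL,
                       input_stack = NULL,
                       channels = list(nucleus = "DAPI",
                                       nucleolus = "B23", fish = "FISH"),
                       segmentation = list(),
                       morphology = list(),
                       fish = list(),
                       screen = NULL) {
  known <- c("simulate", "segment", "morphology", "fish", "screen")
  .assert(all(stages %in% known),
          sprintf("unknown stage(s): %s",
                  paste(setdiff(stages, known), collapse = ", ")))
  simulate <- "simulate" %in% stages
  .assert(simulate + !is.null(input_stack) == 1L ||
            length(stages) == 0L ||
            identical(sort(stages), sort(intersect(stages, "screen"))),
          "exactly one input source: enable 'simulate' or give input_stack")
  if (!is.null(input_stack)) {
    .assert(file.exists(input_stack),
            sprintf("input_stack '%s' not found", input_stack))
  }
  seg <- utils::modifyList(list(min_size = 200, smoothing_sigma = 2,
                                nucleolus_min_size = 20), segmentation)
  fsh <- utils::modifyList(list(threshold = 10, min_sigma = 0.2,
                                max_sigma = 0.45, assoc_tol = 0.25,
                                lamina_tol = 0.5), fish)
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 stages = stages, scene = scene, fish_scene = fish_scene,
                 input_stack = input_stack, channels = channels,
                 segmentation = seg,
                 morphology = do.call(morphology_config, morphology),
                 fish = fsh, screen = screen),
            class = "RunConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [run_config()]
#'   arguments.
#' @return A validated `RunConfig`.
#' @export
read_run_config <- function(path) {
  .assert(file.exists(path), sprintf("config '%s' not found", path),
          class = "nucleoshape_io_error")
  args <- yaml::read_yaml(path)
  do.call(run_config, args)
}

#' Write a RunConfig to YAML (round-trips through [read_run_config()])
#'
#' @param config A `RunConfig`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$morphology <- unclass(x$morphology)
  yaml::write_yaml(x, path)
  invisible(path)
}

.stage_fail <- function(stage, e, outdir) {
  writeLines(c(sprintf("stage: %s", stage), conditionMessage(e)),
             file.path(outdir, "FAILED"))
  stop(structure(class = c("nucleoshape_stage_error", "error", "condition"),
                 list(message = sprintf("stage '%s' failed: %s", stage,
                                        conditionMessage(e)),
                      call = NULL)))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in fixed order (simulate, segment,
#' morphology, fish, screen). Every table is written with a
#' parameter-provenance header; intermediate masks are persisted.
#' Re-running with the same config (same seed) reproduces all tables
#' bit-exactly.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return A `RunReport`: paths of all outputs, per-stage object counts,
#'   a parameter echo and the package version.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  .assert(inherits(config, "RunConfig"), "config must be a RunConfig")
  outdir <- config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  prov <- c(sprintf("nucleoshape %s", as.character(utils::packageVersion("nucleoshape"))),
            sprintf("seed: %d", config$seed),
            sprintf("stages: %s", paste(config$stages, collapse = ",")))
  report <- list(version = as.character(utils::packageVersion("nucleoshape")),
                 seed = config$seed, stages = config$stages,
                 outputs = character(0), counts = list(),
                 parameters = list(segmentation = config$segmentation,
                                   morphology = unclass(config$morphology),
                                   fish = config$fish))
  add_out <- function(p) report$outputs <<- c(report$outputs, p)
  if (length(config$stages) == 0L) {
    class(report) <- "RunReport"
    return(report)
  }

  scene <- NULL
  stack <- NULL
  if ("simulate" %in% config$stages) {
    scene <- tryCatch({
      spec <- do.call(scene_spec, c(config$scene,
                                    list(seed = config$seed)))
      make_cell_scene(spec)
    }, error = function(e) .stage_fail("simulate", e, outdir))
    stack <- scene$stack
    write_stack(stack, file.path(outdir, "scene.tif"))
    add_out(file.path(outdir, "scene.tif"))
    write_tables(scene$truth$nuclei, file.path(outdir, "truth_nuclei.csv"),
                 prov)
    write_tables(scene$truth$nucleoli,
                 file.path(outdir, "truth_nucleoli.csv"), prov)
    add_out(file.path(outdir, "truth_nuclei.csv"))
    add_out(file.path(outdir, "truth_nucleoli.csv"))
    report$counts$simulated_nuclei <- nrow(scene$truth$nuclei)
    report$counts$simulated_nucleoli <- nrow(scene$truth$nucleoli)
  } else if (!is.null(config$input_stack)) {
    stack <- tryCatch(read_stack(config$input_stack),
                      error = function(e) .stage_fail("load", e, outdir))
  }

  needs_image <- any(c("segment", "morphology") %in% config$stages)
  if (needs_image) {
    .assert(!is.null(stack),
            "segment/morphology stages need a simulated scene or input_stack")
    for (role in c("nucleus", "nucleolus")) {
      ch <- config$channels[[role]]
      .assert(ch %in% names(stack$channels),
              sprintf("config references missing channel '%s' (%s)", ch,
                      role),
              class = "nucleoshape_channel_error")
    }
  }

  nuclei <- nucleoli <- NULL
  if ("segment" %in% config$stages) {
    seg <- config$segmentation
    res <- tryCatch({
      nuclei <- segment_nuclei(stack, config$channels$nucleus,
                               min_size = seg$min_size,
                               smoothing_sigma = seg$smoothing_sigma)
      nucleoli <- segment_nucleoli(stack, config$channels$nucleolus,
                                   nuclei,
                                   min_size = seg$nucleolus_min_size)
      tab <- build_nucleus_table(stack, nuclei, nucleoli)
      list(nuclei = nuclei, nucleoli = nucleoli, tab = tab)
    }, error = function(e) .stage_fail("segment", e, outdir))
    nuclei <- res$nuclei; nucleoli <- res$nucleoli
    write_mask(nuclei, file.path(outdir, "nuclei_mask.tif"))
    write_mask(nucleoli, file.path(outdir, "nucleoli_mask.tif"))
    write_tables(res$tab, file.path(outdir, "nucleus_table.csv"), prov)
    add_out(file.path(outdir, "nuclei_mask.tif"))
    add_out(file.path(outdir, "nucleoli_mask.tif"))
    add_out(file.path(outdir, "nucleus_table.csv"))
    report$counts$nuclei <- nrow(res$tab)
    report$counts$nucleoli <- length(attr(nucleoli, "parents"))
  }

  if ("morphology" %in% config$stages) {
    .assert(!is.null(nucleoli),
            "morphology stage needs the segment stage (or run it separately)")
    res <- tryCatch(
      score_population(nucleoli,
                       get_channel(stack, config$channels$nucleolus),
                       cfg = config$morphology),
      error = function(e) .stage_fail("morphology", e, outdir))
    write_tables(res$records, file.path(outdir, "nucleolus_records.csv"),
                 prov)
    cnt <- as.data.frame(res$counts)
    cnt <- cbind(group = rownames(res$counts), cnt)
    write_tables(cnt, file.path(outdir, "ring_contingency.csv"), prov)
    add_out(file.path(outdir, "nucleolus_records.csv"))
    add_out(file.path(outdir, "ring_contingency.csv"))
    report$counts$ring_positive <- sum(res$counts[, "RingShape_pos"])
    report$counts$scored_nucleoli <-
      sum(!res$records$skipped %in% TRUE)
  }

  if ("fish" %in% config$stages) {
    res <- tryCatch({
      .assert(!is.null(config$fish_scene),
              "fish stage needs a fish_scene spec when simulating")
      spec3 <- do.call(scene_spec, c(config$fish_scene,
                                     list(seed = .sub_seed(config$seed,
                                                           99L))))
      fs <- make_fish_scene_3d(spec3)
      .assert(config$channels$fish %in% names(fs$stack$channels),
              sprintf("config references missing channel '%s' (fish)",
                      config$channels$fish),
              class = "nucleoshape_channel_error")
      seg <- config$segmentation
      n3 <- segment_nuclei(fs$stack, config$channels$nucleus,
                           min_size = seg$min_size,
                           smoothing_sigma = seg$smoothing_sigma)
      c3 <- segment_nucleoli(fs$stack, config$channels$nucleolus, n3,
                             min_size = seg$nucleolus_min_size)
      sp <- detect_spots(fs$stack, config$channels$fish, n3,
                         min_sigma = config$fish$min_sigma,
                         max_sigma = config$fish$max_sigma,
                         threshold = config$fish$threshold)
      sp <- measure_distances(sp, n3, c3)
      sp <- assign_compartment(sp, assoc_tol = config$fish$assoc_tol,
                               lamina_tol = config$fish$lamina_tol)
      sp <- select_nascent_foci(sp)
      list(scene = fs, nuclei = n3, spots = sp)
    }, error = function(e) .stage_fail("fish", e, outdir))
    write_stack(res$scene$stack, file.path(outdir, "fish_scene.tif"))
    write_mask(res$nuclei, file.path(outdir, "fish_nuclei_mask.tif"))
    write_tables(res$scene$truth$spots,
                 file.path(outdir, "truth_spots.csv"), prov)
    write_tables(res$spots, file.path(outdir, "fish_spots.csv"), prov)
    comp <- as.data.frame(table(nucleus_id = res$spots$nucleus_id,
                                compartment = res$spots$compartment))
    write_tables(comp, file.path(outdir, "compartment_counts.csv"), prov)
    add_out(file.path(outdir, "fish_scene.tif"))
    add_out(file.path(outdir, "fish_spots.csv"))
    add_out(file.path(outdir, "compartment_counts.csv"))
    report$counts$fish_spots <- nrow(res$spots)
  }

  if ("screen" %in% config$stages) {
    res <- tryCatch({
      scr <- config$screen
      .assert(!is.null(scr), "screen stage needs a screen config")
      plate <- if (!is.null(scr$plate_csv)) {
        screen_plate(read_tables(scr$plate_csv))
      } else {
        args <- scr
        args$gene_effects <- unlist(scr$gene_effects)
        if (is.null(args$seed)) args$seed <- config$seed
        do.call(make_screen_plate, args)
      }
      call_hits(plate_zscores(plate))
    }, error = function(e) .stage_fail("screen", e, outdir))
    write_tables(as.data.frame(res), file.path(outdir, "screen_zscores.csv"),
                 prov)
    add_out(file.path(outdir, "screen_zscores.csv"))
    report$counts$screen_hits <- sum(res$hit)
  }

  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("nucleoshape run report (package", x$version, ")\n")
  cat("  seed:", x$seed, " stages:", paste(x$stages, collapse = ", "), "\n")
  if (length(x$counts)) {
    for (nm in names(x$counts)) cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  }
  if (length(x$outputs)) {
    cat("  outputs:\n")
    for (p in x$outputs) cat("   -", p, "\n")
  }
  invisible(x)
}
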