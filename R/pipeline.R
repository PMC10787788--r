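# Pipeline stages with a YAML config, manifests and reproducible seeds.
# The command-line entry point (inst/cli/sstseg.R) is a thin dispatcher over
# these functions.

#' Read a pipeline run configuration
#'
#' YAML with blocks: `paths` (transcripts, nuclei, profile, out_dir),
#' `pixel_size`, `patch_size`, `elongated_types`, `train` (fields of
#' [train_config()]), `sim` (fields of [sim_config()]), `seed`.
#'
#' @param path YAML file.
#' @return Named list of class `sst_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "sst_run_config")
}

write_manifest <- function(dir, stage, cfg, inputs = character()) {
  hashes <- if (length(inputs)) {
    h <- tools::md5sum(inputs[file.exists(inputs)])
    as.list(h)
  } else list()
  jsonlite::write_json(
    list(stage = stage, time = format(Sys.time(), tz = "UTC"),
         config = unclass(cfg), input_hashes = hashes,
         package_version = as.character(utils::packageVersion("sstseg"))),
    file.path(dir, paste0("manifest_", stage, ".json")), auto_unbox = TRUE)
  invisible(NULL)
}

#' Run pipeline stages
#'
#' `stage` is one of `simulate`, `train`, `predict`, `evaluate`, or `all`
#' (simulate if a `sim` block is present, then train, predict, evaluate).
#' Every stage writes its artifacts and a manifest (config, input hashes,
#' version) into the output directory.
#'
#' @param cfg An `sst_run_config` (or path to one).
#' @param stage Stage name.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(cfg, stage = "all") {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") {
    c(if (!is.null(cfg$sim)) "simulate", "train", "predict", "evaluate")
  } else stage

  if ("simulate" %in% stages) {
    sc <- do.call(sim_config, c(cfg$sim, list(rng_seed = cfg$seed)))
    sim <- simulate_sst(sc)
    sim_dir <- file.path(out_dir, "sim")
    write_sim_dataset(sim, sim_dir)
    # later stages read the simulated artifacts unless paths are given
    if (is.null(cfg$paths$transcripts)) {
      cfg$paths$transcripts <- file.path(sim_dir, "transcripts.csv")
      cfg$paths$nuclei <- file.path(sim_dir, "nuclei.tiff")
      cfg$paths$profile <- file.path(sim_dir, "profile.csv")
      cfg$paths$truth <- file.path(sim_dir, "true_cells.tiff")
    }
    write_manifest(out_dir, "simulate", cfg)
  }

  needs_fit <- any(c("train", "predict", "evaluate") %in% stages)
  if (needs_fit) {
    for (p in c("transcripts", "nuclei", "profile")) {
      if (is.null(cfg$paths[[p]]) || !file.exists(cfg$paths[[p]])) {
        stop("missing input for stage '", stage, "': paths$", p)
      }
    }
    transcripts <- read_transcripts(cfg$paths$transcripts)
    nuclei <- read_label_mask(cfg$paths$nuclei)
    profile <- read_reference_profile(cfg$paths$profile,
                                      unlist(cfg$elongated_types))
    tc_args <- cfg$train
    tc_args$rng_seed <- cfg$seed
    tc <- do.call(train_config, tc_args)
    fit <- sstseg(transcripts, nuclei, profile, config = tc)
    save_checkpoint(fit$params, tc, file.path(out_dir, "checkpoint.rds"))
    utils::write.csv(fit$loss_log, file.path(out_dir, "loss_log.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, "train", cfg,
                   unlist(cfg$paths[c("transcripts", "nuclei", "profile")]))
  }

  if (any(c("predict", "evaluate") %in% stages)) {
    pred <- predict(fit)
    write_label_mask(pred$cell_mask, file.path(out_dir, "cells.tiff"))
    write_gene_cell_matrix(pred$matrix,
                           file.path(out_dir, "gene_cell_matrix.csv"))
    jsonlite::write_json(list(n_cells = pred$n_cells,
                              fraction_assigned = pred$fraction_assigned),
                         file.path(out_dir, "segmentation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, "predict", cfg)
  }

  if ("evaluate" %in% stages) {
    truth <- NULL
    if (!is.null(cfg$paths$truth) && file.exists(cfg$paths$truth)) {
      truth <- list(cell_mask = read_label_mask(cfg$paths$truth))
    }
    report <- evaluate_segmentation(pred, profile, truth = truth)
    write_report(report, file.path(out_dir, "report"))
    write_manifest(out_dir, "evaluate", cfg)
  }
  invisible(out_dir)
}
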