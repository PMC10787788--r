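# The user-facing model interface: fit a self-supervised segmentation model
# on one SST dataset and predict whole-image segmentations from it.

#' Fit a self-supervised cell segmentation model
#'
#' Prepares the dataset (filtering, rasterisation, nucleus typing, expansion
#' masks, marker maps, patch grids) and trains the segmentation backbone on
#' the six biologically-informed losses. Returns a fitted model object;
#' [predict.sstseg()] produces the segmentation and gene-cell matrix.
#'
#' @param transcripts Transcript data.frame (`x`, `y`, `gene`, `qv`).
#' @param nuclei_mask Integer nuclei label mask (H x W).
#' @param profile An `sst_profile` (see [reference_profile()]), carrying the
#'   elongated-cell-type flags.
#' @param config A [train_config()].
#' @param min_qv,exclude_patterns Transcript filtering (see
#'   [filter_transcripts()]).
#' @param round_kernel_d,alpha,l_t,l_vm Expansion-mask parameters (see
#'   [expansion_mask()]).
#' @param marker_percentile,commonality_threshold Training-marker derivation
#'   (see [derive_markers()]).
#' @param verbose Progress messages during training.
#' @return Object of class `sstseg`: the trained weights, loss log, nucleus
#'   summary table, and the prepared dataset.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_sst(sim_config(image_height = 96, image_width = 96,
#'                                n_cells = 8, rng_seed = 7))
#' fit <- sstseg(sim$transcripts, sim$nuclei_mask, sim$profile,
#'               config = train_config(n_iterations = 20, channels = 8,
#'                                     learning_rate = 1e-3))
#' pred <- predict(fit)
#' }
sstseg <- function(transcripts, nuclei_mask, profile,
                   config = train_config(), min_qv = 20,
                   exclude_patterns = c("NegPrb", "Blank-"),
                   round_kernel_d = 20, alpha = 0.9, l_t = 60, l_vm = 3,
                   marker_percentile = 0.10, commonality_threshold = 1 / 3,
                   verbose = FALSE) {
  prep <- prepare_dataset(transcripts, nuclei_mask, profile,
                          patch_size = config$patch_size, min_qv = min_qv,
                          exclude_patterns = exclude_patterns,
                          round_kernel_d = round_kernel_d, alpha = alpha,
                          l_t = l_t, l_vm = l_vm,
                          marker_percentile = marker_percentile,
                          commonality_threshold = commonality_threshold)
  trained <- train_model(prep, config, verbose = verbose)
  structure(list(params = trained$params, loss_log = trained$loss_log,
                 config = config, prep = prep,
                 nuclei_summary = prep$nuclei_summary,
                 call = match.call()),
            class = "sstseg")
}

predict_patches <- function(prep, params, backbone, patches) {
  out <- patches
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (p$empty) {                       # patches empty of nuclei yield no cells
      out[[i]]$labels <- matrix(0L, prep$patch_size, prep$patch_size)
      next
    }
    probs <- forward_patch(list(expression = p$map, nuclei = p$nuclei),
                           params, backbone)
    out[[i]]$labels <- assemble_segmentation(probs)
  }
  out
}

#' Predict the whole-image segmentation from a fitted model
#'
#' Runs patch inference on both grids, merges by nearest patch centre,
#' morphologically refines every cell, and maps transcripts to the final
#' cells.
#'
#' @param object A fitted `sstseg` model.
#' @param newdata Optional list with `transcripts`, `nuclei_mask` (and
#'   optionally a different `profile`) to segment another image with the
#'   trained weights; default: the training dataset.
#' @param refine Apply morphological refinement (default TRUE).
#' @param ... Unused.
#' @return Object of class `sstseg_result`: `cell_mask`, `raw_mask`,
#'   `matrix` (gene-cell counts), `fraction_assigned`, `n_cells`,
#'   `cell_types` (named vector from nucleus typing).
#' @export
predict.sstseg <- function(object, newdata = NULL, refine = TRUE, ...) {
  prep <- if (is.null(newdata)) object$prep else {
    prepare_dataset(newdata$transcripts, newdata$nuclei_mask,
                    if (is.null(newdata$profile)) object$prep$profile else
                      newdata$profile,
                    patch_size = object$config$patch_size,
                    round_kernel_d = object$prep$params_morph$round_kernel_d,
                    alpha = object$prep$params_morph$alpha,
                    l_t = object$prep$params_morph$l_t,
                    l_vm = object$prep$params_morph$l_vm)
  }
  H <- nrow(prep$nuclei_mask); W <- ncol(prep$nuclei_mask)
  prim <- predict_patches(prep, object$params, object$config$backbone,
                          prep$patches_primary)
  shif <- predict_patches(prep, object$params, object$config$backbone,
                          prep$patches_shifted)
  raw <- merge_patch_predictions(prim, shif, H, W)
  mask <- if (refine) refine_mask(raw, prep$nuclei_mask) else raw
  mapped <- map_transcripts_to_cells(prep$transcripts, mask,
                                     colnames(prep$profile))
  types <- stats::setNames(prep$nuclei_summary$type,
                           prep$nuclei_summary$cell_id)
  structure(list(cell_mask = mask, raw_mask = raw, matrix = mapped$matrix,
                 fraction_assigned = mapped$fraction_assigned,
                 n_cells = length(unique(mask[mask > 0])),
                 cell_types = types, prep = prep),
            class = "sstseg_result")
}

#' @export
print.sstseg <- function(x, ...) {
  cat("Self-supervised SST cell segmentation model\n")
  cat(sprintf("  nuclei: %d   genes: %d   image: %d x %d\n",
              nrow(x$nuclei_summary), dim(x$prep$map)[3],
              nrow(x$prep$nuclei_mask), ncol(x$prep$nuclei_mask)))
  cat(sprintf("  backbone: %s (%d channels), %d training steps\n",
              x$config$backbone, x$config$channels, x$config$n_iterations))
  if (nrow(x$loss_log) > 0) {
    cat(sprintf("  final total loss: %.4f\n",
                x$loss_log$total[nrow(x$loss_log)]))
  }
  invisible(x)
}

#' @export
summary.sstseg <- function(object, ...) {
  log <- object$loss_log
  n <- nrow(log)
  type_tab <- table(object$nuclei_summary$type)
  out <- list(
    n_nuclei = nrow(object$nuclei_summary),
    type_counts = type_tab,
    n_elongated = sum(object$nuclei_summary$elongated),
    mean_ecc = mean(object$nuclei_summary$ecc),
    n_steps = n,
    loss_first = if (n >= 1) log[1, -1] else NULL,
    loss_last = if (n >= 1) log[n, -1] else NULL)
  class(out) <- "summary.sstseg"
  out
}

#' @export
print.summary.sstseg <- function(x, ...) {
  cat("Nuclei:", x$n_nuclei, " (", x$n_elongated, "typed elongated; mean ecc",
      sprintf("%.3f", x$mean_ecc), ")\n")
  cat("Type counts:\n"); print(x$type_counts)
  if (!is.null(x$loss_last)) {
    cat(sprintf("Training: %d steps; total loss %.4f -> %.4f\n", x$n_steps,
                x$loss_first$total, x$loss_last$total))
  }
  invisible(x)
}

#' @export
coef.sstseg <- function(object, ...) object$params

#' @export
plot.sstseg <- function(x, ...) {
  log <- x$loss_log
  if (nrow(log) == 0) {
    warning("no training steps logged")
    return(invisible(x))
  }
  graphics::plot(log$step, log$total, type = "l", xlab = "step",
                 ylab = "total loss", main = "Training loss", ...)
  invisible(x)
}

#' @export
print.sstseg_result <- function(x, ...) {
  cat("SST segmentation result\n")
  cat(sprintf("  cells: %d   transcripts assigned: %.1f%%\n",
              x$n_cells, 100 * x$fraction_assigned))
  invisible(x)
}

#' Evaluate a segmentation result
#'
#' Computes the evaluation report: baseline and shape metrics, purity scores
#' and concordance against the reference, spatial diversity, and (when
#' ground truth is supplied) IoU against the true cells.
#'
#' @param result An `sstseg_result`.
#' @param profile An `sst_profile` for markers/concordance (default: the one
#'   used in fitting).
#' @param truth Optional ground truth (`truth` element of [simulate_sst()]).
#' @param region_side Region size for spatial diversity.
#' @return List of class `sstseg_report` with elements `baseline`, `shape`,
#'   `purity`, `concordance`, `diversity`, and optionally `iou`.
#' @export
evaluate_segmentation <- function(result, profile = NULL, truth = NULL,
                                  region_side = NULL) {
  if (is.null(profile)) profile <- result$prep$profile
  mask <- result$cell_mask
  base <- baseline_metrics(result$matrix, mask,
                           n_total_transcripts = nrow(result$prep$transcripts))
  shp <- shape_metrics_mask(mask)
  pm <- derive_purity_markers(profile)
  types <- result$cell_types[rownames(result$matrix)]
  pur <- purity_scores(result$matrix, as.list(types), pm)
  conc <- concordance_with_reference(result$matrix, as.list(types), profile)
  cent <- mask_centroids(mask)
  div <- tryCatch(
    spatial_diversity(mask, as.list(types),
                      base$per_cell, cent, region_side = region_side),
    error = function(e) NULL)
  out <- list(baseline = base, shape = shp, purity = pur,
              concordance = conc, diversity = div)
  if (!is.null(truth)) out$iou <- mask_iou(mask, truth$cell_mask)
  class(out) <- "sstseg_report"
  out
}

#' Write an evaluation report as tidy CSVs + JSON summary
#' @param report An `sstseg_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$baseline$per_cell,
                   file.path(dir, "per_cell.csv"), row.names = FALSE)
  utils::write.csv(report$shape, file.path(dir, "shape.csv"),
                   row.names = FALSE)
  if (!is.null(report$purity$per_type)) {
    utils::write.csv(report$purity$per_type,
                     file.path(dir, "purity_per_type.csv"), row.names = FALSE)
  }
  utils::write.csv(report$concordance$per_type,
                   file.path(dir, "concordance.csv"), row.names = FALSE)
  summary <- list(n_cells = report$baseline$overall$n_cells,
                  proportion_assigned =
                    report$baseline$overall$proportion_assigned,
                  mean_iou = if (!is.null(report$iou)) report$iou$mean_iou
                  else NULL)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
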