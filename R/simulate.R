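# Synthetic subcellular spatial transcriptomics generator.
#
# Cells are non-overlapping ellipses (rotation uniform) whose eccentricity is
# drawn from the range matching their type's elongated flag; nuclei are
# concentric scaled ellipses. Per-cell transcript counts are Poisson; gene
# identities are drawn from the type's profile (a disjoint marker-gene block
# per type, multiplicatively enriched); positions are uniform within the cell
# mask. Background noise transcripts are uniform in space and gene.

#' Simulation configuration
#'
#' @param image_height,image_width Map dimensions in pixels.
#' @param n_cell_types,n_genes,n_cells Counts.
#' @param elongated_type_names Names of elongated types (subset of the
#'   generated type names `type1..typeK`).
#' @param mean_transcripts_per_cell Poisson mean per cell.
#' @param background_noise_rate Expected spurious transcripts per pixel.
#' @param nucleus_to_cell_area_ratio Fraction in (0, 1).
#' @param eccentricity_range_elongated,eccentricity_range_round Intervals in
#'   `[0, 1)` the cell-ellipse eccentricity is drawn from.
#' @param marker_enrichment_fold Multiplicative enrichment of a type's marker
#'   block before renormalisation.
#' @param cell_area_mean Mean cell area in pixel^2 (cell areas are drawn
#'   uniformly within +-20% of this).
#' @param rng_seed Integer seed; all outputs are deterministic given the
#'   config.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(image_height = 256, image_width = 256,
                       n_cell_types = 3, n_genes = 40, n_cells = 50,
                       elongated_type_names = "type3",
                       mean_transcripts_per_cell = 200,
                       background_noise_rate = 0.001,
                       nucleus_to_cell_area_ratio = 0.35,
                       eccentricity_range_elongated = c(0.85, 0.98),
                       eccentricity_range_round = c(0, 0.6),
                       marker_enrichment_fold = 5,
                       cell_area_mean = 500,
                       rng_seed = 1L) {
  cfg <- list(image_height = image_height, image_width = image_width,
              n_cell_types = n_cell_types, n_genes = n_genes,
              n_cells = n_cells,
              elongated_type_names = elongated_type_names,
              mean_transcripts_per_cell = mean_transcripts_per_cell,
              background_noise_rate = background_noise_rate,
              nucleus_to_cell_area_ratio = nucleus_to_cell_area_ratio,
              eccentricity_range_elongated = eccentricity_range_elongated,
              eccentricity_range_round = eccentricity_range_round,
              marker_enrichment_fold = marker_enrichment_fold,
              cell_area_mean = cell_area_mean,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    stopifnot(image_height > 0, image_width > 0, n_cell_types > 0,
              n_genes > 0, n_cells >= 0,
              mean_transcripts_per_cell > 0, background_noise_rate >= 0,
              nucleus_to_cell_area_ratio > 0, nucleus_to_cell_area_ratio < 1,
              all(eccentricity_range_elongated >= 0),
              all(eccentricity_range_elongated < 1),
              all(eccentricity_range_round >= 0),
              all(eccentricity_range_round < 1),
              marker_enrichment_fold > 0, cell_area_mean > 0)
  })
  class(cfg) <- "sim_config"
  cfg
}

sim_type_names <- function(cfg) paste0("type", seq_len(cfg$n_cell_types))
sim_gene_names <- function(cfg) sprintf("g%03d", seq_len(cfg$n_genes))

# disjoint marker block of ceiling(n_genes / n_types) genes per type,
# enriched multiplicatively, renormalised to sampling probabilities
sim_profile_probs <- function(cfg) {
  genes <- sim_gene_names(cfg)
  types <- sim_type_names(cfg)
  block <- ceiling(cfg$n_genes / cfg$n_cell_types)
  probs <- matrix(1, cfg$n_cell_types, cfg$n_genes,
                  dimnames = list(types, genes))
  for (t in seq_along(types)) {
    lo <- (t - 1) * block + 1
    hi <- min(t * block, cfg$n_genes)
    if (lo <= hi) probs[t, lo:hi] <- cfg$marker_enrichment_fold
  }
  probs / rowSums(probs)
}

rasterise_ellipse <- function(h, w, cy, cx, a_semi, b_semi, theta,
                              scale2 = 1) {
  # pixels whose centres satisfy the (scaled) ellipse inequality; pixel (i,j)
  # centre is (i - 0.5, j - 0.5) in continuous (y, x) coordinates
  ri <- max(1, floor(cy - a_semi)):min(h, ceiling(cy + a_semi))
  rj <- max(1, floor(cx - a_semi)):min(w, ceiling(cx + a_semi))
  out <- matrix(FALSE, h, w)
  if (length(ri) == 0 || length(rj) == 0) return(out)
  dy <- matrix(ri - 0.5 - cy, length(ri), length(rj))
  dx <- matrix(rj - 0.5 - cx, length(ri), length(rj), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  out[ri, rj] <- (u / a_semi)^2 + (v / b_semi)^2 <= scale2
  out
}

#' Simulate a synthetic SST dataset
#'
#' @param cfg A [sim_config()].
#' @param max_attempts Bound on rejection-sampling attempts per cell for
#'   non-overlapping placement.
#' @return List with `transcripts` (data.frame x, y, gene, qv),
#'   `nuclei_mask`, `profile` (an `sst_profile`, mean expression =
#'   sampling probability * mean transcripts per cell) and `truth` (list:
#'   `cell_mask`, `nuclei_mask`, `cell_types` named character,
#'   `transcript_origin` integer vector, 0 = background, and the per-cell
#'   geometry table `cells`).
#' @export
simulate_sst <- function(cfg, max_attempts = 200 * max(1, cfg$n_cells)) {
  stopifnot(inherits(cfg, "sim_config"))
  H <- cfg$image_height; W <- cfg$image_width
  types <- sim_type_names(cfg)
  genes <- sim_gene_names(cfg)
  probs <- sim_profile_probs(cfg)
  elong <- types %in% cfg$elongated_type_names

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$rng_seed)

  cell_mask <- matrix(0L, H, W)
  nuc_mask <- matrix(0L, H, W)
  occupied <- matrix(FALSE, H, W)
  cells <- list()
  attempts <- 0
  placed <- 0
  while (placed < cfg$n_cells) {
    attempts <- attempts + 1
    if (attempts > max_attempts) {
      stop(sprintf(paste0(
        "could not place %d non-overlapping cells in %d x %d after %d ",
        "attempts; achievable density ~ %d cells at this size"),
        cfg$n_cells, H, W, max_attempts, placed))
    }
    ty_i <- sample.int(cfg$n_cell_types, 1)
    rng <- if (elong[ty_i]) cfg$eccentricity_range_elongated else
      cfg$eccentricity_range_round
    ecc <- stats::runif(1, rng[1], rng[2])
    area <- stats::runif(1, 0.8, 1.2) * cfg$cell_area_mean
    ratio_ba <- sqrt(1 - ecc^2)
    a_semi <- sqrt(area / (pi * ratio_ba))
    b_semi <- a_semi * ratio_ba
    theta <- stats::runif(1, 0, pi)
    cy <- stats::runif(1, a_semi + 1, H - a_semi - 1)
    cx <- stats::runif(1, a_semi + 1, W - a_semi - 1)
    m <- rasterise_ellipse(H, W, cy, cx, a_semi, b_semi, theta)
    # 1-pixel clearance between neighbouring cells
    if (any(binary_dilate(m, matrix(TRUE, 3, 3)) & occupied)) next
    placed <- placed + 1
    cell_mask[m] <- placed
    nm <- rasterise_ellipse(H, W, cy, cx, a_semi, b_semi, theta,
                            scale2 = cfg$nucleus_to_cell_area_ratio)
    if (!any(nm)) {  # guarantee at least one nucleus pixel
      nm[round(cy) + (round(cx) - 1) * H] <- TRUE
    }
    nuc_mask[nm & m] <- placed
    occupied <- occupied | m
    cells[[placed]] <- data.frame(
      cell_id = placed, type = types[ty_i], cy = cy, cx = cx,
      a_semi = a_semi, b_semi = b_semi, theta = theta, ecc = ecc)
  }
  cells <- if (placed > 0) do.call(rbind, cells) else
    data.frame(cell_id = integer(), type = character(), cy = numeric(),
               cx = numeric(), a_semi = numeric(), b_semi = numeric(),
               theta = numeric(), ecc = numeric())

  # transcripts: per-cell Poisson draws, uniform position within the mask
  xs <- ys <- numeric(0); gs <- character(0); origin <- integer(0)
  for (c_i in seq_len(placed)) {
    n_t <- stats::rpois(1, cfg$mean_transcripts_per_cell)
    if (n_t == 0) next
    pix <- which(cell_mask == c_i)
    pick <- pix[sample.int(length(pix), n_t, replace = TRUE)]
    # pixel (i, j) covers [i-1, i) x [j-1, j) in (y, x)
    pr <- (pick - 1) %% H + 1
    pc <- (pick - 1) %/% H + 1
    ys <- c(ys, pr - 1 + stats::runif(n_t))
    xs <- c(xs, pc - 1 + stats::runif(n_t))
    g_i <- sample.int(cfg$n_genes, n_t, replace = TRUE,
                      prob = probs[cells$type[c_i], ])
    gs <- c(gs, genes[g_i])
    origin <- c(origin, rep.int(c_i, n_t))
  }
  n_bg <- stats::rpois(1, cfg$background_noise_rate * H * W)
  if (n_bg > 0) {
    ys <- c(ys, stats::runif(n_bg, 0, H))
    xs <- c(xs, stats::runif(n_bg, 0, W))
    gs <- c(gs, genes[sample.int(cfg$n_genes, n_bg, replace = TRUE)])
    origin <- c(origin, rep.int(0L, n_bg))
  }
  transcripts <- data.frame(x = xs, y = ys, gene = gs,
                            qv = stats::runif(length(xs), 20, 45))

  profile <- reference_profile(probs * cfg$mean_transcripts_per_cell,
                               intersect(cfg$elongated_type_names, types))
  truth <- list(cell_mask = cell_mask, nuclei_mask = nuc_mask,
                cell_types = stats::setNames(cells$type,
                                             as.character(cells$cell_id)),
                transcript_origin = origin, cells = cells)
  list(transcripts = transcripts, nuclei_mask = nuc_mask, profile = profile,
       truth = truth, config = cfg)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a simulated dataset to disk
#'
#' Transcripts as CSV, masks as 16-bit TIFF, the profile as CSV and the
#' ground truth as CSV (per-cell table) + JSON sidecar (transcript origins).
#'
#' @param sim Result of [simulate_sst()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcripts(sim$transcripts, file.path(dir, "transcripts.csv"))
  write_label_mask(sim$nuclei_mask, file.path(dir, "nuclei.tiff"))
  write_label_mask(sim$truth$cell_mask, file.path(dir, "true_cells.tiff"))
  write_reference_profile(sim$profile, file.path(dir, "profile.csv"))
  utils::write.csv(sim$truth$cells, file.path(dir, "true_cells.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(cell_types = as.list(sim$truth$cell_types),
         transcript_origin = sim$truth$transcript_origin,
         elongated_types = sim$config$elongated_type_names),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Check recovery of generating profiles from ground-truth assignment
#'
#' For each cell type, the Pearson correlation between the generating profile
#' row and the mean expression of that type's cells computed from the
#' ground-truth transcript-to-cell assignment. Types absent from the
#' simulation are reported as `NA` (missing), not an error.
#'
#' @param truth `truth` element of a [simulate_sst()] result.
#' @param transcripts The matching transcript table.
#' @param profile The generating `sst_profile`.
#' @return Named numeric vector of per-type correlations.
#' @export
profile_recovery_check <- function(truth, transcripts, profile) {
  genes <- colnames(profile)
  types <- rownames(profile)
  out <- stats::setNames(rep(NA_real_, length(types)), types)
  assigned <- truth$transcript_origin > 0
  if (!any(assigned)) return(out)
  cell_of <- truth$transcript_origin[assigned]
  gene_of <- factor(transcripts$gene[assigned], levels = genes)
  counts <- table(cell_of, gene_of)
  for (ty in types) {
    ids <- names(truth$cell_types)[truth$cell_types == ty]
    ids <- intersect(ids, rownames(counts))
    if (length(ids) == 0) next
    mean_expr <- colMeans(counts[ids, , drop = FALSE])
    out[ty] <- stats::cor(mean_expr, profile[ty, ])
  }
  out
}
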