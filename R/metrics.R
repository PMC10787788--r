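# Five-category evaluation suite for cell segmentations:
# [A] baseline characteristics (counts, area, density, morphology),
# [B] expression purity vs reference markers and concordance,
# [C] spatial diversity (Shannon entropy vs coefficient of variation),
# [D] neighbour contamination curves, [E] replicability.

#' Baseline per-cell and overall statistics
#'
#' @param matrix Gene-cell count matrix (rows = cells, rownames = labels).
#' @param mask Cell label mask (areas come from pixel counts).
#' @param n_total_transcripts Optional total detected transcripts, used for
#'   the proportion assigned.
#' @return List with `per_cell` (data.frame: cell, n_transcripts, n_genes,
#'   area_px, density), `per_gene` (fraction of cells expressing each gene),
#'   and `overall` (n_cells, total_assigned, proportion_assigned).
#' @export
baseline_metrics <- function(matrix, mask, n_total_transcripts = NULL) {
  areas <- table(factor(mask[mask > 0], levels = rownames(matrix)))
  n_t <- rowSums(matrix)
  n_g <- rowSums(matrix > 0)
  area <- as.numeric(areas)
  per_cell <- data.frame(
    cell = rownames(matrix), n_transcripts = n_t, n_genes = n_g,
    area_px = area,
    density = ifelse(area > 0, n_t / area, 0),
    row.names = NULL)
  per_gene <- colMeans(matrix > 0)
  overall <- list(n_cells = nrow(matrix), total_assigned = sum(matrix),
                  proportion_assigned = if (!is.null(n_total_transcripts))
                    sum(matrix) / n_total_transcripts else NA_real_)
  list(per_cell = per_cell, per_gene = per_gene, overall = overall)
}

#' Cell morphology metrics
#'
#' Eight shape descriptors of one cell, from a boundary polygon or a binary
#' mask (masks are converted via [mask_to_polygon()], then both inputs share
#' one code path): area; elongation = W_bb / H_bb of the (oriented
#' minimum-area, or axis-aligned) bounding box; circularity = 4 pi A /
#' P_convex^2; sphericity = R_I / R_C (maximum inscribed over minimum
#' enclosing circle radius); compactness = 4 pi A / P_cell^2; convexity =
#' P_convex / P_cell; eccentricity = L_minor / L_major from the moment
#' ellipse; solidity = A / A_convex. All seven ratios equal 1 for a circle
#' (elongation 1 for a square) and decrease with irregularity.
#'
#' @param shape Two-column vertex matrix (x, y) or a binary mask matrix.
#' @param bbox `"oriented"` (default) or `"axis"` for the elongation box.
#' @return Named numeric vector of the eight metrics; degenerate shapes
#'   (zero area) give `NA` for all ratios.
#' @export
shape_metrics <- function(shape, bbox = c("oriented", "axis")) {
  bbox <- match.arg(bbox)
  poly <- if (is.matrix(shape) && ncol(shape) == 2 && !all(shape %in% c(0, 1)))
    shape else mask_to_polygon(shape)
  A <- polygon_area(poly)
  if (A <= 0) {
    return(c(area = A, elongation = NA, circularity = NA, sphericity = NA,
             compactness = NA, convexity = NA, eccentricity = NA,
             solidity = NA))
  }
  P_cell <- polygon_perimeter(poly)
  hull <- convex_hull(poly)
  P_convex <- polygon_perimeter(hull)
  A_convex <- polygon_area(hull)
  bb <- if (bbox == "oriented") min_area_bbox(hull) else {
    c(W = diff(range(poly[, 1])), H = diff(range(poly[, 2])))
  }
  R_I <- max_inscribed_radius(poly)
  R_C <- min_enclosing_circle(hull)[3]
  cv <- polygon_covariance(poly)
  lam <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  L_major <- 4 * sqrt(lam[1]); L_minor <- 4 * sqrt(lam[2])
  c(area = unname(A),
    elongation = unname(bb["W"] / bb["H"]),
    circularity = unname(4 * pi * A / P_convex^2),
    sphericity = unname(R_I / R_C),
    compactness = unname(4 * pi * A / P_cell^2),
    convexity = unname(P_convex / P_cell),
    eccentricity = unname(if (L_major > 0) L_minor / L_major else NA),
    solidity = unname(A / A_convex))
}

#' Shape metrics for every cell of a label mask
#' @param mask Integer cell label mask.
#' @inheritParams shape_metrics
#' @return data.frame, one row per label.
#' @export
shape_metrics_mask <- function(mask, bbox = "oriented") {
  ids <- sort(unique(mask[mask > 0]))
  rows <- lapply(ids, function(id) {
    idx <- which(mask == id, arr.ind = TRUE)
    r0 <- max(1, min(idx[, 1]) - 2); r1 <- min(nrow(mask), max(idx[, 1]) + 2)
    c0 <- max(1, min(idx[, 2]) - 2); c1 <- min(ncol(mask), max(idx[, 2]) + 2)
    m <- shape_metrics(mask[r0:r1, c0:c1] == id, bbox)
    data.frame(cell = id, t(m))
  })
  do.call(rbind, rows)
}

prf <- function(predicted, truth_set) {
  tp <- length(intersect(predicted, truth_set))
  precision <- if (length(predicted) > 0) tp / length(predicted) else 0
  recall <- if (length(truth_set) > 0) tp / length(truth_set) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Combine positive and negative marker F1 into the purity F1
#'
#' `2 * (1 - F1_neg) * F1_pos / (1 - F1_neg + F1_pos)`; inputs are expected
#' in `[0, 1]` (identity scaling; optional across-method min-max scaling is
#' applied by the caller before this).
#'
#' @param f1_pos,f1_neg Average positive / negative marker F1 scores.
#' @export
purity_f1 <- function(f1_pos, f1_neg) {
  denom <- 1 - f1_neg + f1_pos
  ifelse(denom > 0, 2 * (1 - f1_neg) * f1_pos / denom, 0)
}

#' Expression-purity scores per cell type
#'
#' Each cell's top-decile genes by expression are its predicted positive
#' genes and its bottom decile the predicted negatives (ties at the decile
#' boundary broken by gene order; zero-count genes are eligible for the
#' bottom decile). These are scored (precision/recall/F1) against the
#' reference marker sets of the cell's assigned type, averaged per type, and
#' combined into the purity F1.
#'
#' @param matrix Gene-cell count matrix.
#' @param types Named character vector: cell id -> type.
#' @param markers Marker sets from [derive_purity_markers()].
#' @return List with `per_cell` (data.frame of P/R/F1 for both polarities)
#'   and `per_type` (averages + `purity_f1`). Types without markers are
#'   excluded with a warning.
#' @export
purity_scores <- function(matrix, types, markers) {
  genes <- colnames(matrix)
  k <- ceiling(0.1 * length(genes))
  rows <- list()
  for (i in seq_len(nrow(matrix))) {
    cell <- rownames(matrix)[i]
    ty <- types[[cell]]
    if (is.null(ty) || !ty %in% names(markers$positive)) next
    if (length(markers$positive[[ty]]) == 0) next
    expr <- stats::setNames(as.numeric(matrix[i, ]), genes)
    ex <- rank_extremes(expr, k)
    p <- prf(ex$top, markers$positive[[ty]])
    n <- prf(ex$bottom, markers$negative[[ty]])
    rows[[length(rows) + 1]] <- data.frame(
      cell = cell, type = ty,
      pos_precision = p[1], pos_recall = p[2], pos_f1 = p[3],
      neg_precision = n[1], neg_recall = n[2], neg_f1 = n[3])
  }
  dropped <- setdiff(unique(unlist(types)), names(markers$positive))
  no_marker <- names(markers$positive)[
    vapply(markers$positive, length, numeric(1)) == 0]
  if (length(c(dropped, no_marker))) {
    warning("types excluded from purity scoring (no markers): ",
            paste(unique(c(dropped, no_marker)), collapse = ", "))
  }
  per_cell <- do.call(rbind, rows)
  if (is.null(per_cell)) return(list(per_cell = NULL, per_type = NULL))
  agg <- stats::aggregate(per_cell[, c("pos_f1", "neg_f1")],
                          by = list(type = per_cell$type), FUN = mean)
  agg$purity_f1 <- purity_f1(agg$pos_f1, agg$neg_f1)
  rownames(agg) <- NULL
  list(per_cell = per_cell, per_type = agg)
}

log_normalise <- function(counts, scale = 1e4) {
  tot <- sum(counts)
  if (tot == 0) return(counts * 0)
  log1p(counts / tot * scale)
}

#' Concordance of segmented expression with the reference
#'
#' Per type: Pearson correlation between the mean log-normalised expression
#' of the segmented cells of that type and the (log1p) reference row; plus
#' the correlation between the observed and reference-implied cell-type
#' proportion vectors (reference proportions taken as uniform when
#' unspecified, so only the observed proportions' correlation against a
#' supplied vector is meaningful; pass `ref_proportions` for a real
#' comparison).
#'
#' @param matrix Gene-cell count matrix.
#' @param types Named character vector: cell id -> type.
#' @param profile An `sst_profile`.
#' @param ref_proportions Optional named reference proportions per type.
#' @return List with `per_type` (data.frame: type, n_cells, pearson_r;
#'   types with < 2 cells or zero-variance references give `NA`) and
#'   `proportion_r` (NA unless `ref_proportions` given).
#' @export
concordance_with_reference <- function(matrix, types, profile,
                                       ref_proportions = NULL) {
  genes <- intersect(colnames(matrix), colnames(profile))
  out <- list()
  for (ty in rownames(profile)) {
    ids <- names(types)[unlist(types) == ty]
    ids <- intersect(ids, rownames(matrix))
    r <- NA_real_
    if (length(ids) >= 2) {
      mean_ln <- colMeans(t(apply(matrix[ids, genes, drop = FALSE], 1,
                                  log_normalise)))
      ref <- log1p(unclass(profile)[ty, genes])
      if (stats::sd(ref) > 0 && stats::sd(mean_ln) > 0) {
        r <- stats::cor(mean_ln, ref)
      }
    }
    out[[ty]] <- data.frame(type = ty, n_cells = length(ids), pearson_r = r)
  }
  per_type <- do.call(rbind, out)
  rownames(per_type) <- NULL
  prop_r <- NA_real_
  if (!is.null(ref_proportions)) {
    obs <- table(factor(unlist(types), levels = rownames(profile)))
    obs <- as.numeric(obs) / max(1, sum(obs))
    ref <- as.numeric(ref_proportions[rownames(profile)])
    if (stats::sd(obs) > 0 && stats::sd(ref) > 0) {
      prop_r <- stats::cor(obs, ref)
    }
  }
  list(per_type = per_type, proportion_r = prop_r)
}

#' Shannon entropy of a composition (natural log)
#' @param x Counts or proportions.
#' @export
shannon_entropy <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Spatial diversity vs variability of cell characteristics
#'
#' Grids the image into square regions; per region computes the Shannon
#' entropy of the cell-type composition (cells assigned by centroid) and the
#' coefficient of variation of each per-cell baseline characteristic; then
#' correlates entropy with each CV across regions.
#'
#' @param mask Cell label mask (for image dimensions).
#' @param types Named character vector: cell id -> type.
#' @param per_cell Per-cell data.frame from [baseline_metrics()] (must have
#'   `cell` plus numeric characteristic columns).
#' @param centroids Two-column matrix (row, col) of cell centroids, rownames
#'   = cell ids.
#' @param region_side Region side length in pixels (default: image split
#'   into ~10 regions per axis).
#' @param min_cells Regions with fewer cells are excluded from CVs
#'   (default 3).
#' @return List with `per_region` (entropy + CVs), `correlations` (Pearson r
#'   of entropy vs each CV; NA when undefined).
#' @export
spatial_diversity <- function(mask, types, per_cell, centroids,
                              region_side = NULL, min_cells = 3) {
  H <- nrow(mask); W <- ncol(mask)
  if (is.null(region_side)) region_side <- max(1, round(min(H, W) / 10))
  ri <- pmin(floor((centroids[, 1] - 1) / region_side), 1e9)
  ci <- pmin(floor((centroids[, 2] - 1) / region_side), 1e9)
  region <- paste0(ri, "_", ci)
  names(region) <- rownames(centroids)
  regs <- unique(region)
  if (length(regs) < 2) stop("need at least 2 non-empty regions")
  chars <- setdiff(names(per_cell)[vapply(per_cell, is.numeric, logical(1))],
                   "cell")
  rows <- list()
  for (rg in regs) {
    ids <- names(region)[region == rg]
    ent <- shannon_entropy(table(unlist(types)[ids]))
    row <- data.frame(region = rg, n_cells = length(ids), entropy = ent)
    for (ch in chars) {
      v <- per_cell[[ch]][match(ids, per_cell$cell)]
      row[[paste0("cv_", ch)]] <- if (length(ids) >= min_cells &&
                                      mean(v, na.rm = TRUE) != 0) {
        stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE)
      } else NA_real_
    }
    rows[[length(rows) + 1]] <- row
  }
  per_region <- do.call(rbind, rows)
  correlations <- vapply(chars, function(ch) {
    cv <- per_region[[paste0("cv_", ch)]]
    ok <- is.finite(cv) & is.finite(per_region$entropy)
    if (sum(ok) < 3 || stats::sd(cv[ok]) == 0 ||
        stats::sd(per_region$entropy[ok]) == 0) return(NA_real_)
    stats::cor(per_region$entropy[ok], cv[ok])
  }, numeric(1))
  list(per_region = per_region, correlations = correlations)
}

#' Neighbour-contamination curve
#'
#' For each cell of type A, the Euclidean distance to the nearest type-B cell
#' centroid; cells are grouped into distance bins and the fraction expressing
#' the given negative marker (a type-B marker) is reported per bin. Lower
#' near-bin fractions indicate less boundary contamination.
#'
#' @param matrix Gene-cell count matrix.
#' @param types Named character vector: cell id -> type.
#' @param centroids Two-column matrix (row, col), rownames = cell ids.
#' @param type_a,type_b Cell-type names.
#' @param marker_genes Character vector of negative-marker genes (markers of
#'   type B).
#' @param breaks Strictly increasing distance-bin edges.
#' @return data.frame: bin, n_cells, fraction_expressing (NA for empty bins).
#' @export
neighbour_contamination <- function(matrix, types, centroids, type_a, type_b,
                                    marker_genes, breaks) {
  stopifnot(all(diff(breaks) > 0))
  tys <- unlist(types)
  a_ids <- names(tys)[tys == type_a]
  b_ids <- names(tys)[tys == type_b]
  if (length(a_ids) == 0 || length(b_ids) == 0) {
    stop("both cell types must be present")
  }
  ca <- centroids[a_ids, , drop = FALSE]
  cb <- centroids[b_ids, , drop = FALSE]
  d <- sqrt(outer(ca[, 1], cb[, 1], `-`)^2 + outer(ca[, 2], cb[, 2], `-`)^2)
  nearest <- apply(d, 1, min)
  gidx <- intersect(marker_genes, colnames(matrix))
  expr <- rowSums(matrix[a_ids, gidx, drop = FALSE]) > 0
  bin <- cut(nearest, breaks, include.lowest = TRUE)
  out <- data.frame(bin = levels(bin))
  out$n_cells <- as.integer(table(bin))
  out$fraction_expressing <- as.numeric(tapply(expr, bin, mean))
  out
}

#' Replicability between two datasets
#'
#' Pearson correlations, across the shared cell types, of the per-type means
#' of each baseline characteristic, plus the correlation of the type
#' proportion vectors.
#'
#' @param per_cell1,per_cell2 Per-cell data.frames ([baseline_metrics()]).
#' @param types1,types2 Named character vectors: cell id -> type.
#' @return List with `characteristic_r` (named vector) and `proportion_r`.
#' @export
replicability <- function(per_cell1, types1, per_cell2, types2) {
  shared <- intersect(unique(unlist(types1)), unique(unlist(types2)))
  if (length(shared) == 0) stop("no shared cell types between replicates")
  chars <- intersect(
    setdiff(names(per_cell1)[vapply(per_cell1, is.numeric, logical(1))],
            "cell"),
    names(per_cell2))
  type_means <- function(per_cell, types, ch) {
    ty <- unlist(types)[as.character(per_cell$cell)]
    vapply(shared, function(t0) mean(per_cell[[ch]][ty == t0], na.rm = TRUE),
           numeric(1))
  }
  characteristic_r <- vapply(chars, function(ch) {
    m1 <- type_means(per_cell1, types1, ch)
    m2 <- type_means(per_cell2, types2, ch)
    ok <- is.finite(m1) & is.finite(m2)
    if (sum(ok) < 2 || stats::sd(m1[ok]) == 0 || stats::sd(m2[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(m1[ok], m2[ok])
  }, numeric(1))
  p1 <- table(factor(unlist(types1), levels = shared))
  p2 <- table(factor(unlist(types2), levels = shared))
  proportion_r <- if (length(shared) >= 2 && stats::sd(p1) > 0 &&
                      stats::sd(p2) > 0) {
    stats::cor(as.numeric(p1) / sum(p1), as.numeric(p2) / sum(p2))
  } else NA_real_
  list(characteristic_r = characteristic_r, proportion_r = proportion_r)
}

#' Centroids of a label mask
#' @param mask Integer label mask.
#' @return Matrix (row, col), rownames = labels.
#' @export
mask_centroids <- function(mask) {
  ids <- sort(unique(mask[mask > 0]))
  out <- t(vapply(ids, function(id) {
    colMeans(which(mask == id, arr.ind = TRUE))
  }, numeric(2)))
  rownames(out) <- ids
  colnames(out) <- c("row", "col")
  out
}

#' Mean intersection-over-union against ground-truth cells
#'
#' Labels are matched by id (predicted cell labels equal their nucleus
#' labels, as do the simulator's ground-truth cells).
#'
#' @param pred,truth Integer label masks.
#' @return List with `per_cell` named IoU vector and `mean_iou`.
#' @export
mask_iou <- function(pred, truth) {
  ids <- sort(unique(truth[truth > 0]))
  iou <- vapply(ids, function(id) {
    p <- pred == id; t0 <- truth == id
    u <- sum(p | t0)
    if (u == 0) return(0)
    sum(p & t0) / u
  }, numeric(1))
  names(iou) <- ids
  list(per_cell = iou, mean_iou = mean(iou))
}
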