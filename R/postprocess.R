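# Whole-image assembly: merge patch predictions from the two staggered grids,
# morphologically refine each cell, and map transcripts to cells.

#' Merge patch predictions from the primary and shifted grids
#'
#' Per pixel, the retained label comes from the patch (from either grid)
#' whose centre is nearest (Euclidean); ties go to the primary grid, then the
#' lower patch origin. Pixels covered only by the primary grid take its
#' prediction.
#'
#' @param primary,shifted Lists of patches (as from [crop_patches()]) with a
#'   `$labels` element added (the per-patch predicted label map).
#' @param height,width Full image dimensions.
#' @return Integer H x W label mask with attribute `provenance` (the winning
#'   grid per pixel, 1 = primary, 2 = shifted).
#' @export
merge_patch_predictions <- function(primary, shifted, height, width) {
  for (p in c(primary, shifted)) {
    if (is.null(p$labels)) {
      stop("missing prediction for patch at origin (",
           p$origin[1], ", ", p$origin[2], ")")
    }
  }
  paste_grid <- function(patches) {
    lab <- matrix(0L, height, width)
    for (p in patches) {
      ps <- nrow(p$labels)
      ii <- p$origin[1]:min(p$origin[1] + ps - 1, height)
      jj <- p$origin[2]:min(p$origin[2] + ps - 1, width)
      lab[ii, jj] <- p$labels[seq_along(ii), seq_along(jj)]
    }
    lab
  }
  lab_p <- paste_grid(primary)
  lab_s <- paste_grid(shifted)
  ps <- nrow(primary[[1]]$labels)
  # squared distance from each pixel to the centre of the covering patch of
  # each grid, separable per axis
  axis_d2 <- function(extent, offset) {
    pos <- seq_len(extent)
    ctr <- offset + ps * floor((pos - 1 - offset) / ps) + (ps + 1) / 2
    (pos - ctr)^2
  }
  d2p <- outer(axis_d2(height, 0), axis_d2(width, 0), `+`)
  d2s <- outer(axis_d2(height, ps / 2), axis_d2(width, ps / 2), `+`)
  covered_s <- matrix(FALSE, height, width)
  for (p in shifted) {
    pss <- nrow(p$labels)
    ii <- p$origin[1]:min(p$origin[1] + pss - 1, height)
    jj <- p$origin[2]:min(p$origin[2] + pss - 1, width)
    covered_s[ii, jj] <- TRUE
  }
  use_s <- covered_s & (d2s < d2p)  # ties -> primary
  out <- lab_p
  out[use_s] <- lab_s[use_s]
  attr(out, "provenance") <- 1L + use_s
  out
}

#' Morphologically refine one cell mask
#'
#' Closing (dilation then erosion, disc in a 5 x 5 window, two iterations
#' each), then the connected component with the largest nucleus overlap is
#' kept (ties: larger component, then lower scan order), its holes are
#' filled, and the nucleus mask is unioned in so the nucleus is always
#' captured. The result is a single 4-connected component containing the
#' nucleus.
#'
#' @param raw Logical/0-1 raw mask of one cell.
#' @param nucleus Logical/0-1 nucleus mask of that cell (non-empty).
#' @return Logical matrix; attribute `empty_input` flags the fallback when
#'   `raw` was empty (the nucleus is returned).
#' @export
refine_cell <- function(raw, nucleus) {
  nucleus <- nucleus > 0
  stopifnot(any(nucleus))
  raw <- raw > 0
  if (!any(raw)) {
    return(structure(nucleus, empty_input = TRUE))
  }
  k5 <- disc_kernel(5)
  m <- binary_dilate(binary_dilate(raw, k5), k5)
  m <- binary_erode(binary_erode(m, k5), k5)
  comp <- label_components(m)
  n_comp <- max(comp)
  if (n_comp > 1) {
    ov <- vapply(seq_len(n_comp), function(k) sum(comp == k & nucleus),
                 numeric(1))
    sz <- vapply(seq_len(n_comp), function(k) sum(comp == k), numeric(1))
    best <- order(-ov, -sz, seq_len(n_comp))[1]
    m <- comp == best
  }
  m <- fill_holes(m)
  m <- m | nucleus
  # union with the nucleus can only reconnect, never split: the nucleus is
  # itself connected, so the result is connected iff the kept component
  # touches it; if it does not (zero overlap), keep nucleus + component
  # merged only when adjacent, else fall back to the nucleus side
  comp2 <- label_components(m)
  if (max(comp2) > 1) {
    keep <- unique(comp2[nucleus])
    m <- comp2 %in% keep[1]
    dim(m) <- dim(comp2)
  }
  structure(m, empty_input = FALSE)
}

#' Refine a full label mask cell by cell
#'
#' Applies [refine_cell()] to every label (on bounding-box crops), then
#' reassembles a disjoint mask: nucleus pixels always belong to their own
#' cell; other contested pixels go to the cell with the nearest nucleus
#' centroid (ties: lower label); finally each cell keeps only the component
#' containing its nucleus.
#'
#' @param raw_mask Integer label mask from [merge_patch_predictions()].
#' @param nuclei_mask Integer nuclei label mask (labels match).
#' @return Integer label mask satisfying: every label is one 4-connected
#'   component containing its whole nucleus; labels are pairwise disjoint.
#' @export
refine_mask <- function(raw_mask, nuclei_mask) {
  H <- nrow(raw_mask); W <- ncol(raw_mask)
  ids <- sort(unique(nuclei_mask[nuclei_mask > 0]))
  margin <- 12L  # closing can grow a mask by <= 2 dilations of radius 2
  cells <- list()
  centroids <- matrix(NA_real_, length(ids), 2)
  for (k in seq_along(ids)) {
    id <- ids[k]
    sel <- raw_mask == id | nuclei_mask == id
    idx <- which(sel, arr.ind = TRUE)
    r0 <- max(1, min(idx[, 1]) - margin); r1 <- min(H, max(idx[, 1]) + margin)
    c0 <- max(1, min(idx[, 2]) - margin); c1 <- min(W, max(idx[, 2]) + margin)
    ref <- refine_cell(raw_mask[r0:r1, c0:c1] == id,
                       nuclei_mask[r0:r1, c0:c1] == id)
    cells[[k]] <- list(id = id, r0 = r0, c0 = c0, mask = ref)
    nidx <- which(nuclei_mask == id, arr.ind = TRUE)
    centroids[k, ] <- colMeans(nidx)
  }
  out <- matrix(0L, H, W)
  claimed_by <- matrix(0L, H, W)   # first claimant
  contested <- matrix(FALSE, H, W)
  for (k in seq_along(ids)) {
    cl <- cells[[k]]
    idx <- which(cl$mask, arr.ind = TRUE)
    gi <- idx[, 1] + cl$r0 - 1L
    gj <- idx[, 2] + cl$c0 - 1L
    lin <- gi + (gj - 1L) * H
    contested[lin[claimed_by[lin] != 0L]] <- TRUE
    claimed_by[lin][claimed_by[lin] == 0L] <- k
  }
  out <- matrix(0L, H, W)
  uncontested <- claimed_by != 0L & !contested
  out[uncontested] <- ids[claimed_by[uncontested]]
  if (any(contested)) {
    cidx <- which(contested, arr.ind = TRUE)
    for (r in seq_len(nrow(cidx))) {
      gi <- cidx[r, 1]; gj <- cidx[r, 2]
      claimants <- integer(0)
      for (k in seq_along(ids)) {
        cl <- cells[[k]]
        li <- gi - cl$r0 + 1L; lj <- gj - cl$c0 + 1L
        if (li >= 1 && lj >= 1 && li <= nrow(cl$mask) &&
            lj <= ncol(cl$mask) && cl$mask[li, lj]) {
          claimants <- c(claimants, k)
        }
      }
      d <- (centroids[claimants, 1] - gi)^2 + (centroids[claimants, 2] - gj)^2
      out[gi, gj] <- ids[claimants[order(d, claimants)[1]]]
    }
  }
  # nucleus pixels always belong to their own cell
  nz <- nuclei_mask > 0
  out[nz] <- nuclei_mask[nz]
  # each cell keeps only the component containing its nucleus
  for (k in seq_along(ids)) {
    id <- ids[k]
    sel <- out == id
    if (!any(sel)) next
    idx <- which(sel, arr.ind = TRUE)
    r0 <- max(1, min(idx[, 1]) - 1L); r1 <- min(H, max(idx[, 1]) + 1L)
    c0 <- max(1, min(idx[, 2]) - 1L); c1 <- min(W, max(idx[, 2]) + 1L)
    crop <- out[r0:r1, c0:c1] == id
    comp <- label_components(crop)
    nuc_comp <- unique(comp[nuclei_mask[r0:r1, c0:c1] == id])
    nuc_comp <- nuc_comp[nuc_comp > 0]
    if (length(nuc_comp) == 0) next
    drop <- crop & !(comp %in% nuc_comp[1] & comp > 0)
    dim(drop) <- dim(crop)
    sub <- out[r0:r1, c0:c1]
    sub[drop] <- 0L
    out[r0:r1, c0:c1] <- sub
  }
  out
}

#' Map transcripts to segmented cells
#'
#' Counts each transcript into the cell whose mask covers its pixel,
#' producing the n_cells x n_genes gene-cell matrix and the fraction of
#' transcripts assigned.
#'
#' @param transcripts Transcript data.frame (same pixel scale as the mask).
#' @param mask Integer cell label mask.
#' @param gene_panel Ordered gene panel (columns); default: genes present.
#' @return List with `matrix` (rows = cell ids present in the mask, in label
#'   order), `fraction_assigned`, `n_assigned`, `n_total`.
#' @export
map_transcripts_to_cells <- function(transcripts, mask, gene_panel = NULL) {
  if (is.null(gene_panel)) gene_panel <- sort(unique(transcripts$gene))
  ids <- sort(unique(mask[mask > 0]))
  H <- nrow(mask)
  row <- floor(transcripts$y) + 1
  col <- floor(transcripts$x) + 1
  inb <- row >= 1 & row <= H & col >= 1 & col <= ncol(mask)
  lab <- rep(0L, nrow(transcripts))
  lab[inb] <- mask[cbind(row[inb], col[inb])]
  gm <- matrix(0L, length(ids), length(gene_panel),
               dimnames = list(ids, gene_panel))
  keep <- lab > 0 & transcripts$gene %in% gene_panel
  if (any(keep)) {
    tab <- table(factor(lab[keep], levels = ids),
                 factor(transcripts$gene[keep], levels = gene_panel))
    gm[] <- as.integer(tab)
  }
  n_total <- nrow(transcripts)
  n_assigned <- sum(lab > 0)
  list(matrix = gm,
       fraction_assigned = if (n_total > 0) n_assigned / n_total else 0,
       n_assigned = n_assigned, n_total = n_total)
}
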