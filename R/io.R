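# Reading/writing the standard SST artifacts and building the expression map.
#
# Coordinate convention: 0-based continuous transcript positions in pixel
# units; pixel (i, j) = (row, col) = (y, x); a position (x, y) is binned to
# row floor(y), col floor(x) (half-open pixel intervals). Internally R
# matrices are 1-based, so stored row = floor(y) + 1.

#' Read / write a transcript table
#'
#' CSV with columns `x`, `y`, `gene` and optional `qv` (phred-scaled quality).
#'
#' @param path File path.
#' @return A data.frame with columns `x`, `y`, `gene` (character) and `qv`
#'   (numeric, `NA` when absent).
#' @export
read_transcripts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("x", "y", "gene")
  if (!all(req %in% names(df))) {
    stop("transcript table must have columns x, y, gene; got: ",
         paste(names(df), collapse = ", "))
  }
  if (!"qv" %in% names(df)) df$qv <- NA_real_
  df$gene <- as.character(df$gene)
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)))
  df[, c("x", "y", "gene", "qv")]
}

#' @rdname read_transcripts
#' @param transcripts Transcript data.frame.
#' @export
write_transcripts <- function(transcripts, path) {
  utils::write.csv(transcripts[, c("x", "y", "gene", "qv")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quality and control-probe filtering of detected transcripts
#'
#' Removes records whose phred-scaled quality `qv` is strictly below
#' `min_qv` (records lacking a quality value are kept), and records whose
#' gene name contains any of the `exclude_patterns` substrings (used for
#' negative-control probes such as "NegPrb" and "Blank-").
#'
#' @param transcripts Transcript data.frame (`x`, `y`, `gene`, `qv`).
#' @param min_qv Quality threshold; records with `qv < min_qv` are dropped.
#'   Default 20.
#' @param exclude_patterns Character vector of substrings; genes containing
#'   any of them are dropped.
#' @return Filtered data.frame with attribute `gene_panel` (sorted unique
#'   surviving genes). Warns (does not error) if nothing survives.
#' @export
filter_transcripts <- function(transcripts, min_qv = 20,
                               exclude_patterns = c("NegPrb", "Blank-")) {
  keep <- is.na(transcripts$qv) | transcripts$qv >= min_qv
  for (pat in exclude_patterns) {
    keep <- keep & !grepl(pat, transcripts$gene, fixed = TRUE)
  }
  out <- transcripts[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no transcripts retained after filtering")
  attr(out, "gene_panel") <- sort(unique(out$gene))
  out
}

#' Rasterise transcripts into an expression map
#'
#' Builds the H x W x n_genes count tensor: `counts[i, j, g]` is the number
#' of records of gene `g` whose position falls in pixel `(i, j)`. Records of
#' genes not in `gene_panel`, and records outside `[0, W) x [0, H)`, are
#' dropped and their counts recorded in attributes `n_dropped_gene` and
#' `n_dropped_oob`.
#'
#' @param transcripts Transcript data.frame.
#' @param height,width Map dimensions in pixels.
#' @param gene_panel Ordered character vector of genes (channel order).
#' @param pixel_size Microns per pixel (metadata only). Default 1.
#' @return A 3D array with `dimnames` on the gene axis and attributes
#'   `pixel_size`, `n_dropped_gene`, `n_dropped_oob`.
#' @export
build_expression_map <- function(transcripts, height, width, gene_panel,
                                 pixel_size = 1) {
  if (height <= 0 || width <= 0) stop("map dimensions must be positive")
  gene_panel <- as.character(gene_panel)
  g <- match(transcripts$gene, gene_panel)
  n_drop_gene <- sum(is.na(g))
  row <- floor(transcripts$y) + 1
  col <- floor(transcripts$x) + 1
  inb <- row >= 1 & row <= height & col >= 1 & col <= width
  n_drop_oob <- sum(!inb & !is.na(g))
  keep <- inb & !is.na(g)
  counts <- array(0L, dim = c(height, width, length(gene_panel)),
                  dimnames = list(NULL, NULL, gene_panel))
  if (any(keep)) {
    tab <- table(row[keep] + (col[keep] - 1) * height +
                   (g[keep] - 1) * height * width)
    idx <- as.integer(names(tab))
    counts[idx] <- as.integer(tab)
  }
  attr(counts, "pixel_size") <- pixel_size
  attr(counts, "n_dropped_gene") <- n_drop_gene
  attr(counts, "n_dropped_oob") <- n_drop_oob
  counts
}

patch_origins <- function(extent, patch, offset) {
  # 1-based origins of a tiling starting at `offset` (0-based)
  starts <- seq(offset, extent - 1, by = patch)
  starts + 1L
}

#' Partition an expression map into patches on two staggered grids
#'
#' The primary grid tiles the map at stride = `patch` starting at the origin;
#' the shifted grid is offset by `patch/2` in both axes. Edge patches are
#' zero-padded to full size (padding recorded). Patches whose nuclei crop
#' contains no labels are flagged `empty`.
#'
#' @param map Expression map (H x W x G array).
#' @param nuclei Integer nuclei label mask (H x W).
#' @param patch Patch side length; must be <= min(H, W) and even.
#' @param offset_grid `"primary"` or `"shifted"`.
#' @return List of patches; each has `map`, `nuclei`, `origin` (1-based
#'   (row, col) of the patch's top-left pixel in the full image; shifted-grid
#'   origins start at patch/2, so pixels in the first half-patch band are
#'   covered only by the primary grid), `pad` (rows/cols of zero padding at
#'   bottom/right), `empty` (logical), and `centre` (patch centre in image
#'   coordinates).
#' @export
crop_patches <- function(map, nuclei, patch, offset_grid = c("primary", "shifted")) {
  offset_grid <- match.arg(offset_grid)
  H <- dim(map)[1]; W <- dim(map)[2]; G <- dim(map)[3]
  stopifnot(patch <= min(H, W))
  off <- if (offset_grid == "primary") 0L else as.integer(patch / 2)
  oi <- patch_origins(H, patch, off)
  oj <- patch_origins(W, patch, off)
  out <- list()
  for (i0 in oi) for (j0 in oj) {
    ii <- i0:min(i0 + patch - 1, H)
    jj <- j0:min(j0 + patch - 1, W)
    pm <- array(0L, dim = c(patch, patch, G), dimnames = dimnames(map))
    pn <- matrix(0L, patch, patch)
    pm[seq_along(ii), seq_along(jj), ] <- map[ii, jj, , drop = FALSE]
    pn[seq_along(ii), seq_along(jj)] <- nuclei[ii, jj]
    out[[length(out) + 1]] <- list(
      map = pm, nuclei = pn, origin = c(i0, j0),
      pad = c(patch - length(ii), patch - length(jj)),
      empty = !any(pn > 0),
      centre = c(i0 + (patch - 1) / 2, j0 + (patch - 1) / 2),
      grid = offset_grid)
  }
  out
}

#' Read / write integer label masks as 16-bit TIFF
#'
#' @param mask Integer matrix (0 = background); labels must be < 65536.
#' @param path File path.
#' @return `read_label_mask` returns an integer matrix with attribute
#'   `connected` (logical vector per label: is the label one 4-connected
#'   component).
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(max(mask) < 65536)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  labs <- sort(unique(m[m > 0]))
  conn <- vapply(labs, function(l) {
    comp <- label_components(m == l)
    max(comp) == 1L
  }, logical(1))
  names(conn) <- labs
  attr(m, "connected") <- conn
  m
}

#' Read / write a gene-cell matrix
#'
#' Round-trip I/O for the n_cells x n_genes count matrix in either CSV
#' (cells as rows, header = genes, first column = cell id) or MatrixMarket
#' (`.mtx` plus `<stem>.cells.tsv` / `<stem>.genes.tsv` sidecars).
#'
#' @param mat Matrix with rownames = cell ids, colnames = genes.
#' @param path Output path; format chosen by extension (`.csv` or `.mtx`).
#' @return `read_gene_cell_matrix` returns the matrix (dense, integer).
#' @export
write_gene_cell_matrix <- function(mat, path) {
  if (grepl("\\.csv$", path)) {
    cells <- rownames(mat)
    if (is.null(cells)) cells <- as.character(seq_len(nrow(mat)))
    df <- data.frame(cell = cells, as.data.frame(mat), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(as.character(rownames(mat)), paste0(stem, ".cells.tsv"))
    writeLines(as.character(colnames(mat)), paste0(stem, ".genes.tsv"))
  } else {
    stop("unsupported extension (use .csv or .mtx): ", path)
  }
  invisible(path)
}

#' @rdname write_gene_cell_matrix
#' @export
read_gene_cell_matrix <- function(path) {
  if (grepl("\\.csv$", path)) {
    df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                   stringsAsFactors = FALSE),
                   error = function(e) stop("malformed gene-cell CSV at ",
                                            path, ": ", conditionMessage(e)))
    if (ncol(df) < 1 || names(df)[1] != "cell") {
      stop("malformed gene-cell CSV at ", path,
           ": first column must be 'cell' (line 1)")
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df$cell)
  } else if (grepl("\\.mtx$", path)) {
    stem <- sub("\\.mtx$", "", path)
    m <- as.matrix(Matrix::readMM(path))
    cells <- readLines(paste0(stem, ".cells.tsv"))
    genes <- readLines(paste0(stem, ".genes.tsv"))
    if (length(cells) != nrow(m) || length(genes) != ncol(m)) {
      stop("malformed MTX sidecars at ", stem,
           ": dimension mismatch with matrix")
    }
    dimnames(m) <- list(cells, genes)
  } else {
    stop("unsupported extension (use .csv or .mtx): ", path)
  }
  storage.mode(m) <- "integer"
  m
}
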