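# Reference cell-type expression profiles and positive/negative marker sets.

#' Construct or read a reference profile
#'
#' A reference profile is a nonnegative cell_type x gene mean-expression
#' matrix with an `elongated` logical attribute per type. All-zero rows are
#' rejected.
#'
#' @param mean_expression Numeric matrix, rownames = cell types, colnames =
#'   genes.
#' @param elongated_types Character vector naming the elongated cell types.
#' @return Object of class `sst_profile` (a matrix with attributes).
#' @export
reference_profile <- function(mean_expression, elongated_types = character()) {
  stopifnot(is.matrix(mean_expression), all(mean_expression >= 0),
            !is.null(rownames(mean_expression)),
            !is.null(colnames(mean_expression)))
  zero <- rowSums(mean_expression) == 0
  if (any(zero)) {
    stop("all-zero profile row(s): ",
         paste(rownames(mean_expression)[zero], collapse = ", "))
  }
  unknown <- setdiff(elongated_types, rownames(mean_expression))
  if (length(unknown)) {
    stop("elongated types absent from profile: ",
         paste(unknown, collapse = ", "))
  }
  attr(mean_expression, "elongated") <-
    rownames(mean_expression) %in% elongated_types
  class(mean_expression) <- c("sst_profile", class(mean_expression))
  mean_expression
}

#' @rdname reference_profile
#' @param path CSV path (rows = cell types, columns = genes, first column =
#'   type name).
#' @export
read_reference_profile <- function(path, elongated_types = character()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  reference_profile(m, elongated_types)
}

#' @rdname reference_profile
#' @param profile An `sst_profile`.
#' @export
write_reference_profile <- function(profile, path) {
  df <- data.frame(cell_type = rownames(profile),
                   as.data.frame(unclass(profile)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Is a cell type flagged elongated?
#' @param profile An `sst_profile`.
#' @return Named logical vector over cell types.
#' @export
elongated_flags <- function(profile) {
  stats::setNames(attr(profile, "elongated"), rownames(profile))
}

# per-type differential score: mean log1p expression of the type minus the
# mean log1p expression of all other types
differential_scores <- function(profile) {
  lx <- log1p(unclass(profile))
  n <- nrow(lx)
  if (n == 1) return(lx)
  other_mean <- (matrix(colSums(lx), n, ncol(lx), byrow = TRUE) - lx) / (n - 1)
  lx - other_mean
}

rank_extremes <- function(scores, k) {
  # deterministic: ties at the boundary broken by gene-name order
  ord <- order(-scores, names(scores))
  list(top = names(scores)[ord[seq_len(k)]],
       bottom = names(scores)[rev(ord)[seq_len(k)]])
}

derive_marker_sets <- function(profile, percentile, commonality_threshold,
                               strict_commonality) {
  stopifnot(percentile > 0, percentile < 0.5)
  sc <- differential_scores(profile)
  types <- rownames(profile)
  genes <- colnames(profile)
  k <- ceiling(percentile * length(genes))
  if (k < 1) stop("percentile yields empty marker sets")
  pos <- neg <- stats::setNames(vector("list", length(types)), types)
  for (ty in types) {
    s <- stats::setNames(sc[ty, ], genes)
    ex <- rank_extremes(s, k)
    pos[[ty]] <- ex$top
    neg[[ty]] <- ex$bottom
  }
  # commonality filter on positive candidates (skipped for a single type);
  # "common" requires sharing between at least two types, so the filter stays
  # meaningful for small type panels where the threshold fraction is < 2 types
  if (length(types) > 1) {
    counts <- table(unlist(pos))
    frac <- counts / length(types)
    shared <- counts >= 2
    common <- if (strict_commonality) {
      names(frac)[shared & frac > commonality_threshold]
    } else {
      names(frac)[shared & frac >= commonality_threshold]
    }
    pos <- lapply(pos, setdiff, y = common)
  }
  for (ty in types) {
    if (length(pos[[ty]]) == 0) {
      warning("no positive markers remain for type ", ty,
              " after commonality filtering")
    }
    both <- intersect(pos[[ty]], neg[[ty]])
    if (length(both)) neg[[ty]] <- setdiff(neg[[ty]], both)
  }
  structure(list(positive = pos, negative = neg, percentile = percentile,
                 commonality_threshold = commonality_threshold,
                 strict_commonality = strict_commonality),
            class = "sst_markers")
}

#' Derive training marker sets
#'
#' Per cell type, genes are ranked by a differential score (mean log1p
#' expression of the type minus the mean over the other types); the top
#' `percentile` fraction (count = ceiling(percentile * n_genes)) are positive
#' candidates and the bottom fraction negative markers. Positive candidates
#' shared by at least `commonality_threshold` of the types (inclusive; default
#' one third) are removed from every positive set. With a single cell type the
#' commonality filter is skipped.
#'
#' @param profile An `sst_profile`.
#' @param percentile Fraction in (0, 0.5); default 0.10.
#' @param commonality_threshold Fraction of cell types; default 1/3.
#' @return An `sst_markers` object: lists `positive`, `negative` keyed by
#'   type, plus the parameters used.
#' @export
derive_markers <- function(profile, percentile = 0.10,
                           commonality_threshold = 1 / 3) {
  derive_marker_sets(profile, percentile, commonality_threshold,
                     strict_commonality = FALSE)
}

#' Derive evaluation (purity) marker sets
#'
#' As [derive_markers()] but positive markers common to strictly more than
#' `commonality_threshold` of the types (default 25%) are removed; a marker
#' present in exactly 25% of types is retained. Errors if the differential
#' scores carry no information (identical profiles for all types).
#'
#' @inheritParams derive_markers
#' @export
derive_purity_markers <- function(profile, percentile = 0.10,
                                  commonality_threshold = 0.25) {
  sc <- differential_scores(profile)
  if (nrow(profile) > 1 && all(abs(sc) < 1e-12)) {
    stop("no discriminative markers: identical profiles for all cell types")
  }
  derive_marker_sets(profile, percentile, commonality_threshold,
                     strict_commonality = TRUE)
}

#' Serialise marker sets to JSON
#' @param markers An `sst_markers` object.
#' @param path Output path.
#' @export
write_marker_sets <- function(markers, path) {
  jsonlite::write_json(unclass(markers), path, auto_unbox = TRUE)
  invisible(path)
}

#' Per-cell positive/negative marker maps
#'
#' Binary h x w maps with 1 wherever any transcript of any marker gene of the
#' given polarity is present, masked by the cell's expansion mask, then
#' dilated with a 3 x 3 structuring element (nearby pixels are assumed to
#' belong to the same cell).
#'
#' @param markers An `sst_markers` object.
#' @param cell_type Cell-type name.
#' @param patch_map Expression map patch (h x w x G with gene dimnames).
#' @param expansion Binary expansion mask, same lateral shape.
#' @return List with logical matrices `m_pos` and `m_neg`.
#' @export
marker_maps_for_cell <- function(markers, cell_type, patch_map, expansion) {
  if (!cell_type %in% names(markers$positive)) {
    stop("unknown cell type: ", cell_type)
  }
  stopifnot(all(dim(expansion) == dim(patch_map)[1:2]))
  genes <- dimnames(patch_map)[[3]]
  presence <- function(set) {
    idx <- which(genes %in% set)
    acc <- matrix(0, dim(patch_map)[1], dim(patch_map)[2])
    for (k in idx) acc <- acc + patch_map[, , k]
    acc > 0
  }
  k3 <- matrix(TRUE, 3, 3)
  m_pos <- binary_dilate(presence(markers$positive[[cell_type]]) & (expansion > 0), k3)
  m_neg <- binary_dilate(presence(markers$negative[[cell_type]]) & (expansion > 0), k3)
  list(m_pos = m_pos, m_neg = m_neg)
}
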