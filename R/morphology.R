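# Nucleus typing, eccentricity, and per-cell expansion masks.

#' Per-nucleus expression vectors
#'
#' Sums the expression map over the pixels of each nucleus label.
#'
#' @param map Expression map (H x W x G array with gene dimnames).
#' @param nuclei Integer nuclei label mask, same lateral shape.
#' @return A labels x genes integer matrix (rownames = labels). Attribute
#'   `zero_expression` flags labels with no transcripts (typing falls back
#'   for those).
#' @export
nucleus_expression <- function(map, nuclei) {
  stopifnot(all(dim(nuclei) == dim(map)[1:2]))
  labs <- sort(unique(nuclei[nuclei > 0]))
  G <- dim(map)[3]
  out <- matrix(0L, length(labs), G,
                dimnames = list(labs, dimnames(map)[[3]]))
  f <- factor(nuclei, levels = labs)
  for (g in seq_len(G)) {
    s <- tapply(map[, , g], f, sum)
    s[is.na(s)] <- 0
    out[, g] <- as.integer(s)
  }
  attr(out, "zero_expression") <- rowSums(out) == 0
  out
}

#' Assign cell types by Spearman correlation with reference profiles
#'
#' Each nucleus expression vector is rank-correlated (Spearman, average
#' ranks on ties) against every reference cell-type row; the assigned type is
#' the argmax, with ties broken by cell-type name order. Zero-variance
#' expression vectors get the fallback type `"unknown_round"` (treated as
#' non-elongated downstream).
#'
#' @param expr Per-nucleus expression matrix (labels x genes).
#' @param profile An `sst_profile`; gene panels are intersected.
#' @return data.frame with `cell_id`, `type`, `rho` (the winning correlation),
#'   plus one `rho_<type>` column per reference type.
#' @export
assign_type_spearman <- function(expr, profile) {
  genes <- intersect(colnames(expr), colnames(profile))
  if (length(genes) == 0) stop("no genes shared between expression and profile")
  e <- expr[, genes, drop = FALSE]
  p <- unclass(profile)[, genes, drop = FALSE]
  types <- rownames(profile)
  rho <- matrix(NA_real_, nrow(e), length(types),
                dimnames = list(rownames(e), types))
  for (i in seq_len(nrow(e))) {
    v <- e[i, ]
    if (stats::var(v) == 0) next
    for (ty in types) {
      if (stats::var(p[ty, ]) == 0) { rho[i, ty] <- NA_real_; next }
      rho[i, ty] <- stats::cor(v, p[ty, ], method = "spearman")
    }
  }
  assigned <- apply(rho, 1, function(r) {
    if (all(is.na(r))) return("unknown_round")
    best <- types[which(r == max(r, na.rm = TRUE))]
    sort(best)[1]  # deterministic: ties broken by cell-type name order
  })
  best_rho <- vapply(seq_len(nrow(rho)), function(i) {
    r <- rho[i, ]
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(cell_id = rownames(expr), type = assigned, rho = best_rho,
                    stringsAsFactors = FALSE)
  colnames(rho) <- paste0("rho_", types)
  cbind(out, as.data.frame(rho))
}

#' Eccentricity of a nucleus mask
#'
#' Fits an ellipse by the second-order central moments of the pixel
#' coordinates (axes = 4 * sqrt(eigenvalue) convention) and returns
#' ecc = sqrt(1 - b^2 / a^2) where `a >= b` are the major and minor axis
#' lengths, together with the major-axis orientation.
#'
#' @param mask Logical (or 0/1) nucleus mask.
#' @return List with `ecc`, `orientation` (radians, angle of the major axis
#'   from the horizontal, in (-pi/2, pi/2]), `a`, `b`, `centroid` (row, col).
#'   A single-pixel mask returns ecc = 0, orientation 0.
#' @export
nucleus_eccentricity <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty nucleus mask")
  centroid <- colMeans(idx)
  if (nrow(idx) == 1) {
    return(list(ecc = 0, orientation = 0, a = 1, b = 1, centroid = centroid))
  }
  cc <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)  # population covariance
  eg <- eigen(cc, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  a <- 4 * sqrt(lam[1])
  b <- 4 * sqrt(lam[2])
  if (a <= 0) return(list(ecc = 0, orientation = 0, a = 1, b = 1,
                          centroid = centroid))
  ecc <- sqrt(max(0, 1 - (b / a)^2))
  # leading eigenvector in (row, col) = (y, x); orientation w.r.t. horizontal
  v <- eg$vectors[, 1]
  orientation <- atan2(v[1], v[2])
  if (orientation <= -pi / 2) orientation <- orientation + pi
  if (orientation > pi / 2) orientation <- orientation - pi
  list(ecc = ecc, orientation = orientation, a = a, b = b, centroid = centroid)
}

#' Eccentricity from exact ellipse axes
#'
#' Closed form ecc = sqrt(1 - b^2/a^2) for an ellipse with major axis `a` and
#' minor axis `b`.
#'
#' @param a,b Major and minor axis lengths, `a >= b > 0`.
#' @export
eccentricity_from_axes <- function(a, b) {
  stopifnot(a >= b, b > 0)
  sqrt(1 - (b / a)^2)
}

#' Elliptical expansion-kernel axes from nucleus eccentricity
#'
#' `l_h = alpha * ecc * l_t`; `l_v = l_t - l_h` when that exceeds the minimum
#' vertical length `l_vm`, else `l_vm`. Both are floored at 1 pixel so the
#' rasterised kernel is valid.
#'
#' @param ecc Nucleus eccentricity in `[0, 1]`.
#' @param alpha Scaling factor, default 0.9.
#' @param l_t Total (horizontal + vertical) kernel length in pixels,
#'   default 60.
#' @param l_vm Minimum vertical length in pixels, default 3.
#' @return List with `l_h`, `l_v` (pixels) and `degenerate` (TRUE when the
#'   horizontal length was floored, i.e. the kernel no longer encodes
#'   elongation).
#' @export
elongated_kernel_axes <- function(ecc, alpha = 0.9, l_t = 60, l_vm = 3) {
  stopifnot(ecc >= 0, ecc <= 1)
  l_h <- alpha * ecc * l_t
  degenerate <- l_h < 1
  l_h <- max(1, l_h)  # floor first so l_h + l_v still sums to l_t
  l_v <- if (l_t - l_h > l_vm) l_t - l_h else l_vm
  list(l_h = l_h, l_v = max(1, l_v), degenerate = degenerate)
}

#' Per-cell expansion mask
#'
#' Non-elongated cells: a single dilation of the nucleus mask with a circular
#' structuring element inscribed in a `round_kernel_d` x `round_kernel_d`
#' window. Elongated cells: dilation with an elliptical element whose axes
#' come from [elongated_kernel_axes()] and which is rotated to the nucleus
#' orientation. The result always contains the nucleus.
#'
#' @param nucleus Logical (or 0/1) nucleus mask (full-image or crop).
#' @param elongated Logical; is the cell's type elongated?
#' @param ecc,orientation Nucleus eccentricity and major-axis angle (radians);
#'   required when `elongated`.
#' @param round_kernel_d Diameter of the circular kernel window, default 20.
#' @param alpha,l_t,l_vm Elliptical kernel parameters, see
#'   [elongated_kernel_axes()].
#' @return Logical matrix, same shape as `nucleus`.
#' @export
expansion_mask <- function(nucleus, elongated = FALSE, ecc = 0,
                           orientation = 0, round_kernel_d = 20,
                           alpha = 0.9, l_t = 60, l_vm = 3) {
  nucleus <- nucleus > 0
  if (!any(nucleus)) return(nucleus)
  kern <- if (elongated) {
    ax <- elongated_kernel_axes(ecc, alpha, l_t, l_vm)
    ellipse_kernel(ax$l_h, ax$l_v, orientation)
  } else {
    disc_kernel(round_kernel_d)
  }
  binary_dilate(nucleus, kern) | nucleus
}

#' Summarise all nuclei of a dataset
#'
#' Computes per-nucleus expression, Spearman typing, ellipse fit and the
#' elongated flag (from the profile's elongated types; the fallback type
#' `"unknown_round"` is non-elongated).
#'
#' @param map Expression map.
#' @param nuclei Nuclei label mask.
#' @param profile An `sst_profile`.
#' @return data.frame (one row per nucleus) with typing columns plus `ecc`,
#'   `orientation`, `centroid_row`, `centroid_col`, `elongated`.
#' @export
summarise_nuclei <- function(map, nuclei, profile) {
  expr <- nucleus_expression(map, nuclei)
  typing <- assign_type_spearman(expr, profile)
  flags <- elongated_flags(profile)
  geom <- t(vapply(rownames(expr), function(l) {
    e <- nucleus_eccentricity(nuclei == as.integer(l))
    c(e$ecc, e$orientation, e$centroid[1], e$centroid[2])
  }, numeric(4)))
  typing$ecc <- geom[, 1]
  typing$orientation <- geom[, 2]
  typing$centroid_row <- geom[, 3]
  typing$centroid_col <- geom[, 4]
  typing$elongated <- ifelse(typing$type %in% names(flags)[flags], TRUE, FALSE)
  typing
}
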