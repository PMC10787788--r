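# The six biologically-informed training losses and their gradients with
# respect to the per-cell foreground probabilities q-hat.
#
# Conventions (all maps are h x w matrices, per-cell quantities are lists of
# length M): the cross-entropy losses (nuclei encapsulation, cell calling,
# positive marker) are pixel means averaged over cells, so their magnitude is
# patch-size invariant; the over-segmentation, overlap, and negative-marker
# losses are pixel sums with the explicitly written normalisations (1/M and
# 1/(M*h*w)). Probabilities are clipped to [eps, 1 - eps] before logs.
# The predicted segmentation entering the cross-entropy losses is the soft
# foreground probability (losses must be differentiable).

.loss_eps <- 1e-7

sigmoid <- function(x) 1 / (1 + exp(-x))

clip01 <- function(p, eps = .loss_eps) pmin(pmax(p, eps), 1 - eps)

as_cell_list <- function(x) if (is.list(x)) x else list(x)

bce_red <- function(target, p, reduction) {
  p <- clip01(p)
  s <- sum(-target * log(p) - (1 - target) * log(1 - p))
  if (reduction == "mean") s / length(p) else s
}

bce_red_grad <- function(target, p, reduction) {
  pc <- clip01(p)
  g <- -target / pc + (1 - target) / (1 - pc)
  if (reduction == "mean") g <- g / length(p)
  g * (p > .loss_eps & p < 1 - .loss_eps)  # clipped pixels have no gradient
}

#' Nuclei encapsulation loss
#'
#' Binary cross-entropy between each cell's nucleus mask and its predicted
#' foreground probability, averaged over the cells of the patch. With
#' `reduction = "mean"` (default) the cross-entropy is a per-pixel mean, so
#' the value is patch-size invariant; `"sum"` gives the raw pixel sum, the
#' scale on which the size-controlling losses of the training objective
#' operate (see the package vignette on loss scales).
#'
#' @param x_nuc Per-cell binary nucleus masks (list of h x w matrices, or a
#'   single matrix).
#' @param y_hat Per-cell foreground probabilities (same structure).
#' @param reduction `"mean"` or `"sum"` over pixels.
#' @return Scalar loss.
#' @export
loss_nuclei_encapsulation <- function(x_nuc, y_hat, reduction = "mean") {
  x_nuc <- as_cell_list(x_nuc); y_hat <- as_cell_list(y_hat)
  mean(mapply(function(t, p) bce_red(t * 1, p, reduction), x_nuc, y_hat))
}

#' @rdname loss_nuclei_encapsulation
#' @return `loss_nuclei_encapsulation_grad`: list of dL/dq-hat matrices.
#' @export
loss_nuclei_encapsulation_grad <- function(x_nuc, y_hat, reduction = "mean") {
  x_nuc <- as_cell_list(x_nuc); y_hat <- as_cell_list(y_hat)
  M <- length(y_hat)
  mapply(function(t, p) bce_red_grad(t * 1, p, reduction) / M, x_nuc, y_hat,
         SIMPLIFY = FALSE)
}

#' Cell-calling loss
#'
#' Binary cross-entropy between each cell's expansion mask and its predicted
#' foreground, averaged over the M cells of the patch. Encourages
#' transcripts near the nucleus (within the cell-type-shaped expansion) to be
#' assigned to the cell.
#'
#' @param e_c Per-cell binary expansion masks.
#' @param y_hat Per-cell foreground probabilities.
#' @inheritParams loss_nuclei_encapsulation
#' @export
loss_cell_calling <- function(e_c, y_hat, reduction = "mean") {
  loss_nuclei_encapsulation(e_c, y_hat, reduction)
}

#' @rdname loss_cell_calling
#' @export
loss_cell_calling_grad <- function(e_c, y_hat, reduction = "mean") {
  loss_nuclei_encapsulation_grad(e_c, y_hat, reduction)
}

#' Over-segmentation loss
#'
#' Penalises cytoplasmic prediction mass exceeding nuclear prediction mass:
#' p_nuc = sum sigmoid(q * x_nuc - 0.5), p_cyto = sum sigmoid(q * (1 - x_nuc)
#' - 0.5); the loss is mean(p_cyto - p_nuc) over cells when the total excess
#' is positive, else 0 (hinge applied to the total).
#'
#' @param q_hat Per-cell foreground probabilities.
#' @param x_nuc Per-cell binary nucleus masks.
#' @export
loss_oversegmentation <- function(q_hat, x_nuc) {
  q_hat <- as_cell_list(q_hat); x_nuc <- as_cell_list(x_nuc)
  diffs <- mapply(function(q, x) {
    sum(sigmoid(q * (1 - x) - 0.5)) - sum(sigmoid(q * x - 0.5))
  }, q_hat, x_nuc)
  if (sum(diffs) > 0) mean(diffs) else 0
}

#' @rdname loss_oversegmentation
#' @export
loss_oversegmentation_grad <- function(q_hat, x_nuc) {
  q_hat <- as_cell_list(q_hat); x_nuc <- as_cell_list(x_nuc)
  M <- length(q_hat)
  diffs <- mapply(function(q, x) {
    sum(sigmoid(q * (1 - x) - 0.5)) - sum(sigmoid(q * x - 0.5))
  }, q_hat, x_nuc)
  active <- sum(diffs) > 0
  mapply(function(q, x) {
    if (!active) return(matrix(0, nrow(q), ncol(q)))
    s_c <- sigmoid(q * (1 - x) - 0.5)
    s_n <- sigmoid(q * x - 0.5)
    (s_c * (1 - s_c) * (1 - x) - s_n * (1 - s_n) * x) / M
  }, q_hat, x_nuc, SIMPLIFY = FALSE)
}

#' Overlap loss
#'
#' Penalises multiple cells predicting the same non-nuclear pixel:
#' s_ov = -(1 - x_nuc) + sum_c sigmoid(q_c * (1 - x_nuc) - 0.5) per pixel,
#' where x_nuc is the union of all nuclei in the patch; the loss is
#' sum(s_ov) / (M h w) when the total is positive, else 0.
#'
#' @param q_hat Per-cell foreground probabilities.
#' @param x_nuc_union Binary union of all nuclei in the patch (h x w).
#' @export
loss_overlap <- function(q_hat, x_nuc_union) {
  q_hat <- as_cell_list(q_hat)
  M <- length(q_hat)
  h <- nrow(x_nuc_union); w <- ncol(x_nuc_union)
  nn <- 1 - (x_nuc_union > 0)
  s <- -nn
  for (q in q_hat) s <- s + sigmoid(q * nn - 0.5)
  tot <- sum(s)
  if (tot > 0) tot / (M * h * w) else 0
}

#' @rdname loss_overlap
#' @export
loss_overlap_grad <- function(q_hat, x_nuc_union) {
  q_hat <- as_cell_list(q_hat)
  M <- length(q_hat)
  h <- nrow(x_nuc_union); w <- ncol(x_nuc_union)
  nn <- 1 - (x_nuc_union > 0)
  s <- -nn
  for (q in q_hat) s <- s + sigmoid(q * nn - 0.5)
  active <- sum(s) > 0
  lapply(q_hat, function(q) {
    if (!active) return(matrix(0, h, w))
    sg <- sigmoid(q * nn - 0.5)
    sg * (1 - sg) * nn / (M * h * w)
  })
}

#' Positive marker loss
#'
#' Binary cross-entropy between each cell's dilated positive-marker map and
#' its predicted foreground, averaged over cells.
#'
#' @param m_pos Per-cell binary positive-marker maps.
#' @param y_hat Per-cell foreground probabilities.
#' @inheritParams loss_nuclei_encapsulation
#' @export
loss_pos_marker <- function(m_pos, y_hat, reduction = "mean") {
  loss_nuclei_encapsulation(m_pos, y_hat, reduction)
}

#' @rdname loss_pos_marker
#' @export
loss_pos_marker_grad <- function(m_pos, y_hat, reduction = "mean") {
  loss_nuclei_encapsulation_grad(m_pos, y_hat, reduction)
}

#' Negative marker loss
#'
#' Per cell, sum over pixels of sigmoid(q * m_neg - 0.5), averaged over cells.
#' Non-marker pixels contribute a constant sigmoid(-0.5) floor with zero
#' gradient (kept verbatim; the floor is an offset, not a training signal).
#'
#' @param m_neg Per-cell binary negative-marker maps.
#' @param q_hat Per-cell foreground probabilities.
#' @export
loss_neg_marker <- function(m_neg, q_hat) {
  m_neg <- as_cell_list(m_neg); q_hat <- as_cell_list(q_hat)
  mean(mapply(function(m, q) sum(sigmoid(q * (m * 1) - 0.5)), m_neg, q_hat))
}

#' @rdname loss_neg_marker
#' @export
loss_neg_marker_grad <- function(m_neg, q_hat) {
  m_neg <- as_cell_list(m_neg); q_hat <- as_cell_list(q_hat)
  M <- length(q_hat)
  mapply(function(m, q) {
    sg <- sigmoid(q * (m * 1) - 0.5)
    sg * (1 - sg) * (m * 1) / M
  }, m_neg, q_hat, SIMPLIFY = FALSE)
}

#' Loss weights
#'
#' @param ne,cc,os,ov,pos,neg Nonnegative scalars; all default to 1.
#' @return Named numeric vector of class `sst_loss_weights`.
#' @export
loss_weights <- function(ne = 1, cc = 1, os = 1, ov = 1, pos = 1, neg = 1) {
  w <- c(ne = ne, cc = cc, os = os, ov = ov, pos = pos, neg = neg)
  stopifnot(all(w >= 0))
  structure(w, class = "sst_loss_weights")
}

#' Weighted total loss
#'
#' @param parts Named numeric vector/list with elements `ne`, `cc`, `os`,
#'   `ov`, `pos`, `neg`.
#' @param weights A [loss_weights()] vector.
#' @return Scalar weighted sum. Errors naming the offending component if any
#'   part is non-finite.
#' @export
total_loss <- function(parts, weights = loss_weights()) {
  parts <- unlist(parts)[names(weights)]
  bad <- !is.finite(parts)
  if (any(bad)) {
    stop("non-finite loss component(s): ",
         paste(names(weights)[bad], collapse = ", "))
  }
  sum(unclass(weights) * parts)
}

#' All loss components for one patch
#'
#' Convenience wrapper computing the six losses (and optionally their
#' gradients w.r.t. the per-cell foreground probabilities) from precomputed
#' per-cell targets.
#'
#' @param q_hat Per-cell foreground probabilities (list).
#' @param targets List with `x_nuc` (per-cell list), `e_c`, `m_pos`, `m_neg`
#'   (per-cell lists) and `nuc_union` (matrix).
#' @param weights A [loss_weights()].
#' @param gradients Also return the weighted total gradient per cell.
#' @param reductions Named character vector giving the pixel reduction of the
#'   three cross-entropy components. The default keeps all three at the
#'   patch-size-invariant per-pixel mean; the trainer uses the size-balance
#'   convention `c(ne = "mean", cc = "sum", pos = "sum")` so that the
#'   cell-growing losses (cell calling, positive marker) act on the same
#'   pixel-sum scale as the size-shrinking over-segmentation loss, with
#'   nuclei encapsulation as a nucleus-anchoring regulariser.
#' @return List with `parts` (named vector), `total`, and optionally `grad`
#'   (per-cell list of dTotal/dq-hat).
#' @export
patch_losses <- function(q_hat, targets, weights = loss_weights(),
                         gradients = FALSE,
                         reductions = c(ne = "mean", cc = "mean",
                                        pos = "mean")) {
  parts <- c(ne = loss_nuclei_encapsulation(targets$x_nuc, q_hat,
                                            reductions[["ne"]]),
             cc = loss_cell_calling(targets$e_c, q_hat, reductions[["cc"]]),
             os = loss_oversegmentation(q_hat, targets$x_nuc),
             ov = loss_overlap(q_hat, targets$nuc_union),
             pos = loss_pos_marker(targets$m_pos, q_hat, reductions[["pos"]]),
             neg = loss_neg_marker(targets$m_neg, q_hat))
  out <- list(parts = parts, total = total_loss(parts, weights))
  if (gradients) {
    g_ne <- loss_nuclei_encapsulation_grad(targets$x_nuc, q_hat,
                                           reductions[["ne"]])
    g_cc <- loss_cell_calling_grad(targets$e_c, q_hat, reductions[["cc"]])
    g_os <- loss_oversegmentation_grad(q_hat, targets$x_nuc)
    g_ov <- loss_overlap_grad(q_hat, targets$nuc_union)
    g_pos <- loss_pos_marker_grad(targets$m_pos, q_hat, reductions[["pos"]])
    g_neg <- loss_neg_marker_grad(targets$m_neg, q_hat)
    w <- unclass(weights)
    out$grad <- lapply(seq_along(q_hat), function(m) {
      w["ne"] * g_ne[[m]] + w["cc"] * g_cc[[m]] + w["os"] * g_os[[m]] +
        w["ov"] * g_ov[[m]] + w["pos"] * g_pos[[m]] + w["neg"] * g_neg[[m]]
    })
  }
  out
}
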