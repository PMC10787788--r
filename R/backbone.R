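# Reference segmentation backbone: a small 3-level encoder-decoder with skip
# connections, written directly in R (im2col convolutions on BLAS matmuls,
# hand-derived backward passes). The backbone is pluggable via a registry;
# the contract is: input = the shared expression patch concatenated
# channel-wise with one cell's binary nucleus mask, output = 2 logit channels
# (background, foreground) at input resolution.

relu <- function(x) pmax(x, 0)

# ---- conv primitives ------------------------------------------------------

im2col3 <- function(x) {
  # x: h x w x C -> (h*w) x (9*C), 3x3 neighbourhood with zero padding
  h <- dim(x)[1]; w <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(h + 2, w + 2, C))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  col <- matrix(0, h * w, 9 * C)
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    col[, ((k - 1) * C + 1):(k * C)] <-
      matrix(xp[di + (1:h), dj + (1:w), ], h * w, C)
  }
  col
}

col2im3 <- function(dcol, h, w, C) {
  dxp <- array(0, c(h + 2, w + 2, C))
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    dxp[di + (1:h), dj + (1:w), ] <- dxp[di + (1:h), dj + (1:w), ] +
      array(dcol[, ((k - 1) * C + 1):(k * C)], c(h, w, C))
  }
  dxp[2:(h + 1), 2:(w + 1), , drop = FALSE]
}

conv3_fwd <- function(x, W, b) {
  h <- dim(x)[1]; w <- dim(x)[2]
  col <- im2col3(x)
  y <- sweep(col %*% W, 2, b, `+`)
  list(y = array(y, c(h, w, length(b))), col = col)
}

conv3_bwd <- function(dy, col, W, h, w, Cin) {
  dym <- matrix(dy, h * w, dim(W)[2])
  list(dW = crossprod(col, dym), db = colSums(dym),
       dx = col2im3(dym %*% t(W), h, w, Cin))
}

conv1_fwd <- function(x, W, b) {
  h <- dim(x)[1]; w <- dim(x)[2]; C <- dim(x)[3]
  xm <- matrix(x, h * w, C)
  y <- sweep(xm %*% W, 2, b, `+`)
  list(y = array(y, c(h, w, length(b))), xm = xm)
}

conv1_bwd <- function(dy, xm, W, h, w) {
  dym <- matrix(dy, h * w, dim(W)[2])
  list(dW = crossprod(xm, dym), db = colSums(dym),
       dx = array(dym %*% t(W), c(h, w, dim(W)[1])))
}

pool2_fwd <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  (x[seq(1, h, 2), seq(1, w, 2), , drop = FALSE] +
     x[seq(2, h, 2), seq(1, w, 2), , drop = FALSE] +
     x[seq(1, h, 2), seq(2, w, 2), , drop = FALSE] +
     x[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]) / 4
}

pool2_bwd <- function(dy) {
  h <- dim(dy)[1] * 2L; w <- dim(dy)[2] * 2L
  dx <- array(0, c(h, w, dim(dy)[3]))
  g <- dy / 4
  dx[seq(1, h, 2), seq(1, w, 2), ] <- g
  dx[seq(2, h, 2), seq(1, w, 2), ] <- g
  dx[seq(1, h, 2), seq(2, w, 2), ] <- g
  dx[seq(2, h, 2), seq(2, w, 2), ] <- g
  dx
}

up2_fwd <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  x[rep(seq_len(h), each = 2), rep(seq_len(w), each = 2), , drop = FALSE]
}

up2_bwd <- function(dy) {
  h <- dim(dy)[1]; w <- dim(dy)[2]
  dy[seq(1, h, 2), seq(1, w, 2), , drop = FALSE] +
    dy[seq(2, h, 2), seq(1, w, 2), , drop = FALSE] +
    dy[seq(1, h, 2), seq(2, w, 2), , drop = FALSE] +
    dy[seq(2, h, 2), seq(2, w, 2), , drop = FALSE]
}

# ---- reference backbone ---------------------------------------------------

he_mat <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
         fan_in, fan_out)
}

ref_unet_init <- function(n_in, channels = 16) {
  C <- channels
  list(w0 = he_mat(n_in, C), b0 = numeric(C),
       we1 = he_mat(9 * C, C), be1 = numeric(C),
       we2 = he_mat(9 * C, C), be2 = numeric(C),
       we3 = he_mat(9 * C, C), be3 = numeric(C),
       wd2 = he_mat(9 * 2 * C, C), bd2 = numeric(C),
       wd1 = he_mat(9 * 2 * C, C), bd1 = numeric(C),
       wo = he_mat(C, 2), bo = numeric(2))
}

ref_unet_forward <- function(params, x) {
  p <- params
  h <- dim(x)[1]; w <- dim(x)[2]
  c0 <- conv1_fwd(x, p$w0, p$b0);  a0 <- relu(c0$y)
  c1 <- conv3_fwd(a0, p$we1, p$be1); a1 <- relu(c1$y)
  p1 <- pool2_fwd(a1)
  c2 <- conv3_fwd(p1, p$we2, p$be2); a2 <- relu(c2$y)
  p2 <- pool2_fwd(a2)
  c3 <- conv3_fwd(p2, p$we3, p$be3); a3 <- relu(c3$y)
  u2 <- up2_fwd(a3)
  k2 <- array(c(u2, a2), c(dim(u2)[1], dim(u2)[2], 2 * dim(u2)[3]))
  c4 <- conv3_fwd(k2, p$wd2, p$bd2); d2 <- relu(c4$y)
  u1 <- up2_fwd(d2)
  k1 <- array(c(u1, a1), c(h, w, 2 * dim(u1)[3]))
  c5 <- conv3_fwd(k1, p$wd1, p$bd1); d1 <- relu(c5$y)
  c6 <- conv1_fwd(d1, p$wo, p$bo)
  list(logits = c6$y,
       cache = list(x = x, c0 = c0, a0 = a0, c1 = c1, a1 = a1, c2 = c2,
                    a2 = a2, c3 = c3, a3 = a3, c4 = c4, d2 = d2, c5 = c5,
                    d1 = d1, c6 = c6, h = h, w = w))
}

ref_unet_backward <- function(params, cache, dlogits) {
  p <- params; cc <- cache
  h <- cc$h; w <- cc$w
  C <- length(p$b0)
  g <- list()
  b6 <- conv1_bwd(dlogits, cc$c6$xm, p$wo, h, w)
  g$wo <- b6$dW; g$bo <- b6$db
  dd1 <- b6$dx * (cc$c5$y > 0)
  b5 <- conv3_bwd(dd1, cc$c5$col, p$wd1, h, w, 2 * C)
  g$wd1 <- b5$dW; g$bd1 <- b5$db
  du1 <- b5$dx[, , 1:C, drop = FALSE]
  da1_skip <- b5$dx[, , (C + 1):(2 * C), drop = FALSE]
  dd2 <- up2_bwd(du1) * (cc$c4$y > 0)
  b4 <- conv3_bwd(dd2, cc$c4$col, p$wd2, h / 2, w / 2, 2 * C)
  g$wd2 <- b4$dW; g$bd2 <- b4$db
  du2 <- b4$dx[, , 1:C, drop = FALSE]
  da2_skip <- b4$dx[, , (C + 1):(2 * C), drop = FALSE]
  da3 <- up2_bwd(du2) * (cc$c3$y > 0)
  b3 <- conv3_bwd(da3, cc$c3$col, p$we3, h / 4, w / 4, C)
  g$we3 <- b3$dW; g$be3 <- b3$db
  da2 <- (pool2_bwd(b3$dx) + da2_skip) * (cc$c2$y > 0)
  b2 <- conv3_bwd(da2, cc$c2$col, p$we2, h / 2, w / 2, C)
  g$we2 <- b2$dW; g$be2 <- b2$db
  da1 <- (pool2_bwd(b2$dx) + da1_skip) * (cc$c1$y > 0)
  b1 <- conv3_bwd(da1, cc$c1$col, p$we1, h, w, C)
  g$we1 <- b1$dW; g$be1 <- b1$db
  da0 <- b1$dx * (cc$c0$y > 0)
  b0 <- conv1_bwd(da0, cc$c0$xm, p$w0, h, w)
  g$w0 <- b0$dW; g$b0 <- b0$db
  g
}

.backbone_registry <- new.env(parent = emptyenv())

#' Register / fetch a segmentation backbone
#'
#' A backbone is a list of three functions: `init(n_in, ...)` returning a
#' named list of weight arrays, `forward(params, x)` returning
#' `list(logits, cache)` with `logits` an h x w x 2 array, and
#' `backward(params, cache, dlogits)` returning gradients with the shapes of
#' the weights.
#'
#' @param name Backbone name.
#' @param backbone List with `init`, `forward`, `backward`.
#' @export
register_backbone <- function(name, backbone) {
  stopifnot(all(c("init", "forward", "backward") %in% names(backbone)))
  assign(name, backbone, envir = .backbone_registry)
  invisible(name)
}

#' @rdname register_backbone
#' @export
get_backbone <- function(name = "ref_unet") {
  if (!exists(name, envir = .backbone_registry)) {
    stop("unknown backbone: ", name)
  }
  get(name, envir = .backbone_registry)
}

register_backbone("ref_unet", list(init = ref_unet_init,
                                   forward = ref_unet_forward,
                                   backward = ref_unet_backward))

# ---- per-cell prediction contract -----------------------------------------

#' Per-cell forward pass over a patch
#'
#' Each cell of the patch is run through the backbone with input = the shared
#' expression patch plus that cell's binary nucleus mask as an extra channel
#' (cells occupy the batch dimension; the nucleus channel is the per-cell
#' conditioning signal). Softmax over the 2 output channels yields
#' foreground/background probabilities per cell.
#'
#' @param batch List with `expression` (h x w x G array), `nuclei` (integer
#'   label matrix) and `cell_ids` (labels to predict; defaults to the labels
#'   present).
#' @param params Backbone weights (from the backbone's `init`).
#' @param backbone Backbone name in the registry.
#' @param keep_cache Keep per-cell forward caches (needed for training).
#' @return List of class `sst_probs`: `foreground` h x w x M array, `cell_ids`,
#'   and (optionally) `caches` and `logits`.
#' @export
forward_patch <- function(batch, params, backbone = "ref_unet",
                          keep_cache = FALSE) {
  bk <- get_backbone(backbone)
  ids <- batch$cell_ids
  if (is.null(ids)) ids <- sort(unique(batch$nuclei[batch$nuclei > 0]))
  stopifnot(length(ids) >= 1)
  h <- dim(batch$expression)[1]; w <- dim(batch$expression)[2]
  G <- dim(batch$expression)[3]
  fg <- array(NA_real_, c(h, w, length(ids)))
  caches <- if (keep_cache) vector("list", length(ids)) else NULL
  logits <- if (keep_cache) vector("list", length(ids)) else NULL
  for (m in seq_along(ids)) {
    x <- array(0, c(h, w, G + 1))
    x[, , seq_len(G)] <- batch$expression
    x[, , G + 1] <- as.numeric(batch$nuclei == ids[m])
    out <- bk$forward(params, x)
    if (!is.numeric(out$logits) || length(dim(out$logits)) != 3 ||
        !all(dim(out$logits) == c(h, w, 2))) {
      stop("backbone contract violation: logits must be h x w x 2")
    }
    # softmax over 2 channels: fg = sigmoid(z_fg - z_bg)
    fg[, , m] <- 1 / (1 + exp(out$logits[, , 1] - out$logits[, , 2]))
    if (keep_cache) { caches[[m]] <- out$cache; logits[[m]] <- out$logits }
  }
  structure(list(foreground = fg, cell_ids = ids, caches = caches,
                 logits = logits), class = "sst_probs")
}

#' Assemble instance probabilities into a patch label map
#'
#' Per pixel, the mean background probability over cells competes with each
#' cell's foreground probability; the argmax decides the label (0 for
#' background). Ties are broken in favour of background, then the lowest cell
#' id.
#'
#' @param probs An `sst_probs` (or any list with `foreground` h x w x M and
#'   `cell_ids`).
#' @return Integer label matrix.
#' @export
assemble_segmentation <- function(probs) {
  fg <- probs$foreground
  ids <- probs$cell_ids
  h <- dim(fg)[1]; w <- dim(fg)[2]; M <- dim(fg)[3]
  bg_mean <- apply(1 - fg, c(1, 2), mean)
  lab <- matrix(0L, h, w)
  best <- bg_mean
  for (m in seq_len(M)) {           # strict > : ties stay with background /
    better <- fg[, , m] > best      # the earlier (lower) cell id
    lab[better] <- as.integer(ids[m])
    best[better] <- fg[, , m][better]
  }
  lab
}
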