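# Low-level binary morphology on plain logical matrices.
#
# Kernels may be even-sized (the 20x20 circular expansion kernel, elliptical
# l_h x l_v kernels), so the anchor is taken at the window centre
# ((nrow+1)/2, (ncol+1)/2), which for even sizes falls between pixels; offsets
# are computed relative to that centre and rounded symmetrically so the
# structuring element is centred as well as the grid allows.

#' Disc-shaped structuring element
#'
#' Binary disc inscribed in a `d` x `d` window: a pixel belongs to the element
#' if its centre lies within distance `d/2` of the window centre.
#'
#' @param d Window side length (kernel diameter) in pixels.
#' @return A `d` x `d` logical matrix.
#' @export
disc_kernel <- function(d) {
  stopifnot(d >= 1)
  ctr <- (d + 1) / 2
  i <- matrix(seq_len(d), d, d)
  j <- t(i)
  (i - ctr)^2 + (j - ctr)^2 <= (d / 2)^2
}

#' Rotated elliptical structuring element
#'
#' Binary ellipse with full horizontal length `lh` and vertical length `lv`,
#' rotated by `theta` radians (counter-clockwise, major axis at angle `theta`
#' from the horizontal), rasterised as the pixels whose centres fall inside
#' the rotated ellipse with semi-axes `lh/2`, `lv/2`.
#'
#' @param lh Horizontal (pre-rotation) full axis length, pixels.
#' @param lv Vertical (pre-rotation) full axis length, pixels.
#' @param theta Rotation angle in radians.
#' @return A square logical matrix large enough to contain the ellipse.
#' @export
ellipse_kernel <- function(lh, lv, theta = 0) {
  stopifnot(lh >= 1, lv >= 1)
  d <- ceiling(max(lh, lv)) + 1L
  if (d %% 2 == 0) d <- d + 1L  # odd window so the centre is a pixel
  ctr <- (d + 1) / 2
  i <- matrix(seq_len(d), d, d)  # row = vertical
  j <- t(i)
  # rotate pixel offsets back into the ellipse frame
  dy <- i - ctr
  dx <- j - ctr
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / (lh / 2))^2 + (v / (lv / 2))^2 <= 1
}

kernel_offsets <- function(kern) {
  # anchor at the floor centre so even-sized kernels keep distinct integer
  # offsets (a half-integer centre would alias pairs of offsets on rounding)
  ctr_i <- floor((nrow(kern) + 1) / 2)
  ctr_j <- floor((ncol(kern) + 1) / 2)
  idx <- which(kern, arr.ind = TRUE)
  cbind(idx[, 1] - ctr_i, idx[, 2] - ctr_j)
}

shift_mat <- function(m, di, dj, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_i <- max(1, 1 - di):min(h, h - di)
  src_j <- max(1, 1 - dj):min(w, w - dj)
  if (length(src_i) == 0 || length(src_j) == 0) return(out)
  out[src_i + di, src_j + dj] <- m[src_i, src_j]
  out
}

#' Binary dilation
#'
#' @param mask Logical (or 0/1) matrix.
#' @param kern Logical structuring element.
#' @return Logical matrix of the same shape.
#' @export
binary_dilate <- function(mask, kern) {
  mask <- mask > 0
  offs <- kernel_offsets(kern)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out | shift_mat(mask, offs[k, 1], offs[k, 2])
  }
  out
}

#' Binary erosion
#'
#' @inheritParams binary_dilate
#' @return Logical matrix of the same shape; pixels where every kernel offset
#'   hits the mask (border treated as background).
#' @export
binary_erode <- function(mask, kern) {
  mask <- mask > 0
  offs <- kernel_offsets(kern)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out & shift_mat(mask, -offs[k, 1], -offs[k, 2])
  }
  out
}

# one step of 4- or 8-connected propagation
grow_step <- function(frontier, conn = 4) {
  out <- shift_mat(frontier, 1, 0) | shift_mat(frontier, -1, 0) |
    shift_mat(frontier, 0, 1) | shift_mat(frontier, 0, -1)
  if (conn == 8) {
    out <- out | shift_mat(frontier, 1, 1) | shift_mat(frontier, 1, -1) |
      shift_mat(frontier, -1, 1) | shift_mat(frontier, -1, -1)
  }
  out | frontier
}

flood_from <- function(mask, seeds, conn = 4) {
  reached <- seeds & mask
  repeat {
    nxt <- grow_step(reached, conn) & mask
    if (identical(nxt, reached)) return(reached)
    reached <- nxt
  }
}

#' Label connected components (4-connectivity)
#'
#' @param mask Logical matrix.
#' @return Integer matrix; 0 = background, components numbered in scan order
#'   (column-major, matching R's matrix storage).
#' @export
label_components <- function(mask) {
  mask <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  remaining <- mask
  nxt <- 1L
  while (any(remaining)) {
    seed_idx <- which(remaining)[1]
    seeds <- matrix(FALSE, nrow(mask), ncol(mask))
    seeds[seed_idx] <- TRUE
    comp <- flood_from(remaining, seeds, conn = 4)
    lab[comp] <- nxt
    remaining <- remaining & !comp
    nxt <- nxt + 1L
  }
  lab
}

#' Fill holes of a binary mask
#'
#' Holes are background regions not reachable from the matrix border through
#' background, with 8-connected background propagation (complementing the
#' 4-connected foreground convention).
#'
#' @param mask Logical matrix.
#' @return Logical matrix with interior holes set to TRUE.
#' @export
fill_holes <- function(mask) {
  mask <- mask > 0
  bg <- !mask
  border <- matrix(FALSE, nrow(mask), ncol(mask))
  border[1, ] <- TRUE; border[nrow(mask), ] <- TRUE
  border[, 1] <- TRUE; border[, ncol(mask)] <- TRUE
  outside <- flood_from(bg, border & bg, conn = 8)
  mask | (bg & !outside)
}
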