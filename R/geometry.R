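# Computational geometry for the cell-shape metrics: polygon area/perimeter,
# convex hull, oriented minimum-area bounding box, maximum inscribed circle,
# minimum enclosing circle, moment-based ellipse axes, and mask-to-polygon
# contour tracing (marching squares via contourLines, so discrete discs
# converge to the analytic identities).

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygon_perimeter <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(sqrt((x2 - x)^2 + (y2 - y)^2))
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

# second-order central moments of the polygon interior (normalised by area):
# the covariance matrix of a uniform distribution over the polygon
polygon_covariance <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  sxx <- sum((x^2 + x * x2 + x2^2) * cr) / (12 * a) - cx^2
  syy <- sum((y^2 + y * y2 + y2^2) * cr) / (12 * a) - cy^2
  sxy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / (24 * a) -
    cx * cy
  matrix(c(sxx, sxy, sxy, syy), 2, 2)
}

convex_hull <- function(xy) {
  xy[rev(grDevices::chull(xy[, 1], xy[, 2])), , drop = FALSE]  # ccw order
}

# oriented minimum-area bounding rectangle by rotating calipers over hull
# edges; returns the extents along the minimising edge direction (W) and its
# perpendicular (H)
min_area_bbox <- function(hull) {
  n <- nrow(hull)
  if (n == 1) return(c(W = 0, H = 0))
  if (n == 2) {
    d <- sqrt(sum((hull[2, ] - hull[1, ])^2))
    return(c(W = d, H = 0))
  }
  best <- NULL
  for (e in seq_len(n)) {
    p1 <- hull[e, ]; p2 <- hull[if (e == n) 1 else e + 1, ]
    v <- p2 - p1
    len <- sqrt(sum(v^2))
    if (len == 0) next
    u <- v / len
    perp <- c(-u[2], u[1])
    pu <- hull %*% u
    pv <- hull %*% perp
    w <- max(pu) - min(pu)
    h <- max(pv) - min(pv)
    if (is.null(best) || w * h < best[1] * best[2] - 1e-12) best <- c(w, h)
  }
  c(W = best[1], H = best[2])
}

point_in_polygon <- function(px, py, xy) {
  # ray casting, vectorised over query points
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (y[i] > py) != (y[j] > py)
    xin <- px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]
    inside <- xor(inside, cross & xin)
    j <- i
  }
  inside
}

dist_to_edges <- function(px, py, xy) {
  # min distance from a single point to the polygon boundary
  x1 <- xy[, 1]; y1 <- xy[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx^2 + dy^2
  t <- ifelse(l2 > 0, ((px - x1) * dx + (py - y1) * dy) / l2, 0)
  t <- pmin(pmax(t, 0), 1)
  min(sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2))
}

# maximum inscribed circle radius: coarse interior grid then Nelder-Mead
# refinement of the signed distance to the boundary
max_inscribed_radius <- function(xy, grid_n = 24) {
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  gx <- seq(xr[1], xr[2], length.out = grid_n)
  gy <- seq(yr[1], yr[2], length.out = grid_n)
  gg <- expand.grid(x = gx, y = gy)
  ins <- point_in_polygon(gg$x, gg$y, xy)
  if (!any(ins)) {
    start <- polygon_centroid(xy)
  } else {
    cand <- gg[ins, ]
    d <- vapply(seq_len(nrow(cand)),
                function(i) dist_to_edges(cand$x[i], cand$y[i], xy),
                numeric(1))
    start <- as.numeric(cand[which.max(d), ])
  }
  obj <- function(p) {
    s <- if (point_in_polygon(p[1], p[2], xy)) 1 else -1
    -s * dist_to_edges(p[1], p[2], xy)
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  max(0, -opt$value)
}

circle_from2 <- function(p, q) {
  c((p + q) / 2, sqrt(sum((p - q)^2)) / 2)
}

circle_from3 <- function(p, q, r) {
  ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
}

in_circle <- function(pt, circ, tol = 1e-9) {
  sqrt((pt[1] - circ[1])^2 + (pt[2] - circ[2])^2) <= circ[3] + tol
}

# Welzl-style incremental minimum enclosing circle (iterative form)
min_enclosing_circle <- function(xy) {
  pts <- unique(xy)
  n <- nrow(pts)
  if (n == 1) return(c(pts[1, ], 0))
  # deterministic shuffle: the incremental algorithm is expected O(n) on a
  # random insertion order but cubic on adversarial (e.g. sorted circular)
  # orders; restore the caller's RNG state afterwards
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(1203077L)
  pts <- pts[sample.int(n), , drop = FALSE]
  circ <- circle_from2(pts[1, ], pts[2, ])
  if (n == 2) return(circ)
  for (i in 3:n) {
    if (in_circle(pts[i, ], circ)) next
    circ <- circle_from2(pts[1, ], pts[i, ])
    for (j in 2:(i - 1)) {
      if (in_circle(pts[j, ], circ)) next
      circ <- circle_from2(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1)) {
        if (in_circle(pts[k, ], circ)) next
        c3 <- circle_from3(pts[i, ], pts[j, ], pts[k, ])
        if (!is.null(c3)) circ <- c3
      }
    }
  }
  circ
}

#' Trace the outer contour of a binary mask as a polygon
#'
#' Marching-squares contour at level 0.5 over the pixel-centre grid; the
#' longest closed contour is returned in (x, y) = (col, row) coordinates.
#' Used so that perimeters of rasterised shapes converge to the analytic
#' values as resolution grows.
#'
#' @param mask Logical/0-1 matrix.
#' @return Two-column matrix of vertices.
#' @export
mask_to_polygon <- function(mask) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- (mask > 0) * 1
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = 0.5)
  if (length(cl) == 0) stop("empty mask")
  lens <- vapply(cl, function(c0) length(c0$x), numeric(1))
  c0 <- cl[[which.max(lens)]]
  # contourLines: x follows the row coordinate, y the column; convert to
  # (x, y) = (col - 1, row - 1) image coordinates (undo the padding offset)
  cbind(x = c0$y - 1, y = c0$x - 1)
}
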