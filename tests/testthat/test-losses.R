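# Brute-force per-pixel oracle for every loss, written as plain loops so it
# shares no code with the vectorised implementations.
oracle_losses <- function(inst, reductions = c(ne = "mean", cc = "mean",
                                               pos = "mean")) {
  sig <- function(x) 1 / (1 + exp(-x))
  clip <- function(p) min(max(p, 1e-7), 1 - 1e-7)
  M <- inst$M; h <- inst$h; w <- inst$w
  bce <- function(target, p, red) {
    acc <- 0
    for (i in 1:h) for (j in 1:w) {
      pc <- clip(p[i, j])
      acc <- acc + (-target[i, j] * log(pc) - (1 - target[i, j]) * log(1 - pc))
    }
    if (red == "mean") acc / (h * w) else acc
  }
  ne <- cc <- pos <- neg <- 0
  diffs <- numeric(M)
  for (m in 1:M) {
    ne <- ne + bce(inst$x_nuc[[m]], inst$q[[m]], reductions[["ne"]]) / M
    cc <- cc + bce(inst$e_c[[m]], inst$q[[m]], reductions[["cc"]]) / M
    pos <- pos + bce(inst$m_pos[[m]], inst$q[[m]], reductions[["pos"]]) / M
    pn <- pc2 <- 0
    for (i in 1:h) for (j in 1:w) {
      pn <- pn + sig(inst$q[[m]][i, j] * inst$x_nuc[[m]][i, j] - 0.5)
      pc2 <- pc2 + sig(inst$q[[m]][i, j] * (1 - inst$x_nuc[[m]][i, j]) - 0.5)
      neg <- neg + sig(inst$q[[m]][i, j] * inst$m_neg[[m]][i, j] - 0.5) / M
    }
    diffs[m] <- pc2 - pn
  }
  os <- if (sum(diffs) > 0) mean(diffs) else 0
  s_tot <- 0
  for (i in 1:h) for (j in 1:w) {
    s <- -(1 - inst$nuc_union[i, j])
    for (m in 1:M) {
      s <- s + sig(inst$q[[m]][i, j] * (1 - inst$nuc_union[i, j]) - 0.5)
    }
    s_tot <- s_tot + s
  }
  ov <- if (s_tot > 0) s_tot / (M * h * w) else 0
  c(ne = ne, cc = cc, os = os, ov = ov, pos = pos, neg = neg)
}

test_that("cross-entropy losses vanish on perfect predictions", {
  x <- matrix(c(1, 0, 0, 1), 2, 2)
  eps <- 1e-7
  y <- pmin(pmax(x, eps), 1 - eps)
  expect_lt(loss_nuclei_encapsulation(x, y), 2 * eps * abs(log(eps)))
  expect_lt(loss_cell_calling(x, y), 2 * eps * abs(log(eps)))
  expect_lt(loss_pos_marker(matrix(0, 2, 2), matrix(eps, 2, 2)), 1e-5)
})

test_that("cross-entropy at uniform 0.5 equals ln 2 per pixel", {
  x <- matrix(rbinom(64, 1, 0.3), 8, 8)
  y <- matrix(0.5, 8, 8)
  expect_equal(loss_nuclei_encapsulation(x, y), log(2))
  expect_equal(loss_pos_marker(x, y), log(2))
  # two cells, one perfect and one at 0.5
  eps <- 1e-7
  e <- list(matrix(1, 8, 8), matrix(1, 8, 8))
  yh <- list(matrix(1 - eps, 8, 8), matrix(0.5, 8, 8))
  expect_equal(loss_cell_calling(e, yh), log(2) / 2, tolerance = 1e-5)
})

test_that("inverted predictions give the maximal clipped cross-entropy", {
  x <- matrix(c(1, 0), 1, 2)
  y <- 1 - x
  expect_equal(loss_nuclei_encapsulation(x, y), abs(log(1e-7)),
               tolerance = 1e-6)
})

test_that("over-segmentation hinge is zero when prediction is within nuclei", {
  x <- matrix(0, 8, 8); x[3:4, 3:4] <- 1
  # q = 0 everywhere: terms cancel pixelwise
  expect_equal(loss_oversegmentation(matrix(0, 8, 8), x), 0)
  # prediction confined to the nucleus: sum is negative -> hinged to 0
  expect_equal(loss_oversegmentation(x, x), 0)
})

test_that("over-segmentation matches the printed pixel-sum example", {
  # q = 1 everywhere, 4-pixel nucleus in 8x8, one cell
  x <- matrix(0, 8, 8); x[1:2, 1:2] <- 1
  q <- matrix(1, 8, 8)
  sig <- function(z) 1 / (1 + exp(-z))
  expected <- 56 * (sig(0.5) - sig(-0.5))
  expect_equal(loss_oversegmentation(q, x), expected)
  expect_equal(expected, 13.715, tolerance = 1e-3)
})

test_that("overlap loss follows the printed pixel-sum examples", {
  x <- matrix(0, 8, 8); x[1:2, 1:2] <- 1
  sig <- function(z) 1 / (1 + exp(-z))
  # one cell, q = 0: total negative -> 0
  expect_equal(loss_overlap(matrix(0, 8, 8), x), 0)
  # two cells both predicting all non-nucleus pixels
  q <- matrix(1, 8, 8)
  tot <- 60 * (2 * sig(0.5) - 1) + 4 * (2 * sig(-0.5) - 0)
  expect_equal(loss_overlap(list(q, q), x), tot / (2 * 64))
})

test_that("negative marker loss has the sigmoid(-0.5) floor", {
  sig <- function(z) 1 / (1 + exp(-z))
  q <- matrix(runif(64), 8, 8)
  expect_equal(loss_neg_marker(matrix(0, 8, 8), q), 64 * sig(-0.5))
  m <- matrix(0, 8, 8); m[4, 4] <- 1
  q1 <- matrix(0, 8, 8); q1[4, 4] <- 1
  expect_equal(loss_neg_marker(m, q1), 63 * sig(-0.5) + sig(0.5))
  # q = 0 on the marker pixel: equals the floor
  expect_equal(loss_neg_marker(m, matrix(0, 8, 8)), 64 * sig(-0.5))
})

test_that("total loss is the weighted sum and flags non-finite parts", {
  parts <- c(ne = 1, cc = 2, os = 3, ov = 4, pos = 5, neg = 6)
  expect_equal(total_loss(parts), 21)
  expect_equal(total_loss(parts, loss_weights(0, 0, 0, 0, 0, 0)), 0)
  parts["ov"] <- NaN
  expect_error(total_loss(parts), "ov")
})

test_that("vectorised losses match the brute-force oracle", {
  for (seed in 1:25) {
    inst <- random_loss_instance(seed)
    got <- patch_losses(inst$q, inst)$parts
    want <- oracle_losses(inst)
    expect_equal(got, want, tolerance = 1e-6)
    # and under the trainer's sum-scale convention
    red <- c(ne = "mean", cc = "sum", pos = "sum")
    got2 <- patch_losses(inst$q, inst, reductions = red)$parts
    want2 <- oracle_losses(inst, red)
    expect_equal(got2, want2, tolerance = 1e-6)
  }
})

test_that("all losses are nonnegative on random instances", {
  for (seed in 26:40) {
    inst <- random_loss_instance(seed)
    expect_true(all(patch_losses(inst$q, inst)$parts >= 0))
  }
})

test_that("analytic gradients match finite differences", {
  fd_check <- function(loss_fn, grad_fn, inst, n_probe = 12, h_fd = 1e-6) {
    g <- grad_fn(inst)
    set.seed(99)
    for (k in seq_len(n_probe)) {
      m <- sample(inst$M, 1)
      i <- sample(inst$h, 1); j <- sample(inst$w, 1)
      qp <- inst$q; qp[[m]][i, j] <- qp[[m]][i, j] + h_fd
      qm <- inst$q; qm[[m]][i, j] <- qm[[m]][i, j] - h_fd
      ip <- inst; ip$q <- qp
      im <- inst; im$q <- qm
      fd <- (loss_fn(ip) - loss_fn(im)) / (2 * h_fd)
      expect_equal(g[[m]][i, j], fd, tolerance = 1e-4)
    }
  }
  for (seed in c(3, 17)) {
    inst <- random_loss_instance(seed)
    fd_check(function(x) loss_nuclei_encapsulation(x$x_nuc, x$q),
             function(x) loss_nuclei_encapsulation_grad(x$x_nuc, x$q), inst)
    fd_check(function(x) loss_cell_calling(x$e_c, x$q, "sum"),
             function(x) loss_cell_calling_grad(x$e_c, x$q, "sum"), inst)
    fd_check(function(x) loss_oversegmentation(x$q, x$x_nuc),
             function(x) loss_oversegmentation_grad(x$q, x$x_nuc), inst)
    fd_check(function(x) loss_overlap(x$q, x$nuc_union),
             function(x) loss_overlap_grad(x$q, x$nuc_union), inst)
    fd_check(function(x) loss_pos_marker(x$m_pos, x$q),
             function(x) loss_pos_marker_grad(x$m_pos, x$q), inst)
    fd_check(function(x) loss_neg_marker(x$m_neg, x$q),
             function(x) loss_neg_marker_grad(x$m_neg, x$q), inst)
  }
})
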