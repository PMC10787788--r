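test_that("a nucleus covering the whole map collects all transcripts", {
  sim <- small_sim()
  map <- build_expression_map(sim$transcripts, 128, 128,
                              colnames(sim$profile))
  one <- matrix(1L, 128, 128)
  expr <- nucleus_expression(map, one)
  expect_equal(as.integer(expr[1, ]), as.integer(apply(map, 3, sum)))
})

test_that("nucleus expression matches a per-transcript point-in-mask oracle", {
  sim <- small_sim()
  map <- build_expression_map(sim$transcripts, 128, 128,
                              colnames(sim$profile))
  expr <- nucleus_expression(map, sim$nuclei_mask)
  row <- floor(sim$transcripts$y) + 1
  col <- floor(sim$transcripts$x) + 1
  lab <- sim$nuclei_mask[cbind(row, col)]
  for (id in rownames(expr)) {
    inside <- lab == as.integer(id)
    oracle <- table(factor(sim$transcripts$gene[inside],
                           levels = colnames(sim$profile)))
    expect_equal(as.integer(expr[id, ]), as.integer(oracle))
  }
})

test_that("zero-expression nuclei are flagged for the typing fallback", {
  map <- array(0L, c(10, 10, 2), dimnames = list(NULL, NULL, c("a", "b")))
  nuc <- matrix(0L, 10, 10); nuc[2:3, 2:3] <- 1L
  expr <- nucleus_expression(map, nuc)
  expect_true(attr(expr, "zero_expression")[["1"]])
})

test_that("Spearman typing recovers exact and reversed rank relations", {
  prof <- block_profile()
  expr <- rbind(`1` = unclass(prof)["type2", ],
                `2` = max(prof) + 1 - unclass(prof)["type2", ])
  out <- assign_type_spearman(expr, prof)
  expect_equal(out$type[1], "type2")
  expect_equal(out$rho[1], 1)
  expect_equal(out[2, "rho_type2"], -1)
})

test_that("zero-variance expression falls back to unknown_round", {
  prof <- block_profile()
  expr <- rbind(`1` = rep(3, ncol(prof)))
  colnames(expr) <- colnames(prof)
  out <- assign_type_spearman(expr, prof)
  expect_equal(out$type, "unknown_round")
})

test_that("noise-free synthetic nuclei are typed to their generating type", {
  sim <- simulate_sst(sim_config(image_height = 192, image_width = 192,
                                 n_cells = 25, background_noise_rate = 0,
                                 rng_seed = 21))
  map <- build_expression_map(sim$transcripts, 192, 192,
                              colnames(sim$profile))
  expr <- nucleus_expression(map, sim$nuclei_mask)
  out <- assign_type_spearman(expr, sim$profile)
  truth <- sim$truth$cell_types[out$cell_id]
  expect_gte(mean(out$type == truth), 0.95)
})

test_that("eccentricity of a disc is near zero and of a circle exact at 0", {
  e <- nucleus_eccentricity(disc_mask(12))
  expect_lt(e$ecc, 0.05)
  expect_equal(eccentricity_from_axes(4, 4), 0)
})

test_that("eccentricity follows the ellipse closed form", {
  expect_equal(eccentricity_from_axes(5, 3), 0.8)
  # rasterised ellipse with a/b = 5/3
  i <- matrix(1:121, 121, 121); j <- t(i)
  m <- ((i - 61) / 50)^2 + ((j - 61) / 30)^2 <= 1
  e <- nucleus_eccentricity(m)
  expect_equal(e$ecc, 0.8, tolerance = 0.01)
  expect_equal(abs(e$orientation), pi / 2, tolerance = 0.05)  # major axis vertical
})

test_that("single-pixel masks give zero eccentricity by convention", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  e <- nucleus_eccentricity(m)
  expect_equal(e$ecc, 0)
  expect_equal(e$orientation, 0)
})

test_that("elliptical kernel axes follow the defaults", {
  expect_equal(elongated_kernel_axes(1), list(l_h = 54, l_v = 6,
                                              degenerate = FALSE))
  ax <- elongated_kernel_axes(0.5)
  expect_equal(c(ax$l_h, ax$l_v), c(27, 33))
})

test_that("zero eccentricity floors the horizontal length", {
  ax <- elongated_kernel_axes(0)
  expect_equal(ax$l_h, 1)
  expect_equal(ax$l_v, 59)
  expect_true(ax$degenerate)
})

test_that("horizontal length is strictly monotone in eccentricity", {
  ecc <- seq(0.1, 1, by = 0.05)
  lh <- vapply(ecc, function(e) elongated_kernel_axes(e)$l_h, numeric(1))
  expect_true(all(diff(lh) > 0))
})

test_that("round expansion of a point nucleus is a ~20 px disc", {
  nuc <- matrix(FALSE, 41, 41); nuc[21, 21] <- TRUE
  ex <- expansion_mask(nuc, elongated = FALSE, round_kernel_d = 20)
  expect_true(ex[21, 21])
  area <- sum(ex)
  expect_equal(area, pi * 10^2, tolerance = 0.05)
  # the dilation identity: all mask pixels lie within d/2 (+ rounding) of the
  # point
  idx <- which(ex, arr.ind = TRUE)
  expect_true(all(sqrt((idx[, 1] - 21)^2 + (idx[, 2] - 21)^2) <= 11))
})

test_that("expansion masks contain their nuclei", {
  sim <- small_sim()
  for (id in 1:3) {
    nuc <- sim$nuclei_mask == id
    elong <- sim$truth$cell_types[[as.character(id)]] == "type3"
    e <- nucleus_eccentricity(nuc)
    ex <- expansion_mask(nuc, elongated = elong, ecc = e$ecc,
                         orientation = e$orientation)
    expect_true(all(ex[nuc]))
  }
})

test_that("an elongated expansion aligns with the nucleus orientation", {
  # synthetic nucleus at 45 degrees
  i <- matrix(1:81, 81, 81); j <- t(i)
  th <- pi / 4
  u <- (j - 41) * cos(th) + (i - 41) * sin(th)
  v <- -(j - 41) * sin(th) + (i - 41) * cos(th)
  nuc <- (u / 12)^2 + (v / 5)^2 <= 1
  e <- nucleus_eccentricity(nuc)
  ex <- expansion_mask(nuc, elongated = TRUE, ecc = e$ecc,
                       orientation = e$orientation)
  fitted <- nucleus_eccentricity(ex)
  expect_lt(abs(abs(fitted$orientation) - pi / 4), 10 * pi / 180)
})

test_that("elongated types show higher mask eccentricity than round types", {
  sim <- simulate_sst(sim_config(image_height = 192, image_width = 192,
                                 n_cells = 20, rng_seed = 31))
  types <- sim$truth$cell_types
  ecc <- vapply(names(types), function(id) {
    nucleus_eccentricity(sim$nuclei_mask == as.integer(id))$ecc
  }, numeric(1))
  if (any(types == "type3") && any(types != "type3")) {
    expect_gt(mean(ecc[types == "type3"]), mean(ecc[types != "type3"]))
  }
})

test_that("empty nuclei leave the expansion unchanged", {
  nuc <- matrix(FALSE, 10, 10)
  expect_equal(expansion_mask(nuc), nuc)
})
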