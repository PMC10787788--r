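test_that("density is transcripts per unit area", {
  m <- matrix(100L, 1, 1, dimnames = list("1", "g"))
  mask <- matrix(0L, 10, 10); mask[1:5, 1:10] <- 1L
  b <- baseline_metrics(m, mask)
  expect_equal(b$per_cell$density, 2.0)
  expect_equal(b$per_cell$area_px, 50)
})

test_that("zero-transcript cells have zero density and genes", {
  m <- matrix(0L, 1, 2, dimnames = list("1", c("a", "b")))
  mask <- matrix(1L, 3, 3)
  b <- baseline_metrics(m, mask)
  expect_equal(b$per_cell$density, 0)
  expect_equal(b$per_cell$n_genes, 0)
})

test_that("per-cell transcript counts match the point-in-mask oracle", {
  sim <- small_sim()
  mapped <- map_transcripts_to_cells(sim$transcripts, sim$truth$cell_mask,
                                     colnames(sim$profile))
  b <- baseline_metrics(mapped$matrix, sim$truth$cell_mask,
                        nrow(sim$transcripts))
  lab <- sim$truth$cell_mask[cbind(floor(sim$transcripts$y) + 1,
                                   floor(sim$transcripts$x) + 1)]
  oracle <- table(factor(lab[lab > 0], levels = b$per_cell$cell))
  expect_equal(unname(b$per_cell$n_transcripts), as.integer(oracle))
  expect_equal(b$overall$proportion_assigned,
               sum(lab > 0) / nrow(sim$transcripts))
})

test_that("all ratio metrics equal 1 on an analytic circle", {
  s <- shape_metrics(circle_polygon(r = 10))
  for (mtr in c("circularity", "sphericity", "compactness", "convexity",
                "eccentricity", "solidity")) {
    expect_equal(s[[mtr]], 1, tolerance = 1e-3, label = mtr)
  }
  expect_equal(s[["area"]], pi * 100, tolerance = 1e-2)
})

test_that("elongation is 1 for a square and W/H for a rectangle", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(shape_metrics(sq)[["elongation"]], 1, tolerance = 1e-9)
  rect <- cbind(c(0, 20, 20, 0), c(0, 0, 10, 10))
  e <- shape_metrics(rect)[["elongation"]]
  expect_true(abs(e - 2) < 1e-9 || abs(e - 0.5) < 1e-9)
  expect_equal(shape_metrics(rect)[["solidity"]], 1, tolerance = 1e-9)
})

test_that("a rotated elongated shape keeps oriented-box elongation", {
  # 2:1 rectangle rotated 30 degrees: axis-aligned box would dilute it
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rect <- cbind(c(0, 20, 20, 0), c(0, 0, 10, 10)) %*% t(R)
  e <- shape_metrics(rect)[["elongation"]]
  expect_true(abs(e - 2) < 1e-6 || abs(e - 0.5) < 1e-6)
})

test_that("solidity is 1 for a regular hexagon (exact arithmetic)", {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  hex <- cbind(10 * cos(th), 10 * sin(th))
  expect_equal(shape_metrics(hex)[["solidity"]], 1, tolerance = 1e-12)
})

test_that("rasterised discs converge to the analytic identities", {
  s <- shape_metrics(disc_mask(20))
  expect_equal(s[["eccentricity"]], 1, tolerance = 5e-2)
  expect_equal(s[["circularity"]], 1, tolerance = 5e-2)
})

test_that("shape inequalities hold on random blobs", {
  set.seed(6)
  for (k in 1:5) {
    m <- matrix(FALSE, 40, 40)
    for (b in 1:3) {
      ci <- sample(10:30, 1); cj <- sample(10:30, 1); r <- sample(4:8, 1)
      i <- matrix(1:40, 40, 40); j <- t(i)
      m <- m | ((i - ci)^2 + (j - cj)^2 <= r^2)
    }
    s <- shape_metrics(m)
    expect_lte(s[["solidity"]], 1 + 1e-9)
    expect_lte(s[["convexity"]], 1 + 1e-9)
    expect_lte(s[["compactness"]], s[["circularity"]] + 1e-9)
  }
})

test_that("degenerate shapes give missing metrics", {
  line <- cbind(c(0, 5, 5, 0), c(0, 0, 0, 0))
  s <- shape_metrics(line)
  expect_true(all(is.na(s[-1])))
})

test_that("purity F1 endpoints and arithmetic follow the formula", {
  expect_equal(purity_f1(1, 0), 1)
  expect_equal(purity_f1(0.5, 0.5), 0.5)
  expect_equal(purity_f1(0, 0.3), 0)
  # monotone in positive F1
  f <- purity_f1(seq(0, 1, 0.1), 0.4)
  expect_true(all(diff(f) >= 0))
})

test_that("marker F1 components are exact for cells matching their type", {
  prof <- block_profile(n_types = 2, n_genes = 10, fold = 20)
  mk <- derive_purity_markers(prof)
  genes <- colnames(prof)
  mat <- matrix(0L, 2, 10, dimnames = list(c("1", "2"), genes))
  mat["1", mk$positive[["type1"]]] <- 50L
  mat["1", setdiff(genes, c(mk$positive[["type1"]],
                            mk$negative[["type1"]]))] <- 5L
  mat["2", mk$positive[["type2"]]] <- 50L
  mat["2", setdiff(genes, c(mk$positive[["type2"]],
                            mk$negative[["type2"]]))] <- 5L
  ps <- purity_scores(mat, list(`1` = "type1", `2` = "type2"), mk)
  expect_true(all(ps$per_type$pos_f1 == 1))
  expect_true(all(ps$per_type$neg_f1 == 1))  # zero-count markers bottom decile
  # and the combination follows the published formula verbatim
  expect_equal(ps$per_type$purity_f1, rep(purity_f1(1, 1), 2))
})

test_that("concordance is exact when segmented means equal the reference", {
  genes <- paste0("g", 1:6)
  r1 <- c(5000, 2000, 1500, 800, 500, 200)  # sums to 1e4
  r2 <- rev(r1)
  m <- rbind(A = r1, B = r2)
  colnames(m) <- genes
  prof <- reference_profile(m)
  mat <- rbind(`1` = r1, `2` = r1, `3` = r2, `4` = r2)
  colnames(mat) <- genes
  conc <- concordance_with_reference(mat, list(`1` = "A", `2` = "A",
                                               `3` = "B", `4` = "B"), prof)
  expect_equal(conc$per_type$pearson_r, c(1, 1))
})

test_that("zero-variance references and small types are flagged missing", {
  genes <- paste0("g", 1:4)
  m <- rbind(A = c(3, 3, 3, 3), B = c(1, 2, 3, 4))
  colnames(m) <- genes
  prof <- reference_profile(m)
  mat <- rbind(`1` = 1:4, `2` = 4:1, `3` = c(1, 1, 2, 2))
  colnames(mat) <- genes
  conc <- concordance_with_reference(mat, list(`1` = "A", `2` = "A",
                                               `3` = "B"), prof)
  expect_true(is.na(conc$per_type$pearson_r[1]))  # constant reference
  expect_true(is.na(conc$per_type$pearson_r[2]))  # < 2 cells
})

test_that("Shannon entropy matches closed forms", {
  expect_equal(shannon_entropy(c(5, 0, 0)), 0)
  expect_equal(shannon_entropy(c(3, 3)), log(2))
  expect_equal(shannon_entropy(rep(1, 7)), log(7))
})

test_that("spatial diversity handles degenerate identical cells", {
  mask <- matrix(0L, 60, 60)
  centroids <- cbind(row = c(10, 10, 10, 50, 50, 50),
                     col = c(10, 11, 12, 50, 51, 52))
  rownames(centroids) <- as.character(1:6)
  per_cell <- data.frame(cell = as.character(1:6), n_transcripts = 5)
  types <- as.list(stats::setNames(rep("A", 6), 1:6))
  d <- spatial_diversity(mask, types, per_cell, centroids, region_side = 30)
  expect_true(all(d$per_region$entropy == 0))
  expect_true(all(d$per_region$cv_n_transcripts == 0))
  expect_true(is.na(d$correlations[["n_transcripts"]]))
})

test_that("contamination fractions hit the trivial extremes", {
  genes <- c("m1", "other")
  mat <- matrix(0L, 4, 2, dimnames = list(as.character(1:4), genes))
  centroids <- cbind(row = c(1, 2, 50, 60), col = c(1, 2, 50, 60))
  rownames(centroids) <- as.character(1:4)
  types <- list(`1` = "A", `2` = "A", `3` = "B", `4` = "B")
  out0 <- neighbour_contamination(mat, types, centroids, "A", "B", "m1",
                                  breaks = c(0, 100, 200))
  expect_true(all(out0$fraction_expressing[out0$n_cells > 0] == 0))
  mat[, "m1"] <- 1L
  out1 <- neighbour_contamination(mat, types, centroids, "A", "B", "m1",
                                  breaks = c(0, 100, 200))
  expect_true(all(out1$fraction_expressing[out1$n_cells > 0] == 1))
  expect_true(is.na(out1$fraction_expressing[out1$n_cells == 0][1]))
})

test_that("over-expanded masks show more near-neighbour contamination", {
  sim <- simulate_sst(sim_config(image_height = 192, image_width = 192,
                                 n_cells = 22, background_noise_rate = 0,
                                 rng_seed = 17))
  types <- as.list(sim$truth$cell_types)
  mk <- derive_purity_markers(sim$profile)
  tys <- unlist(types)
  two <- names(sort(table(tys), decreasing = TRUE))[1:2]
  # over-expanded: dilate every true cell by a large disc (captures
  # neighbouring cells' transcripts)
  over <- matrix(0L, 192, 192)
  for (id in as.integer(names(tys))) {
    d <- binary_dilate(sim$truth$cell_mask == id, disc_kernel(15))
    over[d & over == 0] <- id
  }
  cent <- mask_centroids(sim$truth$cell_mask)
  marker <- mk$positive[[two[2]]]
  breaks <- c(0, 60, 200)
  frac_of <- function(mask) {
    mm <- map_transcripts_to_cells(sim$transcripts, mask,
                                   colnames(sim$profile))$matrix
    neighbour_contamination(mm, types, cent, two[1], two[2], marker,
                            breaks)$fraction_expressing[1]
  }
  expect_gte(frac_of(over), frac_of(sim$truth$cell_mask))
})

test_that("replicability of identical reports is exactly 1", {
  sim <- small_sim()
  mapped <- map_transcripts_to_cells(sim$transcripts, sim$truth$cell_mask,
                                     colnames(sim$profile))
  b <- baseline_metrics(mapped$matrix, sim$truth$cell_mask)
  types <- as.list(sim$truth$cell_types)
  r <- replicability(b$per_cell, types, b$per_cell, types)
  expect_true(all(abs(r$characteristic_r - 1) < 1e-12, na.rm = TRUE))
  expect_equal(r$proportion_r, 1)
})

test_that("anti-correlated per-type means give r = -1", {
  per1 <- data.frame(cell = as.character(1:4),
                     n_transcripts = c(10, 10, 30, 30))
  types <- list(`1` = "A", `2` = "A", `3` = "B", `4` = "B")
  # negate per-type means around the grand mean: A 10 -> 30, B 30 -> 10
  per2 <- data.frame(cell = as.character(1:4),
                     n_transcripts = c(30, 30, 10, 10))
  r <- replicability(per1, types, per2, types)
  expect_equal(unname(r$characteristic_r[["n_transcripts"]]), -1)
})

test_that("noisy sister replicates of a typed tissue correlate strongly", {
  # two replicates drawn from the same type-dependent count model
  mk_rep <- function(seed) {
    set.seed(seed)
    ty <- rep(c("A", "B", "C"), times = c(8, 12, 20))
    mu <- c(A = 50, B = 150, C = 300)[ty]
    per_cell <- data.frame(cell = as.character(seq_along(ty)),
                           n_transcripts = rpois(length(ty), mu))
    list(per_cell = per_cell,
         types = as.list(stats::setNames(ty, per_cell$cell)))
  }
  a <- mk_rep(101); b <- mk_rep(202)
  r <- replicability(a$per_cell, a$types, b$per_cell, b$types)
  expect_gt(r$characteristic_r[["n_transcripts"]], 0.9)
  expect_gt(r$proportion_r, 0.99)
})
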