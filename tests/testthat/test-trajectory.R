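test_that("pseudotime recovers a 1-D synthetic gradient and reverses with
           the root", {
  set.seed(2)
  n <- 150
  t <- sort(runif(n))
  coords <- cbind(10 * t, (10 * t)^1.3 / 4) +
    matrix(rnorm(n * 2, 0, 0.1), n, 2)
  coords <- cbind(coords, matrix(rnorm(n * 6, 0, 0.1), n, 6))
  rownames(coords) <- sprintf("c%03d", seq_len(n))
  pt <- computePseudotime(coords, "c001", k = 10)
  expect_identical(unname(pt["c001"]), 0)
  expect_gte(cor(pt, t, method = "spearman"), 0.9)
  ptRev <- computePseudotime(coords, sprintf("c%03d", n), k = 10)
  expect_lte(cor(ptRev, t, method = "spearman"), -0.9)
  # single-cell subset
  pt1 <- computePseudotime(coords, "c005", cells = "c005")
  expect_identical(as.numeric(pt1), 0)
  expect_error(computePseudotime(coords, "c001", cells = "c002"),
               "not in the requested subset")
})

test_that("cells disconnected from the root are flagged with NA", {
  set.seed(6)
  a <- matrix(rnorm(30 * 2, 0, 0.3), 30, 2)
  b <- matrix(rnorm(10 * 2, 100, 0.3), 10, 2)
  coords <- rbind(a, b)
  rownames(coords) <- sprintf("c%02d", 1:40)
  pt <- computePseudotime(coords, "c01", k = 4)
  expect_true(all(is.na(pt[31:40])))
  expect_true(all(!is.na(pt[1:30])))
  expect_setequal(attr(pt, "disconnected"), sprintf("c%02d", 31:40))
})

test_that("planted latent time is recovered within the gradient
           population across seeds", {
  for (s in 0:4) {
    sce <- pipelineFixture(s)
    cells <- colnames(sce)[sce$cell_type == "Mac V"]
    pt <- pseudotimeOnSubset(sce, cells,
                             earlyMarkers = sprintf("Grad.e%02d", 1:6))
    sub <- attr(pt, "experiment")
    rho <- cor(pt, sub$latent_time, method = "spearman",
               use = "complete.obs")
    expect_gte(abs(rho), 0.9)
  }
})

test_that("potential interpolation handles point masses, constants and
           radial fields", {
  # single cell: nearest node populated with that value
  emb1 <- rbind(c(0.2, 0.8), c(1, 0), c(0, 1))
  f1 <- interpolatePotential(emb1, c(0.7, 0.1, 0.4), nx = 11, ny = 11)
  ix <- which.min(abs(f1@x - 0.2)); iy <- which.min(abs(f1@y - 0.8))
  expect_true(f1@populated[ix, iy])
  expect_equal(f1@potential[ix, iy], 0.7, tolerance = 0.15)
  # constant pseudotime interpolates to the constant
  set.seed(10)
  emb <- matrix(runif(200), 100, 2)
  fc <- interpolatePotential(emb, rep(0.5, 100), nx = 15, ny = 15)
  expect_true(all(abs(fc@potential[fc@populated] - 0.5) < 1e-12))
  # degenerate bounding box
  expect_error(interpolatePotential(matrix(1, 5, 2), runif(5)),
               "degenerate")
  # radial field: potential increases along populated rays from center
  ang <- runif(400, 0, 2 * pi); rad <- sqrt(runif(400))
  embR <- cbind(rad * cos(ang), rad * sin(ang))
  fr <- interpolatePotential(embR, rad, nx = 21, ny = 21)
  mid <- 11
  for (ray in list(cbind(mid:21, mid), cbind(mid, mid:21),
                   cbind(mid:1, mid), cbind(mid, mid:1))) {
    vals <- fr@potential[ray]
    vals <- vals[!is.na(vals)]
    expect_true(all(diff(vals) > -0.05))
  }
})

test_that("local maxima: single peak, constant field, and disjoint
           patches", {
  set.seed(14)
  emb <- as.matrix(expand.grid(seq(0, 1, length.out = 25),
                               seq(0, 1, length.out = 25)))
  peak <- exp(-((emb[, 1] - 0.5)^2 + (emb[, 2] - 0.5)^2) / 0.05)
  f <- interpolatePotential(emb, peak, nx = 25, ny = 25,
                            radiusFactor = 1.1)
  mx <- findLocalMaxima(f)
  expect_identical(nrow(mx), 1L)
  expect_equal(f@x[mx$ix], 0.5, tolerance = 0.05)
  expect_equal(f@y[mx$iy], 0.5, tolerance = 0.05)
  # constant potential: no maxima under the strictness rule
  fconst <- interpolatePotential(emb, rep(0.3, nrow(emb)),
                                 nx = 15, ny = 15)
  expect_identical(nrow(findLocalMaxima(fconst)), 0L)
  # two disjoint populated patches, each with its own peak
  embA <- matrix(rnorm(400, 0, 0.4), 200, 2)
  embB <- matrix(rnorm(400, 8, 0.4), 200, 2)
  emb2 <- rbind(embA, embB)
  pt2 <- c(exp(-rowSums(embA^2)), 2 * exp(-rowSums((embB - 8)^2)))
  f2 <- interpolatePotential(emb2, pt2, nx = 40, ny = 40,
                             radiusFactor = 1.2)
  mx2 <- findLocalMaxima(f2)
  expect_identical(nrow(mx2), 2L)
  expect_true(all(diff(mx2$potential) <= 0))  # sorted descending
})

test_that("gradient is exact on affine potentials and points outward on
           radial fields", {
  emb <- as.matrix(expand.grid(seq(0, 1, length.out = 20),
                               seq(0, 1, length.out = 20)))
  f <- interpolatePotential(emb, 2 * emb[, 1] - emb[, 2] + 0.5,
                            nx = 20, ny = 20, radiusFactor = 1.1)
  gr <- gradientField(f)
  interior <- gr$ix > 1 & gr$ix < 20 & gr$iy > 1 & gr$iy < 20
  expect_equal(gr$gx[interior], rep(2, sum(interior)), tolerance = 1e-6)
  expect_equal(gr$gy[interior], rep(-1, sum(interior)), tolerance = 1e-6)
  # constant potential: zero vectors
  fc <- interpolatePotential(emb, rep(0.4, nrow(emb)), nx = 10, ny = 10)
  grc <- gradientField(fc)
  expect_lt(max(abs(c(grc$gx, grc$gy))), 1e-9)
  # radial field: arrows point away from the center
  set.seed(15)
  ang <- runif(600, 0, 2 * pi); rad <- sqrt(runif(600))
  embR <- cbind(rad * cos(ang), rad * sin(ang))
  fr <- interpolatePotential(embR, rad, nx = 21, ny = 21)
  gr2 <- gradientField(fr)
  interior2 <- gr2$ix > 2 & gr2$ix < 20 & gr2$iy > 2 & gr2$iy < 20 &
    gr2$defined_x & gr2$defined_y & (gr2$x^2 + gr2$y^2) > 0.04
  dots <- gr2$gx[interior2] * gr2$x[interior2] +
    gr2$gy[interior2] * gr2$y[interior2]
  expect_gte(mean(dots > 0), 0.95)
})

test_that("no arrow exits a local maximum toward higher potential", {
  emb <- as.matrix(expand.grid(seq(0, 1, length.out = 25),
                               seq(0, 1, length.out = 25)))
  peak <- exp(-((emb[, 1] - 0.4)^2 + (emb[, 2] - 0.6)^2) / 0.03)
  f <- interpolatePotential(emb, peak, nx = 25, ny = 25,
                            radiusFactor = 1.1)
  mx <- findLocalMaxima(f)
  gr <- gradientField(f)
  at <- gr[gr$ix == mx$ix[1] & gr$iy == mx$iy[1], ]
  # the arrow at the maximum node points toward the continuous peak
  # (uphill), never away from it toward lower potential
  v <- c(0.4 - at$x, 0.6 - at$y)
  expect_gte(at$gx * v[1] + at$gy * v[2], 0)
})
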