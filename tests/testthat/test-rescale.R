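test_that("sum aggregation: constant blocks, identity, brute-force oracle", {
  g1 <- sgrid(matrix(1, 10, 10))
  a1 <- aggregate_sum(g1, 5)
  expect_equal(dim(a1), c(2, 2))
  expect_true(all(a1$values == 25))
  expect_equal(a1$cell_size, 5)

  g <- sgrid(matrix(runif(100), 10, 10))
  expect_identical(aggregate_sum(g, 1), g)

  # brute-force double-loop block sums
  a <- aggregate_sum(g, 5)
  for (i in 1:2) for (j in 1:2) {
    blk <- g$values[((i - 1) * 5 + 1):(i * 5), ((j - 1) * 5 + 1):(j * 5)]
    expect_identical(a$values[i, j], sum(blk))
  }
})

test_that("sum aggregation conserves totals and handles masks and padding", {
  set.seed(2)
  v <- matrix(runif(120), 10, 12)
  mask <- matrix(FALSE, 10, 12)
  mask[1:5, 1:5] <- TRUE  # one fully masked block
  g <- sgrid(v, mask = mask)
  a <- aggregate_sum(g, 5)
  expect_equal(sum(a$values[!a$mask]), sum(v[!mask]))
  expect_true(a$mask[1, 1])  # fully masked block stays masked
  expect_equal(sum(a$mask), 1)  # partially masked blocks are kept

  # non-divisible shape: padded with masked cells, recorded
  g2 <- sgrid(matrix(1, 7, 7))
  a2 <- aggregate_sum(g2, 5)
  expect_equal(dim(a2), c(2, 2))
  expect_equal(a2$meta$padded, c(rows = 3L, cols = 3L))
  expect_equal(sum(a2$values[!a2$mask]), 49)

  expect_error(aggregate_sum(sgrid(matrix(1L, 2, 2), kind = "categorical",
                                   labels = LAND_COVER_CLASSES), 2),
               "undefined for categories")
})

test_that("bilinear resampling: constants, exact linear fields, bounds", {
  target <- grid_geometry(sgrid(matrix(0, 4, 4), cell_size = 1.3,
                                origin = c(0.4, 0.7)))
  const <- resample_bilinear(sgrid(matrix(7, 6, 6)), target)
  expect_true(all(abs(const$values - 7) < 1e-12))

  # f(x, y) = 2x + 3y is reproduced exactly inside the input centre lattice
  g <- sgrid(outer(1:8, 1:8, function(i, j) 0 * i), cell_size = 1)
  cc <- cell_centres(g)
  g$values <- outer(cc$y, cc$x, function(y, x) 2 * x + 3 * y)
  tg <- grid_geometry(sgrid(matrix(0, 5, 5), cell_size = 1,
                            origin = c(0.9, 1.1)))
  out <- resample_bilinear(g, tg)
  oc <- cell_centres(out)
  want <- outer(oc$y, oc$x, function(y, x) 2 * x + 3 * y)
  expect_equal(out$values, want, tolerance = 1e-12)

  # output bounded by input range
  set.seed(3)
  gr <- sgrid(matrix(runif(36), 6, 6))
  rs <- resample_bilinear(gr, grid_geometry(sgrid(matrix(0, 9, 9),
                                                  cell_size = 0.6,
                                                  origin = c(0.2, 0.2))))
  expect_true(min(rs$values) >= min(gr$values) - 1e-12)
  expect_true(max(rs$values) <= max(gr$values) + 1e-12)

  expect_error(resample_bilinear(gr, list(nrow = 0, ncol = 3, cell_size = 1,
                                          origin = c(0, 0))), "zero cells")
})

test_that("bilinear resampling matches an independent interpolation oracle", {
  set.seed(4)
  g <- sgrid(matrix(runif(36), 6, 6))
  tg <- grid_geometry(sgrid(matrix(0, 4, 4), cell_size = 1.2,
                            origin = c(0.5, 0.5)))
  out <- resample_bilinear(g, tg)
  # oracle: straight-line interpolation row-wise then column-wise via approx
  cc <- cell_centres(g)
  oc <- cell_centres(sgrid(matrix(0, 4, 4), cell_size = 1.2,
                           origin = c(0.5, 0.5)))
  rowwise <- sapply(oc$x, function(x)
    apply(g$values, 1, function(row)
      stats::approx(cc$x, row, xout = x, rule = 2)$y))
  oracle <- apply(rowwise, 2, function(col)
    stats::approx(cc$y, col, xout = oc$y, rule = 2)$y)
  expect_equal(out$values, oracle, tolerance = 1e-10)
})

test_that("bilinear excludes masked neighbours with weight renormalisation", {
  v <- matrix(10, 3, 3); v[2, 2] <- NA
  g <- sgrid(v, mask = is.na(v))
  # output centres sit between input centres; the masked centre cell gets
  # weight but is excluded, and the rest renormalise to the constant
  tg <- list(nrow = 2, ncol = 2, cell_size = 1, origin = c(0.5, 0.5))
  out <- resample_bilinear(g, tg)
  expect_false(any(out$mask))
  expect_true(all(abs(out$values - 10) < 1e-12))
})

test_that("majority upscaling: uniform blocks, counted votes, tie-break", {
  u <- sgrid(matrix(4L, 5, 5), kind = "categorical",
             labels = LAND_COVER_CLASSES)
  expect_equal(grid_values(upscale_majority(u, 5)), "tea")

  # 13 forest vs 12 urban in one 5x5 block
  codes <- matrix(c(rep(3L, 13), rep(5L, 12)), 5, 5)
  g <- sgrid(codes, kind = "categorical", labels = LAND_COVER_CLASSES)
  expect_equal(grid_values(upscale_majority(g, 5)), "forest")

  # exact tie: class earliest in the label set wins, tie recorded
  tie <- sgrid(matrix(c(1L, 5L), 2, 1), kind = "categorical",
               labels = LAND_COVER_CLASSES)
  out <- upscale_majority(tie, 2)
  expect_equal(grid_values(out), "agriculture")
  expect_equal(out$meta$ties, 1L)

  expect_error(upscale_majority(sgrid(matrix(1, 2, 2)), 2),
               "undefined for continuous")
})

test_that("majority output labels are a subset of the input label set", {
  set.seed(5)
  g <- sgrid(matrix(sample(1:5, 400, TRUE), 20, 20), kind = "categorical",
             labels = LAND_COVER_CLASSES)
  out <- upscale_majority(g, 4)
  expect_true(all(grid_values(out) %in% LAND_COVER_CLASSES))
  expect_identical(out$labels, g$labels)
})

test_that("rescalers commute with relabelling of the nodata mask", {
  set.seed(6)
  v <- matrix(runif(100), 10, 10)
  mask <- matrix(runif(100) < 0.15, 10, 10)
  g <- sgrid(v, mask = mask)
  # writing NA under the mask must not change any result
  v2 <- v; v2[mask] <- NA
  g2 <- sgrid(v2, mask = mask)
  expect_equal(aggregate_sum(g, 5)$values[!aggregate_sum(g, 5)$mask],
               aggregate_sum(g2, 5)$values[!aggregate_sum(g2, 5)$mask])
  tg <- grid_geometry(sgrid(matrix(0, 7, 7), cell_size = 10 / 7,
                            origin = c(0.5, 0.5)))
  r1 <- resample_bilinear(g, tg); r2 <- resample_bilinear(g2, tg)
  expect_equal(r1$values[!r1$mask], r2$values[!r2$mask])
})
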