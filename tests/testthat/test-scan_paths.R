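# Scan-order construction, inversion and (de)serialization.

test_that("canonical orders match their defining conventions", {
  expect_identical(scanIndices(buildScanOrder(2, 2, "horizontal")),
                   c(0L, 1L, 2L, 3L))
  expect_identical(scanIndices(buildScanOrder(2, 2, "vertical")),
                   c(0L, 2L, 1L, 3L))
  expect_identical(scanIndices(buildScanOrder(3, 3, "antidiagonal")),
                   c(0L, 1L, 3L, 2L, 4L, 6L, 5L, 7L, 8L))
  expect_identical(scanIndices(buildScanOrder(3, 3, "zigzag")),
                   c(0L, 1L, 3L, 6L, 4L, 2L, 5L, 7L, 8L))
  # maindiagonal is the mirrored antidiagonal
  expect_identical(scanIndices(buildScanOrder(2, 3, "maindiagonal")),
                   c(2L, 1L, 5L, 0L, 4L, 3L))
  # reverse is the forward order reversed
  for (kind in c("horizontal", "vertical", "antidiagonal", "maindiagonal",
                 "zigzag"))
    expect_identical(scanIndices(buildScanOrder(4, 5, kind, "reverse")),
                     rev(scanIndices(buildScanOrder(4, 5, kind, "forward"))))
})

test_that("invertOrder inverts permutations and rejects non-permutations", {
  expect_identical(invertOrder(c(0L, 1L, 2L)), c(0L, 1L, 2L))
  expect_identical(invertOrder(c(2L, 0L, 1L)), c(1L, 2L, 0L))
  expect_identical(invertOrder(c(0L, 2L, 1L, 3L)), c(0L, 2L, 1L, 3L))
  set.seed(11)
  for (n in c(1, 2, 7, 40)) {
    o <- sample(n) - 1L
    inv <- invertOrder(o)
    expect_identical(inv[o + 1L], 0:(n - 1L))
  }
  expect_error(invertOrder(c(0L, 0L, 1L)), "permutation")
  expect_error(invertOrder(c(1L, 2L, 3L)), "permutation")
})

test_that("every order is a bijection with a consistent inverse (grid sweep)", {
  for (H in 1:8) for (W in 1:8) {
    for (kind in c("horizontal", "vertical", "antidiagonal", "maindiagonal",
                   "zigzag")) {
      for (dir in c("forward", "reverse")) {
        o <- buildScanOrder(H, W, kind, dir)
        n <- H * W
        expect_identical(sort(scanIndices(o)), 0:(n - 1L))
        expect_identical(scanInverse(o)[scanIndices(o) + 1L], 0:(n - 1L))
      }
    }
  }
})

test_that("anti-diagonal traversal keeps diagonal neighbors adjacent", {
  for (H in 1:8) for (W in 1:8) {
    o <- scanIndices(buildScanOrder(H, W, "antidiagonal"))
    r <- o %/% W
    cc <- o %% W
    d <- r + cc
    same <- which(diff(d) == 0)  # consecutive cells on one anti-diagonal
    if (length(same)) {
      expect_true(all(abs(diff(r)[same]) == 1))
      expect_true(all(abs(diff(cc)[same]) == 1))
    }
  }
})

test_that("raster scanning forgets spatial neighbors; antidiagonal does not", {
  for (H in 2:6) for (W in 2:6) {
    o <- scanIndices(buildScanOrder(H, W, "horizontal"))
    r <- o %/% W
    cc <- o %% W
    # some consecutive tokens are spatially non-adjacent: city-block
    # distance > 1 always; Chebyshev > 1 once a row has >= 3 cells
    manh <- abs(diff(r)) + abs(diff(cc))
    expect_true(any(manh > 1))
    if (W >= 3) {
      cheb <- pmax(abs(diff(r)), abs(diff(cc)))
      expect_true(any(cheb > 1))
    }
    # antidiagonal: a cell's diagonal neighbor on the same anti-diagonal is
    # visited at sequence-index gap exactly 1
    oa <- scanIndices(buildScanOrder(H, W, "antidiagonal"))
    pos <- invertOrder(oa)
    maxGap <- 0L
    for (rr in 0:(H - 1)) for (ccc in 0:(W - 1)) {
      if (rr + 1 <= H - 1 && ccc - 1 >= 0) {  # diagonal neighbor, same d
        gap <- abs(pos[rr * W + ccc + 1L] - pos[(rr + 1) * W + ccc - 1 + 1L])
        maxGap <- max(maxGap, gap)
      }
    }
    if (H > 1 && W > 1) expect_identical(maxGap, 1L)
  }
})

test_that("buildScanSet composes the hybrid path families", {
  ss <- buildScanSet(4, 4, "diagonal", 8)
  expect_s4_class(ss, "ScanSet")
  expect_length(scanOrders(ss), 8)
  kinds <- vapply(scanOrders(ss), scanKind, character(1))
  dirs <- vapply(scanOrders(ss), scanDirection, character(1))
  expect_setequal(unique(kinds), c("horizontal", "vertical", "antidiagonal",
                                   "maindiagonal"))
  expect_identical(sum(dirs == "forward"), 4L)
  # all eight orders distinct bijections
  sigs <- vapply(scanOrders(ss), function(o)
    paste(scanIndices(o), collapse = ","), character(1))
  expect_identical(anyDuplicated(sigs), 0L)

  s4 <- buildScanSet(4, 4, "diagonal", 4)
  expect_length(scanOrders(s4), 4)
  expect_true(all(vapply(scanOrders(s4), scanDirection, character(1)) ==
                    "forward"))

  zz <- buildScanSet(5, 3, "zigzag", 8)
  expect_true(all(vapply(scanOrders(zz), scanKind, character(1)) %in%
                    c("horizontal", "vertical", "zigzag")))
  for (o in scanOrders(zz))
    expect_identical(sort(scanIndices(o)), 0:14L)

  one <- buildScanSet(1, 1, "diagonal", 8)
  for (o in scanOrders(one)) expect_identical(scanIndices(o), 0L)

  expect_error(buildScanSet(4, 4, "diagonal", 5), "scanCount")
  expect_error(buildScanOrder(0, 3, "horizontal"), "positive")
})

test_that("serialize/deserialize round-trips exactly and follows the order", {
  o <- buildScanOrder(2, 2, "vertical")
  g <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)  # [[a,b],[c,d]]
  expect_identical(serializeGrid(g, o), c(1, 3, 2, 4))
  set.seed(5)
  x <- array(rnorm(3 * 5 * 7), c(3, 5, 7))
  for (kind in c("horizontal", "zigzag", "maindiagonal")) {
    ord <- buildScanOrder(5, 7, kind, "reverse")
    expect_identical(deserializeGrid(serializeGrid(x, ord), ord), x)
  }
  zo <- buildScanOrder(3, 3, "zigzag")
  expect_identical(deserializeGrid(matrix(0, 2, 9), zo),
                   array(0, c(2, 3, 3)))
  expect_error(serializeGrid(matrix(0, 3, 3), buildScanOrder(2, 2, "zigzag")),
               "dimensions")
})
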