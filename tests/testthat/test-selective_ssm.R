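# Selective state-space recurrence: discretization, step-size prediction,
# kernel-vs-oracle equivalence, stability, and the multi-head wrapper.

test_that("makeA is strictly negative and elementwise", {
  expect_equal(makeA(0), -1)
  expect_equal(makeA(log(2)), -2)
  expect_equal(makeA(c(0, log(3))), c(-1, -3))
  set.seed(1)
  a <- rnorm(50, sd = 3)
  expect_true(all(makeA(a) < 0))
})

test_that("predictDelta is softplus-positive with the documented values", {
  p0 <- list(W1 = matrix(0, 1, 1), b1 = 0, W2 = matrix(0, 1, 1), b2 = 0)
  expect_equal(predictDelta(0, p0), log(2), tolerance = 1e-12)
  p5 <- list(W1 = matrix(0, 1, 1), b1 = 0, W2 = matrix(0, 1, 1), b2 = 5)
  expect_equal(predictDelta(0, p5), log1p(exp(5)), tolerance = 1e-12)
  expect_equal(predictDelta(0, p5), 5.006715348489, tolerance = 1e-9)
  pneg <- list(W1 = matrix(0, 1, 1), b1 = 0, W2 = matrix(0, 1, 1), b2 = -40)
  expect_gt(predictDelta(0, pneg), 0)
  expect_lt(predictDelta(0, pneg), 1e-15)
  set.seed(2)
  pr <- list(W1 = matrix(rnorm(6), 2, 3), b1 = rnorm(2),
             W2 = matrix(rnorm(2), 1, 2), b2 = rnorm(1))
  d <- predictDelta(matrix(rnorm(30), 3), pr)
  expect_length(d, 10)
  expect_true(all(d > 0))
})

test_that("zero-order-hold discretization has the closed-form values", {
  d0 <- discretizeStep(0, c(-1, -2))
  expect_equal(d0$Abar, c(1, 1))
  expect_equal(d0$Phi, c(0, 0))
  d1 <- discretizeStep(1, -1)
  expect_equal(d1$Abar, exp(-1), tolerance = 1e-12)
  expect_equal(d1$Phi, 1 - exp(-1), tolerance = 1e-12)
  dts <- discretizeStep(1e-8, -1)
  expect_equal(dts$Phi / 1e-8, 1, tolerance = 1e-7)
  # invariants: Abar in (0,1), Phi >= 0 for delta > 0
  set.seed(3)
  for (i in 1:20) {
    dd <- discretizeStep(runif(1, 1e-4, 5), -exp(rnorm(4)))
    expect_true(all(dd$Abar > 0 & dd$Abar < 1))
    expect_true(all(dd$Phi >= 0))
  }
})

test_that("small-step limit: ||Phi - delta|| obeys the quadratic bound", {
  A <- -exp(c(-1, 0, 1.2))
  for (delta in c(1e-3, 1e-5)) {
    d <- discretizeStep(delta, A)
    bound <- delta^2 * max(abs(A)) / 2 * exp(delta * max(abs(A)))
    expect_lte(max(abs(d$Phi - delta)), bound)
  }
})

test_that("selective scan reproduces the hand-unrolled recurrence", {
  # N=1, fixed delta=1, a=0 (A=-1), B=1, C=1, D=0, u=(1,0,0):
  # phi = 1-e^-1; h1 = phi, h2 = e^-1 h1, h3 = e^-2 phi
  p <- fixedDeltaHead(1, 1, delta = 1, mode = "static", aRaw = 0, Dskip = 0,
                      B = 1, C = 1)
  y <- selectiveScan(matrix(c(1, 0, 0), 1), p)
  phi <- 1 - exp(-1)
  expect_equal(as.vector(y), c(phi, exp(-1) * phi, exp(-2) * phi),
               tolerance = 1e-10)
  expect_equal(as.vector(y), c(0.632121, 0.232544, 0.085548),
               tolerance = 1e-5)
})

test_that("pure skip path and zero input behave exactly", {
  set.seed(4)
  p <- ssmHeadParams(3, 4, mode = "static", C = rep(0, 4), Dskip = rep(1, 3))
  u <- matrix(rnorm(30), 3)
  expect_equal(selectiveScan(u, p), u)  # C == 0, D == 1 -> identity
  p2 <- ssmHeadParams(2, 4)
  expect_equal(selectiveScan(matrix(0, 2, 9), p2), matrix(0, 2, 9))
  expect_error(selectiveScan(matrix(c(1, NA), 1), p2), "finite")
})

test_that("vectorized kernel equals the naive per-step oracle (randomized)", {
  set.seed(42)
  worst <- 0
  for (i in 1:200) {
    Ch <- sample(1:4, 1)
    L <- sample(1:32, 1)
    N <- sample(1:8, 1)
    mode <- sample(c("selective", "static"), 1)
    p <- ssmHeadParams(Ch, N, mode = mode,
                       aRaw = rnorm(N), Dskip = rnorm(Ch))
    u <- matrix(rnorm(Ch * L), Ch, L)
    worst <- max(worst, max(abs(selectiveScan(u, p) -
                                  selectiveScanRef(u, p))))
  }
  expect_lte(worst, 1e-10)
})

test_that("homogeneous recurrence decays monotonically (stability)", {
  set.seed(6)
  for (i in 1:10) {
    N <- 5L
    A <- makeA(rnorm(N, sd = 2))
    delta <- runif(1, 0.01, 2)
    st <- discretizeStep(delta, A)
    h <- rnorm(N, sd = 10)
    norms <- numeric(40)
    for (t in 1:40) {
      h <- st$Abar * h
      norms[t] <- sqrt(sum(h^2))
    }
    expect_true(all(diff(norms) < 0 | norms[-40] == 0))
  }
})

test_that("multiHeadScan preserves spatial shape across a grid sweep", {
  set.seed(8)
  for (H in c(1, 3, 5, 8)) for (W in c(1, 4, 8)) {
    ss <- buildScanSet(H, W, "diagonal", 8)
    heads <- lapply(1:8, function(j) ssmHeadParams(2, 3))
    x <- array(rnorm(2 * H * W), c(2, H, W))
    y <- multiHeadScan(x, ss, heads, ln = TRUE)
    expect_identical(dim(y), dim(x))
  }
})

test_that("multiHeadScan: skip-only head passes the gated-projected input", {
  set.seed(9)
  H <- 4; W <- 5
  ss <- new("ScanSet",
            orders = list(buildScanOrder(H, W, "horizontal")),
            scanType = "diagonal", scanCount = 1L)
  head <- ssmHeadParams(3, 4, mode = "static", C = rep(0, 4),
                        Dskip = rep(1, 3))
  x <- array(rnorm(3 * H * W), c(3, H, W))
  gate <- matrix(runif(3 * H * W), 3, H * W)
  y <- multiHeadScan(x, ss, list(head), ln = NULL, gate = gate)
  expect_equal(y, MambaSR:::.matToGrid(MambaSR:::.gridToMat(x) * gate, H, W),
               tolerance = 1e-12)
})

test_that("permuting heads together with their orders leaves output unchanged", {
  set.seed(10)
  H <- 4; W <- 4
  ss <- buildScanSet(H, W, "diagonal", 4)
  heads <- lapply(1:4, function(j) ssmHeadParams(2, 3))
  x <- array(rnorm(2 * H * W), c(2, H, W))
  y1 <- multiHeadScan(x, ss, heads, ln = NULL)  # head-mean projection
  perm <- c(3, 1, 4, 2)
  ssPerm <- new("ScanSet", orders = scanOrders(ss)[perm],
                scanType = "diagonal", scanCount = 4L)
  y2 <- multiHeadScan(x, ssPerm, heads[perm], ln = NULL)
  expect_equal(y1, y2, tolerance = 1e-12)
})
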