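# Block matching, the 3D group transform, the NLS functional, the
# collaborative-shrinkage x-update and the aggregation operator.

test_that("block matching ranks by distance with row-major tie-breaking", {
  pp <- smallNLS()
  # constant image: all distances zero, members in scan order after the ref
  flat <- matrix(42, 16, 16)
  g <- findSimilarBlocks(flat, c(7, 7), pp)
  expect_identical(g@memberIndices[1, ], c(7L, 7L))
  expect_true(all(g@distances == 0))
  # the 15 x 15 window centred on the block reaches the image corner, so the
  # first non-reference candidates in row-major scan order are (1,1), (1,2)
  expect_identical(g@memberIndices[2, ], c(1L, 1L))
  expect_identical(g@memberIndices[3, ], c(1L, 2L))

  # a planted exact duplicate of the reference is member 2
  set.seed(10)
  img <- matrix(rnorm(32 * 32, 100, 30), 32, 32)
  img[12:15, 6:9] <- img[5:8, 5:8]           # the duplicate
  g2 <- findSimilarBlocks(img, c(5, 5), nlsParams(blockSize = 4,
    groupSize = 4, searchWindow = 21))
  expect_identical(g2@memberIndices[2, ], c(12L, 6L))
  expect_equal(g2@distances[2], 0)

  expect_error(findSimilarBlocks(matrix(0, 8, 8), c(6, 6), pp), "outside")
  expect_error(findSimilarBlocks(matrix(0, 8, 8), c(3, 3),
    nlsParams(blockSize = 4, groupSize = 64, searchWindow = 5)),
    "window too small")
})

test_that("group membership matches an exhaustive distance sort", {
  set.seed(11)
  img <- pixels(makePhantom(32, 32, texturePeriod = 4, nShapes = 2, seed = 11))
  pp <- nlsParams(blockSize = 4, groupSize = 6, searchWindow = 13)
  for (ref in list(c(5, 5), c(10, 17), c(29, 29))) {
    g <- findSimilarBlocks(img, ref, pp)
    # brute force: enumerate candidates, compute distances, stable sort
    n <- 4L
    cr <- ref[1] + 1L; cc <- ref[2] + 1L   # centre pixel (n-1)/2 = 1 offset
    half <- 6L
    rows <- max(1L, cr - half):min(32L - n + 1L, cr + half - n + 1L)
    cols <- max(1L, cc - half):min(32L - n + 1L, cc + half - n + 1L)
    refBlk <- img[ref[1]:(ref[1] + 3), ref[2]:(ref[2] + 3)]
    cand <- expand.grid(c = cols, r = rows)[, c("r", "c")]
    cand <- cand[order(cand$r, cand$c), ]
    cand <- cand[!(cand$r == ref[1] & cand$c == ref[2]), ]
    d <- apply(cand, 1, function(rc)
      sum((img[rc[1]:(rc[1] + 3), rc[2]:(rc[2] + 3)] - refBlk)^2))
    ord <- order(d)[1:5]
    expect_equal(g@memberIndices[-1, , drop = FALSE],
                 unname(as.matrix(cand[ord, ])))
    expect_equal(g@distances[-1], unname(d[ord]))
  }
})

test_that("the 3D group transform is orthonormal with the closed-form DC response", {
  img <- makePhantom(64, 64, seed = 1)
  for (tf in c("dct3d", "dct2d_haar1d")) {
    pp <- smallNLS(transform = tf)
    g <- findSimilarBlocks(img, c(9, 9), pp)
    cs <- groupTransform(g, pp)
    expect_lt(abs(sum(cs@coefficients^2) - sum(g@stack^2)), 1e-8)
    expect_lt(max(abs(groupInverseTransform(cs, pp) - g@stack)), 1e-10)
  }
  # constant stack: a single DC coefficient a * sqrt(n * n * m)
  pp <- smallNLS()
  gf <- findSimilarBlocks(matrix(3, 16, 16), c(5, 5), pp)
  cs <- groupTransform(gf, pp)
  expect_equal(cs@coefficients[1, 1, 1], 3 * sqrt(4 * 4 * 4))
  expect_lt(max(abs(cs@coefficients[-1])), 1e-10)
})

test_that("the NLS functional is recomputed by an independent oracle", {
  pp <- nlsParams(blockSize = 4, groupSize = 4, searchWindow = 15, step = 4)
  img <- pixels(makePhantom(32, 32, texturePeriod = 4, seed = 3))
  expect_equal(nlsNorm(matrix(0, 16, 16), pp), 0)
  v <- nlsNorm(img, pp)
  expect_equal(nlsNorm(2.5 * img, pp), 2.5 * v, tolerance = 1e-12)

  # independent recomputation: R block matching oracle + closed-form DCT
  Tn <- oracleDCT(4); Tm <- oracleDCT(4)
  total <- 0
  grid <- c(seq(1, 29, by = 4))
  for (r in grid) for (cc in grid) {
    g <- findSimilarBlocks(img, c(r, cc), pp)
    coef <- array(0, c(4, 4, 4))
    for (k in 1:4) coef[, , k] <- Tn %*% g@stack[, , k] %*% t(Tn)
    flat <- matrix(coef, 16, 4) %*% t(Tm)
    total <- total + sum(abs(flat))
  }
  expect_equal(v, total, tolerance = 1e-10)
})

test_that("aggregation is a partition of unity over covered pixels", {
  set.seed(12)
  r <- matrix(rnorm(64, 100, 10), 8, 8)
  # two overlapping untouched blocks reproduce r exactly where covered
  st <- array(0, c(4, 4, 2))
  st[, , 1] <- r[1:4, 1:4]; st[, , 2] <- r[3:6, 3:6]
  out <- aggregateBlocks(list(st), list(rbind(c(1L, 1L), c(3L, 3L))), c(8, 8),
                         fallback = r)
  expect_equal(out, r)
  # single block covering everything
  one <- array(r, c(8, 8, 1))
  expect_equal(aggregateBlocks(list(one), list(rbind(c(1L, 1L))), c(8, 8)), r)
  # overlap of two identical constant blocks stays at the common value
  cb <- array(5, c(4, 4, 2))
  out2 <- aggregateBlocks(list(cb), list(rbind(c(1L, 1L), c(2L, 2L))), c(8, 8))
  expect_true(all(out2[2:4, 2:4] == 5))
  expect_true(all(out2[6:8, ] == 0))   # uncovered -> fallback zeros
})

test_that("the x-update has exact no-op and full-shrinkage limits", {
  for (step in c(2L, 3L)) {   # strides with partial overlap
    pp <- smallNLS(step = step)
    u <- pixels(makePhantom(32, 32, seed = step))
    expect_lt(max(abs(solveXSubproblem(u, 0, 0, 1.3, pp) - u)), 1e-8)
  }
  # threshold beyond every coefficient: covered pixels collapse to zero
  pp <- smallNLS()
  u <- pixels(makePhantom(32, 32, seed = 5))
  K <- 4 * 4 * 4; N <- length(u)
  lamHuge <- (max(abs(u)) * sqrt(K) * 10) * N / (pp@thresholdScale * K)
  expect_lt(max(abs(solveXSubproblem(u, 0, lamHuge, 1, pp))), 1e-10)
  expect_error(solveXSubproblem(u, 0, 1, 0, pp), "rhoNLS")
})

test_that("a single-group instance matches the dense transform-shrink oracle", {
  set.seed(13)
  r <- matrix(rnorm(36, 50, 20), 6, 6)
  pp <- nlsParams(blockSize = 6, groupSize = 1, searchWindow = 7, step = 6)
  lam <- 40; rho <- 2; phi <- matrix(rnorm(36), 6, 6)
  out <- solveXSubproblem(r, phi, lam, rho, pp)
  rr <- r - phi / rho
  thr <- pp@thresholdScale * 36 * lam / (36 * rho)
  C <- oracleDCT(6)
  co <- C %*% rr %*% t(C)
  co <- sign(co) * pmax(abs(co) - thr, 0)
  expect_lt(max(abs(out - t(C) %*% co %*% C)), 1e-8)
})

test_that("transform-domain shrinkage weakly decreases the NLS functional", {
  pp <- smallNLS()
  u <- pixels(addGaussianNoise(makePhantom(32, 32, seed = 6), 15, seed = 6))
  before <- nlsNorm(u, pp)
  x <- solveXSubproblem(u, 0, 30, 1, pp)
  l1b <- attr(x, "l1Before"); l1a <- attr(x, "l1After")
  expect_lte(l1a, l1b)
  expect_lte(nlsNorm(x, pp), before)
})
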