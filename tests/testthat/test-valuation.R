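test_that("opposite normalization maps endpoints and midpoint as stated", {
  expect_equal(scaleOpposite(0, 0, 1), 1)
  expect_equal(scaleOpposite(1, 0, 1), -1)
  expect_equal(scaleOpposite(0.25, 0, 0.5), 0)
  expect_equal(scaleOpposite(0.5, 0, 0.5), -1)
  # affine identities used for D and r
  D <- seq(0, 1, by = 0.05)
  expect_equal(scaleOpposite(D, 0, 1), 2 * (0.5 - D))
  r <- seq(0, 0.5, by = 0.05)
  expect_equal(scaleOpposite(r, 0, 0.5), 4 * (0.25 - r))
  expect_error(scaleOpposite(0.5, 1, 0), "a < b")
  expect_error(scaleOpposite(2, 0, 1), "lie in")
})

test_that("factors follow the hand-evaluated formulas on a 3-vote cell", {
  a <- array(c(TRUE, TRUE, FALSE), c(3, 1, 1))
  sheet <- makeSheet(a)
  f <- computeFactors(sheet)
  expect_equal(f@D[1, 1], 1 / 3)
  expect_equal(as.vector(f@r[1, 1, ]), c(0, 0, 0.5))
  expect_equal(as.vector(f@rscaled[1, 1, ]), c(1, 1, -1))
  expect_equal(f@taskValue, c(lab01 = 1 / 3))
  expect_equal(f@Dscaled[1, 1], 2 * (0.5 - 1 / 3))
})

test_that("unanimous cells carry zero data value and full credit", {
  sheet <- makeSheet(array(TRUE, c(3, 2, 2)))
  f <- computeFactors(sheet)
  expect_true(all(f@D == 0))
  expect_true(all(f@r == 0))
  expect_true(all(f@rscaled == 1))
  expect_true(all(f@Dscaled == 1))
})

test_that("normalized time means sum to 1 and equal 1/K for equal times", {
  sheet <- makeSheet(array(TRUE, c(2, 3, 4)), timings = 6.5)
  f <- computeFactors(sheet)
  expect_equal(unname(f@timeMean), rep(1 / 4, 4))
  set.seed(15)
  sheet2 <- randomSheet(3, 10, 5)
  expect_equal(sum(computeFactors(sheet2)@timeMean), 1)
})

test_that("factor ranges hold on random sheets", {
  set.seed(21)
  for (rep in 1:30) {
    I <- sample(2:5, 1)
    sheet <- randomSheet(I, sample(2:12, 1), sample(1:4, 1),
                         acc = runif(I, 0.5, 1))
    f <- computeFactors(sheet)
    expect_true(all(f@D >= 0 & f@D <= 1))
    expect_true(all(f@r >= 0 & f@r <= 0.5))
    expect_true(all(abs(f@Dscaled) <= 1))
    expect_true(all(abs(f@rscaled) <= 1))
  }
})

test_that("the 2-annotator hand expansion matches in both weight modes", {
  # img1 votes (T, T), img2 votes (T, F); stipulated pseudo truth (T, T)
  a <- array(c(TRUE, TRUE, TRUE, FALSE), c(2, 2, 1))
  sheet <- makeSheet(a)
  pseudo <- new("PseudoTruth",
                consensus = matrix(TRUE, 1, 2),
                support = matrix(c(2L, 1L), 1, 2),
                tie = matrix(c(FALSE, TRUE), 1, 2), nAnnotators = 2L)
  f <- computeFactors(sheet, pseudo)
  # hand expansion: D = (0, 0.5); T = 0.25; tbar = 1
  expect_equal(as.vector(f@D), c(0, 0.5))
  expect_equal(unname(f@taskValue), 0.25)
  expect_equal(unname(f@timeMean), 1)
  # scaled mode: S_i = (0.25 + 1) * (Dsc1 * rsc1 + Dsc2 * rsc2)
  #   A: 1.25 * (1 * 1 + 0 * 1)  = 1.25
  #   B: 1.25 * (1 * 1 + 0 * -1) = 1.25  -> equal shares
  al <- rewardAllocation(f, 1000, mode = "scaled_D")
  expect_equal(unname(scores(al)), c(1.25, 1.25))
  expect_equal(unname(shares(al)), c(500, 500))
  # unscaled mode: S = (0.625, -0.625) -> negative-score error
  expect_error(rewardAllocation(f, 1000, mode = "unscaled_D"),
               "degenerate annotator score")
})

test_that("allocations conserve the budget and respect symmetry", {
  set.seed(33)
  for (rep in 1:25) {
    I <- sample(2:4, 1)
    sheet <- randomSheet(I, sample(3:15, 1), sample(1:3, 1),
                         acc = runif(I, 0.7, 0.98))
    budget <- runif(1, 10, 5000)
    al <- suppressWarnings(rewardAllocation(computeFactors(sheet), budget))
    expect_equal(sum(shares(al)), budget, tolerance = 1e-9)
    expect_true(all(shares(al) >= 0))
  }
  # exchangeable annotators: identical answers -> equal split
  sheet <- makeSheet(array(rep(c(TRUE, FALSE), each = 3), c(3, 2, 1)),
                     timings = 4)
  al <- rewardAllocation(computeFactors(sheet), 900)
  expect_equal(unname(shares(al)), rep(300, 3))
})

test_that("permuting annotators permutes shares; relabeling images does not", {
  set.seed(44)
  sheet <- randomSheet(3, 12, 2, acc = c(0.95, 0.85, 0.75))
  al <- rewardAllocation(computeFactors(sheet), 100)
  perm <- c(3, 1, 2)
  a2 <- annotations(sheet)[perm, , ]
  dimnames(a2)[[1]] <- dimnames(annotations(sheet))[[1]]  # same ids, swapped rows
  sheet2 <- makeSheet(a2, timings = timings(sheet)[perm, , ])
  al2 <- rewardAllocation(computeFactors(sheet2), 100)
  expect_equal(unname(shares(al2)), unname(shares(al))[perm])

  # image relabeling: reverse image order
  a3 <- annotations(sheet)[, 12:1, ]
  dimnames(a3)[[2]] <- dimnames(annotations(sheet))[[2]]
  sheet3 <- makeSheet(a3, timings = timings(sheet)[, 12:1, ])
  al3 <- rewardAllocation(computeFactors(sheet3), 100)
  expect_equal(shares(al3), shares(al))
})

test_that("flipping an answer to correct never decreases that share", {
  set.seed(55)
  for (rep in 1:40) {
    sheet <- randomSheet(3, 10, 2, acc = runif(3, 0.75, 0.95))
    ps <- pseudoAnswer(sheet)
    a <- annotations(sheet)
    wrong <- which(a[1, , ] != t(consensus(ps)), arr.ind = TRUE)
    if (!nrow(wrong)) next
    w <- wrong[sample(nrow(wrong), 1), , drop = FALSE]
    a2 <- a
    a2[1, w[1, 1], w[1, 2]] <- !a2[1, w[1, 1], w[1, 2]]
    sheet2 <- makeSheet(a2, timings = timings(sheet))
    al1 <- suppressWarnings(
      rewardAllocation(computeFactors(sheet, ps), 100))
    al2 <- suppressWarnings(
      rewardAllocation(computeFactors(sheet2, ps), 100))
    expect_gte(shares(al2)[1], shares(al1)[1] - 1e-9)
  }
})

test_that("largest-remainder rounding yields integer tokens summing exactly", {
  set.seed(66)
  for (rep in 1:20) {
    I <- sample(2:5, 1)
    sheet <- randomSheet(I, 10, 2, acc = runif(I, 0.8, 0.98))
    al <- suppressWarnings(
      rewardAllocation(computeFactors(sheet), 1000, rounding = TRUE))
    expect_true(all(shares(al) == round(shares(al))))
    expect_equal(sum(shares(al)), 1000)
  }
})

test_that("an all-zero score sheet falls back to an equal split with warning", {
  sheet <- makeSheet(array(TRUE, c(3, 2, 2)))  # fully unanimous
  f <- computeFactors(sheet)
  expect_warning(al <- rewardAllocation(f, 600, mode = "unscaled_D"),
                 "splitting the budget equally")
  expect_equal(unname(shares(al)), rep(200, 3))
  # scaled mode keeps positive symmetric scores, no fallback
  expect_silent(al2 <- rewardAllocation(f, 600, mode = "scaled_D"))
  expect_equal(unname(shares(al2)), rep(200, 3))
})

test_that("the end-to-end evaluation wires all stages together", {
  sc <- cxrScenario(seed = 8, nImages = 150)
  sim <- simulateStudy(sc$world, sc$profiles, sc$aiAccuracy)
  res <- evaluateDataset(sim$sheet, budget = 1000, ai = sim$ai)
  expect_s4_class(res$summary, "AgreementSummary")
  expect_s4_class(res$factors, "RewardFactors")
  expect_s4_class(res$gate, "GateReport")
  expect_equal(sum(shares(res$allocation)), 1000, tolerance = 1e-9)
  # without an AI reference there is no gate
  res2 <- evaluateDataset(sim$sheet, budget = 1000)
  expect_null(res2$gate)
})
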