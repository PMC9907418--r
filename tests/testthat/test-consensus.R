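# Independent direct-formula oracles, kept deliberately naive.

fleissOracle <- function(votes) {
  # votes: items x raters logical matrix
  I <- ncol(votes)
  Pitems <- numeric(nrow(votes))
  for (m in seq_len(nrow(votes))) {
    n1 <- sum(votes[m, ]); n0 <- I - n1
    Pitems[m] <- (n1 * (n1 - 1) + n0 * (n0 - 1)) / (I * (I - 1))
  }
  p <- mean(votes)
  Pe <- p^2 + (1 - p)^2
  if (Pe >= 1) return(NA_real_)
  (mean(Pitems) - Pe) / (1 - Pe)
}

cohenOracle <- function(x, y) {
  a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y); d <- sum(!x & !y)
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) / n) * ((a + c) / n) + ((c + d) / n) * ((b + d) / n)
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

test_that("pseudo answer is the strict majority with recorded support", {
  # votes (T, T, F) -> True, support 2; (F, F, F) -> False, support 3
  a <- array(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), c(3, 2, 1))
  pt <- pseudoAnswer(makeSheet(a))
  expect_identical(as.vector(consensus(pt)), c(TRUE, FALSE))
  expect_identical(as.vector(support(pt)), c(2L, 3L))
  expect_false(any(pt@tie))
})

test_that("even splits resolve to negative (or the AI) and are flagged", {
  a <- array(c(TRUE, FALSE), c(2, 1, 1))
  sheet <- makeSheet(a)
  pt <- pseudoAnswer(sheet)
  expect_false(consensus(pt)[1, 1])
  expect_identical(support(pt)[1, 1], 1L)
  expect_true(pt@tie[1, 1])
  # an AI reference overrides the conservative tie rule
  ai <- makeAI(sheet, matrix(TRUE, 1, 1))
  ptAI <- pseudoAnswer(sheet, ai = ai)
  expect_true(consensus(ptAI)[1, 1])
  expect_true(ptAI@tie[1, 1])
})

test_that("pseudo answer is invariant to annotator ordering", {
  set.seed(5)
  sheet <- randomSheet(5, 8, 3)
  perm <- sample(5)
  a2 <- annotations(sheet)[perm, , ]
  dimnames(a2)[[1]] <- dimnames(annotations(sheet))[[1]][perm]
  sheet2 <- makeSheet(a2)
  expect_identical(consensus(pseudoAnswer(sheet)),
                   consensus(pseudoAnswer(sheet2)))
})

test_that("agreement accounting satisfies the partition identity", {
  set.seed(9)
  for (rep in 1:20) {
    sheet <- randomSheet(sample(2:5, 1), sample(2:10, 1), sample(1:4, 1))
    s <- agreementSummary(sheet)
    expect_identical(s@allPositive + s@allNegative + s@discordant, s@total)
    expect_identical(s@total, nImages(sheet) * nLabels(sheet))
    expect_equal(s@unanimityFraction,
                 (s@allPositive + s@allNegative) / s@total)
  }
})

test_that("agreement summary handles the perfect and fully discordant ends", {
  a <- array(rep(c(TRUE, FALSE), each = 6), c(3, 2, 2))
  s <- agreementSummary(makeSheet(a))
  expect_identical(s@discordant, 0L)
  expect_equal(s@unanimityFraction, 1)
  expect_equal(s@pairwiseAgreement, 1)

  one <- array(c(TRUE, TRUE, FALSE), c(3, 1, 1))
  s1 <- agreementSummary(makeSheet(one))
  expect_identical(c(s1@allPositive, s1@allNegative, s1@discordant),
                   c(0L, 0L, 1L))
  expect_equal(s1@unanimityFraction, 0)
})

test_that("Fleiss's kappa matches the direct-formula oracle", {
  # frozen 2-rater example: votes (T,T), (F,F), (T,F), (F,T) -> kappa 0
  a <- array(NA, c(2, 4, 1))
  a[1, , 1] <- c(TRUE, FALSE, TRUE, FALSE)
  a[2, , 1] <- c(TRUE, FALSE, FALSE, TRUE)
  expect_equal(fleissKappa(makeSheet(a)), 0)

  set.seed(31)
  for (rep in 1:50) {
    I <- sample(2:5, 1); J <- sample(2:12, 1); K <- sample(1:3, 1)
    sheet <- randomSheet(I, J, K, acc = runif(I, 0.5, 1))
    votes <- t(matrix(annotations(sheet), nrow = I))  # items x raters
    expect_equal(suppressWarnings(fleissKappa(sheet)), fleissOracle(votes),
                 tolerance = 1e-12)
  }
})

test_that("degenerate one-category ratings yield the NA sentinel", {
  allT <- makeSheet(array(TRUE, c(3, 4, 2)))
  expect_warning(k <- fleissKappa(allT), "single category")
  expect_true(is.na(k))
  expect_warning(k2 <- cohenKappa(rep(TRUE, 5), rep(TRUE, 5)),
                 "no chance variation")
  expect_true(is.na(k2))
})

test_that("independent uniform raters give kappa near zero", {
  set.seed(123)
  a <- array(runif(2 * 4000) < 0.5, c(2, 4000, 1))
  expect_lt(abs(fleissKappa(makeSheet(a))), 0.05)
  x <- runif(4000) < 0.5; y <- runif(4000) < 0.5
  expect_lt(abs(cohenKappa(x, y)), 0.05)
})

test_that("Cohen's kappa matches closed form, oracle and e1071", {
  x <- c(TRUE, TRUE, FALSE, FALSE); y <- c(TRUE, FALSE, FALSE, TRUE)
  expect_equal(cohenKappa(x, x), 1)
  expect_lte(cohenKappa(x, !x), 0)

  # frozen 2x2 contingency (a, b, c, d) = (40, 10, 20, 30): kappa = 0.4
  xs <- rep(c(TRUE, TRUE, FALSE, FALSE), c(40, 10, 20, 30))
  ys <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 20, 30))
  expect_equal(cohenKappa(xs, ys), 0.4)
  expect_equal(cohenKappa(xs, ys), cohenOracle(xs, ys))
  expect_equal(cohenKappa(xs, ys),
               e1071::classAgreement(table(xs, ys))$kappa)

  set.seed(17)
  for (rep in 1:50) {
    n <- sample(3:60, 1)
    x <- runif(n) < runif(1, 0.2, 0.8)
    y <- ifelse(runif(n) < 0.7, x, runif(n) < 0.5)
    ko <- cohenOracle(x, y)
    kp <- suppressWarnings(cohenKappa(x, y))
    expect_equal(kp, ko, tolerance = 1e-12)
  }
})

test_that("kappa is 1 only under perfect agreement with both classes present", {
  set.seed(2)
  for (rep in 1:30) {
    sheet <- randomSheet(3, 6, 2, acc = runif(3, 0.5, 1))
    k <- suppressWarnings(fleissKappa(sheet))
    if (!is.na(k)) {
      expect_lte(k, 1)
      if (agreementSummary(sheet)@discordant > 0) expect_lt(k, 1)
    }
  }
})

test_that("discrepancy matrices equal the brute-force pairwise count", {
  # identical annotators -> all zero
  a <- array(rep(c(TRUE, FALSE), each = 2), c(2, 1, 2))
  expect_true(all(discrepancyMatrix(makeSheet(a)) == 0))

  # single disagreement increments exactly one symmetric pair
  b <- array(TRUE, c(3, 2, 2)); b[2, 1, 2] <- FALSE
  d <- discrepancyMatrix(makeSheet(b))
  expect_identical(sum(d), 4)  # two labels? no: one cell, pairs (1,2),(2,3), x2 symmetric
  expect_identical(d[2, 1, 2], 1)
  expect_identical(d[2, 2, 1], 1)
  expect_identical(d[2, 2, 3], 1)
  expect_true(all(d[1, , ] == 0))

  set.seed(77)
  sheet <- randomSheet(4, 7, 3)
  got <- discrepancyMatrix(sheet)
  a <- annotations(sheet)
  for (k in 1:3) for (i1 in 1:4) for (i2 in 1:4) {
    n <- 0
    for (j in 1:7) if (a[i1, j, k] != a[i2, j, k]) n <- n + 1
    expect_identical(got[k, i1, i2], as.numeric(n))
  }
  # diagonal zero, symmetric
  for (k in 1:3) {
    expect_true(all(diag(got[k, , ]) == 0))
    expect_identical(got[k, , ], t(got[k, , ]))
  }
})
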