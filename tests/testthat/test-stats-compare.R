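# Exact Wilcoxon signed-rank test, paired summaries, normalization, BMI
# and the cohort comparison report.

test_that("exact Wilcoxon matches hand-computable cases", {
  r <- wilcoxonSignedRank(c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 15)
  expect_equal(r$pValue, 2 / 32)
  expect_identical(r$method, "exact")

  r1 <- wilcoxonSignedRank(c(3))
  expect_equal(r1$pValue, 1)

  r7 <- wilcoxonSignedRank(rep(15, 7) + (1:7) * 1e-6)
  expect_equal(r7$pValue, 2 / 128)

  expect_error(wilcoxonSignedRank(rep(0, 5)), "zero")
})

test_that("exact p equals the full 2^n enumeration on random data", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    d <- round(rnorm(n, sd = 2), sample(0:1, 1))  # induces ties and zeros
    if (all(d == 0)) d[1] <- 1
    mine <- wilcoxonSignedRank(d)
    expect_equal(mine$pValue, oracleWilcoxonExact(d), tolerance = 1e-12)
  }
  # tie-free cases also agree with the standard exact implementation
  set.seed(12)
  for (i in 1:20) {
    d <- rnorm(8)
    mine <- wilcoxonSignedRank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(mine$pValue, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic))
  }
})

test_that("signed-rank invariants hold", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    a <- wilcoxonSignedRank(x, y)
    b <- wilcoxonSignedRank(x + 5, y + 5)        # shift invariance
    expect_equal(a$pValue, b$pValue, tolerance = 1e-12)
    s <- wilcoxonSignedRank(y, x)                # two-sided symmetry
    expect_equal(a$pValue, s$pValue, tolerance = 1e-12)
    # W+ + W- equals the total rank sum
    expect_equal(a$statistic + s$statistic,
                 a$nEffective * (a$nEffective + 1) / 2, tolerance = 1e-9)
    # rank invariance under positive rescaling (height normalization)
    h <- runif(1, 1.5, 2)
    expect_equal(wilcoxonSignedRank(x / h, y / h)$pValue, a$pValue,
                 tolerance = 1e-12)
  }
})

test_that("the exact test is conservative under the null", {
  # exact null distribution at n = 7: P(p <= alpha) <= alpha for all
  # attainable alpha
  ranks <- 1:7
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 7)))
  Ws <- drop(signs %*% ranks)
  pOf <- function(w) min(1, 2 * min(mean(Ws <= w), mean(Ws >= w)))
  pAll <- vapply(Ws, pOf, numeric(1))
  for (alpha in sort(unique(pAll)))
    expect_lte(mean(pAll <= alpha), alpha)

  # simulated null at n = 7
  set.seed(41)
  hits <- replicate(1000, wilcoxonSignedRank(rnorm(7))$pValue <= 0.05)
  expect_gte(mean(hits), 0.01)
  expect_lte(mean(hits), 0.07)
})

test_that("paired absolute summaries and median ranges are exact", {
  s <- pairedAbsSummary(c(1, 2, 5), c(3, 2, 1))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 2)
  s0 <- pairedAbsSummary(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s0$mean, 0); expect_equal(s0$sd, 0)
  s1 <- pairedAbsSummary(1, 3)
  expect_true(is.na(s1$sd)); expect_false(s1$sdDefined)
  set.seed(6)
  x <- rnorm(40); y <- rnorm(40)
  s2 <- pairedAbsSummary(x, y)
  a <- abs(x - y)
  expect_equal(s2$sd, sqrt(sum((a - mean(a))^2) / 39), tolerance = 1e-12)

  expect_equal(medianRange(c(3, 1, 2)),
               list(median = 2, min = 1, max = 3))
  expect_equal(medianRange(c(1, 2, 3, 4))$median, 2.5)
  expect_error(medianRange(numeric(0)), "empty")
  set.seed(9)
  v <- rnorm(25)
  vs <- sort(v)
  expect_equal(medianRange(v)$median, vs[13])
})

test_that("height normalization and BMI follow the table conventions", {
  expect_equal(normalizeByHeight(34.1, 169), 34.1 / 1690, tolerance = 1e-12)
  expect_equal(normalizeByHeight(0, 175), 0)
  expect_error(normalizeByHeight(10, 0), "positive")

  expect_equal(bmi(85, 169), 29.8)
  expect_equal(bmi(61, 181), 18.6)
  expect_equal(bmi(50, 153), 21.4)
  expect_error(bmi(-1, 170), "positive")
})

test_that("compareMethods flags the systematic differences", {
  subj <- sprintf("S%d", 1:7)
  base <- runif(7, 10, 20)
  mk <- function(par, method, val) data.frame(
    subject = subj, muscle = "GA", parameter = par, method = method,
    value = val, height_cm = seq(155, 185, by = 5),
    stringsAsFactors = FALSE)
  set.seed(2)
  tab <- rbind(mk("PA", "US", base), mk("PA", "DTI", base + 15),
               mk("FL", "US", base * 2), mk("FL", "DTI", base * 2))
  rep <- compareMethods(tab)
  pa <- rep[rep$parameter == "PA" & rep$scale == "raw", ]
  expect_equal(pa$p, 2 / 128, tolerance = 1e-12)
  expect_true(pa$significant)
  expect_equal(pa$absMean, 15, tolerance = 1e-12)
  fl <- rep[rep$parameter == "FL" & rep$scale == "raw", ]
  expect_false(fl$significant)
  expect_equal(fl$absMean, 0)
  # FL (a length) is additionally analyzed height-normalized
  expect_true(any(rep$parameter == "FL" & rep$scale == "height_normalized"))
  expect_false(any(rep$parameter == "PA" & rep$scale == "height_normalized"))
})

test_that("a no-effect cohort keeps its type-I error near the exact level", {
  set.seed(3)
  hits <- 0; nRep <- 400
  for (i in seq_len(nRep)) {
    x <- rnorm(7, 30, 5)
    y <- x + rnorm(7, 0, 2)   # zero method effect
    if (wilcoxonSignedRank(x, y)$pValue <= 0.05) hits <- hits + 1
  }
  rate <- hits / nRep
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.07)
})
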