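# Discretization, mutual information, mRMR, ICC, chi-squared.

test_that("mean +/- sd discretization follows the inclusive boundary rule", {
  # mean 5, sd ~5.77: no value reaches the +/- 1 sd thresholds
  expect_equal(as.integer(discretize(c(0, 0, 10, 10))), rep(0L, 4))
  # mean 0, sd 10: boundaries are inclusive, so -10 and 10 are low/high
  expect_equal(as.integer(discretize(c(-10, 0, 10))), c(-1L, 0L, 1L))
  cst <- discretize(rep(3, 5))
  expect_true(all(cst == 0L))
  expect_true(isTRUE(attr(cst, "constant")))
})

test_that("mutual information matches the entropy-identity oracle", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0.0)
  x3 <- c(0, 0, 1, 1, 2, 2)
  expect_equal(mutual_information(x3, x3), log2(3), tolerance = 1e-12)

  set.seed(12)
  for (i in 1:15) {
    x <- sample(0:2, 30, replace = TRUE)
    y <- sample(0:3, 30, replace = TRUE)
    expect_equal(mutual_information(x, y), mi_entropy_oracle(x, y), tolerance = 1e-12)
    expect_equal(mutual_information(x, y), mutual_information(y, x), tolerance = 1e-12)
    expect_equal(mutual_information(x, x), mi_entropy_oracle(x, x), tolerance = 1e-12)
    expect_gte(mutual_information(x, y), 0)
  }
  expect_error(mutual_information(1:4, 1:5), "length")
})

test_that("greedy mRMR matches brute-force evaluation on a planted cohort", {
  set.seed(3)
  n <- 40
  label <- rep(c("a", "g"), each = n / 2)
  X <- rnorm(n) + 2 * (label == "a")                 # strongly informative
  Y <- rnorm(n) + 1 * (label == "a") + 0.5 * rnorm(n) # weaker, independent of X
  tab <- data.frame(case_id = seq_len(n), label = label,
                    X = X, Xcopy = X, Y = Y)
  res <- mrmr_select(tab, 3)
  expect_equal(res$selected[1], "X")      # ties to canonical order: X before Xcopy
  expect_equal(res$selected[2], "Y")      # the copy is fully redundant
  expect_equal(res$selected[3], "Xcopy")

  # brute-force greedy with the independent MI oracle reproduces each step
  disc <- lapply(tab[c("X", "Xcopy", "Y")], discretize)  # all continuous here
  rel <- vapply(disc, function(d) mi_entropy_oracle(d, label), numeric(1))
  pick1 <- names(which.max(rel))
  expect_equal(res$selected[1], pick1)
  rest <- setdiff(names(disc), pick1)
  score2 <- vapply(rest, function(f) {
    rel[[f]] - mi_entropy_oracle(disc[[f]], disc[[pick1]])
  }, numeric(1))
  expect_equal(res$selected[2], names(which.max(score2)))
  expect_equal(res$relevance[1], max(rel), tolerance = 1e-12)

  # a feature equal to the label ranks first
  tab$perfect <- as.integer(label == "a") * 20
  expect_equal(mrmr_select(tab, 1)$selected, "perfect")

  # all-constant features: zero scores, canonical order, flagged
  cst <- data.frame(case_id = 1:6, label = rep(c("a", "g"), 3),
                    f1 = 1, f2 = 2, f3 = 3)
  rc <- mrmr_select(cst, 2)
  expect_equal(rc$selected, c("f1", "f2"))
  expect_equal(rc$score, c(0, 0))
  expect_setequal(rc$constant_features, c("f1", "f2", "f3"))

  expect_error(mrmr_select(cst, 5), "exceeds")
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  # identical test/retest, non-constant
  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc(cbind(a = x), cbind(a = x))$icc, 1.0)

  # hand 5-case table: agreement with the aov-based oracle to 1e-10
  t1 <- c(10.1, 11.3, 9.8, 12.0, 10.7)
  t2 <- c(10.3, 11.0, 10.0, 12.4, 10.5)
  expect_equal(icc(cbind(f = t1), cbind(f = t2))$icc,
               icc_aov_oracle(t1, t2), tolerance = 1e-10)

  # absolute agreement penalizes a constant offset below the correlation
  off <- icc(cbind(f = t1), cbind(f = t1 + 5))$icc
  expect_lt(off, cor(t1, t1 + 5))

  # independent noise: |ICC| < 0.3 at n = 50
  set.seed(20)
  a <- matrix(rnorm(50), ncol = 1); b <- matrix(rnorm(50), ncol = 1)
  colnames(a) <- colnames(b) <- "f"
  expect_lt(abs(icc(a, b)$icc), 0.3)

  # symmetry under swapping test and retest
  expect_equal(icc(cbind(f = t1), cbind(f = t2))$icc,
               icc(cbind(f = t2), cbind(f = t1))$icc, tolerance = 1e-12)

  # constant everywhere: reported as 0 with a flag
  z <- icc(cbind(f = rep(1, 4)), cbind(f = rep(1, 4)))
  expect_equal(z$icc, 0)
  expect_true(z$flagged)

  # stability classes at the thresholds
  rep3 <- icc(cbind(f = t1), cbind(f = t2))
  expect_true(rep3$stability %in% c("high", "moderate", "unstable"))
  expect_error(icc(cbind(f = 1:2), cbind(f = 1:2)), "3 cases")
  expect_error(icc(cbind(f = 1:5), cbind(f = 1:4)), "shape")
})

test_that("chi-squared association matches direct computation", {
  a <- rep(c("p", "q"), each = 10)
  r1 <- chi2_association(a, a)
  expect_equal(r1$statistic, 20.0)
  expect_equal(r1$df, 1)

  b <- rep(c("p", "q"), 10)
  r2 <- chi2_association(a, b)
  expect_equal(r2$statistic, 0.0)
  expect_equal(r2$p_value, 1.0)

  # 2x3 with equal rows: perfect independence
  x <- rep(c("u", "v"), each = 6)
  y <- rep(c("a", "b", "c"), 4)
  r3 <- chi2_association(x, y)
  expect_equal(r3$statistic, 0.0)
  expect_equal(r3$df, 2)

  # invariant to category permutation
  perm <- chi2_association(rev(a), rev(a))
  expect_equal(perm$statistic, r1$statistic)

  # cross-check against the classic Pearson test (no continuity correction)
  set.seed(5)
  u <- sample(c("p", "q"), 40, replace = TRUE)
  v <- sample(c("x", "y", "z"), 40, replace = TRUE)
  ref <- suppressWarnings(chisq.test(table(u, v), correct = FALSE))
  got <- chi2_association(u, v)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  expect_error(chi2_association(rep("p", 20), a), "2 categories")
  expect_error(chi2_association(a, b[1:10]), "length")
})
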