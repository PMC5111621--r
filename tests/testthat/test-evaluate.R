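test_that("the worked confusion example reproduces the published row", {
  # 24 disease / 23 control subjects, 20 and 15 correctly classified
  labels <- c(rep(1, 24), rep(-1, 23))
  preds <- c(rep(1, 20), rep(-1, 4), rep(-1, 15), rep(1, 8))
  m <- computeMetrics(labels, preds)
  expect_equal(m@tp, 20L); expect_equal(m@tn, 15L)
  expect_equal(m@fp, 8L); expect_equal(m@fn, 4L)
  p1 <- function(x) floor(x * 1000 + 0.5) / 10
  expect_equal(p1(m@sensitivity), 83.3)
  expect_equal(p1(m@specificity), 65.2)
  expect_equal(p1(m@balancedAccuracy), 74.3)
  expect_equal(p1(m@ppv), 71.4)
  expect_equal(p1(m@npv), 78.9)
})

test_that("metric identities hold for random confusion patterns", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    labels <- sample(c(1, -1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    preds <- sample(c(1, -1), n, replace = TRUE)
    m <- computeMetrics(labels, preds)
    expect_equal(m@tp + m@fn, sum(labels == 1))
    expect_equal(m@tn + m@fp, sum(labels == -1))
    expect_equal(m@balancedAccuracy, (m@sensitivity + m@specificity) / 2)
    expect_equal(m@sensitivity, m@tp / (m@tp + m@fn))
    expect_equal(m@specificity, m@tn / (m@tn + m@fp))
    if (!is.na(m@ppv)) expect_equal(m@ppv, m@tp / (m@tp + m@fp))
    if (!is.na(m@npv)) expect_equal(m@npv, m@tn / (m@tn + m@fn))
  }
  # undefined PPV is NA, not zero
  m0 <- computeMetrics(c(1, -1, -1), c(-1, -1, -1))
  expect_true(is.na(m0@ppv))
  expect_equal(m0@npv, 2 / 3)
  # perfect prediction
  mp <- computeMetrics(c(1, 1, -1), c(1, 1, -1), c(2, 3, -1))
  expect_equal(mp@balancedAccuracy, 1); expect_equal(mp@rocAuc, 1)
  expect_error(computeMetrics(c(1, 1), c(1, 1)), "both classes")
})

test_that("the AUC equals the Mann-Whitney pair statistic", {
  expect_equal(rocAuc(c(1, 1, -1, -1), c(2, 3, 0, 1)), 1)
  expect_equal(rocAuc(c(1, 1, -1, -1), c(1, 3, 2, 4)), 0.25)
  expect_equal(rocAuc(c(1, -1, 1, -1), rep(0.7, 4)), 0.5)
  # brute-force pair oracle with midrank ties, n <= 12
  set.seed(52)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    y <- c(1, -1, sample(c(1, -1), n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # force ties
    pos <- sc[y == 1]; neg <- sc[y == -1]
    wins <- 0
    for (a in pos) for (b in neg)
      wins <- wins + (a > b) + 0.5 * (a == b)
    expect_equal(rocAuc(y, sc), wins / (length(pos) * length(neg)))
    expect_equal(rocAuc(-y, sc), 1 - rocAuc(y, sc))
  }
})

test_that("the AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  y <- sample(c(1, -1), 30, replace = TRUE)
  y[1:2] <- c(1, -1)
  sc <- rnorm(30)
  expect_equal(rocAuc(y, sc),
               as.numeric(pROC::auc(pROC::roc(y, sc, levels = c(-1, 1),
                                              direction = "<", quiet = TRUE))))
})

test_that("permutation p-values follow the counting definition", {
  # constant-prediction classifier on balanced labels: all null BAs 0.5
  constRunner <- function(labels) {
    p <- rep(-1, length(labels))
    (mean(p[labels == 1] == 1) + mean(p[labels == -1] == -1)) / 2
  }
  y <- rep(c(1, -1), 6)
  pt <- permutationTest(constRunner, y, nPerm = 50, seed = 1)
  expect_true(all(pt@nullBas == 0.5))
  expect_equal(pt@observed, 0.5)
  expect_equal(pt@pValue, 1)
  # observed above every null value gives p = 0 unsmoothed, (0+1)/(m+1) smoothed
  oneRunner <- local({
    first <- TRUE
    function(labels) {
      if (first) { first <<- FALSE; return(1) }
      0.5
    }
  })
  pt0 <- permutationTest(oneRunner, y, nPerm = 19, seed = 2)
  expect_equal(pt0@pValue, 0)
  oneRunner2 <- local({
    first <- TRUE
    function(labels) {
      if (first) { first <<- FALSE; return(1) }
      0.5
    }
  })
  pts <- permutationTest(oneRunner2, y, nPerm = 19, seed = 2,
                         smoothed = TRUE)
  expect_equal(pts@pValue, 1 / 20)
})

test_that("permutations preserve class counts and are seed-reproducible", {
  seen <- list()
  countRunner <- function(labels) {
    seen[[length(seen) + 1]] <<- labels
    mean(labels == 1)
  }
  y <- stats::setNames(c(rep(1, 4), rep(-1, 6)), letters[1:10])
  pt1 <- permutationTest(countRunner, y, nPerm = 20, seed = 9)
  for (lab in seen[-1])
    expect_equal(sum(lab == 1), 4)
  pt2 <- permutationTest(countRunner, y, nPerm = 20, seed = 9)
  expect_identical(pt1@nullBas, pt2@nullBas)
  expect_identical(pt1@pValue, pt2@pValue)
})

test_that("the permutation null is centred near chance on real folds", {
  # study-scale null cohort: leave-one-out null accuracies sit close to
  # 0.5 (small-sample LOO pessimism shrinks with cohort size)
  sim <- simulateCohort(delta = 0, seed = 55)
  r <- fixedPvarRunner(sim$cohort, 0.5)
  pt <- permutationTest(r, classLabels(sim$cohort), nPerm = 150, seed = 7)
  expect_gt(mean(pt@nullBas), 0.42)
  expect_lt(mean(pt@nullBas), 0.58)
  expect_gt(pt@pValue, 0.01)
})
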