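test_that("design matrices hold raw powers of relative time", {
  expect_equal(buildDesignMatrix(c(0, 2.5), 1),
               matrix(c(1, 1, 0, 2.5), 2, 2))
  expect_equal(buildDesignMatrix(0, 0), matrix(1, 1, 1))
  t3 <- c(0, 1, 2)
  expect_equal(buildDesignMatrix(t3, 2), unname(cbind(1, t3, t3^2)))
  expect_error(buildDesignMatrix(c(0, 0, 1), 1), "strictly increasing")
})

test_that("trajectory fits match closed-form least squares", {
  # two-point line: intercept = v0, slope = (v1 - v0) / tDelta
  v0 <- c(1, -2, 0.5); v1 <- c(3, 0, 0.5)
  B <- fitTrajectory(c(0, 2.5), rbind(v0, v1), order = 1)
  expect_equal(B[1, ], v0)
  expect_equal(B[2, ], (v1 - v0) / 2.5)
  # exact recovery from noiseless samples on a known line
  tt <- c(0, 1, 2.5, 3, 4.5)
  a <- c(2, -1); b <- c(0.3, 1.2)
  X <- outer(tt, b) + rep(1, 5) %o% a
  B2 <- fitTrajectory(tt, X, order = 1)
  expect_equal(B2[1, ], a, tolerance = 1e-12)
  expect_equal(B2[2, ], b, tolerance = 1e-12)
  # simple-linear-regression oracle: y = (0,1,1) at t = (0,1,2)
  B3 <- fitTrajectory(c(0, 1, 2), cbind(c(0, 1, 1)), order = 1)
  expect_equal(B3[2, 1], 0.5)
  expect_equal(B3[1, 1], 1 / 6)
  expect_error(fitTrajectory(c(0, 1), cbind(c(1, 2)), order = 2),
               "insufficient time-points")
})

test_that("fits agree with the normal-equations solution on random cases", {
  set.seed(7)
  for (rep in 1:10) {
    m <- sample(3:6, 1); D <- sample(2:10, 1); P <- sample(1:2, 1)
    if (m < P + 1) next
    tt <- sort(runif(m, 0, 5))
    X <- matrix(rnorm(m * D), m, D)
    B <- fitTrajectory(tt, X, order = P)
    Z <- buildDesignMatrix(tt, P)
    Bo <- solve(crossprod(Z), crossprod(Z, X))
    expect_equal(B, unname(Bo), tolerance = 1e-8)
    # residuals orthogonal to the design columns
    expect_lt(max(abs(crossprod(Z, X - Z %*% B))), 1e-8)
  }
})

test_that("a time-origin shift changes only the intercept row", {
  tt <- c(0, 1.5, 3)
  X <- matrix(rnorm(9, sd = 2), 3, 3)
  B0 <- fitTrajectory(tt, X, order = 1)
  B5 <- fitTrajectory(tt + 5, X, order = 1)
  expect_equal(B0[2, ], B5[2, ], tolerance = 1e-10)
  expect_false(isTRUE(all.equal(B0[1, ], B5[1, ])))
})

test_that("the coefficient matrix stacks per-subject slopes with exclusions", {
  toy <- toyCohort(l = 5, D = 6, tDelta = 2)
  sm <- assembleCoefficientMatrix(toy$cohort, order = 1, extract = 1)
  expect_s4_class(sm, "SlopeMatrix")
  expect_equal(slopeValues(sm), toy$slopes, tolerance = 1e-10,
               ignore_attr = TRUE)
  # identical slopes give identical rows
  D <- 4
  s <- c(1, -0.5, 0, 2)
  feats <- matrix(0, D, 6)
  for (i in 1:3) {
    b <- rnorm(D)
    feats[, 2 * i - 1] <- b
    feats[, 2 * i] <- b + s * 3
  }
  coh <- longitudinalCohort(feats, subject = rep(letters[1:3], each = 2),
                            label = rep(c(1, -1, 1), each = 2),
                            time = rep(c(0, 3), 3))
  smEq <- assembleCoefficientMatrix(coh)
  expect_equal(slopeValues(smEq), matrix(rep(s, each = 3), 3, D),
               tolerance = 1e-12)
  # single-scan subjects are excluded with a warning
  feats1 <- cbind(feats, rnorm(D))
  coh1 <- longitudinalCohort(feats1,
                             subject = c(rep(letters[1:3], each = 2), "d"),
                             label = c(rep(c(1, -1, 1), each = 2), -1),
                             time = c(rep(c(0, 3), 3), 0))
  expect_warning(sm1 <- assembleCoefficientMatrix(coh1), "excluding")
  expect_setequal(slopeSubjects(sm1), letters[1:3])
  expect_error(suppressWarnings(
    assembleCoefficientMatrix(subsetSubjects(coh1, c("a", "d")))),
    "fewer than 2")
})

test_that("the interval-scaled difference matrix follows the scaling law", {
  expect_equal(slopeValues(lmDifferenceMatrix(
    matrix(c(1, 2), 1), matrix(c(3, 6), 1), 2)), matrix(c(1, 2), 1))
  B <- matrix(rnorm(8), 2, 4)
  z <- lmDifferenceMatrix(B, B, 1.5)
  expect_true(all(slopeValues(z) == 0))
  # same raw difference, intervals (1, 2): row 2 is half of row 1
  base <- matrix(0, 2, 3)
  fol <- matrix(rep(c(2, 4, 6), each = 2), 2, 3)
  sm <- lmDifferenceMatrix(base, fol, c(1, 2))
  expect_equal(slopeValues(sm)[2, ], slopeValues(sm)[1, ] / 2)
  expect_identical(sm@scaling, "lm-unbalanced")
  expect_error(lmDifferenceMatrix(base, fol, c(1, 0)), "positive")
})

test_that("two-time-point least squares equals the difference matrix", {
  # the balanced two-scan identity, checked per subject on a toy cohort
  toy <- toyCohort(l = 8, D = 12, tDelta = 2.5, noise = 0.3, seed = 3)
  ltc <- assembleCoefficientMatrix(toy$cohort)
  lm_ <- slopeMatrix(toy$cohort, source = "lm-balanced")
  expect_equal(slopeValues(ltc), slopeValues(lm_), tolerance = 1e-10)
})
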