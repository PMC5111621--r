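test_that("separable toy geometry gives the expected support vectors", {
  X <- rbind(c(1, 0), c(-1, 0))
  clf <- trainSVC(linearKernel(X), labels = c(1, -1))
  expect_true(all(clf@alphaSigned != 0))       # both points are SVs
  expect_gt(predict(clf, linearKernel(matrix(c(0.9, 0), 1), X)), 0)
  expect_lt(predict(clf, linearKernel(matrix(c(-5, 1), 1), X)), 0)
  expect_error(trainSVC(linearKernel(X), labels = c(1, 1)), "both classes")
})

test_that("the SMO solution matches LIBSVM on random problems", {
  skip_if_not_installed("e1071")
  set.seed(31)
  worstE <- 0
  for (rep in 1:10) {
    n <- sample(8:24, 1); d <- sample(2:6, 1)
    y <- rep(c(1, -1), length.out = n)
    X <- matrix(rnorm(n * d), n, d) + outer(y, rep(0.5, d))
    clf <- fitLinearSVC(X, y, cost = 1)
    dec <- predict(clf, X)
    m <- e1071::svm(X, factor(y, levels = c(1, -1)), kernel = "linear",
                    cost = 1, scale = FALSE, tolerance = 1e-8)
    dv <- attr(predict(m, X, decision.values = TRUE), "decision.values")
    s <- if (colnames(dv)[1] == "1/-1") 1 else -1
    worstE <- max(worstE, max(abs(dec - s * as.numeric(dv))))
  }
  expect_lt(worstE, 1e-3)
})

test_that("SMO class predictions agree with kernlab on its kernel interface", {
  skip_if_not_installed("kernlab")
  set.seed(36)
  for (rep in 1:5) {
    n <- 2 * sample(5:12, 1)
    d <- sample(2:6, 1)
    y <- rep(c(1, -1), n / 2)
    X <- matrix(rnorm(n * d), n, d) + outer(y, rep(0.8, d))
    clf <- trainSVC(linearKernel(X), y)
    dec <- predict(clf, linearKernel(X))
    km <- kernlab::ksvm(kernlab::as.kernelMatrix(linearKernel(X)),
                        factor(y, levels = c(1, -1)), C = 1)
    dk <- as.numeric(kernlab::predict(km, kernlab::as.kernelMatrix(
      linearKernel(X)[, kernlab::SVindex(km), drop = FALSE]),
      type = "decision"))
    s2 <- sign(sum(dk * dec))
    expect_gte(mean(sign(dec) == sign(s2 * dk)), 0.9)
  }
})

test_that("duplicating every training point leaves decisions unchanged", {
  set.seed(32)
  X <- matrix(rnorm(10 * 3), 10, 3)
  y <- rep(c(1, -1), 5)
  Xt <- matrix(rnorm(6), 2, 3)
  c1 <- fitLinearSVC(X, y, cost = 1)
  # duplicated problem at halved cost has the same optimal hyperplane
  c2 <- fitLinearSVC(rbind(X, X), c(y, y), cost = 0.5)
  expect_equal(predict(c1, Xt), predict(c2, Xt), tolerance = 1e-4)
})

test_that("label flips negate decision values and dual coefficients", {
  set.seed(33)
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- rep(c(1, -1), 6)
  Xt <- matrix(rnorm(8), 2, 4)
  cp <- fitLinearSVC(X, y)
  cm <- fitLinearSVC(X, -y)
  expect_equal(predict(cp, Xt), -predict(cm, Xt), tolerance = 1e-6)
  expect_true(all(cp@alphaSigned * y >= 0))
  expect_true(all(abs(cp@alphaSigned) <= cp@cost + 1e-6))
})

test_that("exact zero decisions are classed as control", {
  clf <- new("TrainedSVC", alphaSigned = numeric(2), bias = 0, cost = 1,
             trainFeatures = matrix(0, 2, 3), labels = c(1, -1),
             space = "ambient")
  expect_equal(unname(predict(clf, matrix(1, 1, 3), type = "class")), -1)
})

test_that("transfer-mode folds share one basis; within-set folds do not", {
  simL <- simulateCohort(nPos = 5, nNeg = 5, D = 40, m = 2, seed = 41)
  simC <- simulateCohort(nPos = 4, nNeg = 4, D = 40, m = 1, seed = 42)
  # rename classification subjects to keep the sets disjoint
  cohC <- simC$cohort
  SummarizedExperiment::colData(cohC)$subject <-
    paste0("c_", SummarizedExperiment::colData(cohC)$subject)
  cfg <- cvConfig(pvarGrid = 0.6, timepoint = "baseline")
  ids <- subjectIds(cohC)
  f1 <- runFold(cohC, ids[1], 0.6, cfg, longitudinal = simL$cohort)
  f2 <- runFold(cohC, ids[2], 0.6, cfg, longitudinal = simL$cohort)
  expect_identical(basisMatrix(f1$basis), basisMatrix(f2$basis))
  # within-set: excluding the test subject's slope row changes the basis
  cohW <- simL$cohort
  cfgW <- cvConfig(pvarGrid = 0.6)
  w1 <- runFold(cohW, subjectIds(cohW)[1], 0.6, cfgW)
  w2 <- runFold(cohW, subjectIds(cohW)[2], 0.6, cfgW)
  expect_gt(max(abs(basisMatrix(w1$basis) - basisMatrix(w2$basis))), 1e-6)
  # overlap between longitudinal and classification sets is refused
  expect_error(runFold(simL$cohort, subjectIds(simL$cohort)[1], 0.6, cfg,
                       longitudinal = simL$cohort), "disjoint")
})

test_that("held-out follow-up data cannot leak into within-set predictions", {
  sim <- simulateCohort(nPos = 5, nNeg = 5, D = 30, seed = 43)
  coh <- sim$cohort
  cfg <- cvConfig(pvarGrid = 0.6)
  tid <- subjectIds(coh)[1]
  f0 <- runFold(coh, tid, 0.6, cfg)
  # corrupt the held-out subject's follow-up used only through projection:
  # the basis must be identical since the slope row is excluded by design
  coh2 <- coh
  asy <- SummarizedExperiment::assay(coh2, "features")
  asy[, 2] <- asy[, 2] + 100  # subject 1's follow-up scan column
  SummarizedExperiment::assay(coh2, "features") <- asy
  f1 <- runFold(coh2, tid, 0.6, cfg)
  expect_identical(basisMatrix(f0$basis), basisMatrix(f1$basis))
})

test_that("a one-point grid reduces nested CV to plain LOO (reference path)", {
  sim <- simulateCohort(nPos = 6, nNeg = 6, D = 50, seed = 44)
  coh <- sim$cohort
  cfg <- cvConfig(pvarGrid = 0.5)
  cv <- nestedLooCv(coh, cfg)
  ids <- subjectIds(coh)
  for (t in c(1, 5, 12)) {
    f <- runFold(coh, ids[t], 0.5, cfg)
    expect_equal(unname(f$decision), cvPredictions(cv)$decision[t],
                 tolerance = 1e-5)
  }
  # the precomputed fixed-pvar runner agrees with the nested driver
  r <- fixedPvarRunner(coh, 0.5, cfg)
  expect_equal(r(classLabels(coh)), cvMetrics(cv)@balancedAccuracy)
})

test_that("nested CV is deterministic and finds easy slope-subspace signal", {
  sim <- simulateCohort(nPos = 8, nNeg = 8, D = 60, r = 1, delta = 1.5,
                        sigmaSlope = 0.1, sigmaNoise = 0.02,
                        seed = 45)
  cfg <- cvConfig(pvarGrid = seq(0.1, 0.9, 0.2))
  cv1 <- nestedLooCv(sim$cohort, cfg)
  cv2 <- nestedLooCv(sim$cohort, cfg)
  expect_identical(cvPredictions(cv1), cvPredictions(cv2))
  # signal concentrated in the top eigenslope: high accuracy, small pvar
  expect_gt(cvMetrics(cv1)@balancedAccuracy, 0.9)
  expect_lte(stats::median(cvPredictions(cv1)$pvar), 0.5)
})

test_that("cv configuration is validated", {
  expect_error(cvConfig(pvarGrid = c(0.5, 0.3)), "increasing")
  expect_error(cvConfig(pvarGrid = c(0, 0.5)), "\\(0, 1\\]")
  expect_error(nestedLooCv(simulateCohort(nPos = 1, nNeg = 1, D = 5,
                                          seed = 1)$cohort),
               "at least 3")
})
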