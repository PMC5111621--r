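test_that("subject tables parse, group and sort scans per subject", {
  f <- writeTable(data.frame(
    subject_id = c("a", "b", "a"), label = c(1, -1, 1),
    time = c(63.5, 70.0, 61.0), source = c(2, 3, 1)))
  tab <- readSubjectTable(f)
  expect_equal(tab$subject_id, c("a", "a", "b"))
  # times are relative to each subject's first scan
  expect_equal(tab$time, c(0, 2.5, 0))
  expect_equal(tab$source[1:2], c(1, 2))
  m <- table(tab$subject_id)
  expect_equal(as.integer(m[c("a", "b")]), c(2L, 1L))
})

test_that("subject table parsing is independent of row order", {
  df <- data.frame(subject_id = rep(c("a", "b", "c"), each = 2),
                   label = rep(c(1, -1, 1), each = 2),
                   time = c(0, 2, 1, 3, 0.5, 2.5),
                   source = 1:6)
  t1 <- readSubjectTable(writeTable(df))
  t2 <- readSubjectTable(writeTable(df[sample(6), ]))
  # same grouping and ordering modulo subject first-appearance order
  t2 <- t2[order(t2$subject_id, t2$time), ]
  t1 <- t1[order(t1$subject_id, t1$time), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2)
})

test_that("subject table validation names the offending column or value", {
  bad <- writeTable(data.frame(subject_id = "a", label = 0, time = 0,
                               source = 1))
  expect_error(readSubjectTable(bad), "label must be \\+1 or -1")
  missing <- writeTable(data.frame(subject_id = "a", label = 1, source = 1))
  expect_error(readSubjectTable(missing), "time")
  dup <- writeTable(data.frame(subject_id = c("a", "a"), label = c(1, 1),
                               time = c(1, 1), source = 1:2))
  expect_error(readSubjectTable(dup), "duplicate")
})

test_that("matrix and NIfTI loading routes produce identical cohorts", {
  mask <- toyMask()
  D <- mask@D
  set.seed(42)
  n <- 4
  X <- matrix(rnorm(n * D), n, D)
  df <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                   label = rep(c(1, -1), each = 2),
                   time = c(0, 2, 0, 2), source = 1:4)
  cohM <- buildCohort(df, X)

  dir <- tempfile(); dir.create(dir)
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, sprintf("scan%d.nii.gz", i))
    img <- RNifti::asNifti(unmask(mask, X[i, ]))
    RNifti::writeNifti(img, paths[i], datatype = "double")
  }
  dfN <- df; dfN$source <- paths
  cohN <- loadCohortNifti(writeTable(dfN), mask)
  expect_equal(featureMatrix(cohN), featureMatrix(cohM),
               ignore_attr = TRUE)
  expect_equal(classLabels(cohN), classLabels(cohM))
})

test_that("mask vectorization is a bijection on masked voxels", {
  mask <- toyMask()
  img <- array(1, dim(mask@volume))
  expect_equal(applyMask(img, mask), rep(1, mask@D))
  set.seed(1)
  v <- rnorm(mask@D)
  expect_identical(applyMask(unmask(mask, v), mask), v)
  # composition is idempotent
  vol <- unmask(mask, v)
  expect_identical(unmask(mask, applyMask(vol, mask)), vol)
  expect_error(applyMask(array(0, c(2, 2, 2)), mask), "dimensions")
  expect_error(brainMask(array(0, c(2, 2, 2))), "empty mask")
})

test_that("metrics JSON round-trips at full precision with 1-decimal display", {
  labels <- c(rep(1, 24), rep(-1, 23))
  preds <- c(rep(1, 20), rep(-1, 4), rep(-1, 15), rep(1, 8))
  set.seed(5)
  rep_ <- computeMetrics(labels, preds, rnorm(47))
  f <- tempfile(fileext = ".json")
  writeMetrics(rep_, f)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  # balanced accuracy 0.742753... renders as 74.3 (half-up, 1 decimal)
  expect_equal(x$display$balanced_accuracy_pct, 74.3)
  back <- readMetrics(f)
  for (s in c("tp", "fp", "tn", "fn", "sensitivity", "specificity",
              "balancedAccuracy", "ppv", "npv", "rocAuc"))
    expect_equal(slot(back, s), slot(rep_, s))
  empty <- new("MetricsReport", tp = 0L, fp = 0L, tn = 0L, fn = 0L,
               sensitivity = NA_real_, specificity = NA_real_,
               balancedAccuracy = NA_real_, ppv = NA_real_, npv = NA_real_,
               rocAuc = NA_real_, nPos = 0L, nNeg = 0L)
  expect_error(writeMetrics(empty, tempfile()), "empty report")
})

test_that("cohort validity enforces the longitudinal invariants", {
  X <- matrix(0, 3, 4)
  expect_error(longitudinalCohort(X, subject = rep("a", 4),
                                  label = c(1, 1, 1, 0),
                                  time = 0:3), "label")
  expect_error(longitudinalCohort(X, subject = rep("a", 4),
                                  label = rep(1, 4),
                                  time = c(0, 1, 1, 2)), "duplicate")
  coh <- longitudinalCohort(X, subject = c("a", "a", "b", "b"),
                            label = c(1, 1, -1, -1), time = c(3, 1, 0, 5))
  expect_equal(unname(nScans(coh)), c(2L, 2L))
  expect_equal(scanTimes(coh)$a, c(0, 2))
})
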