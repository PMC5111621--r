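# Linear soft-margin SVC (LIBSVM via e1071) and the within-set /
# information-transferring nested LOO-CV orchestration.

# Solve the soft-margin dual on a kernel via the compiled SMO; returns
# signed SV coefficients and bias with positive decisions meaning +1.
.svcSolveKernel <- function(K, y, cost) {
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training labels")
  s <- .Call_smo_solve(K, as.numeric(y), cost)
  # snap coefficients within solver tolerance of the box bounds
  a <- s$alphaSigned
  a[abs(a) < 1e-10] <- 0
  a[a > cost - 1e-10 & a < cost + 1e-10] <- cost
  a[a < -cost + 1e-10 & a > -cost - 1e-10] <- -cost
  list(alphaSigned = a, bias = s$bias)
}

# Same, from explicit feature vectors.
.svcSolve <- function(X, y, cost) {
  .svcSolveKernel(tcrossprod(X), y, cost)
}

#' Fit a linear SVC on explicit feature vectors
#'
#' Trains the C-cost soft-margin linear support-vector classifier (SMO on
#' the linear kernel) on a feature matrix.  Features should already be
#' centred with the
#' training means (see [centerFeatures()]); the centred matrix is stored so
#' that the primal weight map [weightMap()] and kernel-form decision values
#' can be reproduced exactly.
#'
#' @param X n x d numeric feature matrix (centred training features).
#' @param labels +/-1 vector of length n.
#' @param cost the C cost parameter (default 1).
#' @param space feature-space tag stored on the classifier
#'   (\code{"ambient"} or \code{"compact"}); taken from \code{attr(X,
#'   "space")} when present.
#' @return a \linkS4class{TrainedSVC}.
#' @export
fitLinearSVC <- function(X, labels, cost = 1, space = NULL) {
  X <- as.matrix(X)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +/-1")
  if (is.null(space)) space <- attr(X, "space")
  if (is.null(space)) space <- "ambient"
  s <- .svcSolve(X, labels, cost)
  Xs <- X; attributes(Xs) <- attributes(X)[c("dim", "dimnames")]
  new("TrainedSVC", alphaSigned = s$alphaSigned, bias = s$bias, cost = cost,
      trainFeatures = Xs, labels = labels, space = space)
}

#' Train a linear SVC from a precomputed kernel
#'
#' Solves the standard C-cost soft-margin dual on a symmetric PSD kernel
#' matrix with the package's SMO solver (maximal-violating-pair working-set
#' selection, the optimization LIBSVM performs).  Decision values for new
#' samples are obtained from the cross-kernel against the training samples:
#' \code{predict(clf, K_cross)}.  For kernel-trained classifiers the
#' \code{trainFeatures} slot holds the training kernel itself.
#'
#' @param K symmetric PSD n x n training kernel.
#' @param labels +/-1 vector of length n.
#' @param cost the C cost parameter (default 1).
#' @return a \linkS4class{TrainedSVC} with \code{space = "kernel"}.
#' @export
trainSVC <- function(K, labels, cost = 1) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("training kernel must be square")
  if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
    stop("training kernel must be symmetric")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +/-1")
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(max(ev, 0), 1))
    stop("training kernel is not positive semi-definite")
  s <- .svcSolveKernel(K, labels, cost)
  new("TrainedSVC", alphaSigned = s$alphaSigned, bias = s$bias, cost = cost,
      trainFeatures = K, labels = labels, space = "kernel")
}

#' Decision values and class predictions
#'
#' For a kernel-trained classifier \code{newdata} is the cross-kernel
#' (test x train); for a feature-trained classifier it is a feature matrix
#' centred with the training means.  The decision value is
#' sum_i alphaSigned_i K(x_i, x) + bias; predictions are its sign, with an
#' exact tie at 0 broken to -1 (conservative toward the control class).
#'
#' @param object a \linkS4class{TrainedSVC}.
#' @param newdata cross-kernel or feature matrix.
#' @param type \code{"decision"} (numeric values), \code{"class"} (+/-1) or
#'   \code{"both"} (data.frame).
#' @return per \code{type}.
#' @export
setMethod("predict", "TrainedSVC",
  function(object, newdata, type = c("decision", "class", "both")) {
    type <- match.arg(type)
    newdata <- as.matrix(newdata)
    Kc <- if (object@space == "kernel") {
      if (ncol(newdata) != length(object@alphaSigned))
        stop("cross-kernel columns must align with training samples")
      newdata
    } else {
      if (ncol(newdata) != ncol(object@trainFeatures))
        stop("feature width does not match training features")
      tcrossprod(newdata, object@trainFeatures)
    }
    dec <- as.numeric(Kc %*% object@alphaSigned + object@bias)
    names(dec) <- rownames(newdata)
    if (type == "decision") return(dec)
    cls <- ifelse(dec > 0, 1, -1)
    if (type == "class") return(cls)
    data.frame(decision = dec, predicted = cls)
  })

setMethod("show", "TrainedSVC", function(object) {
  cat(sprintf(
    "TrainedSVC: %d training samples (%d SVs), C = %g, space '%s'\n",
    length(object@labels), sum(object@alphaSigned != 0), object@cost,
    object@space))
})

#' Cross-validation configuration
#'
#' Bundles the tunable settings of the nested LOO-CV pipeline.  The single
#' tuned model parameter is the explained-variance fraction pvar selecting
#' the number of retained eigenslopes; the default grid spans 5\% to 95\%
#' in steps of 5\%.  C is fixed at 1 by default.
#'
#' @param pvarGrid strictly increasing explained-variance fractions in
#'   (0, 1].
#' @param cost SVC cost C.
#' @param timepoint cross-sectional scan used for classification:
#'   \code{"followup"} (second scan), \code{"baseline"} (first) or
#'   \code{"final"} (last).
#' @param slopeSource slope-matrix construction route, see [slopeMatrix()].
#' @param lmPair scan pair for the LM routes, see [slopeMatrix()].
#' @param center centre the slope matrix before PCA (see
#'   [computeEigenslopes()]).
#' @param seed integer seed recorded with results (the CV itself is
#'   deterministic; the seed matters for callers adding randomness).
#' @return a list of class \code{"cvConfig"}.
#' @export
cvConfig <- function(pvarGrid = seq(0.05, 0.95, by = 0.05), cost = 1,
                     timepoint = c("followup", "baseline", "final"),
                     slopeSource = c("lm-balanced", "lm-unbalanced", "ltc"),
                     lmPair = c("first-last", "last-two"),
                     center = TRUE, seed = NULL) {
  pvarGrid <- as.numeric(pvarGrid)
  if (!length(pvarGrid) || any(pvarGrid <= 0 | pvarGrid > 1))
    stop("pvarGrid values must lie in (0, 1]")
  if (is.unsorted(pvarGrid, strictly = TRUE))
    stop("pvarGrid must be strictly increasing")
  structure(list(pvarGrid = pvarGrid, cost = cost,
                 timepoint = match.arg(timepoint),
                 slopeSource = match.arg(slopeSource),
                 lmPair = match.arg(lmPair),
                 center = isTRUE(center), seed = seed),
            class = "cvConfig")
}

# Subjects of `cohort` eligible to contribute a slope row under `config`.
.slopeEligible <- function(cohort, config) {
  need <- if (config$slopeSource == "ltc") 2L else 2L
  ids <- subjectIds(cohort)
  ids[nScans(cohort)[ids] >= need]
}

# Resolve per-subject labels, applying any override.
.cvLabels <- function(cohort, labels) {
  y <- classLabels(cohort)
  if (!is.null(labels)) {
    labels <- unlist(labels)
    if (is.null(names(labels))) {
      if (length(labels) != length(y))
        stop("unnamed label override must cover every subject")
      names(labels) <- names(y)
    }
    y[names(labels)] <- as.numeric(labels)
  }
  if (!all(y %in% c(-1, 1))) stop("labels must be +/-1")
  y
}

#' Run one cross-validation fold (reference path)
#'
#' Executes the full per-fold pipeline at a fixed explained variance:
#' slope matrix from the longitudinal training set L (the longitudinal set
#' minus the test subjects in within-set mode; the disjoint longitudinal
#' cohort in transfer mode), eigenslope PCA at \code{pvar}, ambient
#' projection of the training and test cross-sectional samples, centring
#' with the training means, linear kernels, SVC training on N and
#' prediction of T.  The subspace never sees the test subjects'
#' longitudinal data in within-set mode.
#'
#' @param cohort classification cohort (set C).
#' @param test character vector of held-out subject ids (set T).
#' @param pvar explained-variance fraction for this fold.
#' @param config a [cvConfig()].
#' @param longitudinal disjoint longitudinal cohort for transfer mode
#'   (default NULL: within-set mode).
#' @param labels optional named +/-1 override of subject labels.
#' @return list with \code{subjects}, \code{decision}, \code{predicted},
#'   \code{k}, \code{basis} (the fold's \linkS4class{EigenslopeBasis}) and
#'   \code{classifier}.
#' @export
runFold <- function(cohort, test, pvar, config = cvConfig(),
                    longitudinal = NULL, labels = NULL) {
  stopifnot(is(cohort, "LongitudinalCohort"))
  y <- .cvLabels(cohort, labels)
  Csub <- subjectIds(cohort)
  if (!all(test %in% Csub)) stop("test subjects must belong to the cohort")
  N <- setdiff(Csub, test)
  if (length(unique(y[N])) < 2L)
    stop("classification training set must contain both classes")
  if (is.null(longitudinal)) {
    L <- setdiff(.slopeEligible(cohort, config), test)
    srcCoh <- cohort
  } else {
    stopifnot(is(longitudinal, "LongitudinalCohort"))
    if (length(intersect(subjectIds(longitudinal), Csub)))
      stop("transfer mode requires disjoint longitudinal and classification sets")
    L <- .slopeEligible(longitudinal, config)
    srcCoh <- longitudinal
  }
  if (length(L) < 2L) stop("longitudinal training set too small")
  sm <- slopeMatrix(srcCoh, source = config$slopeSource,
                    lmPair = config$lmPair, subjects = L)
  basis <- computeEigenslopes(sm, pvar = pvar, center = config$center)
  Xn <- crossSection(cohort, config$timepoint, N)
  Xt <- crossSection(cohort, config$timepoint, test)
  Pn <- projectFeatures(Xn, basis, space = "ambient")
  Pt <- projectFeatures(Xt, basis, space = "ambient")
  cf <- centerFeatures(Pn, Pt)
  clf <- fitLinearSVC(cf$train, y[N], cost = config$cost, space = "ambient")
  dec <- predict(clf, cf$others[[1]], type = "decision")
  list(subjects = test, decision = dec,
       predicted = ifelse(dec > 0, 1, -1), k = retainedK(basis),
       basis = basis, classifier = clf)
}

# Eigen-scores of all classification samples for one fold's slope subset.
# G0 = S S' over all longitudinal subjects, M0 = X S'.  Returns the n x r
# score matrix (X projected on the fold's eigenslopes, scaled to unit
# basis) and the cumulative explained-variance profile.
.foldScores <- function(G0, M0, idx, center) {
  G <- G0[idx, idx, drop = FALSE]
  A <- M0[, idx, drop = FALSE]
  if (center) {
    rm_ <- rowMeans(G)
    G <- G - outer(rm_, rep(1, length(idx))) -
      outer(rep(1, length(idx)), rm_) + mean(G)
    A <- A - rowMeans(A)
  }
  e <- eigen(G, symmetric = TRUE)
  d <- e$values
  keep <- d > max(d, 0) * 1e-12 & d > 0
  if (!any(keep)) stop("no slope variance")
  d <- d[keep]
  V <- e$vectors[, keep, drop = FALSE]
  list(scores = A %*% V %*% diag(1 / sqrt(d), length(d)),
       cum = cumsum(d) / sum(d))
}

.kForPvar <- function(pvar, cum) {
  k <- which(cum >= pvar - 1e-12)[1]
  if (is.na(k)) length(cum) else k
}

# Fit-and-predict on compact scores for a set of retained ranks k, warm-
# starting each solve from the previous k's dual solution (the kernel only
# grows by a PSD increment between successive ks).  Linear-SVM decisions
# are translation invariant, so the compact scores are used uncentred;
# the reference path (runFold) centres explicitly and agrees to solver
# tolerance.  Falls back to the majority training label when the training
# labels are single-class.
.scoreDecisions <- function(scores, trainRows, testRows, ks, y, cost) {
  ytr <- y[trainRows]
  ksU <- sort(unique(as.integer(ks)))
  if (length(unique(ytr)) < 2L) {
    warning("single-class inner training set: defaulting to majority label")
    maj <- if (sum(ytr == 1) > sum(ytr == -1)) 1 else -1
    return(list(ks = ksU,
                dec = matrix(maj * 1e-6, length(testRows), length(ksU))))
  }
  tr <- scores[trainRows, , drop = FALSE]
  te <- scores[testRows, , drop = FALSE]
  dec <- matrix(NA_real_, length(testRows), length(ksU))
  Ktr <- matrix(0, nrow(tr), nrow(tr))
  Kte <- matrix(0, nrow(te), nrow(tr))
  prevK <- 0L
  warm <- NULL
  for (q in seq_along(ksU)) {
    idx <- (prevK + 1L):ksU[q]
    trq <- tr[, idx, drop = FALSE]
    Ktr <- Ktr + tcrossprod(trq)
    Kte <- Kte + tcrossprod(te[, idx, drop = FALSE], trq)
    s <- .Call_smo_solve(Ktr, ytr, cost, 1e-6, 1000000L, warm)
    warm <- s$alpha
    dec[, q] <- Kte %*% s$alphaSigned + s$bias
    prevK <- ksU[q]
  }
  list(ks = ksU, dec = dec)
}

# Label-independent setup shared by the CV drivers: classification
# subjects, eligible longitudinal subjects, slope Gram matrix G0 = S S' and
# cross-products M0 = X S' of the cross-sectional samples with the slopes.
.cvSetup <- function(cohort, config, mode, longitudinal) {
  stopifnot(is(cohort, "LongitudinalCohort"))
  if (mode == "transfer" && is.null(longitudinal))
    stop("transfer mode needs a longitudinal cohort")
  if (mode == "within" && !is.null(longitudinal))
    stop("within mode must not be given a separate longitudinal cohort")
  Csub <- subjectIds(cohort)
  if (length(Csub) < 3L) stop("need at least 3 classification subjects")
  srcCoh <- if (mode == "within") cohort else longitudinal
  if (mode == "transfer" && length(intersect(subjectIds(srcCoh), Csub)))
    stop("transfer mode requires disjoint longitudinal and classification sets")
  Lbar <- .slopeEligible(srcCoh, config)
  if (length(Lbar) < 3L) stop("longitudinal set too small")
  sm <- suppressWarnings(
    slopeMatrix(srcCoh, source = config$slopeSource, lmPair = config$lmPair,
                subjects = Lbar))
  S <- slopeValues(sm)
  X <- crossSection(cohort, config$timepoint, Csub)
  list(Csub = Csub, Lbar = slopeSubjects(sm), G0 = tcrossprod(S),
       M0 = tcrossprod(X, S), within = mode == "within")
}

#' Nested leave-one-out cross-validation over the explained-variance grid
#'
#' Runs the full prediction experiment: an outer LOO-CV over the
#' classification subjects makes one prediction per subject; within each
#' outer fold, an inner LOO-CV over the remaining training subjects
#' evaluates every explained-variance fraction in the grid and the fraction
#' with the highest pooled inner balanced accuracy (smallest fraction on
#' ties) is used for the outer prediction.  The eigenslope basis is
#' recomputed inside every inner fold excluding both held-out subjects'
#' longitudinal data, so no test information leaks into the subspace.  With
#' a one-point grid the inner loop is skipped and the scheme reduces to
#' plain LOO at that fraction.
#'
#' In within-set mode the longitudinal set is the classification cohort
#' itself; in transfer mode a disjoint \code{longitudinal} cohort provides
#' the slopes and the basis is constant across folds.  The run is
#' deterministic given data and configuration.
#'
#' @param cohort classification cohort (set C; needs >= 3 subjects).
#' @param config a [cvConfig()].
#' @param mode \code{"within"} or \code{"transfer"}.
#' @param longitudinal disjoint longitudinal cohort (transfer mode).
#' @param labels optional named +/-1 override of subject labels (used by
#'   permutation testing).
#' @return a \linkS4class{CVResult}.
#' @export
nestedLooCv <- function(cohort, config = cvConfig(),
                        mode = c("within", "transfer"),
                        longitudinal = NULL, labels = NULL) {
  mode <- match.arg(mode)
  y <- .cvLabels(cohort, labels)
  su <- .cvSetup(cohort, config, mode, longitudinal)
  Csub <- su$Csub; Lbar <- su$Lbar; G0 <- su$G0; M0 <- su$M0
  n <- length(Csub)
  grid <- config$pvarGrid
  center <- config$center
  cost <- config$cost
  within <- mode == "within"
  fsFull <- if (!within) .foldScores(G0, M0, seq_along(Lbar), center)
  dec <- pred <- chosen <- kOut <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    Nrows <- setdiff(seq_len(n), t)
    if (length(unique(y[Csub[Nrows]])) < 2L)
      stop("classification training set must contain both classes")
    if (length(grid) > 1L) {
      innerDec <- matrix(NA_real_, length(Nrows), length(grid))
      for (jj in seq_along(Nrows)) {
        j <- Nrows[jj]
        fs <- if (within)
          .foldScores(G0, M0, which(!Lbar %in% Csub[c(t, j)]), center)
        else fsFull
        ks <- vapply(grid, .kForPvar, integer(1), cum = fs$cum)
        sd <- .scoreDecisions(fs$scores, setdiff(Nrows, j), j, ks,
                              y[Csub], cost)
        innerDec[jj, ] <- sd$dec[1L, match(ks, sd$ks)]
      }
      yN <- y[Csub[Nrows]]
      bas <- apply(innerDec, 2L, function(d) {
        p <- ifelse(d > 0, 1, -1)
        (mean(p[yN == 1] == 1) + mean(p[yN == -1] == -1)) / 2
      })
      pv <- grid[which.max(bas)]
    } else pv <- grid
    fs <- if (within) .foldScores(G0, M0, which(Lbar != Csub[t]), center)
    else fsFull
    k <- .kForPvar(pv, fs$cum)
    dec[t] <- .scoreDecisions(fs$scores, Nrows, t, k, y[Csub], cost)$dec[1L, 1L]
    pred[t] <- if (dec[t] > 0) 1 else -1
    chosen[t] <- pv
    kOut[t] <- k
  }
  res <- data.frame(subject = Csub, label = as.numeric(y[Csub]),
                    decision = dec, predicted = pred, pvar = chosen,
                    k = as.integer(kOut), row.names = NULL)
  new("CVResult", predictions = res,
      metrics = computeMetrics(res$label, res$predicted, res$decision),
      config = unclass(config), mode = mode)
}

# Precompute the label-independent per-fold training kernels and test
# cross-kernels of a plain LOO at one fixed pvar; permutation testing then
# only re-runs the SMO per fold.
.looFoldKernels <- function(cohort, pvar, config, mode, longitudinal) {
  su <- .cvSetup(cohort, config, mode, longitudinal)
  n <- length(su$Csub)
  fsFull <- if (!su$within)
    .foldScores(su$G0, su$M0, seq_along(su$Lbar), config$center)
  folds <- lapply(seq_len(n), function(t) {
    fs <- if (su$within)
      .foldScores(su$G0, su$M0, which(su$Lbar != su$Csub[t]), config$center)
    else fsFull
    k <- .kForPvar(pvar, fs$cum)
    tr <- fs$scores[-t, seq_len(k), drop = FALSE]
    te <- fs$scores[t, seq_len(k), drop = FALSE]
    list(Ktr = tcrossprod(tr), kte = as.numeric(tcrossprod(te, tr)))
  })
  list(subjects = su$Csub, folds = folds)
}

#' Plain LOO-CV on unprojected cross-sectional features
#'
#' The cross-sectional comparison classifier: leave-one-out CV training the
#' linear SVC directly on the (training-mean-centred) raw feature vectors
#' at the configured time-point, with no subspace projection.
#'
#' @param cohort classification cohort.
#' @param config a [cvConfig()] (only \code{timepoint} and \code{cost} are
#'   used).
#' @param labels optional named +/-1 label override.
#' @return a \linkS4class{CVResult} (pvar and k are NA).
#' @export
looCvUnprojected <- function(cohort, config = cvConfig(), labels = NULL) {
  stopifnot(is(cohort, "LongitudinalCohort"))
  y <- .cvLabels(cohort, labels)
  Csub <- subjectIds(cohort)
  n <- length(Csub)
  if (n < 3L) stop("need at least 3 classification subjects")
  X <- crossSection(cohort, config$timepoint, Csub)
  K0 <- tcrossprod(X)
  dec <- numeric(n)
  for (t in seq_len(n)) {
    Nrows <- setdiff(seq_len(n), t)
    # centring by the training means only shifts the bias; work in the
    # kernel directly
    Ktr <- K0[Nrows, Nrows]
    mu <- colMeans(K0[Nrows, Nrows])
    Kc <- Ktr - outer(mu, rep(1, n - 1)) - outer(rep(1, n - 1), mu) + mean(Ktr)
    clf <- trainSVC(Kc, y[Csub[Nrows]], cost = config$cost)
    kc <- K0[t, Nrows] - mu - mean(K0[t, Nrows]) + mean(Ktr)
    dec[t] <- predict(clf, matrix(kc, 1L), type = "decision")
  }
  res <- data.frame(subject = Csub, label = as.numeric(y[Csub]),
                    decision = dec, predicted = ifelse(dec > 0, 1, -1),
                    pvar = NA_real_, k = NA_integer_, row.names = NULL)
  new("CVResult", predictions = res,
      metrics = computeMetrics(res$label, res$predicted, res$decision),
      config = unclass(config), mode = "within")
}

#' @rdname cvMetrics
#' @param x a \linkS4class{CVResult}.
#' @export
setMethod("cvMetrics", "CVResult", function(x) x@metrics)

#' @rdname cvPredictions
#' @param x a \linkS4class{CVResult}.
#' @export
setMethod("cvPredictions", "CVResult", function(x) x@predictions)

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (%s-set LOO-CV, %d subjects)\n", object@mode,
              nrow(object@predictions)))
  show(object@metrics)
})
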