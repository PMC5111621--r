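#' Simulate a two-group longitudinal cohort with low-rank slope signal
#'
#' Generates the kind of data the eigenslope method assumes: each subject i
#' follows a linear trajectory x_i(t) = b_i + s_i t + noise, where the
#' per-subject slope s_i = W (theta_g + eta_i) lives in a random rank-r
#' subspace spanned by the orthonormal D x r matrix W.  The two groups'
#' mean slopes differ by a vector of norm \code{delta} inside that subspace
#' (the progressive, disease-linked component of change), while
#' \code{eta_i ~ N(0, sigmaSlope^2 I_r)} disperses individual slopes within
#' it.  Intercepts are isotropic N(0, sigmaBaseline^2) across all D
#' dimensions, optionally offset between groups by \code{baselineShift}
#' along a random direction (0 = no cross-sectional signal at baseline).
#' Observation noise is i.i.d. N(0, sigmaNoise^2) per sample and dimension.
#'
#' Balanced designs scan every subject \code{m} times at a fixed interval
#' \code{tDelta}; unbalanced designs draw the number of scans per subject
#' uniformly from \code{mRange} and the inter-scan gaps uniformly from
#' \code{gapRange} (years).
#'
#' The defaults describe a desk-scale cohort (40 subjects, D = 500, r = 3)
#' whose projected-feature separability is moderate -- comparable to
#' mid-70s balanced accuracy -- while the unprojected problem stays hard
#' because the baseline dispersion spreads over all D dimensions.
#'
#' @param nPos,nNeg subjects per class (+1 disease / -1 control).
#' @param D feature dimensionality.
#' @param r rank of the slope-signal subspace (r <= D).
#' @param delta between-group mean-slope difference (vector norm, units of
#'   feature change per year).
#' @param sigmaSlope within-group slope dispersion inside the subspace.
#' @param sigmaNoise per-sample observation noise sd.
#' @param sigmaBaseline intercept dispersion sd.
#' @param baselineShift between-group cross-sectional offset at baseline.
#' @param design \code{"balanced"} or \code{"unbalanced"}.
#' @param tDelta fixed inter-scan interval in years (balanced design).
#' @param m scans per subject (balanced design).
#' @param mRange integer range of scans per subject (unbalanced design).
#' @param gapRange range of inter-scan gaps in years (unbalanced design).
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @return list with \code{cohort} (a \linkS4class{LongitudinalCohort}) and
#'   \code{truth}: \code{basis} (W), \code{slopes} (l x D true slopes, rows
#'   named by subject), \code{intercepts}, \code{groupSlopeMeans} and
#'   \code{delta}.
#' @export
simulateCohort <- function(nPos = 20, nNeg = 20, D = 500, r = 3,
                           delta = 0.6, sigmaSlope = 0.3, sigmaNoise = 0.1,
                           sigmaBaseline = 1, baselineShift = 0,
                           design = c("balanced", "unbalanced"),
                           tDelta = 2.5, m = 2, mRange = c(2, 4),
                           gapRange = c(0.8, 3.0), seed = NULL) {
  design <- match.arg(design)
  if (r > D) stop("r must not exceed D")
  if (any(c(sigmaSlope, sigmaNoise, sigmaBaseline) < 0))
    stop("dispersions must be >= 0")
  if (m < 1) stop("m must be >= 1")
  .withSeed(seed, {
    W <- qr.Q(qr(matrix(rnorm(D * r), D, r)))
    u <- rnorm(r); u <- u / sqrt(sum(u^2))
    thetaPos <- delta * u
    vShift <- rnorm(D); vShift <- vShift / sqrt(sum(vShift^2))
    ids <- c(sprintf("pos%02d", seq_len(nPos)),
             sprintf("neg%02d", seq_len(nNeg)))
    labels <- c(rep(1, nPos), rep(-1, nNeg))
    l <- nPos + nNeg
    slopes <- matrix(0, l, D, dimnames = list(ids, NULL))
    intercepts <- matrix(0, l, D, dimnames = list(ids, NULL))
    cols <- vector("list", l)
    subj <- lab <- tim <- vector("list", l)
    for (i in seq_len(l)) {
      theta <- if (labels[i] == 1) thetaPos else rep(0, r)
      s_i <- as.numeric(W %*% (theta + rnorm(r, sd = sigmaSlope)))
      b_i <- rnorm(D, sd = sigmaBaseline) +
        if (labels[i] == 1) baselineShift * vShift else 0
      slopes[i, ] <- s_i
      intercepts[i, ] <- b_i
      times <- if (design == "balanced") {
        seq(0, by = tDelta, length.out = m)
      } else {
        # index into the candidate counts (sample(x, 1) on a scalar x
        # would draw from 1:x)
        mCand <- seq(mRange[1], mRange[2])
        mi <- mCand[sample.int(length(mCand), 1L)]
        cumsum(c(0, runif(mi - 1L, gapRange[1], gapRange[2])))
      }
      cols[[i]] <- vapply(times, function(t)
        b_i + s_i * t + rnorm(D, sd = sigmaNoise), numeric(D))
      subj[[i]] <- rep(ids[i], length(times))
      lab[[i]] <- rep(labels[i], length(times))
      tim[[i]] <- times
    }
    cohort <- longitudinalCohort(
      do.call(cbind, cols), subject = unlist(subj), label = unlist(lab),
      time = unlist(tim), featureSpace = "generic")
    list(cohort = cohort,
         truth = list(basis = W, slopes = slopes, intercepts = intercepts,
                      groupSlopeMeans = list(
                        pos = as.numeric(W %*% thetaPos),
                        neg = rep(0, D)),
                      delta = delta))
  })
}

#' Randomly thin a balanced cohort into an unbalanced one
#'
#' Drops non-baseline scans independently with probability \code{dropProb},
#' subject to the policy's minimum number of retained scans per subject
#' (\code{"keep-all"} drops nothing; \code{"min-2"} keeps at least a
#' baseline and one follow-up; \code{"min-1"} keeps at least the
#' baseline).  Baseline scans are never dropped, so relative times are
#' preserved.  Reproducible given \code{seed}.
#'
#' @param cohort a \linkS4class{LongitudinalCohort}.
#' @param policy retention policy.
#' @param dropProb per-scan drop probability.
#' @param seed integer seed.
#' @return a \linkS4class{LongitudinalCohort}.
#' @export
makeUnbalanced <- function(cohort, policy = c("min-2", "min-1", "keep-all"),
                           dropProb = 0.3, seed = NULL) {
  policy <- match.arg(policy)
  stopifnot(is(cohort, "LongitudinalCohort"))
  if (policy == "keep-all") return(cohort)
  minKeep <- if (policy == "min-2") 2L else 1L
  .withSeed(seed, {
    sj <- as.character(colData(cohort)$subject)
    keep <- logical(ncol(cohort))
    for (s in unique(sj)) {
      i <- which(sj == s)
      ki <- c(TRUE, runif(length(i) - 1L) >= dropProb)
      # re-add randomly dropped follow-ups until the policy minimum holds
      while (sum(ki) < min(minKeep, length(i))) {
        cand <- which(!ki)
        ki[cand[sample.int(length(cand), 1L)]] <- TRUE
      }
      keep[i] <- ki
    }
    cohort[, keep]
  })
}
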