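# Shared fixture builders; everything is generated in code at test time.

# Tiny deterministic cohort built by hand: l subjects, two scans each at a
# fixed interval, known intercepts/slopes, optional noise.
toyCohort <- function(l = 6, D = 8, tDelta = 2, noise = 0, seed = 1) {
  set.seed(seed)
  slopes <- matrix(rnorm(l * D), l, D)
  intercepts <- matrix(rnorm(l * D), l, D)
  cols <- matrix(0, D, 2 * l)
  for (i in seq_len(l)) {
    cols[, 2 * i - 1] <- intercepts[i, ] + rnorm(D, sd = noise)
    cols[, 2 * i] <- intercepts[i, ] + slopes[i, ] * tDelta +
      rnorm(D, sd = noise)
  }
  ids <- sprintf("s%02d", seq_len(l))
  labs <- rep(c(1, -1), length.out = l)
  coh <- longitudinalCohort(
    cols, subject = rep(ids, each = 2), label = rep(labs, each = 2),
    time = rep(c(0, tDelta), l))
  list(cohort = coh, slopes = slopes, intercepts = intercepts, ids = ids,
       tDelta = tDelta)
}

# A small 3-D mask with an irregular pattern.
toyMask <- function() {
  vol <- array(0, c(4, 3, 2))
  vol[c(1, 5, 8, 13, 20, 24)] <- 1
  brainMask(vol, affine = diag(c(2, 2, 2, 1)))
}

# Write a subject table to a temp file and return its path.
writeTable <- function(df, sep = ",") {
  f <- tempfile(fileext = ".csv")
  utils::write.table(df, f, sep = sep, row.names = FALSE, quote = FALSE)
  f
}

# sin-based largest principal angle in radians (stable near zero)
largestPrincipalAngleRad <- function(A, B) {
  qa <- qr.Q(qr(as.matrix(A)))
  qb <- qr.Q(qr(as.matrix(B)))
  max(svd(qb - qa %*% crossprod(qa, qb))$d)  # = sin(theta_max)
}
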