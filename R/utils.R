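# Internal helpers shared across modules.

# Round a fraction to a percentage with 1 decimal, half-up (table style:
# 0.742753 -> 74.3).  base::round() rounds half to even, so do it explicitly.
.percent1 <- function(x) {
  ifelse(is.na(x), NA_real_, floor(x * 1000 + 0.5) / 10)
}

# Round half-up to `digits` decimals.
.roundHalfUp <- function(x, digits) {
  m <- 10^digits
  ifelse(is.na(x), NA_real_, floor(x * m + 0.5) / m)
}

# Run `expr` under a temporary RNG state seeded with `seed` (if non-NULL),
# restoring the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assertMatrix <- function(x, what = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
  invisible(x)
}

# Largest principal angle (degrees) between the column spans of A and B.
#' Principal angles between subspaces
#'
#' Computes the principal angles (in degrees, non-decreasing) between the
#' column spans of two matrices, after orthonormalizing each.  Useful for
#' assessing how well an estimated eigenslope basis recovers a known
#' subspace.
#'
#' @param A,B matrices with the same number of rows.
#' @return numeric vector of principal angles in degrees.
#' @export
principalAngles <- function(A, B) {
  qa <- qr.Q(qr(as.matrix(A)))
  qb <- qr.Q(qr(as.matrix(B)))
  s <- svd(crossprod(qa, qb))$d
  s <- pmin(pmax(s, -1), 1)
  sort(acos(s) * 180 / pi)
}
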