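# internal helpers shared across modules

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# z-score each column; zero-variance columns are left at zero (all entries
# replaced by 0) rather than NaN.  sd uses the n-1 denominator.
#' @keywords internal
#' @noRd
zscore_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sd <- sqrt(colSums(xc^2) / max(1L, nrow(x) - 1L))
  ok <- sd > 0
  xc[, ok] <- sweep(xc[, ok, drop = FALSE], 2, sd[ok], "/")
  xc[, !ok] <- 0
  attr(xc, "degenerate") <- which(!ok)
  xc
}

# Pearson correlation of each row of `m` with vector `y` (vectorised).
#' @keywords internal
#' @noRd
row_cor <- function(m, y) {
  m <- as.matrix(m)
  n <- length(y)
  stopifnot(ncol(m) == n)
  yc <- y - mean(y)
  mc <- m - rowMeans(m)
  denom <- sqrt(rowSums(mc^2) * sum(yc^2))
  out <- as.vector(mc %*% yc) / denom
  out[denom == 0] <- NA_real_
  out
}

# Fisher z with clipping of |r| at 1 - 1e-7 so perfect correlations stay finite.
#' @keywords internal
#' @noRd
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

# Two-sided permutation p with add-one correction:
# p = (1 + #{|null| >= |obs|}) / (1 + n_perm).
#' @keywords internal
#' @noRd
perm_pvalue <- function(obs, null) {
  null <- null[is.finite(null)]
  if (!is.finite(obs) || length(null) == 0L) return(NA_real_)
  (1 + sum(abs(null) >= abs(obs))) / (1 + length(null))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
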