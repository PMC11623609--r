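#' Cross-run room pattern similarity matrix
#'
#' Correlates the room templates from the first pre-learning room-video run
#' with those from the second: `S[i, j]` is the Pearson correlation between
#' the run-1 pattern of room `i` and the run-2 pattern of room `j`. The
#' matrix is not symmetric in general; the diagonal measures the stability
#' of each room's pattern over time, the off-diagonal its similarity to
#' other rooms.
#'
#' @param templates_run1,templates_run2 `template_set` objects (or bare
#'   condition x vertex matrices) with identical room ordering and vertex
#'   dimension.
#' @return n_rooms x n_rooms numeric matrix; entries involving a
#'   zero-variance pattern are `NaN` (with a warning).
#' @export
similarity_matrix <- function(templates_run1, templates_run2) {
  p1 <- if (inherits(templates_run1, "template_set")) templates_run1$patterns else as.matrix(templates_run1)
  p2 <- if (inherits(templates_run2, "template_set")) templates_run2$patterns else as.matrix(templates_run2)
  stopifnot(nrow(p1) == nrow(p2), ncol(p1) == ncol(p2))
  sd1 <- apply(p1, 1, stats::sd)
  sd2 <- apply(p2, 1, stats::sd)
  if (any(c(sd1, sd2) == 0, na.rm = TRUE))
    warning("zero-variance pattern(s); affected similarity entries set to NaN")
  S <- suppressWarnings(stats::cor(t(p1), t(p2)))
  S[is.na(S)] <- NaN
  unname(S)
}

#' Room reliability scores from a similarity matrix
#'
#' The reliability of room `r` is the stability of its pattern minus its
#' distinctiveness penalty: `rel[r] = S[r, r] - mean(S[r, -r])`, using the
#' off-diagonal entries of row `r` (run-1 room `r` against all other run-2
#' rooms). Large positive values mean the room's pattern is more similar to
#' itself over time than to other rooms.
#'
#' @param S Similarity matrix from [similarity_matrix()].
#' @param margin `"row"` (default; run-1 room vs other run-2 rooms) or
#'   `"col"` for the column variant.
#' @return Numeric vector of length `n_rooms`; `NaN` rows propagate to `NaN`
#'   scores.
#' @examples
#' S <- matrix(c(.9, .1, .2, 0, .8, .4, .3, .1, .7), 3, byrow = TRUE)
#' reliability_scores(S) # 0.75 0.60 0.50
#' @export
reliability_scores <- function(S, margin = c("row", "col")) {
  margin <- match.arg(margin)
  S <- as.matrix(S)
  n <- nrow(S)
  stopifnot(n == ncol(S), n >= 2)
  if (margin == "col") S <- t(S)
  d <- diag(S)
  off_mean <- (rowSums(S) - d) / (n - 1)
  as.numeric(d - off_mean)
}

#' Group-level reliability map
#'
#' Given per-participant mean reliability (averaged over rooms within
#' participant) for each searchlight, performs a one-sample t-test against
#' zero across participants per searchlight, then Benjamini-Hochberg FDR
#' across searchlights.
#'
#' @param mean_rel Participant x searchlight matrix of mean reliability.
#' @param q_threshold FDR level (default 0.05).
#' @return A `brain_map` data frame (`stat` = t value; searchlights with
#'   zero across-participant variance get `NA` p and are excluded from FDR).
#' @export
group_reliability_map <- function(mean_rel, q_threshold = 0.05) {
  mean_rel <- as.matrix(mean_rel)
  if (nrow(mean_rel) < 3)
    stop("group map requires at least 3 participants")
  stat <- p <- rep(NA_real_, ncol(mean_rel))
  for (j in seq_len(ncol(mean_rel))) {
    x <- mean_rel[, j]
    x <- x[is.finite(x)]
    if (length(x) >= 3 && stats::sd(x) > 0) {
      tt <- stats::t.test(x, mu = 0)
      stat[j] <- unname(tt$statistic)
      p[j] <- tt$p.value
    }
  }
  brain_map(stat, p, q_threshold)
}

#' Regression of room reliability on room features
#'
#' Per searchlight and participant, regresses the 23 room reliabilities on
#' the room feature table (z-scored features plus intercept; the binary
#' `has_window` column is left as is). Betas are averaged across
#' participants; inference is by permutation — room reliability is shuffled
#' across rooms within participant `n_perm` times and the regression redone —
#' with two-sided permutation p-values and BH-FDR across searchlights per
#' feature.
#'
#' @param rel Array participant x searchlight x room of reliability scores.
#' @param features n_rooms x n_features numeric matrix (z-scored except
#'   binary columns); column names label the output.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @param q_threshold FDR level (default 0.001).
#' @return List with `beta` (searchlight x feature matrix of mean betas) and
#'   `maps` (list of `brain_map` per feature).
#' @export
feature_regression <- function(rel, features, n_perm = 1000, seed,
                               q_threshold = 0.001) {
  stopifnot(n_perm >= 100)
  if (missing(seed)) stop("`seed` is required")
  features <- as.matrix(features)
  n_rooms <- dim(rel)[3]
  stopifnot(nrow(features) == n_rooms)
  X <- cbind(intercept = 1, features)
  if (kappa(crossprod(X)) > 1e8)
    stop("collinear features (condition number > 1e8)")
  XtXinv_Xt <- solve(crossprod(X), t(X)) # (k+1) x n_rooms projector
  n_sub <- dim(rel)[1]
  n_sl <- dim(rel)[2]
  n_feat <- ncol(features)

  mean_betas <- function(rel_arr) {
    # average over participants of per-participant OLS betas (drop intercept)
    out <- matrix(0, n_sl, n_feat)
    for (s in seq_len(n_sub)) {
      Ys <- matrix(rel_arr[s, , ], nrow = n_sl) # searchlight x room
      B <- XtXinv_Xt %*% t(Ys)                  # (k+1) x n_sl
      out <- out + t(B[-1, , drop = FALSE])
    }
    out / n_sub
  }
  obs <- mean_betas(rel)

  null <- array(NA_real_, c(n_perm, n_sl, n_feat))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- rel
      for (s in seq_len(n_sub)) {
        sh <- sample.int(n_rooms)
        perm[s, , ] <- perm[s, , sh, drop = FALSE]
      }
      null[b, , ] <- mean_betas(perm)
    }
  })

  maps <- vector("list", n_feat)
  names(maps) <- colnames(features)
  for (f in seq_len(n_feat)) {
    p <- vapply(seq_len(n_sl),
                function(j) perm_pvalue(obs[j, f], null[, j, f]), numeric(1))
    maps[[f]] <- brain_map(obs[, f], p, q_threshold)
  }
  list(beta = obs, maps = maps)
}
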