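# Map-level statistics relating room reliability to object reinstatement.
#
# Data layout used throughout this file:
#  * rel     — array [participant x searchlight x room] of reliability
#  * scores  — list over recall task types ("guided", "free") of
#              [participant x room] matrices of room-aligned object
#              reinstatement (participant s's entry for room r is the score
#              of the object paired to r under s's own pairing); NaN where
#              the object was never recalled
#  * covars  — list over task types of list(room = [participant x room],
#              object = [participant x room]) room-reinstatement covariates

# per-(participant, task) complete-room subset; NULL if < min_rooms rows
#' @keywords internal
#' @noRd
complete_rooms <- function(y, extra = NULL, min_rooms = 4L) {
  ok <- is.finite(y)
  if (!is.null(extra)) for (e in extra) ok <- ok & is.finite(e)
  if (sum(ok) < min_rooms) NULL else which(ok)
}

# permutation index stream shared between raw / partial / delta analyses:
# perms[[b]] is a [participant x room] matrix of room orderings. One shuffle
# per participant per permutation, applied to BOTH recall task types: the
# shuffle relabels the room-object assignment, so guided and free scores
# move together and their within-participant dependence is preserved under
# the null.
#' @keywords internal
#' @noRd
make_perm_indices <- function(n_perm, n_sub, n_rooms, seed) {
  with_seed(seed, {
    lapply(seq_len(n_perm), function(b)
      t(vapply(seq_len(n_sub), function(s) sample.int(n_rooms),
               integer(n_rooms))))
  })
}

#' Fisher-z composite reliability-reinstatement map
#'
#' For every searchlight, correlates each participant's room reliabilities
#' with the reinstatement scores of the paired objects (Pearson, over
#' complete room-object pairs; participants with fewer than `min_rooms`
#' complete pairs, or a constant variable, are excluded), Fisher-z
#' transforms the correlations (clipping `|r|` at `1 - 1e-7`), averages
#' across participants, and then averages across the recall task types. The
#' result is the composite z statistic per searchlight.
#'
#' @param rel Array participant x searchlight x room of reliability.
#' @param scores List over task types of participant x room reinstatement
#'   matrices (room-aligned; `NaN` = never recalled).
#' @param min_rooms Minimum complete pairs per participant (default 4).
#' @return Numeric vector of composite z statistics (length = number of
#'   searchlights).
#' @export
fisher_average_map <- function(rel, scores, min_rooms = 4L) {
  n_sub <- dim(rel)[1]
  n_sl <- dim(rel)[2]
  task_means <- vapply(scores, function(sc) {
    zs <- matrix(NA_real_, n_sub, n_sl)
    for (s in seq_len(n_sub)) {
      ok <- complete_rooms(sc[s, ], min_rooms = min_rooms)
      if (is.null(ok)) next
      y <- sc[s, ok]
      if (stats::sd(y) == 0) {
        warning("constant reinstatement for participant ", s, "; excluded")
        next
      }
      r <- row_cor(matrix(rel[s, , ok], nrow = n_sl), y)
      zs[s, ] <- fisher_z(r)
    }
    colMeans(zs, na.rm = TRUE)
  }, numeric(n_sl))
  rowMeans(matrix(task_means, nrow = n_sl))
}

#' Object-label permutation null for the composite map
#'
#' Each permutation shuffles, independently within each participant, the
#' assignment of reinstatement scores to rooms — one relabeling per
#' participant, applied to both recall task types, mirroring a shuffle of
#' the object labels themselves — then recomputes the identical Fisher-z
#' composite. The returned matrix is the null distribution of the composite
#' statistic per searchlight.
#'
#' @inheritParams fisher_average_map
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed (ignored when `perm_indices` is supplied).
#' @param perm_indices Optional permutation stream from an earlier call, so
#'   two analyses can share identical (paired) permutations.
#' @return n_perm x n_searchlight matrix of null composite statistics.
#' @export
pairlabel_null <- function(rel, scores, n_perm = 1000, seed,
                           min_rooms = 4L, perm_indices = NULL) {
  stopifnot(n_perm >= 100)
  n_sub <- dim(rel)[1]
  n_rooms <- dim(rel)[3]
  if (is.null(perm_indices)) {
    if (missing(seed)) stop("`seed` is required")
    perm_indices <- make_perm_indices(n_perm, n_sub, n_rooms, seed)
  }
  t(vapply(seq_len(n_perm), function(b) {
    sc_b <- lapply(seq_along(scores), function(t) {
      sc <- scores[[t]]
      for (s in seq_len(n_sub)) sc[s, ] <- sc[s, perm_indices[[b]][s, ]]
      sc
    })
    suppressWarnings(fisher_average_map(rel, sc_b, min_rooms = min_rooms))
  }, numeric(dim(rel)[2])))
}

#' Reliability-reinstatement map with permutation inference
#'
#' Convenience wrapper: computes the Fisher-z composite map, its
#' object-label permutation null, two-sided permutation p-values with
#' add-one correction, and BH-FDR across searchlights.
#'
#' @inheritParams pairlabel_null
#' @param q_threshold FDR level (default 0.05).
#' @return List with `map` (a `brain_map`) and `null` (the permutation
#'   matrix, for reuse in [map_contrast()]).
#' @export
reliability_reinstatement_map <- function(rel, scores, n_perm = 1000, seed,
                                          q_threshold = 0.05, min_rooms = 4L,
                                          perm_indices = NULL) {
  stat <- suppressWarnings(fisher_average_map(rel, scores, min_rooms))
  null <- pairlabel_null(rel, scores, n_perm, seed, min_rooms, perm_indices)
  p <- vapply(seq_along(stat), function(j) perm_pvalue(stat[j], null[, j]),
              numeric(1))
  list(map = brain_map(stat, p, q_threshold), null = null)
}

# residualize y (length n) and the searchlight x room reliability block on
# the covariate design; returns NULL if non-constant covariates are
# collinear (participant excluded upstream). Constant covariate columns are
# dropped silently so that all-zero covariates reduce to the raw analysis.
#' @keywords internal
#' @noRd
residualize_pair <- function(y, rel_mat, covar_room, covar_obj) {
  Z <- cbind(1, room = covar_room, object = covar_obj)
  keep <- c(TRUE, apply(Z[, -1, drop = FALSE], 2, stats::sd) > 0)
  Z <- Z[, keep, drop = FALSE]
  if (qr(Z)$rank < ncol(Z)) return(NULL)
  H <- Z %*% solve(crossprod(Z), t(Z))
  list(y_res = as.numeric(y - H %*% y),
       rel_res = rel_mat - rel_mat %*% t(H))
}

#' Partial-correlation map controlling for room reinstatement
#'
#' Within each participant and task type, residualizes both the object
#' reinstatement scores and the room reliabilities on the two
#' room-reinstatement covariates (evidence during room-speaking and during
#' object-speaking recall timepoints, plus an intercept), correlates the two
#' residual vectors, and forms the same Fisher-z composite as
#' [fisher_average_map()]. Inference shuffles the object-reinstatement
#' residuals within participant and recomputes the composite. Participants
#' whose covariates are collinear are excluded with a warning; constant
#' (e.g. all-zero) covariates are dropped, in which case the partial map
#' equals the raw map.
#'
#' @inheritParams pairlabel_null
#' @param covars List over task types of `list(room =, object =)`
#'   participant x room covariate matrices.
#' @param q_threshold FDR level (default 0.05).
#' @return List with `map` (a `brain_map`), `stat`, and `null`.
#' @export
partial_correlation_map <- function(rel, scores, covars, n_perm = 1000, seed,
                                    q_threshold = 0.05, min_rooms = 4L,
                                    perm_indices = NULL) {
  stopifnot(length(covars) == length(scores), n_perm >= 100)
  n_sub <- dim(rel)[1]
  n_sl <- dim(rel)[2]
  n_rooms <- dim(rel)[3]
  if (is.null(perm_indices)) {
    if (missing(seed)) stop("`seed` is required")
    perm_indices <- make_perm_indices(n_perm, n_sub, n_rooms, seed)
  }
  # residualize once per (participant, task)
  res <- lapply(seq_along(scores), function(t) lapply(seq_len(n_sub), function(s) {
    ok <- complete_rooms(scores[[t]][s, ],
                         list(covars[[t]]$room[s, ], covars[[t]]$object[s, ]),
                         min_rooms)
    if (is.null(ok)) return(NULL)
    y <- scores[[t]][s, ok]
    if (stats::sd(y) == 0) return(NULL)
    rp <- residualize_pair(y, matrix(rel[s, , ok], nrow = n_sl),
                           covars[[t]]$room[s, ok], covars[[t]]$object[s, ok])
    if (is.null(rp)) {
      warning("collinear covariates for participant ", s, "; excluded")
      return(NULL)
    }
    c(rp, list(rooms = ok))
  }))
  composite <- function(perm = NULL) {
    task_means <- vapply(seq_along(res), function(t) {
      zs <- matrix(NA_real_, n_sub, n_sl)
      for (s in seq_len(n_sub)) {
        rp <- res[[t]][[s]]
        if (is.null(rp)) next
        y <- rp$y_res
        if (!is.null(perm)) {
          # shuffle the object-reinstatement residuals within participant,
          # using the shared room-permutation stream restricted to the
          # complete rooms (ranks reduce it to a subset permutation; on the
          # full room set this is exactly the raw analysis' shuffle)
          y <- y[rank(perm[s, rp$rooms])]
        }
        if (stats::sd(y) == 0) next
        zs[s, ] <- fisher_z(row_cor(rp$rel_res, y))
      }
      colMeans(zs, na.rm = TRUE)
    }, numeric(n_sl))
    rowMeans(matrix(task_means, nrow = n_sl))
  }
  stat <- composite()
  null <- t(vapply(seq_len(n_perm), function(b) composite(perm_indices[[b]]),
                   numeric(n_sl)))
  p <- vapply(seq_along(stat), function(j) perm_pvalue(stat[j], null[, j]),
              numeric(1))
  list(map = brain_map(stat, p, q_threshold), stat = stat, null = null)
}

#' Participant-specific model comparison (delta R-squared)
#'
#' For each searchlight, compares how well a participant's object
#' reinstatement is predicted from their *own* room reliabilities versus
#' from every other participant's reliabilities: `R2_own` is the coefficient
#' of determination of the OLS fit on the participant's own reliabilities;
#' `R2_other` refits the same simple regression using each other
#' participant's reliability vector as the predictor and averages the N-1
#' values. The delta (own minus other), averaged across participants and
#' task types, is positive where reliability carries participant-specific
#' (idiosyncratic) predictive value. Inference is by the same object-label
#' shuffle as [pairlabel_null()]; the final intersection mask additionally
#' requires a positive significant composite map.
#'
#' @inheritParams pairlabel_null
#' @param q_threshold FDR level (default 0.05).
#' @param composite_map Optional `brain_map` from
#'   [reliability_reinstatement_map()] used for the intersection mask.
#' @return List with `map` (a `brain_map` of delta R-squared), `null`,
#'   `intersection` (logical; `NULL` when no composite map is supplied), and
#'   `per_participant` (participant x searchlight matrix of task-averaged
#'   deltas, for across-participant standard errors).
#' @export
participant_specific_delta <- function(rel, scores, n_perm = 1000, seed,
                                       q_threshold = 0.05, min_rooms = 4L,
                                       perm_indices = NULL,
                                       composite_map = NULL) {
  stopifnot(n_perm >= 100)
  n_sub <- dim(rel)[1]
  n_sl <- dim(rel)[2]
  n_rooms <- dim(rel)[3]
  if (is.null(perm_indices)) {
    if (missing(seed)) stop("`seed` is required")
    perm_indices <- make_perm_indices(n_perm, n_sub, n_rooms, seed)
  }
  # stacked reliability block: rows grouped by participant, for vectorised
  # correlation of one score vector against every participant's reliabilities
  stack <- do.call(rbind, lapply(seq_len(n_sub), function(j)
    matrix(rel[j, , ], nrow = n_sl)))
  delta_stat <- function(perm = NULL, detail = FALSE) {
    sub_sum <- matrix(0, n_sub, n_sl)
    sub_n <- matrix(0L, n_sub, n_sl)
    task_means <- vapply(seq_along(scores), function(t) {
      ds <- matrix(NA_real_, n_sub, n_sl)
      for (s in seq_len(n_sub)) {
        y_full <- scores[[t]][s, ]
        if (!is.null(perm)) y_full <- y_full[perm[s, ]]
        ok <- complete_rooms(y_full, min_rooms = min_rooms)
        if (is.null(ok)) next
        y <- y_full[ok]
        if (stats::sd(y) == 0) next
        r2 <- matrix(row_cor(stack[, ok, drop = FALSE], y)^2,
                     nrow = n_sl, ncol = n_sub)
        own <- r2[, s]
        other <- (rowSums(r2, na.rm = TRUE) - ifelse(is.na(own), 0, own)) /
          (n_sub - 1)
        ds[s, ] <- own - other
        sub_sum[s, ] <<- sub_sum[s, ] + ds[s, ]
        sub_n[s, ] <<- sub_n[s, ] + 1L
      }
      colMeans(ds, na.rm = TRUE)
    }, numeric(n_sl))
    out <- rowMeans(matrix(task_means, nrow = n_sl))
    if (detail) attr(out, "per_participant") <- sub_sum / pmax(sub_n, 1L)
    out
  }
  stat <- delta_stat(detail = TRUE)
  per_participant <- attr(stat, "per_participant")
  attr(stat, "per_participant") <- NULL
  null <- t(vapply(seq_len(n_perm), function(b) delta_stat(perm_indices[[b]]),
                   numeric(n_sl)))
  p <- vapply(seq_along(stat), function(j) perm_pvalue(stat[j], null[, j]),
              numeric(1))
  map <- brain_map(stat, p, q_threshold)
  intersection <- NULL
  if (!is.null(composite_map))
    intersection <- map$sig & map$stat > 0 &
      composite_map$sig & composite_map$stat > 0
  list(map = map, null = null, intersection = intersection,
       per_participant = per_participant)
}

#' Contrast between two composite maps with paired permutations
#'
#' Subtracts the partial-correlation composite from the raw composite per
#' searchlight; the null distribution is the difference of the paired
#' permutation statistics (both analyses must have used the same
#' permutation stream), with two-sided permutation p-values and BH-FDR.
#'
#' @param raw_stat,partial_stat Composite statistics per searchlight.
#' @param raw_null,partial_null Matching n_perm x n_searchlight null
#'   matrices from paired permutations.
#' @param q_threshold FDR level (default 0.05).
#' @return A `brain_map` of differences.
#' @export
map_contrast <- function(raw_stat, raw_null, partial_stat, partial_null,
                         q_threshold = 0.05) {
  if (!all(dim(raw_null) == dim(partial_null)))
    stop("unpaired permutations: null dimensions differ")
  diff <- raw_stat - partial_stat
  null <- raw_null - partial_null
  p <- vapply(seq_along(diff), function(j) perm_pvalue(diff[j], null[, j]),
              numeric(1))
  brain_map(diff, p, q_threshold)
}

#' Full scaffold analysis: raw, partial, contrast and delta maps
#'
#' Runs [reliability_reinstatement_map()], [partial_correlation_map()],
#' [map_contrast()] and [participant_specific_delta()] on a shared
#' permutation stream so the contrast uses paired permutations.
#'
#' @inheritParams partial_correlation_map
#' @return List with `raw`, `partial`, `contrast`, `delta`.
#' @export
scaffold_analysis <- function(rel, scores, covars, n_perm = 1000, seed,
                              q_threshold = 0.05, min_rooms = 4L) {
  if (missing(seed)) stop("`seed` is required")
  perms <- make_perm_indices(n_perm, dim(rel)[1], dim(rel)[3], seed)
  raw <- reliability_reinstatement_map(rel, scores, n_perm,
                                       q_threshold = q_threshold,
                                       min_rooms = min_rooms,
                                       perm_indices = perms)
  partial <- partial_correlation_map(rel, scores, covars, n_perm,
                                     q_threshold = q_threshold,
                                     min_rooms = min_rooms,
                                     perm_indices = perms)
  contrast <- map_contrast(raw$map$stat, raw$null, partial$stat,
                           partial$null, q_threshold)
  delta <- participant_specific_delta(rel, scores, n_perm,
                                      q_threshold = q_threshold,
                                      min_rooms = min_rooms,
                                      perm_indices = perms,
                                      composite_map = raw$map)
  list(raw = raw, partial = partial, contrast = contrast, delta = delta)
}
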