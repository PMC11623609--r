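#' Build an HRF-convolved design matrix from an event matrix
#'
#' For each condition, forms the TR-resolution boxcar indicator from the
#' event matrix, convolves it with the canonical double-gamma HRF sampled at
#' the TR, and z-scores the resulting column. Conditions that never occur
#' yield an all-zero column and a warning.
#'
#' @param events An `event_matrix` (see [events_from_segments()]).
#' @param n_conditions Number of modeled conditions (columns).
#' @param hrf_params Optional named list overriding [canonical_hrf()]
#'   parameters (`peak`, `undershoot`, `ratio`, `duration`).
#' @return A `design_matrix`: list with `data` (TR x condition matrix,
#'   z-scored columns), `condition_ids`, `zero_columns` (integer ids of
#'   degenerate conditions), `tr_seconds`, `hrf_params`.
#' @export
build_design_matrix <- function(events, n_conditions, hrf_params = list()) {
  stopifnot(inherits(events, "event_matrix"))
  n_tr <- events$n_tr
  X <- matrix(0, n_tr, n_conditions)
  for (c in seq_len(n_conditions)) {
    box <- as.numeric(!is.na(events$labels) & events$labels == c)
    if (any(box > 0)) X[, c] <- hrf_convolve(box, events$tr_seconds, hrf_params)
  }
  Xz <- zscore_cols(X)
  zero_cols <- attr(Xz, "degenerate")
  attr(Xz, "degenerate") <- NULL
  if (length(zero_cols) > 0)
    warning("condition(s) absent from events; all-zero design column(s): ",
            paste(zero_cols, collapse = ", "))
  structure(list(data = Xz, condition_ids = seq_len(n_conditions),
                 zero_columns = zero_cols, tr_seconds = events$tr_seconds,
                 hrf_params = hrf_params),
            class = "design_matrix")
}

# OLS of Y (TR x vertex) on X (TR x condition); zero columns excluded from
# the fit and returned as NA rows; rank deficiency among non-zero columns is
# an error naming the collinear conditions.
#' @keywords internal
#' @noRd
ols_patterns <- function(X, Y) {
  nz <- which(colSums(abs(X)) > 0)
  B <- matrix(NA_real_, ncol(X), ncol(Y))
  if (length(nz) > 0) {
    Xn <- X[, nz, drop = FALSE]
    qrx <- qr(Xn)
    if (qrx$rank < ncol(Xn)) {
      bad <- nz[qrx$pivot[(qrx$rank + 1):ncol(Xn)]]
      stop("rank-deficient design: collinear condition(s) ",
           paste(bad, collapse = ", "))
    }
    B[nz, ] <- qr.coef(qrx, Y)
  }
  B
}

#' Fit condition templates by ordinary least squares
#'
#' Extracts the characteristic spatial pattern of each condition by fitting,
#' for every vertex, an OLS regression of its timeseries on the HRF-convolved
#' design. With `run_scope = "joint"` all runs are concatenated and a single
#' template set is returned (the procedure used for object templates, fitted
#' simultaneously across both object-video runs); with
#' `run_scope = "per-run"` each run is fitted separately and a list of
#' template sets is returned (the procedure used for room templates, one set
#' per pre-learning room-video run).
#'
#' @param timeseries A TR x vertex matrix, or a list of such matrices (one
#'   per run). Vertex columns are expected to be z-scored per run.
#' @param design A `design_matrix` (or bare matrix), or a list of them
#'   parallel to `timeseries`.
#' @param run_scope `"joint"` or `"per-run"`.
#' @return A `template_set` — list with `patterns` (condition x vertex
#'   matrix; `NA` rows for conditions absent from the design), `run_scope` —
#'   or a list of `template_set` objects for `run_scope = "per-run"`.
#' @export
fit_templates <- function(timeseries, design,
                          run_scope = c("joint", "per-run")) {
  run_scope <- match.arg(run_scope)
  as_mat <- function(d) if (inherits(d, "design_matrix")) d$data else as.matrix(d)
  if (!is.list(timeseries) || is.matrix(timeseries)) timeseries <- list(timeseries)
  if (inherits(design, "design_matrix") || is.matrix(design)) design <- list(design)
  stopifnot(length(timeseries) == length(design))
  for (i in seq_along(timeseries)) {
    if (nrow(as_mat(design[[i]])) != nrow(timeseries[[i]]))
      stop("design rows must match timeseries rows (run ", i, ")")
  }
  one <- function(X, Y) {
    structure(list(patterns = ols_patterns(X, Y), run_scope = run_scope),
              class = "template_set")
  }
  if (run_scope == "joint") {
    one(do.call(rbind, lapply(design, as_mat)), do.call(rbind, timeseries))
  } else {
    lapply(seq_along(timeseries),
           function(i) one(as_mat(design[[i]]), timeseries[[i]]))
  }
}

#' @export
print.template_set <- function(x, ...) {
  cat("<template_set> ", nrow(x$patterns), " conditions x ",
      ncol(x$patterns), " vertices (", x$run_scope, ")\n", sep = "")
  invisible(x)
}
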