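#' Classifier specification
#'
#' Settings for the leave-one-participant-out multinomial logistic
#' classifier, fixed across folds and recorded with outputs.
#'
#' @param regularization_strength L2 (ridge) penalty passed to the fitting
#'   backend. Default 0.01.
#' @param max_iter Maximum optimizer iterations. Default 1e5.
#' @param feature_standardization Standardize vertex features before
#'   fitting. Default TRUE.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(regularization_strength = 0.01, max_iter = 1e5,
                            feature_standardization = TRUE) {
  stopifnot(regularization_strength >= 0, max_iter > 0)
  structure(list(regularization_strength = regularization_strength,
                 max_iter = max_iter,
                 feature_standardization = feature_standardization),
            class = "classifier_spec")
}

#' Train a multinomial logistic classifier on condition templates
#'
#' Training samples are the template rows of the N-1 training participants
#' (one row per condition per template set), labeled by condition id. The
#' model is an L2-penalized multinomial logistic regression (ridge,
#' `alpha = 0`, fixed penalty) fitted with glmnet; prediction uses the
#' extracted coefficient matrix directly (softmax over linear scores), so
#' the fitted model is a plain weight matrix.
#'
#' @param template_sets List of `template_set` objects (one or more per
#'   training participant, all with the same condition ordering and vertex
#'   dimension).
#' @param spec A [classifier_spec()].
#' @return A `palace_classifier`: list with `weights` (class x (1+vertex)
#'   matrix, first column the intercept), `classes`, `spec`.
#' @export
train_classifier <- function(template_sets, spec = classifier_spec()) {
  if (length(template_sets) < 2)
    stop("need template sets from at least 2 training participants")
  pats <- lapply(template_sets, function(ts)
    if (inherits(ts, "template_set")) ts$patterns else as.matrix(ts))
  n_class <- nrow(pats[[1]])
  x <- do.call(rbind, pats)
  y <- rep(seq_len(n_class), times = length(pats))
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  if (!all(seq_len(n_class) %in% y))
    stop("class(es) missing from the training set: ",
         paste(setdiff(seq_len(n_class), y), collapse = ", "))
  # constant features carry no class information; exclude them from the fit
  # (weight 0) and fall back to an intercept-only model if none remain
  varying <- which(apply(x, 2, stats::sd) > 0)
  if (length(varying) == 0) {
    W <- cbind(log(as.numeric(table(factor(y, levels = seq_len(n_class))))),
               matrix(0, n_class, ncol(x)))
    return(palace_classifier(W, classes = seq_len(n_class), spec = spec))
  }
  # glmnet is unreliable when handed a single lambda; fit a short decreasing
  # path ending at the requested penalty and extract coefficients there
  lam <- spec$regularization_strength * c(64, 16, 4, 2, 1)
  fit <- withCallingHandlers(
    glmnet::glmnet(x[, varying, drop = FALSE],
                   factor(y, levels = seq_len(n_class)),
                   family = "multinomial", alpha = 0, lambda = lam,
                   standardize = spec$feature_standardization,
                   maxit = spec$max_iter),
    warning = function(w) {
      # one observation per class per training participant is the design;
      # glmnet flags small classes every time, which is expected here
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit, s = spec$regularization_strength)
  W <- matrix(0, n_class, ncol(x) + 1)
  Wv <- t(vapply(co, function(b) as.numeric(b), numeric(length(varying) + 1)))
  W[, 1] <- Wv[, 1]
  W[, varying + 1L] <- Wv[, -1, drop = FALSE]
  palace_classifier(W, classes = seq_len(n_class), spec = spec)
}

#' @param weights Class x (1 + n_vertex) weight matrix, first column the
#'   intercept.
#' @param classes Class ids (defaults to row indices).
#' @rdname train_classifier
#' @export
palace_classifier <- function(weights, classes = seq_len(nrow(weights)),
                              spec = NULL) {
  weights <- as.matrix(weights)
  structure(list(weights = weights, classes = classes, spec = spec),
            class = "palace_classifier")
}

#' @export
print.palace_classifier <- function(x, ...) {
  cat("<palace_classifier> ", nrow(x$weights), " classes, ",
      ncol(x$weights) - 1, " features\n", sep = "")
  invisible(x)
}

#' Per-TR class-evidence timeseries from a trained classifier
#'
#' Applies the classifier to a (z-scored) vertex timeseries and returns the
#' class-probability distribution at every event TR. The event-to-signal
#' alignment approximates the HRF delay: the probability assigned to event
#' TR `t` is computed from the signal at TR `t + hrf_shift_tr` (study
#' default: 4 TRs of 1.3 s). Trailing event TRs with no shifted signal are
#' dropped; the count is recorded in the `n_dropped` attribute.
#'
#' @param model A `palace_classifier`.
#' @param timeseries TR x vertex matrix matching the model's feature
#'   dimension.
#' @param hrf_shift_tr Non-negative integer shift in TRs. Default 4.
#' @return Matrix (`evidence_timeseries`) of size (n_tr - shift) x n_class;
#'   rows sum to 1.
#' @export
predict_evidence <- function(model, timeseries, hrf_shift_tr = 4L) {
  stopifnot(inherits(model, "palace_classifier"), hrf_shift_tr >= 0)
  X <- as.matrix(timeseries)
  if (ncol(X) != ncol(model$weights) - 1)
    stop("timeseries vertex dimension does not match the classifier")
  if (nrow(X) <= hrf_shift_tr)
    stop("timeseries shorter than the HRF shift of ", hrf_shift_tr, " TRs")
  n_ev <- nrow(X) - hrf_shift_tr
  Xs <- X[seq_len(n_ev) + hrf_shift_tr, , drop = FALSE]
  scores <- cbind(1, Xs) %*% t(model$weights)
  scores <- scores - apply(scores, 1, max) # numerical stability
  P <- exp(scores)
  P <- P / rowSums(P)
  colnames(P) <- model$classes
  structure(P, class = c("evidence_timeseries", class(P)),
            hrf_shift_tr = as.integer(hrf_shift_tr),
            n_dropped = as.integer(hrf_shift_tr))
}

#' Classification accuracy of an evidence timeseries against event labels
#'
#' Over labeled event TRs only: the predicted class is the argmax of the
#' probability row (ties broken toward the lowest class id); accuracy is the
#' fraction of labeled TRs predicted correctly.
#'
#' @param evidence Evidence matrix from [predict_evidence()] (n_ev x
#'   n_class).
#' @param events An `event_matrix`; only its first `nrow(evidence)` TRs are
#'   used (the evidence rows are aligned to event TRs 1..n_ev).
#' @return Accuracy in `[0, 1]`, or `NaN` if no TR is labeled.
#' @export
score_accuracy <- function(evidence, events) {
  P <- as.matrix(evidence)
  labels <- events$labels[seq_len(min(nrow(P), events$n_tr))]
  P <- P[seq_along(labels), , drop = FALSE]
  keep <- !is.na(labels)
  if (!any(keep)) return(NaN)
  pred <- max.col(P[keep, , drop = FALSE], ties.method = "first")
  mean(pred == labels[keep])
}

#' Contiguity-preserving permutation null for classification accuracy
#'
#' Decomposes the event label sequence into maximal contiguous segments of
#' identical labels (unlabeled stretches stay fixed), then, per permutation,
#' reassigns the segments' class identities by a uniform random permutation
#' without replacement — segment boundaries and lengths are preserved — and
#' recomputes accuracy against the same evidence.
#'
#' @inheritParams score_accuracy
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Numeric vector of `n_perm` null accuracies.
#' @export
contiguity_null <- function(evidence, events, n_perm = 1000, seed) {
  if (missing(seed)) stop("`seed` is required")
  P <- as.matrix(evidence)
  n_ev <- min(nrow(P), events$n_tr)
  labels <- events$labels[seq_len(n_ev)]
  enc <- ifelse(is.na(labels), 0L, labels)
  runs <- rle(enc)
  seg_idx <- which(runs$values > 0L)
  if (length(seg_idx) < 2)
    stop("need at least 2 contiguous labeled segments for the null")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev <- list(n_tr = n_ev, labels = labels)
  class(ev) <- "event_matrix"
  with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      new_vals <- runs$values
      new_vals[seg_idx] <- runs$values[seg_idx][sample.int(length(seg_idx))]
      lab <- labels
      for (i in seg_idx) lab[starts[i]:ends[i]] <- new_vals[i]
      ev$labels <- lab
      score_accuracy(P, ev)
    }, numeric(1))
  })
}

#' Select a top-k classifier network from unit accuracies
#'
#' Candidate units (all searchlights plus hippocampus ROIs) are ranked by
#' the z-score of their true classification accuracy against their
#' permutation null — `z = (true - mean(null)) / sd(null)` — with true
#' accuracies and null distributions averaged across participants and runs
#' upstream, in the same way. The top `k` units form the network.
#'
#' @param true_accuracy Numeric vector of per-unit accuracies.
#' @param null_accuracy n_perm x n_unit matrix of per-unit null accuracies
#'   (element-wise averaged across participants/runs like `true_accuracy`).
#' @param k Network size (study design: 50).
#' @param name Optional network label (`"ROCN"`, `"POCN"`, `"RRCN"`).
#' @return A `network_mask`: list with `name`, `members` (k unit ids, ties
#'   broken toward the lowest id), `zscores` (all units).
#' @export
select_network <- function(true_accuracy, null_accuracy, k = 50,
                           name = NULL) {
  null_accuracy <- as.matrix(null_accuracy)
  n_unit <- length(true_accuracy)
  stopifnot(ncol(null_accuracy) == n_unit, k >= 1, k <= n_unit)
  mu <- colMeans(null_accuracy)
  sd <- apply(null_accuracy, 2, stats::sd)
  z <- (true_accuracy - mu) / sd
  if (any(sd == 0)) {
    warning("null sd is 0 for ", sum(sd == 0), " unit(s); excluded")
    z[sd == 0] <- -Inf
  }
  members <- order(-z, seq_len(n_unit))[seq_len(k)]
  structure(list(name = name, members = sort(members), zscores = z, k = k),
            class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  cat("<network_mask> ", x$name %||% "unnamed", ": ", length(x$members),
      " units\n", sep = "")
  invisible(x)
}

#' Reinstatement scores from recall-period classifier evidence
#'
#' For each class `c`, pools every event TR — across all supplied runs —
#' where the condition `label_map[c]` (default `c` itself) was being
#' verbally recalled with event kind `kind`, takes the mean probability of
#' class `c` over those TRs within each network unit, and averages across
#' units. With `kind = "object"` and the identity map this is the object
#' reinstatement score; with a room classifier, `kind = "room"` gives
#' room-recall room evidence, and `label_map = pairing` (room to paired
#' object) gives object-recall room evidence.
#'
#' @param evidence_by_unit List over network units; each element a list over
#'   recall runs of evidence matrices from [predict_evidence()].
#' @param events_by_run List of `event_matrix` objects, parallel to the
#'   per-unit run lists (guided runs are pooled by passing all 11 together;
#'   free recall is scored separately).
#' @param kind Event kind whose TRs are pooled: `"object"` or `"room"`.
#' @param label_map Optional integer vector mapping class id to the event
#'   label to pool over (default: identity).
#' @return Numeric vector of per-class scores in `[0, 1]`; `NaN` for classes
#'   never recalled.
#' @export
reinstatement_scores <- function(evidence_by_unit, events_by_run,
                                 kind = c("object", "room"),
                                 label_map = NULL) {
  kind <- match.arg(kind)
  n_class <- ncol(as.matrix(evidence_by_unit[[1]][[1]]))
  label_map <- label_map %||% seq_len(n_class)
  n_runs <- length(events_by_run)
  out <- rep(NaN, n_class)
  # recall-TR index per run, per target label
  tr_sets <- lapply(seq_len(n_runs), function(r) {
    ev <- events_by_run[[r]]
    n_ev <- min(ev$n_tr, nrow(as.matrix(evidence_by_unit[[1]][[r]])))
    lab <- ev$labels[seq_len(n_ev)]
    knd <- ev$kinds[seq_len(n_ev)]
    lapply(seq_len(n_class), function(c)
      which(!is.na(lab) & lab == label_map[c] & knd == kind))
  })
  for (c in seq_len(n_class)) {
    per_unit <- vapply(evidence_by_unit, function(runs) {
      vals <- unlist(lapply(seq_len(n_runs), function(r) {
        trs <- tr_sets[[r]][[c]]
        if (length(trs) == 0) numeric(0)
        else as.matrix(runs[[r]])[trs, c]
      }))
      if (length(vals) == 0) NaN else mean(vals)
    }, numeric(1))
    out[c] <- mean(per_unit)
  }
  out
}
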