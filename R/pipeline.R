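# Dataset-level wrappers tying the modules together on a synthetic_dataset.

# per-run room design matrices for one participant
#' @keywords internal
#' @noRd
run_design <- function(run, n_conditions) {
  suppressWarnings(build_design_matrix(run$events, n_conditions))
}

#' Measured room reliability for every participant and searchlight
#'
#' Fits per-run room templates on the two pre-learning room-video runs (OLS
#' on the HRF-convolved design, all vertices at once), then computes the
#' cross-run similarity matrix and reliability scores within each
#' searchlight.
#'
#' @param dataset A `synthetic_dataset` whose `room_video` runs carry
#'   neural data.
#' @return Array participant x searchlight x room of reliability scores.
#' @export
room_reliability_by_searchlight <- function(dataset) {
  cf <- dataset$config
  n_sub <- cf$n_participants
  n_rooms <- cf$n_rooms
  blocks <- dataset$searchlights
  rel <- array(NA_real_, c(n_sub, length(blocks), n_rooms))
  for (s in seq_len(n_sub)) {
    r1 <- dataset$runs[[s]]$room_pre_1
    r2 <- dataset$runs[[s]]$room_pre_2
    if (is.null(r1$data) || is.null(r2$data))
      stop("room_video runs carry no neural data; simulate with ",
           "tasks including 'room_video'")
    ts <- fit_templates(list(r1$data, r2$data),
                        list(run_design(r1, n_rooms), run_design(r2, n_rooms)),
                        run_scope = "per-run")
    for (j in seq_along(blocks)) {
      S <- suppressWarnings(
        similarity_matrix(ts[[1]]$patterns[, blocks[[j]], drop = FALSE],
                          ts[[2]]$patterns[, blocks[[j]], drop = FALSE]))
      rel[s, j, ] <- reliability_scores(S)
    }
  }
  rel
}

#' Condition templates per participant for decoding
#'
#' Object templates are fitted jointly across both post-learning
#' object-video runs (a single set per participant); room templates are
#' fitted per run on the two pre-learning room-video runs (two sets per
#' participant, both returned as training material).
#'
#' @param dataset A `synthetic_dataset` with neural data for the relevant
#'   runs.
#' @param kind `"object"` or `"room"`.
#' @return List over participants; each element a list of `template_set`
#'   objects (length 1 for objects, 2 for rooms).
#' @export
condition_templates <- function(dataset, kind = c("object", "room")) {
  kind <- match.arg(kind)
  cf <- dataset$config
  n_cond <- cf$n_rooms
  lapply(seq_len(cf$n_participants), function(s) {
    if (kind == "object") {
      r1 <- dataset$runs[[s]]$object_post_1
      r2 <- dataset$runs[[s]]$object_post_2
      list(fit_templates(list(r1$data, r2$data),
                         list(run_design(r1, n_cond), run_design(r2, n_cond)),
                         run_scope = "joint"))
    } else {
      r1 <- dataset$runs[[s]]$room_pre_1
      r2 <- dataset$runs[[s]]$room_pre_2
      fit_templates(list(r1$data, r2$data),
                    list(run_design(r1, n_cond), run_design(r2, n_cond)),
                    run_scope = "per-run")
    }
  })
}

# subset a per-participant template list to one unit's vertices
#' @keywords internal
#' @noRd
subset_templates <- function(templates, vertices) {
  lapply(templates, function(per_sub)
    lapply(per_sub, function(ts)
      structure(list(patterns = ts$patterns[, vertices, drop = FALSE],
                     run_scope = ts$run_scope), class = "template_set")))
}

#' Leave-one-participant-out unit accuracies with contiguity nulls
#'
#' For every candidate unit (searchlight vertex set) and every held-out
#' participant, trains the multinomial classifier on the other participants'
#' templates restricted to that unit, predicts class evidence on the
#' held-out participant's test runs, and scores accuracy against the run's
#' event labels, together with the contiguity-preserving permutation null.
#' True accuracies and null distributions are averaged element-wise across
#' participants and runs.
#'
#' @param dataset A `synthetic_dataset`.
#' @param units List of integer vertex vectors (candidate units).
#' @param train_kind `"object"` (object templates; ROCN/POCN wiring) or
#'   `"room"` (pre-learning room templates; RRCN wiring).
#' @param test_task Task whose runs are decoded: `"room_recall"` (ROCN),
#'   `"object_video"` (POCN and RRCN) or `"room_video"`.
#' @param spec A [classifier_spec()].
#' @param n_perm Permutations for the null (default 200).
#' @param seed Integer seed.
#' @param hrf_shift_tr Event-to-signal shift in TRs (default 4).
#' @return List with `true` (per-unit mean accuracy) and `null` (n_perm x
#'   n_unit matrix of element-wise averaged null accuracies).
#' @export
lopo_unit_accuracy <- function(dataset, units,
                               train_kind = c("object", "room"),
                               test_task = c("room_recall", "object_video",
                                             "room_video"),
                               spec = classifier_spec(), n_perm = 200,
                               seed, hrf_shift_tr = 4L) {
  train_kind <- match.arg(train_kind)
  test_task <- match.arg(test_task)
  if (missing(seed)) stop("`seed` is required")
  cf <- dataset$config
  n_sub <- cf$n_participants
  templates <- condition_templates(dataset, kind = train_kind)
  # test-run event labels: what the decoder should recover
  test_events <- function(s, run) {
    ev <- run$events
    if (train_kind == "object" && test_task %in% c("room_recall",
                                                   "room_video")) {
      # decode the covertly recalled object while its room is on screen
      ev$labels <- dataset$pairings[[s]][ev$labels]
    } else if (train_kind == "room" && test_task == "object_video") {
      # decode the covertly recalled room while its object is on screen
      ev$labels <- order(dataset$pairings[[s]])[ev$labels]
    }
    ev
  }
  n_unit <- length(units)
  true_sum <- rep(0, n_unit)
  null_sum <- matrix(0, n_perm, n_unit)
  n_avg <- 0L
  for (s in seq_len(n_sub)) {
    test_runs <- Filter(function(r) identical(r$task, test_task),
                        dataset$runs[[s]])
    for (run in test_runs) {
      if (is.null(run$data)) stop("test runs carry no neural data")
      ev <- test_events(s, run)
      n_avg <- n_avg + 1L
      for (u in seq_len(n_unit)) {
        tr <- subset_templates(templates[-s], units[[u]])
        model <- train_classifier(unlist(tr, recursive = FALSE), spec)
        evid <- predict_evidence(model, run$data[, units[[u]], drop = FALSE],
                                 hrf_shift_tr)
        true_sum[u] <- true_sum[u] + score_accuracy(evid, ev)
        null_sum[, u] <- null_sum[, u] +
          contiguity_null(evid, ev, n_perm,
                          seed = seed + 7L * s + 131L * u + run$run)
      }
    }
  }
  list(true = true_sum / n_avg, null = null_sum / n_avg)
}

#' Recall-period evidence for a network's units
#'
#' Trains one leave-one-participant-out classifier per network unit and
#' held-out participant and applies it to the participant's recall runs of
#' the given task type.
#'
#' @inheritParams lopo_unit_accuracy
#' @param task `"guided"` (all 11 runs) or `"free"`.
#' @return List over participants; each a list over units; each a list over
#'   recall runs of evidence matrices, plus attribute `events` (list over
#'   participants of the runs' event matrices).
#' @export
recall_evidence <- function(dataset, units,
                            train_kind = c("object", "room"),
                            task = c("guided", "free"),
                            spec = classifier_spec(), hrf_shift_tr = 4L) {
  train_kind <- match.arg(train_kind)
  task <- match.arg(task)
  cf <- dataset$config
  templates <- condition_templates(dataset, kind = train_kind)
  out <- vector("list", cf$n_participants)
  events <- vector("list", cf$n_participants)
  for (s in seq_len(cf$n_participants)) {
    recall_runs <- Filter(function(r) identical(r$task, task),
                          dataset$runs[[s]])
    events[[s]] <- lapply(recall_runs, function(r) r$events)
    out[[s]] <- lapply(units, function(vv) {
      tr <- subset_templates(templates[-s], vv)
      model <- train_classifier(unlist(tr, recursive = FALSE), spec)
      lapply(recall_runs, function(run) {
        if (is.null(run$data)) stop("recall runs carry no neural data")
        predict_evidence(model, run$data[, vv, drop = FALSE], hrf_shift_tr)
      })
    })
  }
  attr(out, "events") <- events
  out
}

#' Room-aligned pair-table inputs from the generator's truth table
#'
#' Builds the `scores` and `covars` structures consumed by the scaffold-map
#' functions directly from the planted reinstatement amplitudes: the object
#' reinstatement score of room `r` for participant `s` is the planted
#' amplitude of the object paired to `r`, set to `NaN` when that object was
#' never verbally recalled in the task's transcripts; covariates are the
#' emitted room-reinstatement measurements.
#'
#' @param dataset A `synthetic_dataset`.
#' @return List with `scores` (list `guided`, `free` of participant x room
#'   matrices) and `covars` (parallel list of `room` / `object` covariate
#'   matrices).
#' @export
truth_pair_inputs <- function(dataset) {
  cf <- dataset$config
  n_sub <- cf$n_participants
  n_rooms <- cf$n_rooms
  tr <- dataset$truth
  get <- function(col) {
    m <- matrix(NA_real_, n_sub, n_rooms)
    m[cbind(tr$participant, tr$room)] <- tr[[col]]
    m
  }
  a_guided <- get("a_guided")
  a_free <- get("a_free")
  for (s in seq_len(n_sub)) {
    rec_g <- unique(unlist(lapply(dataset$transcripts[[s]]$guided,
                                  function(seg) seg$label[seg$kind == "object"])))
    fr <- dataset$transcripts[[s]]$free
    rec_f <- unique(fr$label[fr$kind == "object"])
    room_of_object <- order(dataset$pairings[[s]])
    miss_g <- setdiff(seq_len(n_rooms), room_of_object[rec_g])
    miss_f <- setdiff(seq_len(n_rooms), room_of_object[rec_f])
    a_guided[s, miss_g] <- NaN
    a_free[s, miss_f] <- NaN
  }
  list(
    scores = list(guided = a_guided, free = a_free),
    covars = list(
      guided = list(room = get("rrcn_room_guided"),
                    object = get("rrcn_obj_guided")),
      free = list(room = get("rrcn_room_free"),
                  object = get("rrcn_obj_free")))
  )
}
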