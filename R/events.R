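#' Transcript segments and TR-resolution event matrices
#'
#' Recall transcripts and stimulus schedules are represented as *segments*:
#' data frames with columns `label` (1-based condition id), `kind`
#' (`"room"` or `"object"`), `onset` and `offset` (seconds, `offset > onset`).
#' [events_from_segments()] downsamples segments to the TR grid using the
#' midpoint rule: TR `t` (0-based, covering `[t*TR, (t+1)*TR)`) receives the
#' label of the segment containing the TR midpoint, and no label if no
#' segment covers the midpoint. Segments of the same kind may not overlap;
#' where segments of different kinds cover the same midpoint the
#' most recent (later-onset) segment wins, ties going to the object segment.
#'
#' @param segments Data frame of segments (may have zero rows).
#' @param tr_seconds TR duration in seconds.
#' @param n_tr Number of TRs in the target grid.
#' @return An `event_matrix`: list with `n_tr`, `tr_seconds`, `labels`
#'   (integer, `NA` = no condition) and `kinds` (character, `NA` = none).
#' @examples
#' seg <- data.frame(label = 3, kind = "room", onset = 0, offset = 2.6)
#' ev <- events_from_segments(seg, tr_seconds = 1.3, n_tr = 4)
#' ev$labels # 3 3 NA NA
#' @export
events_from_segments <- function(segments, tr_seconds, n_tr) {
  stopifnot(tr_seconds > 0, n_tr >= 0)
  segments <- as.data.frame(segments)
  labels <- rep(NA_integer_, n_tr)
  kinds <- rep(NA_character_, n_tr)
  if (nrow(segments) > 0) {
    if (!all(segments$kind %in% c("room", "object")))
      stop("segment kind must be 'room' or 'object'")
    if (any(segments$offset <= segments$onset))
      stop("segments must have offset > onset")
    if (any(segments$offset > n_tr * tr_seconds + 1e-9))
      stop("segment offsets exceed the run duration n_tr * tr_seconds")
    mid <- (seq_len(n_tr) - 0.5) * tr_seconds
    onset_at <- rep(-Inf, n_tr)
    for (kind in c("room", "object")) {
      seg_k <- segments[segments$kind == kind, , drop = FALSE]
      claimed <- rep(FALSE, n_tr)
      for (i in seq_len(nrow(seg_k))) {
        hit <- mid >= seg_k$onset[i] & mid < seg_k$offset[i]
        if (any(hit & claimed)) {
          stop("overlapping segments of kind '", kind, "' at label(s) ",
               paste(unique(c(seg_k$label[i],
                              labels[hit & claimed])), collapse = ", "))
        }
        claimed <- claimed | hit
        # cross-kind: later onset wins; exact ties go to the object segment
        take <- hit & (seg_k$onset[i] > onset_at |
                         (seg_k$onset[i] == onset_at & kind == "object"))
        labels[take] <- as.integer(seg_k$label[i])
        kinds[take] <- kind
        onset_at[take] <- seg_k$onset[i]
      }
    }
  }
  structure(list(n_tr = as.integer(n_tr), tr_seconds = tr_seconds,
                 labels = labels, kinds = kinds),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat("<event_matrix> ", x$n_tr, " TRs @ ", x$tr_seconds, "s; ",
      sum(!is.na(x$labels)), " labeled\n", sep = "")
  invisible(x)
}

#' Block-design video schedule as an event matrix
#'
#' Builds the event matrix for a video run: each condition in `order` is
#' shown for `video_seconds` followed by `isi_seconds` of rest, and the
#' schedule is downsampled to TRs with the same midpoint rule as
#' [events_from_segments()].
#'
#' @param order Integer vector of condition ids in presentation order
#'   (possibly empty).
#' @param video_seconds,isi_seconds Video and inter-stimulus durations in
#'   seconds (study design: 10 s video, 5 s ISI).
#' @param tr_seconds TR duration in seconds (study design: 1.3 s).
#' @param kind Condition kind for all videos, `"room"` or `"object"`.
#' @param n_tr Grid length; defaults to the smallest grid containing the
#'   whole schedule.
#' @return An `event_matrix`.
#' @export
video_events <- function(order, video_seconds = 10, isi_seconds = 5,
                         tr_seconds = 1.3, kind = "room", n_tr = NULL) {
  stopifnot(video_seconds > 0, isi_seconds >= 0, tr_seconds > 0)
  n <- length(order)
  total <- n * (video_seconds + isi_seconds)
  n_tr <- n_tr %||% ceiling(total / tr_seconds)
  if (n == 0) return(events_from_segments(data.frame(), tr_seconds, n_tr))
  seg <- data.frame(
    label = as.integer(order),
    kind = kind,
    onset = (seq_len(n) - 1) * (video_seconds + isi_seconds),
    offset = (seq_len(n) - 1) * (video_seconds + isi_seconds) + video_seconds
  )
  events_from_segments(seg, tr_seconds, n_tr)
}

#' Score a recall transcript for object recall accuracy
#'
#' Guided recall is scored out of the 5 objects paired (via `pairing`) to the
#' cued 5-room path; free recall out of all paired objects. An object counts
#' as recalled if its label appears in any object segment of the transcript,
#' regardless of order or of whether the associated room was also recalled.
#'
#' @param segments Transcript segment data frame (see
#'   [events_from_segments()]).
#' @param task `"guided"` or `"free"`.
#' @param cued_path Integer vector of cued room ids (required for guided;
#'   length 5 in the study design).
#' @param pairing Integer vector mapping room id to paired object id.
#' @return List with `n_correct`, `n_total`, `accuracy`, `task`.
#' @export
score_recall <- function(segments, task = c("guided", "free"),
                         cued_path = NULL, pairing) {
  task <- match.arg(task)
  segments <- as.data.frame(segments)
  recalled <- unique(segments$label[segments$kind == "object"])
  if (task == "guided") {
    if (is.null(cued_path)) stop("guided recall requires a cued_path")
    targets <- pairing[cued_path]
  } else {
    targets <- pairing
  }
  n_correct <- sum(targets %in% recalled)
  list(task = task, n_correct = as.integer(n_correct),
       n_total = length(targets), accuracy = n_correct / length(targets))
}

#' Per-condition speaking-time deviation test
#'
#' For each condition of the given kind, computes the across-participant mean
#' total speaking time and tests whether that condition's speaking time
#' deviates from each participant's grand mean (the average over all
#' conditions of the same kind): a one-sample t-test on the within-participant
#' deviations against zero, Bonferroni-corrected over conditions.
#'
#' @param transcripts List (one per participant) of segment data frames with
#'   all recall runs pooled.
#' @param kind `"room"` or `"object"`.
#' @param n_conditions Number of conditions; conditions never spoken get time
#'   0 (they are not dropped).
#' @return Data frame with one row per condition: `condition`,
#'   `mean_seconds`, `t`, `p`, `p_bonferroni`, `degenerate` (TRUE where the
#'   deviation variance is zero and the t-test is undefined).
#' @export
speaking_time_test <- function(transcripts, kind = c("room", "object"),
                               n_conditions) {
  kind <- match.arg(kind)
  n_sub <- length(transcripts)
  if (n_sub < 3) stop("speaking_time_test requires at least 3 participants")
  times <- matrix(0, n_sub, n_conditions)
  for (s in seq_len(n_sub)) {
    seg <- as.data.frame(transcripts[[s]])
    seg <- seg[seg$kind == kind, , drop = FALSE]
    if (nrow(seg) > 0) {
      agg <- tapply(seg$offset - seg$onset, factor(seg$label,
                                                   levels = seq_len(n_conditions)),
                    sum, default = 0)
      times[s, ] <- as.numeric(agg)
    }
  }
  dev <- times - rowMeans(times)
  out <- data.frame(condition = seq_len(n_conditions),
                    mean_seconds = colMeans(times),
                    t = NA_real_, p = NA_real_, p_bonferroni = NA_real_,
                    degenerate = FALSE)
  for (c in seq_len(n_conditions)) {
    d <- dev[, c]
    if (stats::sd(d) == 0) {
      out$degenerate[c] <- TRUE
    } else {
      tt <- stats::t.test(d, mu = 0)
      out$t[c] <- unname(tt$statistic)
      out$p[c] <- tt$p.value
      out$p_bonferroni[c] <- min(1, tt$p.value * n_conditions)
    }
  }
  out
}

#' Temporal contiguity of free-recall room transitions
#'
#' For each participant's ordered room-recall sequence (consecutive repeats
#' collapsed first), computes the proportion of transitions that land on a
#' room adjacent to the current room, and the per-participant chance level:
#' the mean over transitions of `degree(current) / (n_rooms - 1)`. Observed
#' and chance proportions are compared with a paired t-test across
#' participants.
#'
#' @param room_sequences List (one per participant) of integer room-id
#'   sequences in recall order.
#' @param graph A `palace_graph`.
#' @return List with `per_participant` (data frame: `observed`, `chance`),
#'   `t`, `p`, `n_excluded` (participants with fewer than 2 distinct
#'   consecutive rooms, dropped with a warning).
#' @export
contiguity_analysis <- function(room_sequences, graph) {
  n_rooms <- graph$n_rooms
  obs <- chance <- rep(NA_real_, length(room_sequences))
  for (s in seq_along(room_sequences)) {
    seq_s <- as.integer(room_sequences[[s]])
    seq_s <- seq_s[c(TRUE, diff(seq_s) != 0)] # collapse self-loops
    if (length(seq_s) < 2) next
    cur <- seq_s[-length(seq_s)]
    nxt <- seq_s[-1]
    obs[s] <- mean(graph$adjacency[cbind(cur, nxt)])
    chance[s] <- mean(graph$degree[cur] / (n_rooms - 1))
  }
  keep <- !is.na(obs)
  if (any(!keep))
    warning(sum(!keep), " participant(s) excluded: fewer than 2 distinct ",
            "consecutive rooms")
  tt <- if (sum(keep) >= 2 && stats::sd(obs[keep] - chance[keep]) > 0)
    stats::t.test(obs[keep], chance[keep], paired = TRUE) else NULL
  list(per_participant = data.frame(participant = seq_along(room_sequences),
                                    observed = obs, chance = chance),
       t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       p = if (is.null(tt)) NA_real_ else tt$p.value,
       n_excluded = sum(!keep))
}

#' Read / write transcript segments in a BIDS-events-style TSV dialect
#'
#' Columns: `onset` (s), `duration` (s), `trial_type` (condition id),
#' `event_kind` (`room` or `object`).
#'
#' @param segments Segment data frame (`label`, `kind`, `onset`, `offset`).
#' @param path TSV file path.
#' @export
write_events_tsv <- function(segments, path) {
  df <- data.frame(onset = segments$onset,
                   duration = segments$offset - segments$onset,
                   trial_type = segments$label,
                   event_kind = segments$kind)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  data.frame(label = as.integer(df$trial_type), kind = df$event_kind,
             onset = df$onset, offset = df$onset + df$duration)
}
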