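#' Simulation configuration for the synthetic memory-palace study
#'
#' Bundles and validates every parameter of the generative model. The
#' defaults reproduce the study design: 25 participants, a 23-room palace
#' with the 2/3/4-degree distribution, 1.3 s TRs, 10 s videos with 5 s ISI,
#' two pre-learning room-video runs, two post-learning object-video runs,
#' two room-video object-recall runs, 11 guided-recall runs and 1
#' free-recall run.
#'
#' The planted-effect model: per room `r` and participant `s`, reliability
#' `lambda = clip(lambda0 + g_r + u_sr, 0.01, 0.99)` with group component
#' `g_r ~ N(0, g_sd^2)` shared across participants and idiosyncratic
#' component `u_sr ~ N(0, u_sd^2)`; room reinstatement amplitude
#' `m = gamma * lambda + noise`; object reinstatement amplitude
#' `a = alpha + beta_direct * lambda + beta_mediated * m + noise` (drawn
#' independently per recall task type). Reliability enters the neural data
#' as a mixing weight: the run-k room pattern is
#' `sqrt(lambda) * P_sr + sqrt(1 - lambda) * fresh noise`, where
#' `P_sr = sqrt(1 - tau) * G_r + sqrt(tau) * eta_sr` mixes a group template
#' with participant idiosyncrasy `tau`.
#'
#' @param n_participants Number of participants (default 25).
#' @param n_rooms Number of rooms (default 23).
#' @param degree_sequence Palace degree sequence; default is the 16/6/1
#'   rooms of degree 2/3/4 when `n_rooms = 23`, else a ring.
#' @param vertices_per_searchlight,n_searchlights Synthetic searchlights are
#'   disjoint blocks of this many vertices (defaults 30 and 40).
#' @param signal_searchlight_fraction Fraction of searchlights carrying
#'   room/object structure; the rest are pure noise (default 0.25).
#' @param tr_seconds,video_seconds,isi_seconds Timing (defaults 1.3/10/5 s).
#' @param tau_idiosyncrasy Participant-idiosyncrasy share of template
#'   variance, in `[0, 1]` (default 0.3).
#' @param lambda0,g_sd,u_sd Reliability base level and component SDs
#'   (defaults 0.5/0.15/0.15).
#' @param alpha,beta_direct,beta_mediated,gamma Amplitude-model coefficients
#'   (defaults 0.3/0.6/0/0.8).
#' @param noise_sd Vertex noise SD of the BOLD-like signal (default 1).
#' @param amp_noise_sd SD of the amplitude-model noise terms (default 0.1).
#' @param covar_noise_sd Measurement noise SD of the emitted
#'   room-reinstatement covariates (default 0.02).
#' @param recall_prob Probability that a room (and, independently, its
#'   object) is verbally recalled in a recall run (default 0.95).
#' @param n_guided_runs Number of guided-recall runs (default 11).
#' @param path_length Rooms per guided cue path (default 5).
#' @param seed Integer seed; mandatory.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_participants = 25L, n_rooms = 23L,
                       degree_sequence = NULL,
                       vertices_per_searchlight = 30L, n_searchlights = 40L,
                       signal_searchlight_fraction = 0.25,
                       tr_seconds = 1.3, video_seconds = 10, isi_seconds = 5,
                       tau_idiosyncrasy = 0.3,
                       lambda0 = 0.5, g_sd = 0.15, u_sd = 0.15,
                       alpha = 0.3, beta_direct = 0.6, beta_mediated = 0,
                       gamma = 0.8,
                       noise_sd = 1, amp_noise_sd = 0.1,
                       covar_noise_sd = 0.02,
                       recall_prob = 0.95, n_guided_runs = 11L,
                       path_length = 5L, seed) {
  if (missing(seed)) stop("`seed` is mandatory in sim_config")
  shares <- c(signal_searchlight_fraction = signal_searchlight_fraction,
              tau_idiosyncrasy = tau_idiosyncrasy,
              recall_prob = recall_prob)
  if (any(shares < 0 | shares > 1))
    stop("variance shares / proportions must be in [0, 1]: ",
         paste(names(shares)[shares < 0 | shares > 1], collapse = ", "))
  if (any(c(tr_seconds, video_seconds) <= 0) || isi_seconds < 0)
    stop("durations must be positive")
  stopifnot(n_participants >= 2, n_rooms >= 2, vertices_per_searchlight >= 2,
            n_searchlights >= 1, noise_sd >= 0, amp_noise_sd >= 0,
            covar_noise_sd >= 0, g_sd >= 0, u_sd >= 0,
            n_guided_runs >= 1, path_length >= 1, path_length <= n_rooms)
  if (is.null(degree_sequence)) {
    degree_sequence <- if (n_rooms == 23L) c(rep(2L, 16), rep(3L, 6), 4L)
    else rep(2L, n_rooms)
  }
  stopifnot(length(degree_sequence) == n_rooms)
  structure(as.list(environment()), class = "sim_config")
}

#' Sample independent random room-object pairings
#'
#' Each participant receives their own uniform random bijection between
#' rooms and objects, reproducible per seed.
#'
#' @param n_rooms Number of rooms (= number of objects).
#' @param n_participants Number of participants (>= 2, as required by the
#'   leave-one-participant-out design).
#' @param seed Integer seed.
#' @return List of integer vectors; element `s` maps room id to the object
#'   id placed in it for participant `s`.
#' @export
sample_pairings <- function(n_rooms, n_participants, seed) {
  if (n_participants < 2)
    stop("need at least 2 participants (leave-one-out is undefined)")
  if (missing(seed)) stop("`seed` is required")
  with_seed(seed, lapply(seq_len(n_participants),
                         function(s) sample.int(n_rooms)))
}

#' Synthetic room feature table
#'
#' Generates per-room physical features alongside the graph-theoretic
#' degree: occupied-volume ratio, background object count, floor area,
#' corner count and a binary window indicator. Continuous features are
#' returned raw; [feature_regression()] expects them z-scored (binary
#' columns excepted).
#'
#' @param graph A `palace_graph`.
#' @param seed Integer seed.
#' @return Data frame with one row per room.
#' @export
room_features <- function(graph, seed) {
  if (missing(seed)) stop("`seed` is required")
  n <- graph$n_rooms
  with_seed(seed, data.frame(
    room = seq_len(n),
    degree = graph$degree,
    occupied_ratio = stats::runif(n, 0.1, 0.6),
    object_count = stats::rpois(n, 10),
    floor_area = stats::runif(n, 20, 80),
    corners = sample(4:8, n, replace = TRUE),
    has_window = stats::rbinom(n, 1, 0.5)
  ))
}

# self-avoiding random walk: `len` distinct, consecutively adjacent rooms
#' @keywords internal
#' @noRd
sample_path <- function(graph, len, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    path <- sample.int(graph$n_rooms, 1)
    while (length(path) < len) {
      nbrs <- setdiff(which(graph$adjacency[path[length(path)], ]), path)
      if (length(nbrs) == 0) break # dead end; restart
      path <- c(path, nbrs[sample.int(length(nbrs), 1)])
    }
    if (length(path) == len) return(path)
  }
  stop("failed to sample a connected path of length ", len)
}

# transcript for one recall run: for each room in `order`, a room segment
# then an object segment (each present with probability recall_prob),
# durations U(3, 10) s, gaps U(0.5, 2) s
#' @keywords internal
#' @noRd
sample_transcript <- function(order, pairing, recall_prob) {
  t <- 2
  rows <- list()
  for (r in order) {
    if (stats::runif(1) < recall_prob) {
      d <- stats::runif(1, 3, 10)
      rows[[length(rows) + 1L]] <- data.frame(label = r, kind = "room",
                                              onset = t, offset = t + d)
      t <- t + d + stats::runif(1, 0.5, 2)
    }
    if (stats::runif(1) < recall_prob) {
      d <- stats::runif(1, 3, 10)
      rows[[length(rows) + 1L]] <- data.frame(label = pairing[r],
                                              kind = "object",
                                              onset = t, offset = t + d)
      t <- t + d + stats::runif(1, 0.5, 2)
    }
  }
  if (length(rows) == 0) data.frame(label = integer(0), kind = character(0),
                                    onset = numeric(0), offset = numeric(0))
  else do.call(rbind, rows)
}

# 1-based vertex blocks of the synthetic searchlights
#' @keywords internal
#' @noRd
sim_searchlight_blocks <- function(config) {
  v <- config$vertices_per_searchlight
  lapply(seq_len(config$n_searchlights), function(k) ((k - 1L) * v + 1L):(k * v))
}

#' Simulate a full synthetic study dataset
#'
#' Generates the palace graph, pairings, room features, planted reliability
#' and reinstatement effects, recall transcripts, run schedules, and
#' (optionally) BOLD-like vertex timeseries for every run. Searchlights are
#' disjoint vertex blocks; only the configured signal subset carries room or
#' object structure, the rest are pure noise. Neural signal is the sum of
#' active condition patterns scaled by their amplitudes, convolved with the
#' canonical HRF at the TR, plus white vertex noise, then z-scored per
#' vertex per run.
#'
#' @param config A [sim_config()].
#' @param tasks Character subset of
#'   `c("room_video", "object_video", "room_recall", "guided", "free")`
#'   selecting which runs get neural data (schedules, transcripts and the
#'   truth table are always generated). Default: all.
#' @return A `synthetic_dataset` list: `config`, `graph`, `pairings`,
#'   `features`, `signal_searchlights`, `searchlights` (vertex blocks),
#'   `truth` (data frame of planted `lambda`, `m`, and `a` values plus
#'   emitted reinstatement covariates), `runs` (per participant, named list
#'   of runs with `task`, `data`, `events`, and for recall runs `segments`
#'   and `cued_path`), and `transcripts`.
#' @export
simulate_dataset <- function(config,
                             tasks = c("room_video", "object_video",
                                       "room_recall", "guided", "free")) {
  stopifnot(inherits(config, "sim_config"))
  # tasks = character(0) generates schedules, transcripts and truth only
  if (length(tasks) > 0) tasks <- match.arg(tasks, several.ok = TRUE)
  cf <- config
  n_sub <- cf$n_participants
  n_rooms <- cf$n_rooms
  V <- cf$vertices_per_searchlight
  n_sl <- cf$n_searchlights
  V_total <- V * n_sl

  graph <- build_palace_graph(cf$degree_sequence, seed = cf$seed)
  pairings <- sample_pairings(n_rooms, n_sub, seed = cf$seed + 1L)
  features <- room_features(graph, seed = cf$seed + 2L)

  with_seed(cf$seed + 3L, {
    n_signal <- max(1L, round(cf$signal_searchlight_fraction * n_sl))
    signal_sl <- sort(sample.int(n_sl, n_signal))
    blocks <- sim_searchlight_blocks(cf)
    sig_vertices <- unlist(blocks[signal_sl])
    n_sig_v <- length(sig_vertices)

    # planted reliability and amplitudes ---------------------------------
    g_r <- stats::rnorm(n_rooms, 0, cf$g_sd)
    u <- matrix(stats::rnorm(n_sub * n_rooms, 0, cf$u_sd), n_sub)
    lambda_raw <- cf$lambda0 + matrix(g_r, n_sub, n_rooms, byrow = TRUE) + u
    lambda <- pmin(pmax(lambda_raw, 0.01), 0.99)
    if (mean(lambda != lambda_raw) > 0.1)
      warning("reliability clipped at its bounds for more than 10% of rooms")
    m <- cf$gamma * lambda + matrix(stats::rnorm(n_sub * n_rooms, 0,
                                                 cf$amp_noise_sd), n_sub)
    a_of <- function() cf$alpha + cf$beta_direct * lambda +
      cf$beta_mediated * m +
      matrix(stats::rnorm(n_sub * n_rooms, 0, cf$amp_noise_sd), n_sub)
    a_guided <- a_of()
    a_free <- a_of()
    a_cued <- a_of() # room-video object-recall runs
    meas <- function() m + matrix(stats::rnorm(n_sub * n_rooms, 0,
                                               cf$covar_noise_sd), n_sub)
    rrcn_room_guided <- meas(); rrcn_obj_guided <- meas()
    rrcn_room_free <- meas(); rrcn_obj_free <- meas()

    # shared and participant templates (signal vertices only) ------------
    tau <- cf$tau_idiosyncrasy
    G <- matrix(stats::rnorm(n_sig_v * n_rooms), n_sig_v) # group room
    O <- matrix(stats::rnorm(n_sig_v * n_rooms), n_sig_v) # group object
    P <- lapply(seq_len(n_sub), function(s)
      sqrt(1 - tau) * G + sqrt(tau) * matrix(stats::rnorm(n_sig_v * n_rooms),
                                             n_sig_v))
    Q <- lapply(seq_len(n_sub), function(s)
      sqrt(1 - tau) * O + sqrt(tau) * matrix(stats::rnorm(n_sig_v * n_rooms),
                                             n_sig_v))

    run_pattern <- function(s, k_unused) {
      # fresh-noise room patterns for one room-video run
      lam <- matrix(lambda[s, ], n_sig_v, n_rooms, byrow = TRUE)
      sqrt(lam) * P[[s]] + sqrt(1 - lam) *
        matrix(stats::rnorm(n_sig_v * n_rooms), n_sig_v)
    }

    video_ntr <- ceiling(n_rooms * (cf$video_seconds + cf$isi_seconds) /
                           cf$tr_seconds) + 8L

    # neural assembly: amplitude boxcars (per condition) convolved with the
    # HRF, times pattern vectors, noise added, z-scored per vertex
    assemble <- function(comp_list, n_tr) {
      Y <- matrix(stats::rnorm(n_tr * V_total, 0, cf$noise_sd), n_tr, V_total)
      for (comp in comp_list) {
        # comp: list(course = n_tr amplitude vector, pattern = n_sig_v vector)
        conv <- hrf_convolve(comp$course, cf$tr_seconds)
        Y[, sig_vertices] <- Y[, sig_vertices] + outer(conv, comp$pattern)
      }
      Yz <- zscore_cols(Y)
      attr(Yz, "degenerate") <- NULL
      Yz
    }
    boxcar_from_events <- function(ev, label, kind, amp) {
      as.numeric(!is.na(ev$labels) & ev$labels == label &
                   ev$kinds == kind) * amp
    }

    truth <- do.call(rbind, lapply(seq_len(n_sub), function(s)
      data.frame(participant = s, room = seq_len(n_rooms),
                 object = pairings[[s]],
                 lambda = lambda[s, ], m = m[s, ],
                 a_guided = a_guided[s, ], a_free = a_free[s, ],
                 a_cued = a_cued[s, ],
                 rrcn_room_guided = rrcn_room_guided[s, ],
                 rrcn_obj_guided = rrcn_obj_guided[s, ],
                 rrcn_room_free = rrcn_room_free[s, ],
                 rrcn_obj_free = rrcn_obj_free[s, ])))

    runs <- vector("list", n_sub)
    transcripts <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      pr <- pairings[[s]]
      room_of_object <- order(pr) # inverse pairing: object id -> room id
      sub_runs <- list()

      # pre-learning room videos (2) and post-learning room-video object
      # recall (2): presented room at amplitude 1 with run-fresh patterns;
      # the post runs additionally carry covert object reinstatement
      for (k in 1:2) {
        for (post in c(FALSE, TRUE)) {
          ord <- sample.int(n_rooms)
          ev <- video_events(ord, cf$video_seconds, cf$isi_seconds,
                             cf$tr_seconds, kind = "room", n_tr = video_ntr)
          name <- if (post) sprintf("room_recall_%d", k)
          else sprintf("room_pre_%d", k)
          want <- if (post) "room_recall" else "room_video"
          data <- NULL
          if (want %in% tasks) {
            Rk <- run_pattern(s, k)
            comps <- lapply(seq_len(n_rooms), function(r)
              list(course = boxcar_from_events(ev, r, "room", 1),
                   pattern = Rk[, r]))
            if (post) {
              comps <- c(comps, lapply(seq_len(n_rooms), function(r)
                list(course = boxcar_from_events(ev, r, "room",
                                                 a_cued[s, r]),
                     pattern = Q[[s]][, pr[r]])))
            }
            data <- assemble(comps, video_ntr)
          }
          sub_runs[[name]] <- list(task = want, run = k, data = data,
                                   events = ev)
        }
      }

      # post-learning object videos (2): presented object at amplitude 1,
      # plus covert reinstatement of the paired room at amplitude m
      for (k in 1:2) {
        ord <- sample.int(n_rooms)
        ev <- video_events(ord, cf$video_seconds, cf$isi_seconds,
                           cf$tr_seconds, kind = "object", n_tr = video_ntr)
        data <- NULL
        if ("object_video" %in% tasks) {
          comps <- c(
            lapply(seq_len(n_rooms), function(o)
              list(course = boxcar_from_events(ev, o, "object", 1),
                   pattern = Q[[s]][, o])),
            lapply(seq_len(n_rooms), function(o)
              list(course = boxcar_from_events(ev, o, "object",
                                               m[s, room_of_object[o]]),
                   pattern = P[[s]][, room_of_object[o]])))
          data <- assemble(comps, video_ntr)
        }
        sub_runs[[sprintf("object_post_%d", k)]] <-
          list(task = "object_video", run = k, data = data, events = ev)
      }

      # recall runs: 11 guided + 1 free ---------------------------------
      guided_tx <- vector("list", cf$n_guided_runs)
      recall_run <- function(segments, task, a_vec) {
        n_tr <- ceiling((max(c(segments$offset, 10)) + 2) / cf$tr_seconds) + 8L
        ev <- events_from_segments(segments, cf$tr_seconds, n_tr)
        data <- NULL
        if (task %in% tasks) {
          ev_room <- events_from_segments(
            segments[segments$kind == "room", , drop = FALSE],
            cf$tr_seconds, n_tr)
          ev_obj <- events_from_segments(
            segments[segments$kind == "object", , drop = FALSE],
            cf$tr_seconds, n_tr)
          comps <- list()
          for (r in unique(segments$label[segments$kind == "room"])) {
            comps[[length(comps) + 1L]] <-
              list(course = boxcar_from_events(ev_room, r, "room", m[s, r]),
                   pattern = P[[s]][, r])
          }
          for (o in unique(segments$label[segments$kind == "object"])) {
            r <- room_of_object[o]
            comps[[length(comps) + 1L]] <-
              list(course = boxcar_from_events(ev_obj, o, "object",
                                               a_vec[r]),
                   pattern = Q[[s]][, o])
            # the cued room stays reinstated while its object is described
            comps[[length(comps) + 1L]] <-
              list(course = boxcar_from_events(ev_obj, o, "object",
                                               m[s, r]),
                   pattern = P[[s]][, r])
          }
          data <- assemble(comps, n_tr)
        }
        list(ev = ev, data = data)
      }
      for (g in seq_len(cf$n_guided_runs)) {
        path <- sample_path(graph, cf$path_length)
        segments <- sample_transcript(path, pr, cf$recall_prob)
        rr <- recall_run(segments, "guided", a_guided[s, ])
        sub_runs[[sprintf("guided_%02d", g)]] <-
          list(task = "guided", run = g, data = rr$data, events = rr$ev,
               segments = segments, cued_path = path)
        guided_tx[[g]] <- segments
      }
      free_order <- sample.int(n_rooms)
      segments <- sample_transcript(free_order, pr, cf$recall_prob)
      rr <- recall_run(segments, "free", a_free[s, ])
      sub_runs[["free_1"]] <- list(task = "free", run = 1, data = rr$data,
                                   events = rr$ev, segments = segments,
                                   cued_path = NULL)
      transcripts[[s]] <- list(guided = guided_tx, free = segments)
      runs[[s]] <- sub_runs
    }

    structure(list(config = cf, graph = graph, pairings = pairings,
                   features = features,
                   signal_searchlights = signal_sl,
                   searchlights = blocks,
                   truth = truth, runs = runs, transcripts = transcripts),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", x$config$n_participants, " participants, ",
      x$config$n_rooms, " rooms, ", x$config$n_searchlights,
      " searchlights (", length(x$signal_searchlights), " signal)\n",
      sep = "")
  invisible(x)
}
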