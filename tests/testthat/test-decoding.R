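test_that("classifier separates well-separated classes and is deterministic", {
  set.seed(2)
  proto <- matrix(rnorm(2 * 30, sd = 4), 2)
  tsets <- lapply(1:2, function(s) proto + matrix(rnorm(60, sd = 0.1), 2))
  m1 <- train_classifier(tsets)
  m2 <- train_classifier(tsets)
  expect_identical(m1$weights, m2$weights)
  ev <- predict_evidence(m1, proto, hrf_shift_tr = 0)
  expect_equal(max.col(ev), 1:2)
  # identical templates across classes: uniform probabilities
  flat <- lapply(1:2, function(s) matrix(1, 4, 10))
  mflat <- train_classifier(flat)
  evf <- predict_evidence(mflat, matrix(rnorm(30), 3), hrf_shift_tr = 0)
  expect_equal(as.numeric(evf), rep(1 / 4, 12), tolerance = 1e-6)
  expect_error(train_classifier(tsets[1]), "2 training participants")
})

test_that("evidence equals a hand softmax and respects the HRF shift", {
  W <- rbind(c(0.5, 1, -1), c(-0.2, 0.3, 0.8)) # intercept + 2 features
  model <- palace_classifier(W)
  X <- rbind(c(1, 2), c(0, -1), c(2, 0.5))
  ev <- predict_evidence(model, X, hrf_shift_tr = 0)
  for (t in 1:3) {
    z <- W %*% c(1, X[t, ])
    expect_equal(as.numeric(ev[t, ]), as.numeric(exp(z) / sum(exp(z))),
                 tolerance = 1e-12)
  }
  expect_equal(rowSums(ev), rep(1, 3), tolerance = 1e-9)
  # shift: evidence row t comes from signal row t + shift
  ev1 <- predict_evidence(model, X, hrf_shift_tr = 1)
  expect_equal(nrow(ev1), 2)
  expect_equal(attr(ev1, "n_dropped"), 1L)
  expect_equal(as.numeric(ev1[1, ]), as.numeric(ev[2, ]))
  expect_error(predict_evidence(model, X, hrf_shift_tr = 3), "shorter")
})

test_that("accuracy scoring follows the argmax and lowest-id tie rule", {
  lab <- c(1L, 2L, 2L, NA, 2L, 3L, 2L, NA, 3L, 1L)
  evm <- events_from_segments(data.frame(), 1, 10)
  evm$labels <- lab
  P <- matrix(0.1, 10, 3)
  top <- rep(1:3, length.out = 10)
  P[cbind(1:10, top)] <- 0.8
  # hand count: labeled TRs 1,2,3,5,6,7,9,10 -> correct at 1,2,5,6,9,10
  expect_equal(score_accuracy(P, evm), 6 / 8)
  one_hot <- matrix(0, 10, 3)
  one_hot[cbind(1:10, ifelse(is.na(lab), 1, lab))] <- 1
  expect_equal(score_accuracy(one_hot, evm), 1)
  # uniform evidence: tie rule predicts class 1 everywhere
  expect_equal(score_accuracy(matrix(1 / 3, 10, 3), evm),
               mean(lab[!is.na(lab)] == 1))
  evm$labels <- rep(NA_integer_, 10)
  expect_true(is.nan(score_accuracy(P, evm)))
})

test_that("contiguity null permutes segment identities, preserving structure", {
  # 4 equal-length segments separated by rest
  lab <- rep(c(1L, NA, 2L, NA, 3L, NA, 4L, NA), each = 5)
  evm <- events_from_segments(data.frame(), 1, length(lab))
  evm$labels <- lab
  # uniform evidence: every permutation scores the tie-rule base rate
  Pu <- matrix(1 / 4, length(lab), 4)
  nulls <- contiguity_null(Pu, evm, n_perm = 50, seed = 1)
  expect_equal(nulls, rep(mean(lab[!is.na(lab)] == 1), 50))
  # perfect evidence: null mean approaches the 1/k fixed-point rate
  Pp <- matrix(0, length(lab), 4)
  Pp[!is.na(lab), ] <- t(sapply(lab[!is.na(lab)], function(l)
    replace(rep(0, 4), l, 1)))
  nulls <- contiguity_null(Pp, evm, n_perm = 4000, seed = 2)
  expect_equal(mean(nulls), 1 / 4, tolerance = 0.02)
  expect_identical(contiguity_null(Pp, evm, 100, seed = 9),
                   contiguity_null(Pp, evm, 100, seed = 9))
  evm$labels <- rep(1L, length(lab))
  expect_error(contiguity_null(Pp, evm, 10, seed = 1), "2 contiguous")
})

test_that("network selection ranks by null-referenced z with stated tie rules", {
  set.seed(5)
  true_acc <- c(0.9, 0.5, 0.52, 0.1)
  null <- matrix(rnorm(400, 0.5, 0.05), 100, 4)
  nm <- select_network(true_acc, null, k = 2)
  expect_equal(nm$members, c(1, 3))
  expect_length(select_network(true_acc, null, k = 4)$members, 4)
  null[, 2] <- 0.5 # degenerate null sd
  expect_warning(nm0 <- select_network(true_acc, null, k = 3), "sd is 0")
  expect_false(2 %in% nm0$members)
})

test_that("reinstatement pools TRs across runs, not run means", {
  # two runs with unequal numbers of recall TRs for class 1
  ev1 <- events_from_segments(
    data.frame(label = 1, kind = "object", onset = 0, offset = 3), 1, 10)
  ev2 <- events_from_segments(
    data.frame(label = 1, kind = "object", onset = 0, offset = 1), 1, 10)
  P1 <- matrix(1 / 2, 10, 2)
  P1[, 1] <- 0.8
  P2 <- matrix(1 / 2, 10, 2)
  P2[, 1] <- 0.2
  sc <- reinstatement_scores(list(list(P1, P2)), list(ev1, ev2))
  # pooled mean over 3 + 1 TRs, not mean of run means
  expect_equal(sc[1], (3 * 0.8 + 1 * 0.2) / 4)
  expect_true(is.nan(sc[2])) # class 2 never recalled
  # constant evidence gives the constant; one-hot gives 1
  sc_flat <- reinstatement_scores(list(list(matrix(1 / 2, 10, 2))), list(ev1))
  expect_equal(sc_flat[1], 1 / 2)
  # label_map redirects pooling (room evidence during object recall)
  ev_obj <- events_from_segments(
    data.frame(label = 2, kind = "object", onset = 0, offset = 4), 1, 10)
  P <- cbind(rep(0.7, 10), rep(0.3, 10))
  sc_map <- reinstatement_scores(list(list(P)), list(ev_obj),
                                 kind = "object", label_map = c(2L, 1L))
  expect_equal(sc_map[1], 0.7) # room 1's object is 2; pools object-2 TRs
})

test_that("room classifiers decode the recalled room from object videos", {
  # RRCN wiring: train on pre-learning room templates, test on object-video
  # runs where the paired room is covertly reinstated; POCN wiring is the
  # same machinery with object templates on the same runs
  cf <- tiny_config(seed = 88, n_participants = 3, n_searchlights = 2,
                    vertices_per_searchlight = 60,
                    signal_searchlight_fraction = 0.5,
                    tau_idiosyncrasy = 0, lambda0 = 0.9, g_sd = 0, u_sd = 0,
                    gamma = 0.8, amp_noise_sd = 0, noise_sd = 0.1,
                    n_guided_runs = 1)
  ds <- quiet_dataset(cf, tasks = c("room_video", "object_video"))
  unit <- ds$searchlights[ds$signal_searchlights]
  rrcn <- lopo_unit_accuracy(ds, unit, train_kind = "room",
                             test_task = "object_video", n_perm = 100,
                             seed = 5)
  expect_gt(rrcn$true, mean(rrcn$null) + 5 * sd(rrcn$null))
  pocn <- lopo_unit_accuracy(ds, unit, train_kind = "object",
                             test_task = "object_video", n_perm = 100,
                             seed = 6)
  expect_gt(pocn$true, mean(pocn$null) + 5 * sd(pocn$null))
})

test_that("object decoding stays at chance when object amplitudes are zero", {
  # room signal present in the test runs but no object reinstatement: the
  # leave-one-participant-out design must not pick up room identity
  cf <- tiny_config(seed = 61, n_participants = 3, n_searchlights = 2,
                    vertices_per_searchlight = 40,
                    signal_searchlight_fraction = 0.5,
                    alpha = 0, beta_direct = 0, beta_mediated = 0,
                    amp_noise_sd = 0, noise_sd = 0.2, tau_idiosyncrasy = 0)
  ds <- quiet_dataset(cf, tasks = c("object_video", "room_recall"))
  sig_unit <- ds$searchlights[ds$signal_searchlights]
  acc <- lopo_unit_accuracy(ds, sig_unit, train_kind = "object",
                            test_task = "room_recall", n_perm = 100,
                            seed = 3)
  base <- mean(acc$null)
  expect_lt(abs(acc$true - base), 3 * sd(acc$null))
})
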