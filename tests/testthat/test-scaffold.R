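# small pair-table worlds used across the scaffold tests
make_world <- function(n_sub = 6, n_sl = 4, n_rooms = 23, b = 0,
                       seed = 1, noise = 0.3) {
  set.seed(seed)
  rel <- array(rnorm(n_sub * n_sl * n_rooms), c(n_sub, n_sl, n_rooms))
  mk_scores <- function() {
    sc <- matrix(rnorm(n_sub * n_rooms, 0, noise), n_sub)
    if (b != 0) sc <- sc + b * t(sapply(seq_len(n_sub),
                                        function(s) rel[s, 1, ]))
    sc
  }
  list(rel = rel, scores = list(guided = mk_scores(), free = mk_scores()))
}

test_that("composite matches the hand Pearson + atanh oracle on a 5-room toy", {
  rel <- array(0, c(1, 1, 5))
  rel[1, 1, ] <- c(0.1, 0.4, 0.2, 0.8, 0.5)
  y <- c(0.05, 0.3, 0.1, 0.6, 0.45)
  stat <- suppressWarnings(fisher_average_map(rel, list(matrix(y, 1))))
  expect_equal(stat, atanh(cor(rel[1, 1, ], y)), tolerance = 1e-12)
  # perfect linear relation hits the clipped maximum
  stat1 <- suppressWarnings(
    fisher_average_map(rel, list(matrix(2 * rel[1, 1, ] + 1, 1))))
  expect_equal(stat1, atanh(1 - 1e-7))
})

test_that("composite is invariant to participant and task ordering", {
  w <- make_world(b = 0.4, seed = 8)
  s0 <- fisher_average_map(w$rel, w$scores)
  perm <- c(4, 2, 6, 1, 3, 5)
  s1 <- fisher_average_map(w$rel[perm, , ],
                           lapply(w$scores, function(m) m[perm, ]))
  expect_equal(s0, s1, tolerance = 1e-12)
  s2 <- fisher_average_map(w$rel, rev(w$scores))
  expect_equal(s0, s2, tolerance = 1e-12)
})

test_that("composite is near zero under independence", {
  w <- make_world(n_sub = 25, n_sl = 2, b = 0, seed = 12)
  stat <- fisher_average_map(w$rel, w$scores)
  se <- 1 / sqrt((23 - 3) * 25 * 2)
  expect_lt(max(abs(stat)), 3 * se)
})

test_that("label-shuffle null calibrates and detects a planted effect", {
  w <- make_world(n_sub = 8, n_sl = 6, b = 0.5, seed = 30)
  res <- reliability_reinstatement_map(w$rel, w$scores, n_perm = 300,
                                       seed = 4)
  expect_true(res$map$sig[1])       # searchlight 1 carries the effect
  # noise searchlights show no systematic effect (individual false
  # positives at the FDR level are possible; calibration is tested below)
  expect_gt(mean(res$map$p[-1]), 0.15)
  expect_lt(max(abs(res$map$stat[-1])), res$map$stat[1] / 2)
  # determinism of the permutation stream
  res2 <- reliability_reinstatement_map(w$rel, w$scores, n_perm = 300,
                                        seed = 4)
  expect_identical(res$null, res2$null)
})

test_that("partial correlation equals the raw map when covariates are zero", {
  w <- make_world(b = 0.4, seed = 5)
  zero <- matrix(0, dim(w$rel)[1], dim(w$rel)[3])
  covars <- list(guided = list(room = zero, object = zero),
                 free = list(room = zero, object = zero))
  perms <- palacerel:::make_perm_indices(100, dim(w$rel)[1], dim(w$rel)[3],
                                         seed = 2)
  raw <- reliability_reinstatement_map(w$rel, w$scores, 100,
                                       perm_indices = perms)
  par <- partial_correlation_map(w$rel, w$scores, covars, 100,
                                 perm_indices = perms)
  expect_equal(par$stat, raw$map$stat, tolerance = 1e-10)
  expect_equal(par$null, raw$null, tolerance = 1e-10)
})

test_that("partial correlation removes a purely mediated association", {
  set.seed(77)
  n_sub <- 10; n_rooms <- 23
  rel <- array(rnorm(n_sub * 2 * n_rooms), c(n_sub, 2, n_rooms))
  m <- 0.8 * t(sapply(1:n_sub, function(s) rel[s, 1, ])) +
    matrix(rnorm(n_sub * n_rooms, 0, 0.2), n_sub)
  sc <- 0.8 * m + matrix(rnorm(n_sub * n_rooms, 0, 0.2), n_sub)
  scores <- list(guided = sc, free = sc)
  meas <- function() m + matrix(rnorm(length(m), 0, 0.05), nrow(m))
  covars <- list(guided = list(room = meas(), object = meas()),
                 free = list(room = meas(), object = meas()))
  raw <- fisher_average_map(rel, scores)
  par <- partial_correlation_map(rel, scores, covars, n_perm = 200, seed = 3)
  expect_gt(raw[1], 0.5)
  expect_lt(abs(par$stat[1]), 2 * sd(par$null[, 1]))
})

test_that("map contrast requires paired permutations and nulls out on equality", {
  w <- make_world(b = 0.3, seed = 9)
  perms <- palacerel:::make_perm_indices(120, 6, 23, seed = 2)
  raw <- reliability_reinstatement_map(w$rel, w$scores, 120,
                                       perm_indices = perms)
  ct <- map_contrast(raw$map$stat, raw$null, raw$map$stat, raw$null)
  expect_equal(ct$stat, rep(0, 4))
  expect_false(any(ct$sig))
  expect_error(map_contrast(raw$map$stat, raw$null, raw$map$stat,
                            raw$null[1:50, ]), "unpaired")
})

test_that("delta R2 vanishes for shared reliability and follows the oracle", {
  set.seed(14)
  n_sub <- 5; n_rooms <- 23
  shared <- rnorm(n_rooms)
  rel <- array(0, c(n_sub, 1, n_rooms))
  for (s in 1:n_sub) rel[s, 1, ] <- shared
  sc <- matrix(rnorm(n_sub * n_rooms), n_sub)
  scores <- list(guided = sc, free = sc)
  d <- participant_specific_delta(rel, scores, n_perm = 100, seed = 2)
  expect_equal(d$map$stat, 0, tolerance = 1e-12)
  # scores an exact linear function of own reliability: R2_own = 1, so
  # delta = 1 - mean over others of r^2 (oracle computed by loops)
  rel2 <- array(rnorm(n_sub * 1 * n_rooms), c(n_sub, 1, n_rooms))
  sc2 <- t(sapply(1:n_sub, function(s) 2 * rel2[s, 1, ] - 1))
  d2 <- participant_specific_delta(rel2, list(guided = sc2, free = sc2),
                                   n_perm = 100, seed = 2)
  oracle <- mean(sapply(1:n_sub, function(s) {
    r2o <- sapply(setdiff(1:n_sub, s),
                  function(j) cor(rel2[j, 1, ], sc2[s, ])^2)
    1 - mean(r2o)
  }))
  expect_equal(d2$map$stat, oracle, tolerance = 1e-10)
})

test_that("permutation p-values are valid under the null", {
  # across many independent null worlds, P(p <= alpha) stays near alpha
  ps <- unlist(lapply(1:60, function(i) {
    w <- make_world(n_sub = 6, n_sl = 2, b = 0, seed = 100 + i)
    reliability_reinstatement_map(w$rel, w$scores, n_perm = 120,
                                  seed = i)$map$p
  }))
  for (alpha in c(0.01, 0.05, 0.1)) {
    rate <- mean(ps <= alpha)
    expect_lt(rate, alpha + 2 * sqrt(alpha * (1 - alpha) / length(ps)))
  }
})
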