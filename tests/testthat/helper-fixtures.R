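# shared fixtures: tiny study configurations kept deliberately small so the
# suite stays fast; scenario-specific parameters are set at the call site

tiny_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(n_participants = 4L, n_searchlights = 6L,
                   vertices_per_searchlight = 20L,
                   signal_searchlight_fraction = 0.34,
                   n_guided_runs = 2L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

quiet_dataset <- function(config, ...) {
  suppressWarnings(simulate_dataset(config, ...))
}

# independent re-implementation of the greedy redundancy-removal rule used
# as an oracle for build_searchlights (plain loops, no shared code)
greedy_oracle <- function(neighbors, hops, floor) {
  n <- length(neighbors)
  ego <- function(v) {
    cur <- v
    for (h in seq_len(hops)) cur <- unique(c(cur, unlist(neighbors[cur])))
    sort(cur)
  }
  units <- lapply(seq_len(n), ego)
  alive <- rep(TRUE, n)
  cov <- integer(n)
  for (u in units) cov[u] <- cov[u] + 1L
  repeat {
    cand <- Filter(function(u) all(cov[units[[u]]] > floor), which(alive))
    if (length(cand) == 0) break
    scores <- vapply(cand, function(u) sum(cov[units[[u]]]), numeric(1))
    pick <- cand[which.max(scores)] # which.max takes the first = lowest index
    alive[pick] <- FALSE
    cov[units[[pick]]] <- cov[units[[pick]]] - 1L
  }
  list(centers = which(alive), coverage = cov)
}
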