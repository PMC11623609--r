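#' Surface meshes for searchlight construction
#'
#' A `mesh` is a vertex-adjacency structure standing in for a cortical
#' surface: `n_vertices`, `neighbors` (list of integer neighbor vectors,
#' symmetric, no self-neighbors) and optional `coords` (n x 3 matrix, mm).
#'
#' @param edges Two-column integer matrix of undirected vertex edges
#'   (1-based).
#' @param n_vertices Number of vertices; defaults to the maximum index in
#'   `edges`.
#' @param coords Optional n x 3 coordinate matrix.
#' @return A `mesh` object.
#' @export
make_mesh <- function(edges, n_vertices = NULL, coords = NULL) {
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
  n <- n_vertices %||% max(edges)
  if (any(edges[, 1] == edges[, 2])) stop("self-neighbors are not allowed")
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    nb[[a]] <- union(nb[[a]], b)
    nb[[b]] <- union(nb[[b]], a)
  }
  nb <- lapply(nb, sort)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, ncol(coords) == 3)
  }
  structure(list(n_vertices = n, neighbors = nb, coords = coords),
            class = "mesh")
}

#' @param n Number of vertices on the ring.
#' @rdname make_mesh
#' @export
ring_mesh <- function(n) {
  make_mesh(cbind(seq_len(n), c(seq_len(n)[-1], 1L)), n_vertices = n)
}

#' @param nx,ny Grid dimensions of a 4-connected lattice mesh.
#' @rdname make_mesh
#' @export
lattice_mesh <- function(nx, ny) {
  id <- function(i, j) (j - 1L) * nx + i
  e <- list()
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (i < nx) e[[length(e) + 1L]] <- c(id(i, j), id(i + 1L, j))
    if (j < ny) e[[length(e) + 1L]] <- c(id(i, j), id(i, j + 1L))
  }
  coords <- cbind(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx), 0)
  make_mesh(do.call(rbind, e), n_vertices = nx * ny, coords = coords)
}

# vertices within `hops` graph hops of `center` (including the center)
#' @keywords internal
#' @noRd
ego_vertices <- function(mesh, center, hops) {
  frontier <- center
  seen <- rep(FALSE, mesh$n_vertices)
  seen[center] <- TRUE
  for (h in seq_len(hops)) {
    nxt <- unique(unlist(mesh$neighbors[frontier]))
    nxt <- nxt[!seen[nxt]]
    if (length(nxt) == 0) break
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Build a searchlight set by greedy redundancy removal
#'
#' Starts with one searchlight per vertex (members = all vertices within
#' `radius_hops` graph hops of the center) and then iteratively removes the
#' most redundant searchlight — the one with the largest summed member
#' coverage among those whose removal leaves every one of their members
#' still covered by at least `min_coverage` searchlights — until no more can
#' be removed. Ties are broken toward the lowest center index, so the result
#' is deterministic.
#'
#' @param mesh A `mesh`.
#' @param radius_hops Searchlight radius in graph hops. Default 2.
#' @param min_coverage Coverage floor: every vertex must remain a member of
#'   at least this many searchlights (study design: 10).
#' @return A `searchlight_set`: list with `centers` (integer vector),
#'   `members` (list of integer vectors, parallel to `centers`) and
#'   `coverage` (per-vertex count).
#' @export
build_searchlights <- function(mesh, radius_hops = 2L, min_coverage = 10L) {
  stopifnot(min_coverage >= 1)
  n <- mesh$n_vertices
  members <- lapply(seq_len(n), function(v) ego_vertices(mesh, v, radius_hops))
  centers <- seq_len(n)
  coverage <- integer(n)
  for (m in members) coverage[m] <- coverage[m] + 1L
  if (any(coverage < min_coverage))
    stop("mesh too sparse: initial coverage below the floor of ",
         min_coverage, " at vertex ", which(coverage < min_coverage)[1])

  alive <- rep(TRUE, length(members))
  repeat {
    best <- 0L
    best_score <- -Inf
    for (u in which(alive)) {
      mem <- members[[u]]
      if (all(coverage[mem] >= min_coverage + 1L)) {
        score <- sum(coverage[mem])
        if (score > best_score) { # strict: ties keep the lowest center index
          best_score <- score
          best <- u
        }
      }
    }
    if (best == 0L) break
    alive[best] <- FALSE
    mem <- members[[best]]
    coverage[mem] <- coverage[mem] - 1L
    stopifnot(all(coverage >= min_coverage))
  }
  structure(list(centers = centers[alive], members = members[alive],
                 coverage = coverage),
            class = "searchlight_set")
}

#' @export
print.searchlight_set <- function(x, ...) {
  cat("<searchlight_set> ", length(x$centers), " searchlights; coverage ",
      min(x$coverage), "-", max(x$coverage), "\n", sep = "")
  invisible(x)
}

#' Split an ROI by a coordinate threshold
#'
#' Partitions ROI vertices by a strict threshold on one coordinate axis, as
#' used to split the hippocampus into anterior (`y > -20` mm) and posterior
#' (`y <= -20` mm) portions.
#'
#' @param roi_vertices Integer vertex ids.
#' @param coords n x 3 coordinate matrix for the whole mesh (mm).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param threshold Threshold in mm; vertices strictly above go to `above`,
#'   vertices at or below go to `at_or_below`.
#' @return List with integer vectors `above` and `at_or_below`.
#' @export
split_roi_by_axis <- function(roi_vertices, coords, axis = c("y", "x", "z"),
                              threshold = -20) {
  axis <- match.arg(axis)
  roi_vertices <- as.integer(roi_vertices)
  if (length(roi_vertices) == 0)
    return(list(above = integer(0), at_or_below = integer(0)))
  if (is.null(coords)) stop("coords are required to split an ROI")
  coords <- as.matrix(coords)
  if (any(roi_vertices > nrow(coords)) ||
      anyNA(coords[roi_vertices, , drop = FALSE]))
    stop("missing coordinates for some ROI vertices")
  v <- coords[roi_vertices, match(axis, c("x", "y", "z"))]
  list(above = roi_vertices[v > threshold],
       at_or_below = roi_vertices[v <= threshold])
}

#' Write a searchlight set as TSV
#'
#' One row per (unit, member): columns `unit_id`, `center`, `member`.
#' @param sl A `searchlight_set`.
#' @param path TSV path.
#' @export
write_searchlights_tsv <- function(sl, path) {
  df <- do.call(rbind, lapply(seq_along(sl$centers), function(i)
    data.frame(unit_id = i, center = sl$centers[i], member = sl$members[[i]])))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
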