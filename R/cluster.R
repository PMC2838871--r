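# Alphabet derivation from a fragment-angle cloud: grid density prefilter,
# OPTICS nearest-neighbour ordering, Drop-Down hierarchical cluster
# extraction, representative selection and redundancy removal.  The distance
# throughout is the aRMSD of (phi1, phi2, theta) with periodic theta.

.as_angle_matrix <- function(points) {
  m <- as.matrix(points)
  if (ncol(m) < 3L) stop("expected columns (phi1, phi2, theta)")
  m <- m[, 1:3, drop = FALSE]
  storage.mode(m) <- "double"
  colnames(m) <- c("phi1", "phi2", "theta")
  m
}

#' Grid density prefilter for fragment clouds
#'
#' Lays a cubic grid over the angle space (theta binned on its periodic
#' range) and discards all points falling in cells with fewer than
#' `min_count` members.  This removes sparse, uninformative regions before
#' the quadratic-cost OPTICS ordering.
#'
#' @param points n x 3 matrix of (phi1, phi2, theta) in degrees.
#' @param cell grid resolution in degrees (default 2).
#' @param min_count minimum cell population to retain (default 10).
#' @return The retained subset of `points`, with attribute `kept` (logical
#'   mask over the input rows; any `labels` attribute is subset alongside).
#' @export
grid_prefilter <- function(points, cell = 2, min_count = 10) {
  if (!is.finite(cell) || cell <= 0) stop("'cell' must be positive")
  m <- .as_angle_matrix(points)
  nphi <- ceiling(180 / cell)
  ntheta <- round(360 / cell)
  i1 <- pmin(floor(m[, 1L] / cell), nphi - 1L)
  i2 <- pmin(floor(m[, 2L] / cell), nphi - 1L)
  i3 <- floor((m[, 3L] + 180) / cell) %% ntheta  # wrap-aware theta binning
  key <- paste(i1, i2, i3)
  counts <- table(key)
  kept <- as.vector(counts[key]) >= min_count
  if (!any(kept)) warning("grid prefilter removed every point")
  out <- m[kept, , drop = FALSE]
  lab <- attr(points, "labels")
  if (!is.null(lab)) attr(out, "labels") <- lab[kept]
  attr(out, "kept") <- kept
  out
}

# aRMSD from point i of P to all rows of P (vectorised inner loop of OPTICS).
.dist_to_all <- function(P, i) {
  d1 <- abs(P[, 1L] - P[i, 1L])
  d2 <- abs(P[, 2L] - P[i, 2L])
  dt <- abs(P[, 3L] - P[i, 3L])
  dt <- pmin(dt, 360 - dt)
  sqrt((d1 * d1 + d2 * d2 + dt * dt) / 3)
}

#' OPTICS density ordering of a fragment cloud
#'
#' Orders points by a nearest-neighbour walk, recording for each point its
#' core distance (radius of the smallest neighbourhood holding `min_pts`
#' points, the point itself included) and its reachability distance from the
#' walk (`max(core_distance(predecessor), d(predecessor, point))`, minimised
#' over the expansion frontier).  Low reachability marks dense regions.  The
#' walk starts at the first point (deterministic); the first ordered point of
#' each connected component has undefined reachability, stored as `Inf`.
#' With the default neighbourhood radius of 200 degrees every point is
#' reachable and none is noise (the largest aRMSD the angle space admits is
#' well below 200).
#'
#' @param points n x 3 matrix of (phi1, phi2, theta) in degrees.
#' @param min_pts minimum neighbourhood population (>= 2).
#' @param eps neighbourhood radius in degrees (default 200).
#' @return Object of class `optics_result`: `order` (permutation of row
#'   indices in walk order), `reachability` and `core_distance` (degrees,
#'   aligned with `order`), `eps`, `min_pts`, `n`.
#' @export
optics_order <- function(points, min_pts, eps = 200) {
  P <- .as_angle_matrix(points)
  n <- nrow(P)
  if (min_pts < 2L) stop("'min_pts' must be at least 2")
  if (min_pts > n) stop("'min_pts' exceeds the number of points")
  processed <- logical(n)
  reach <- rep(Inf, n)        # current best reachability per unvisited point
  order_out <- integer(n)
  reach_out <- numeric(n)
  core_out <- numeric(n)
  for (step in seq_len(n)) {
    cand <- which(!processed)
    i <- cand[which.min(reach[cand])]         # Inf everywhere -> lowest index
    processed[i] <- TRUE
    d <- .dist_to_all(P, i)
    within <- d <= eps
    core <- if (sum(within) >= min_pts)
      sort(d[within], partial = min_pts)[min_pts] else Inf
    order_out[step] <- i
    reach_out[step] <- reach[i]
    core_out[step] <- core
    if (is.finite(core)) {
      upd <- !processed & within
      reach[upd] <- pmin(reach[upd], pmax(core, d[upd]))
    }
  }
  structure(list(order = order_out, reachability = reach_out,
                 core_distance = core_out, eps = eps,
                 min_pts = as.integer(min_pts), n = n),
            class = "optics_result")
}

#' @export
print.optics_result <- function(x, ...) {
  cat(sprintf("<optics_result> %d points, min_pts %d, eps %g\n",
              x$n, x$min_pts, x$eps))
  invisible(x)
}

#' Drop-Down hierarchical cluster extraction
#'
#' Carves the reachability profile into a cluster hierarchy by a density
#' threshold descending through the sorted reachability values.  At each
#' threshold, a candidate cluster is a maximal contiguous run of ordered
#' points whose reachability lies below the threshold, enclosed by two
#' threshold-exceeding positions more than `min_pts` apart; a candidate is
#' accepted if it is at least `min_pts` smaller than its parent.  The whole
#' profile is scanned first (root clusters), then accepted clusters are
#' processed in turn (breadth-first), which makes the extraction order run
#' from the most to the least populated attractors.
#'
#' @param optics an `optics_result`.
#' @param min_pts separation/shrink parameter; defaults to the OPTICS value.
#' @return Object of class `cluster_tree`: data.frame `nodes` with columns
#'   `id` (extraction order), `parent`, `lo`, `hi` (positions in the OPTICS
#'   order, inclusive), `size`, `depth`.  Node 1 is the root (all points).
#' @export
dropdown_extract <- function(optics, min_pts = optics$min_pts) {
  stopifnot(inherits(optics, "optics_result"))
  r <- optics$reachability
  n <- optics$n
  nodes <- data.frame(id = 1L, parent = 0L, lo = 1L, hi = n,
                      size = n, depth = 0L)
  queue <- 1L
  while (length(queue)) {
    pid <- queue[1L]
    queue <- queue[-1L]
    lo <- nodes$lo[pid]
    hi <- nodes$hi[pid]
    psize <- nodes$size[pid]
    if (hi - lo + 1L <= min_pts) next
    interior <- (lo + 1L):hi
    thresholds <- sort(unique(r[interior][is.finite(r[interior])]),
                       decreasing = TRUE)
    accepted <- matrix(integer(), ncol = 2L)
    for (t in thresholds) {
      # boundaries: the parent's entry position and every interior position
      # whose reachability reaches the threshold; hi+1 closes the last run
      bounds <- c(lo, interior[r[interior] >= t], hi + 1L)
      bounds <- sort(unique(bounds))
      for (b in seq_len(length(bounds) - 1L)) {
        b1 <- bounds[b]
        b2 <- bounds[b + 1L]
        if (b2 - b1 <= min_pts) next            # not "more than MinPts apart"
        clo <- b1 + 1L
        chi <- b2 - 1L
        size <- chi - clo + 1L
        if (size > psize - min_pts) next        # must shrink by >= MinPts
        if (nrow(accepted) &&
            any(clo >= accepted[, 1L] & chi <= accepted[, 2L])) next
        accepted <- rbind(accepted, c(clo, chi))
        nid <- nrow(nodes) + 1L
        nodes <- rbind(nodes, data.frame(id = nid, parent = pid, lo = clo,
                                         hi = chi, size = size,
                                         depth = nodes$depth[pid] + 1L))
        queue <- c(queue, nid)
      }
    }
  }
  structure(list(nodes = nodes, min_pts = as.integer(min_pts)),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d clusters, max depth %d\n",
              nrow(x$nodes), max(x$nodes$depth)))
  invisible(x)
}

#' Cluster representatives by highest local density
#'
#' For every extracted cluster, selects the member with the lowest core
#' distance (the point sitting in the densest neighbourhood); core-distance
#' ties break to the earliest position in the OPTICS order.  Rows are
#' returned in extraction order, i.e. most populated attractors first.
#'
#' @param tree a `cluster_tree`.
#' @param optics the `optics_result` the tree was extracted from.
#' @param points the point matrix that was ordered.
#' @return data.frame with one row per cluster: `cluster`, `parent`,
#'   `rep_position` (OPTICS-order position), `rep_index` (row of `points`),
#'   `core_distance`, `phi1`, `phi2`, `theta`.
#' @export
select_representatives <- function(tree, optics, points) {
  stopifnot(inherits(tree, "cluster_tree"), inherits(optics, "optics_result"))
  P <- .as_angle_matrix(points)
  nodes <- tree$nodes
  rep_pos <- vapply(seq_len(nrow(nodes)), function(i) {
    rng <- nodes$lo[i]:nodes$hi[i]
    rng[which.min(optics$core_distance[rng])]   # stable: lowest position wins
  }, integer(1))
  rep_idx <- optics$order[rep_pos]
  data.frame(cluster = nodes$id, parent = nodes$parent,
             rep_position = rep_pos, rep_index = rep_idx,
             core_distance = optics$core_distance[rep_pos],
             phi1 = P[rep_idx, 1L], phi2 = P[rep_idx, 2L],
             theta = P[rep_idx, 3L])
}

#' Fit the intra-cluster distance peak and derive a redundancy cutoff
#'
#' The distribution of pairwise cRMSDs between four-residue fragments is
#' multi-modal; the intra-cluster peak (same conformation) is log-normal
#' below 1 Angstrom.  A maximum-likelihood log-normal is fitted to the
#' sub-1.0-Angstrom distances and the one-sigma quantile
#' `exp(meanlog + sdlog)` -- below which about 84% of intra-cluster pairs
#' fall -- is returned as the redundancy cutoff.
#'
#' @param distances numeric vector of pairwise cRMSDs in Angstrom (>= 100
#'   values recommended).
#' @param upper upper bound of the intra-cluster peak (default 1.0).
#' @return List: `meanlog`, `sdlog`, their standard errors (`se`), `cutoff`
#'   (Angstrom) and `n_used`.
#' @export
fit_redundancy_cutoff <- function(distances, upper = 1.0) {
  x <- distances[is.finite(distances) & distances > 0 & distances < upper]
  if (length(x) < 2L)
    stop("need at least 2 positive distances below ", upper, " Angstrom to fit")
  fit <- MASS::fitdistr(x, "lognormal")
  meanlog <- unname(fit$estimate["meanlog"])
  sdlog <- unname(fit$estimate["sdlog"])
  list(meanlog = meanlog, sdlog = sdlog, se = unname(fit$sd),
       cutoff = exp(meanlog + sdlog), n_used = length(x))
}

#' Remove redundant representatives
#'
#' Greedy keep-first pass over representatives in extraction (density)
#' order: a representative is discarded if its canonical-coordinate cRMSD to
#' any already accepted one falls below the cutoff, so the earlier-extracted
#' (more important) attractor survives.
#'
#' @param reps k x 3 matrix of representative angle triples in extraction
#'   order.
#' @param cutoff redundancy cRMSD cutoff in Angstrom (default 0.307).
#' @param bond virtual bond length for canonical coordinates.
#' @return Integer vector of retained row indices (in extraction order).
#' @export
redundancy_filter <- function(reps, cutoff = 0.307, bond = 3.8) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("'cutoff' must be positive")
  m <- .as_angle_matrix(reps)
  frags <- lapply(seq_len(nrow(m)), function(i) build_fragment(m[i, ], bond))
  kept <- integer()
  for (i in seq_len(nrow(m))) {
    redundant <- any(vapply(kept, function(j)
      crmsd(frags[[i]], frags[[j]]) < cutoff, TRUE))
    if (!redundant) kept <- c(kept, i)
  }
  kept
}

#' Derive a Structural Alphabet from a fragment cloud
#'
#' Full pipeline: grid prefilter, OPTICS ordering, Drop-Down extraction,
#' density-ordered representative selection, redundancy removal.  Surviving
#' representatives are lettered A, B, C, ... by the position of each
#' representative along the reachability walk, and the alphabet is named
#' `M<min_pts>K<size>`.  Deterministic for a given cloud (the OPTICS walk
#' starts at the first point).
#'
#' @param points n x 3 matrix of (phi1, phi2, theta) in degrees.
#' @param min_pts OPTICS/Drop-Down density parameter.
#' @param eps OPTICS neighbourhood radius in degrees.
#' @param cell,min_count grid prefilter parameters; `min_count = 0` disables
#'   the prefilter.
#' @param cutoff redundancy cRMSD cutoff in Angstrom.
#' @param bond virtual bond length of the canonical fragments.
#' @param name alphabet name; default `M<min_pts>K<size>`.
#' @return A [structural_alphabet()] with attributes `optics` (the
#'   `optics_result`), `tree` (the `cluster_tree`) and `representatives`
#'   (the pre-filter representative table).
#' @export
derive_alphabet <- function(points, min_pts, eps = 200, cell = 2,
                            min_count = 10, cutoff = 0.307, bond = 3.8,
                            name = NULL) {
  P <- .as_angle_matrix(points)
  if (min_pts > nrow(P)) stop("'min_pts' exceeds the number of points")
  if (min_count > 0) P <- grid_prefilter(P, cell = cell, min_count = min_count)
  if (!nrow(P)) stop("no points left after grid prefilter")
  opt <- optics_order(P, min_pts = min_pts, eps = eps)
  tree <- dropdown_extract(opt, min_pts = min_pts)
  reps <- select_representatives(tree, opt, P)
  kept <- redundancy_filter(as.matrix(reps[, c("phi1", "phi2", "theta")]),
                            cutoff = cutoff, bond = bond)
  reps_kept <- reps[kept, , drop = FALSE]
  reps_kept <- reps_kept[order(reps_kept$rep_position), , drop = FALSE]
  k <- nrow(reps_kept)
  if (is.null(name)) name <- sprintf("M%dK%d", as.integer(min_pts), k)
  ab <- structural_alphabet(
    as.matrix(reps_kept[, c("phi1", "phi2", "theta")]),
    letters = default_letters(k), name = name, bond = bond)
  attr(ab, "optics") <- opt
  attr(ab, "tree") <- tree
  attr(ab, "representatives") <- reps
  ab
}
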