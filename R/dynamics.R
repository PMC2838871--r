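# Gaussian Network Model analysis (Kirchhoff matrix, pseudo-inverse, RMSF,
# cross-correlations), matrix overlap, and ensemble profiling (per-fragment
# RMSF versus Shannon entropy of structural-string encodings).

#' Gaussian Network Model of a C-alpha trace
#'
#' Builds the elastic-network Kirchhoff matrix (off-diagonal -1 for residue
#' pairs within the contact cutoff, diagonal = contact count) and its
#' pseudo-inverse via eigendecomposition with the single zero mode removed.
#' Fluctuation magnitudes and cross-correlations follow from the
#' pseudo-inverse; the kT/gamma prefactor is set to 1, so fluctuations are
#' in arbitrary units -- only scale-free quantities (correlations, overlaps)
#' are meaningful downstream.
#'
#' @param trace a `ca_trace` (N >= 3) or N x 3 coordinate matrix.
#' @param cutoff contact distance in Angstrom (default 7).
#' @param normalise normalise cross-correlations to unit diagonal (default
#'   TRUE).
#' @return Object of class `gnm_result`: `kirchhoff`, `pinv`, `rmsf`
#'   (`sqrt(diag(pinv))`), `cross_corr`, `cutoff`, `normalised`.
#' @export
gnm <- function(trace, cutoff = 7, normalise = TRUE) {
  X <- .as_coords(trace)
  n <- nrow(X)
  if (n < 3L) stop("GNM needs at least 3 residues")
  D <- as.matrix(dist(X))
  K <- -(D <= cutoff) * 1
  dimnames(K) <- NULL
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  eg <- eigen(K, symmetric = TRUE)
  tol <- 1e-10 * max(eg$values)
  zero <- eg$values < tol
  if (sum(zero) > 1L) {
    comp <- .graph_components(D <= cutoff)
    stop(sprintf(
      "contact graph is disconnected (%d components of sizes %s); GNM undefined",
      max(comp), paste(tabulate(comp), collapse = ", ")))
  }
  keep <- which(!zero)
  pinv <- eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
  pinv <- (pinv + t(pinv)) / 2
  rmsf <- sqrt(pmax(diag(pinv), 0))
  cc <- if (normalise) pinv / tcrossprod(rmsf) else pinv
  structure(list(kirchhoff = K, pinv = pinv, rmsf = rmsf, cross_corr = cc,
                 cutoff = cutoff, normalised = normalise),
            class = "gnm_result")
}

#' @export
print.gnm_result <- function(x, ...) {
  cat(sprintf("<gnm_result> %d residues, cutoff %g Angstrom\n",
              nrow(x$kirchhoff), x$cutoff))
  invisible(x)
}

# connected components of an adjacency matrix (BFS); returns component id
# per node.
.graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Overlap between two symmetric matrices
#'
#' `1 - d(A, B) / (tr(A'A) + tr(B'B))` with `d(A, B) = tr((A-B)'(A-B))`:
#' 1 for identical matrices, 0 when `tr(A'B) = 0` (no overlap), symmetric in
#' its arguments.  Used to compare GNM cross-correlation matrices of native
#' and reconstructed structures.
#'
#' @param A,B symmetric matrices of equal shape, not both zero.
#' @return Scalar overlap (at most 1).
#' @export
matrix_overlap <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("matrices must have equal shape")
  if (max(abs(A - t(A))) > 1e-8 * max(abs(A), 1) ||
      max(abs(B - t(B))) > 1e-8 * max(abs(B), 1))
    stop("matrices must be symmetric")
  denom <- sum(A * A) + sum(B * B)
  if (denom == 0) stop("overlap undefined: both matrices are zero")
  1 - sum((A - B)^2) / denom
}

#' Flexibility fidelity of a reconstruction
#'
#' Runs the GNM on the native and the reconstructed structure and reports
#' the Pearson correlation of the two RMSF profiles together with the
#' overlap of the two cross-correlation matrices.  Values near 1 mean the
#' alphabet encoding preserved the native contact network and intrinsic
#' flexibility.
#'
#' @param native,reconstructed `ca_trace`s of equal length.
#' @param cutoff GNM contact cutoff in Angstrom.
#' @param normalise compare normalised cross-correlations (default TRUE).
#' @return List: `rmsf_pearson`, `cc_overlap`, plus both `gnm_result`s.
#' @export
flexibility_fidelity <- function(native, reconstructed, cutoff = 7,
                                 normalise = TRUE) {
  gn <- gnm(native, cutoff = cutoff, normalise = normalise)
  gr <- gnm(reconstructed, cutoff = cutoff, normalise = normalise)
  if (length(gn$rmsf) != length(gr$rmsf))
    stop("native and reconstructed traces must have equal length")
  list(rmsf_pearson = cor(gn$rmsf, gr$rmsf),
       cc_overlap = matrix_overlap(gn$cross_corr, gr$cross_corr),
       native = gn, reconstructed = gr)
}

#' Per-fragment RMSF profile of an ensemble
#'
#' For each of the N-3 sliding four-residue windows: superpose the window's
#' atoms in every frame onto the reference (frame 1) window, removing
#' roto-translation; compute each atom's RMSF about its mean position over
#' frames; report the quadratic mean of the four atomic RMSFs.  Rigid-body
#' motion of whole frames therefore contributes nothing.
#'
#' @param ens a `ca_ensemble` (>= 2 frames for a non-trivial profile).
#' @return Numeric vector of length N-3 (Angstrom).
#' @export
fragment_rmsf_profile <- function(ens) {
  stopifnot(inherits(ens, "ca_ensemble"))
  nf <- length(ens$frames)
  n <- nrow(ens$frames[[1L]]$coords)
  if (n < 4L) stop("frames must contain at least 4 residues")
  nw <- n - 3L
  if (nf < 2L) {
    warning("single-frame ensemble: RMSF profile is zero")
    return(numeric(nw))
  }
  out <- numeric(nw)
  for (w in seq_len(nw)) {
    idx <- w:(w + 3L)
    ref <- ens$frames[[1L]]$coords[idx, , drop = FALSE]
    aligned <- array(0, dim = c(nf, 4L, 3L))
    for (f in seq_len(nf))
      aligned[f, , ] <- superpose(ens$frames[[f]]$coords[idx, , drop = FALSE],
                                  ref)$fitted
    mean_pos <- apply(aligned, c(2L, 3L), mean)
    dev2 <- vapply(seq_len(4L), function(a)
      mean(rowSums((aligned[, a, , drop = FALSE][, 1L, ] -
                      matrix(mean_pos[a, ], nf, 3L, byrow = TRUE))^2)), 0)
    out[w] <- sqrt(mean(dev2))  # quadratic mean of the 4 atomic RMSFs
  }
  out
}

# encode every frame; returns frames x windows letter matrix.  Frames are
# perturbed copies of one intact chain, so chain-break detection is off.
.encode_frames <- function(ens, alphabet, method = c("local", "global"),
                           heap = 16) {
  method <- match.arg(method)
  t(vapply(ens$frames, function(fr) {
    if (method == "local") encode_local(fr, alphabet, break_range = NULL)$letters
    else reconstruct_global(fr, alphabet, heap = heap,
                            break_range = NULL)$encoding$letters
  }, character(nrow(ens$frames[[1L]]$coords) - 3L)))
}

#' Shannon-entropy profile of an encoded ensemble
#'
#' Encodes every frame as a structural string and evaluates, per fragment
#' position, the Shannon entropy `S_i = -sum_j p_ij log2 p_ij` of the letter
#' distribution across frames (`p_ij` = fraction of frames assigning letter
#' j at position i).  Rigid positions score 0; the upper bound is `log2 k`.
#' Gap characters (chain-break windows) are excluded from the distribution.
#'
#' @param ens a `ca_ensemble`.
#' @param alphabet a `structural_alphabet`.
#' @param method `"local"` or `"global"` encoding.
#' @param heap beam width for global encoding.
#' @return Numeric vector of length N-3 (bits), with the frames x windows
#'   letter matrix as attribute `letters`.
#' @export
entropy_profile <- function(ens, alphabet, method = c("local", "global"),
                            heap = 16) {
  stopifnot(inherits(ens, "ca_ensemble"))
  letters <- .encode_frames(ens, alphabet, method, heap)
  ent <- apply(letters, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(NA_real_)
    p <- tabulate(factor(col, levels = unique(col)))
    p <- p / sum(p)
    -sum(p * log2(p))
  })
  attr(ent, "letters") <- letters
  ent
}

#' Flexibility-entropy profile of an ensemble
#'
#' Couples the geometric fragment flexibility (per-window RMSF) with the
#' encoding variability (per-window Shannon entropy) of a conformational
#' ensemble and reports their Pearson correlation plus the ensemble means
#' used in protein-level summaries.  A well-behaved alphabet assigns many
#' letters only where the backbone genuinely moves, so r substantially
#' above 0 indicates robust ensemble encoding.
#'
#' @inheritParams entropy_profile
#' @return Object of class `ensemble_profile`: `fragment_rmsf`, `entropy`,
#'   `pearson_r` (NA with a warning when either track has zero variance),
#'   `mean_rmsf`, `mean_entropy`, `method`.
#' @export
ensemble_profile <- function(ens, alphabet, method = c("local", "global"),
                             heap = 16) {
  method <- match.arg(method)
  rmsf <- fragment_rmsf_profile(ens)
  ent <- entropy_profile(ens, alphabet, method = method, heap = heap)
  ok <- !is.na(ent)
  r <- if (sd(rmsf[ok]) == 0 || sd(ent[ok]) == 0) {
    warning("zero-variance track: flexibility-entropy correlation undefined")
    NA_real_
  } else cor(rmsf[ok], ent[ok])
  structure(list(fragment_rmsf = rmsf, entropy = as.numeric(ent),
                 pearson_r = r, mean_rmsf = mean(rmsf),
                 mean_entropy = mean(ent[ok]), method = method),
            class = "ensemble_profile")
}

#' @export
print.ensemble_profile <- function(x, ...) {
  cat(sprintf(
    "<ensemble_profile> %d windows [%s fit]: r = %.3f, mean RMSF %.3f A, mean S %.3f bit\n",
    length(x$entropy), x$method, x$pearson_r, x$mean_rmsf, x$mean_entropy))
  invisible(x)
}

#' Correlation between fragment flexibility and encoding entropy
#'
#' Convenience wrapper around [ensemble_profile()] returning the Pearson
#' correlation and the protein-level means.
#'
#' @inheritParams entropy_profile
#' @return List: `pearson_r`, `mean_rmsf`, `mean_entropy`.
#' @export
flexibility_entropy_correlation <- function(ens, alphabet,
                                            method = c("local", "global"),
                                            heap = 16) {
  p <- ensemble_profile(ens, alphabet, method = method, heap = heap)
  list(pearson_r = p$pearson_r, mean_rmsf = p$mean_rmsf,
       mean_entropy = p$mean_entropy)
}
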