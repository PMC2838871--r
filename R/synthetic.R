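# Synthetic fixtures: chains grown from letter strings, perturbed
# conformational ensembles, and labelled angle-space clouds.  These stand in
# for curated structure corpora and constraint-based ensemble generators so
# that every other module can be exercised without downloads.

#' Grow a chain from a letter string
#'
#' Head-to-tail fragment assembly run generatively: the chain starts as the
#' first letter's canonical four atoms; each further letter appends exactly
#' one atom placed from internal coordinates (virtual bond, the letter's
#' phi2 and theta relative to the last three chain atoms).  Window 1 of the
#' result realises all three angles of letter 1; every window i realises
#' letter i's (phi2, theta) exactly, while its phi1 is inherited from the
#' preceding window through the three shared atoms.
#'
#' @param letters character string (or vector of single letters) over the
#'   alphabet.
#' @param alphabet a `structural_alphabet`.
#' @param bond virtual bond length (default: the alphabet's).
#' @return A [ca_trace()] of length `nchar(letters) + 3`.
#' @examples
#' chain_from_letters("AAPUY", m32k25())
#' @export
chain_from_letters <- function(letters, alphabet, bond = alphabet$bond) {
  stopifnot(inherits(alphabet, "structural_alphabet"))
  if (length(letters) == 1L && nchar(letters) != 1L)
    letters <- strsplit(letters, "")[[1L]]
  if (!length(letters)) stop("empty letter string")
  idx <- match(letters, alphabet$letters)
  if (anyNA(idx))
    stop("unknown letter(s): ", paste(unique(letters[is.na(idx)]), collapse = ", "))
  coords <- build_fragment(alphabet$angles[idx[1L], ], bond)
  for (j in idx[-1L]) {
    n <- nrow(coords)
    coords <- rbind(coords,
                    place_atom(coords[n - 2L, ], coords[n - 1L, ], coords[n, ],
                               bond, alphabet$angles[j, 2L],
                               alphabet$angles[j, 3L]))
  }
  ca_trace(coords, id = paste(letters, collapse = ""))
}

.noise_models <- c("none", "cartesian", "angular", "graded")

#' Generate a synthetic conformational ensemble
#'
#' Frame 1 is the noise-free chain grown from `letters`; every further frame
#' is an independently perturbed copy.  Noise models: `"cartesian"` adds
#' isotropic Gaussian displacements of sd `sigma` Angstrom to every atom
#' (virtual bonds are slightly broken, as in real coordinate error);
#' `"angular"` perturbs the chain's internal angle sequence by Gaussian
#' noise of sd `sigma` degrees and rebuilds Cartesian coordinates (bonds
#' stay exact); `"graded"` is Cartesian noise whose per-atom sd is linearly
#' interpolated from `sigma[1]` to `sigma[2]` along the chain, giving a
#' known flexibility gradient.
#'
#' @param letters letter string defining the reference chain.
#' @param alphabet a `structural_alphabet`.
#' @param n_frames number of frames (>= 1).
#' @param noise one of `"none"`, `"cartesian"`, `"angular"`, `"graded"`.
#' @param sigma noise amplitude: scalar (Angstrom or degrees), or length-2
#'   `c(start, end)` for `"graded"`.
#' @param seed RNG seed (reproducible frames).
#' @param bond virtual bond length.
#' @return A [ca_ensemble()].
#' @export
make_ensemble <- function(letters, alphabet, n_frames = 100,
                          noise = c("none", "cartesian", "angular", "graded"),
                          sigma = 0.3, seed = 1, bond = alphabet$bond) {
  noise <- match.arg(noise)
  if (n_frames < 1L) stop("'n_frames' must be at least 1")
  if (any(sigma < 0)) stop("'sigma' must be non-negative")
  ref <- chain_from_letters(letters, alphabet, bond = bond)
  n <- nrow(ref$coords)
  set.seed(seed)
  if (noise == "graded" && length(sigma) != 2L)
    stop("graded noise needs sigma = c(start, end)")
  sig_atom <- switch(noise,
    none = rep(0, n),
    cartesian = rep(sigma[1L], n),
    graded = seq(sigma[1L], sigma[2L], length.out = n),
    angular = NULL)
  frames <- vector("list", n_frames)
  frames[[1L]] <- ref
  frames[[1L]]$id <- paste0(ref$id, ".1")
  if (n_frames > 1L) for (f in 2:n_frames) {
    coords <- if (noise == "angular") {
      .perturbed_chain(ref$id, alphabet, sigma[1L], bond)
    } else {
      ref$coords + matrix(rnorm(3L * n, sd = rep(sig_atom, 3L)), n, 3L)
    }
    frames[[f]] <- ca_trace(coords, residue_ids = ref$residue_ids,
                            chain_id = ref$chain_id,
                            id = paste0(ref$id, ".", f))
  }
  ca_ensemble(frames, source_id = ref$id)
}

# rebuild a chain with Gaussian-perturbed internal angles (degrees)
.perturbed_chain <- function(letter_string, alphabet, sigma, bond) {
  idx <- match(strsplit(letter_string, "")[[1L]], alphabet$letters)
  ang1 <- alphabet$angles[idx[1L], ] + rnorm(3L, sd = sigma)
  ang1[1L] <- .reflect_phi(ang1[1L])
  ang1[2L] <- .reflect_phi(ang1[2L])
  ang1[3L] <- wrap_theta(ang1[3L])
  coords <- build_fragment(ang1, bond)
  for (j in idx[-1L]) {
    n <- nrow(coords)
    phi2 <- .reflect_phi(alphabet$angles[j, 2L] + rnorm(1L, sd = sigma))
    theta <- wrap_theta(alphabet$angles[j, 3L] + rnorm(1L, sd = sigma))
    coords <- rbind(coords,
                    place_atom(coords[n - 2L, ], coords[n - 1L, ], coords[n, ],
                               bond, phi2, theta))
  }
  coords
}

# reflect bond-angle samples at the (0, 180] boundaries instead of clipping,
# so boundary-adjacent centres do not pile up density at the edge
.reflect_phi <- function(x) {
  x <- x %% 360
  x <- ifelse(x > 180, 360 - x, x)
  ifelse(x == 0, .Machine$double.eps, x)
}

#' Sample a labelled fragment-angle cloud
#'
#' Draws wrapped/reflected Gaussian samples in (phi1, phi2, theta) around
#' given centres: theta noise wraps on its 360-degree period, phi noise is
#' reflected at the (0, 180] boundaries.  True cluster labels are retained
#' for recovery scoring of the alphabet-derivation pipeline.
#'
#' @param centres k x 3 matrix of angle triples (degrees).
#' @param sigmas per-centre (or scalar) Gaussian sd in degrees.
#' @param counts per-centre (or scalar) sample counts (>= 1).
#' @param seed RNG seed.
#' @return n x 3 angle matrix with attribute `labels` (integer centre index
#'   per row).
#' @export
make_angle_cloud <- function(centres, sigmas = 1, counts = 200, seed = 1) {
  centres <- .as_angle_matrix(centres)
  k <- nrow(centres)
  sigmas <- rep_len(sigmas, k)
  counts <- rep_len(as.integer(counts), k)
  if (any(counts < 1L)) stop("'counts' must be at least 1")
  if (any(sigmas < 0)) stop("'sigmas' must be non-negative")
  set.seed(seed)
  rows <- lapply(seq_len(k), function(i) {
    n <- counts[i]
    cbind(.reflect_phi(rnorm(n, centres[i, 1L], sigmas[i])),
          .reflect_phi(rnorm(n, centres[i, 2L], sigmas[i])),
          wrap_theta(rnorm(n, centres[i, 3L], sigmas[i])))
  })
  out <- do.call(rbind, rows)
  colnames(out) <- c("phi1", "phi2", "theta")
  attr(out, "labels") <- rep(seq_len(k), counts)
  out
}
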