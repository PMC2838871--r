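# Shared fixtures and independent oracles.  Fixtures are generated in code;
# oracles are deliberately naive (brute force / closed form) and never share
# code paths with the implementation they check.

pdb_atom <- function(serial, elety, resname, chain, resno, x, y, z,
                     altloc = " ", occ = 1, element = " C") {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", elety), altloc, resname, chain, resno,
          x, y, z, occ, 0, element)
}

# 4-residue single-chain toy file
toy_pdb <- function(path) {
  lines <- sapply(1:4, function(i)
    pdb_atom(i, "CA", "ALA", "A", i, 3.8 * (i - 1), (i %% 2) * 1.5, 0))
  writeLines(c(lines, "END"), path)
  path
}

# two chains; chain B shifted
two_chain_pdb <- function(path) {
  a <- sapply(1:4, function(i) pdb_atom(i, "CA", "ALA", "A", i, 3.8 * i, 0, 0))
  b <- sapply(1:5, function(i)
    pdb_atom(10 + i, "CA", "GLY", "B", i, 3.8 * i, 10, 0))
  writeLines(c(a, b, "END"), path)
  path
}

# one residue with altloc A (occ 0.4) and B (occ 0.6): B must win
altloc_pdb <- function(path) {
  lines <- c(
    pdb_atom(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom(2, "CA", "ALA", "A", 2, 3.8, 0, 0, altloc = "A", occ = 0.4),
    pdb_atom(3, "CA", "ALA", "A", 2, 3.9, 0, 0, altloc = "B", occ = 0.6),
    pdb_atom(4, "CA", "ALA", "A", 3, 7.6, 1.5, 0),
    pdb_atom(5, "CA", "ALA", "A", 4, 11.4, 0, 0),
    "END")
  writeLines(lines, path)
  path
}

multi_model_pdb <- function(path, shifts = c(0, 0.5, 1)) {
  body <- unlist(lapply(seq_along(shifts), function(m) {
    c(sprintf("MODEL     %4d", m),
      sapply(1:4, function(i)
        pdb_atom(i, "CA", "ALA", "A", i, 3.8 * (i - 1), shifts[m], 0)),
      "ENDMDL")
  }))
  writeLines(c(body, "END"), path)
  path
}

# brute-force aRMSD (scalar, independent of angle_distance)
bf_armsd <- function(a, b) {
  dt <- abs(a[3] - b[3]) %% 360
  dt <- min(dt, 360 - dt)
  sqrt((abs(a[1] - b[1])^2 + abs(a[2] - b[2])^2 + dt^2) / 3)
}

# brute-force core distances: full distance matrix + sort (self included)
bf_core_distances <- function(points, min_pts, eps = 200) {
  n <- nrow(points)
  apply(sapply(1:n, function(i)
    sapply(1:n, function(j) bf_armsd(points[i, ], points[j, ]))),
    2, function(d) {
      d <- d[d <= eps]
      if (length(d) >= min_pts) sort(d)[min_pts] else Inf
    })
}

random_triples <- function(n, seed = 1) {
  set.seed(seed)
  cbind(runif(n, 0.01, 180), runif(n, 0.01, 180), runif(n, -179.99, 180))
}

# naive RMSD minimisation over rotations (grid + local polish), oracle for
# superpose(); translation handled by centring.
bf_min_rmsd <- function(X, Y, n_starts = 200, seed = 1) {
  set.seed(seed)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rot <- function(p) {  # Euler zyz
    cz1 <- cos(p[1]); sz1 <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz2 <- cos(p[3]); sz2 <- sin(p[3])
    Rz1 <- matrix(c(cz1, sz1, 0, -sz1, cz1, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rz2 <- matrix(c(cz2, sz2, 0, -sz2, cz2, 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(p) sqrt(mean(rowSums((Xc %*% rot(p) - Yc)^2)))
  best <- Inf
  for (s in 1:n_starts) {
    p0 <- runif(3, 0, 2 * pi)
    o <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}
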