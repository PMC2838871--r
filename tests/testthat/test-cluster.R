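test_that("grid prefilter applies the cell population threshold", {
  pts <- matrix(rep(c(90, 90, 50), each = 9), 9, 3)
  expect_warning(out <- grid_prefilter(pts, min_count = 10), "every point")
  expect_equal(nrow(out), 0)
  pts10 <- matrix(rep(c(90, 90, 50), each = 10), 10, 3)
  expect_equal(nrow(grid_prefilter(pts10, min_count = 10)), 10)
})

test_that("grid prefilter separates dense clusters from stragglers", {
  dense <- make_angle_cloud(rbind(c(100, 100, 40)), sigmas = 1, counts = 500,
                            seed = 8)
  set.seed(9)
  stragglers <- cbind(runif(20, 1, 180), runif(20, 1, 180), runif(20, -179, 180))
  cloud <- rbind(dense[, 1:3], stragglers)
  attr(cloud, "labels") <- c(attr(dense, "labels"), rep(2L, 20))
  out <- grid_prefilter(cloud, cell = 2, min_count = 10)
  lab <- attr(out, "labels")
  expect_true(all(lab == 1))            # stragglers removed entirely
  # deterministic fixture: direct cell counting retains 436 of the 500
  # dense points (the Gaussian centre sits on a cell corner, so its tail
  # cells fall below the population threshold)
  expect_identical(sum(lab == 1), 436L)
})

test_that("grid prefilter handles the angle-range boundaries", {
  # theta = 180 and phi = 180 are legal and must bin into real cells
  pts <- rbind(matrix(rep(c(90, 90, 180), each = 10), 10, 3),
               matrix(rep(c(180, 179.9, -179.9), each = 10), 10, 3))
  out <- grid_prefilter(pts, cell = 2, min_count = 10)
  expect_equal(nrow(out), 20)
})

test_that("OPTICS core distances equal the brute-force k-NN oracle", {
  for (seed in 1:3) {
    cloud <- make_angle_cloud(rbind(c(90, 90, 50), c(120, 130, -150),
                                    c(150, 60, 100)),
                              sigmas = c(1, 3, 8), counts = c(60, 50, 40),
                              seed = seed)
    opt <- optics_order(cloud, min_pts = 10)
    expect_identical(sort(opt$order), seq_len(nrow(cloud)))  # permutation
    bf <- bf_core_distances(cloud, 10)
    expect_equal(opt$core_distance, bf[opt$order], tolerance = 1e-9)
    expect_true(is.infinite(opt$reachability[1]))
    expect_true(all(opt$core_distance <= opt$eps))
  }
})

test_that("OPTICS orders well-separated clusters contiguously", {
  cloud <- make_angle_cloud(rbind(c(90, 90, 50), c(140, 140, -120)),
                            sigmas = 1, counts = 100, seed = 12)
  opt <- optics_order(cloud, min_pts = 10)
  lab <- attr(cloud, "labels")[opt$order]
  runs <- rle(lab)$lengths
  expect_length(runs, 2)               # each cluster one contiguous block
  r <- opt$reachability[-1]
  expect_equal(sum(r > 20), 1)         # exactly one inter-cluster jump
})

test_that("OPTICS degenerate and error cases", {
  same <- matrix(rep(c(90, 90, 0), each = 12), 12, 3)
  opt <- optics_order(same, min_pts = 3)
  expect_true(all(opt$reachability[-1] == 0))
  expect_error(optics_order(same, min_pts = 13), "exceeds")
  expect_error(optics_order(same, min_pts = 1), "at least 2")
})

test_that("Drop-Down on flat reachability yields a single root", {
  opt <- structure(list(order = 1:40, reachability = c(Inf, rep(1, 39)),
                        core_distance = rep(1, 40), eps = 200,
                        min_pts = 5L, n = 40L),
                   class = "optics_result")
  tree <- dropdown_extract(opt)
  expect_equal(nrow(tree$nodes), 1)
  expect_equal(tree$nodes$size, 40)
})

test_that("Drop-Down recovers three labelled Gaussian clusters", {
  centres <- rbind(c(90, 90, 50), c(130, 120, -160), c(100, 150, 120))
  cloud <- make_angle_cloud(centres, sigmas = 1, counts = 200, seed = 17)
  opt <- optics_order(cloud, min_pts = 20)
  tree <- dropdown_extract(opt)
  leaves <- tree$nodes[!(tree$nodes$id %in% tree$nodes$parent), ]
  expect_equal(nrow(leaves), 3)
  truth <- attr(cloud, "labels")
  for (i in seq_len(nrow(leaves))) {
    members <- truth[opt$order[leaves$lo[i]:leaves$hi[i]]]
    purity <- max(table(members)) / length(members)
    expect_gte(purity, 0.95)
  }
  # children are proper subranges, at least min_pts smaller than parents
  ch <- tree$nodes[tree$nodes$parent > 0, ]
  par <- tree$nodes[match(ch$parent, tree$nodes$id), ]
  expect_true(all(ch$lo >= par$lo & ch$hi <= par$hi))
  expect_true(all(ch$size <= par$size - tree$min_pts))
})

test_that("Drop-Down resolves a dense core nested in a broad cluster", {
  broad <- make_angle_cloud(rbind(c(110, 110, 0)), sigmas = 8, counts = 300,
                            seed = 23)
  core <- make_angle_cloud(rbind(c(110, 110, 0)), sigmas = 1, counts = 150,
                           seed = 24)
  cloud <- rbind(broad[, 1:3], core[, 1:3])
  opt <- optics_order(cloud, min_pts = 20)
  tree <- dropdown_extract(opt)
  expect_gte(max(tree$nodes$depth), 1)  # the core appears below the root
})

test_that("representatives sit at the density maxima", {
  centres <- rbind(c(90, 90, 50), c(130, 120, -160), c(100, 150, 120))
  cloud <- make_angle_cloud(centres, sigmas = 1, counts = 200, seed = 31)
  opt <- optics_order(cloud, min_pts = 20)
  tree <- dropdown_extract(opt)
  reps <- select_representatives(tree, opt, cloud)
  expect_equal(reps$cluster, tree$nodes$id)  # extraction order
  # representative core distance never exceeds any member's
  for (i in seq_len(nrow(reps))) {
    rng <- tree$nodes$lo[i]:tree$nodes$hi[i]
    expect_lte(reps$core_distance[i], min(opt$core_distance[rng]) + 1e-12)
  }
  # leaf representatives each land near a distinct true centre
  leaves <- reps[!(reps$cluster %in% tree$nodes$parent), ]
  hit <- apply(as.matrix(leaves[, c("phi1", "phi2", "theta")]), 1, function(a)
    which.min(angle_distance(a, centres)))
  expect_setequal(hit, 1:3)
  dmin <- apply(as.matrix(leaves[, c("phi1", "phi2", "theta")]), 1, function(a)
    min(angle_distance(a, centres)))
  expect_true(all(dmin < 0.5))
})

test_that("single-cluster representative approximates the true centre", {
  cloud <- make_angle_cloud(rbind(c(100, 100, 40)), sigmas = 1, counts = 500,
                            seed = 41)
  opt <- optics_order(cloud, min_pts = 20)
  reps <- select_representatives(dropdown_extract(opt), opt, cloud)
  expect_lt(angle_distance(unlist(reps[1, c("phi1", "phi2", "theta")]),
                           c(100, 100, 40)), 0.5)
})

test_that("log-normal redundancy fit recovers known parameters", {
  set.seed(51)
  x <- rlnorm(10000, meanlog = log(0.2), sdlog = 0.45)
  fit <- fit_redundancy_cutoff(x)
  expect_lt(abs(fit$meanlog - log(0.2)), 3 * fit$se[1])
  expect_lt(abs(fit$sdlog - 0.45), 3 * fit$se[2])
  expect_equal(fit$cutoff, exp(fit$meanlog + fit$sdlog))
  # ~84% of the intra-cluster peak falls below the one-sigma cutoff
  expect_equal(mean(x < fit$cutoff), 0.841, tolerance = 0.02)
  expect_error(fit_redundancy_cutoff(c(2, 3)), "below")
})

test_that("redundancy filter keeps the earlier-extracted representative", {
  ab <- m32k25()$angles
  far <- ab[c("A", "U", "Y"), ]           # mutually well separated
  expect_identical(redundancy_filter(far), 1:3)
  dup <- rbind(far, far["U", , drop = FALSE])
  expect_identical(redundancy_filter(dup), 1:3)  # duplicate dropped, first kept
  expect_error(redundancy_filter(far, cutoff = 0), "positive")
})

test_that("derive_alphabet recovers three Gaussian attractors exactly", {
  centres <- rbind(c(90, 90, 50), c(130, 120, -160), c(100, 150, 120))
  cloud <- make_angle_cloud(centres, sigmas = 1, counts = 200, seed = 61)
  ab <- derive_alphabet(cloud, min_pts = 20, min_count = 0)
  expect_equal(length(ab$letters), 3)
  expect_identical(ab$name, "M20K3")
  # each centre resolved by a distinct letter well below the inter-centre
  # separation (sub-0.5-degree accuracy is asserted across seeds in the
  # acceptance suite)
  hit <- apply(centres, 1, function(cc)
    which.min(angle_distance(cc, ab$angles)))
  expect_setequal(hit, 1:3)
  d <- apply(centres, 1, function(cc)
    min(angle_distance(cc, ab$angles)))
  expect_true(all(d < 1))
  # deterministic: identical rerun
  ab2 <- derive_alphabet(cloud, min_pts = 20, min_count = 0)
  expect_identical(ab$angles, ab2$angles)
  expect_error(derive_alphabet(cloud[1:10, ], min_pts = 50), "exceeds")
})

test_that("raising min_pts never increases the leaf count", {
  centres <- rbind(c(90, 90, 50), c(130, 120, -160), c(100, 150, 120),
                   c(160, 70, -60))
  cloud <- make_angle_cloud(centres, sigmas = c(1, 2, 1.5, 1), counts = 150,
                            seed = 71)
  leaf_count <- function(mp) {
    opt <- optics_order(cloud, min_pts = mp)
    tree <- dropdown_extract(opt)
    sum(!(tree$nodes$id %in% tree$nodes$parent))
  }
  counts <- vapply(c(10, 20, 40, 80), leaf_count, 0)
  expect_true(all(diff(counts) <= 0))
})
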