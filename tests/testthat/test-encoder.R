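test_that("single canonical fragments self-encode with zero error", {
  ab <- m32k25()
  for (l in c("B", "K", "U", "Y")) {
    enc <- encode_local(ab$canonical[[l]], ab)
    expect_identical(enc$letters, l)
    expect_lt(enc$per_position_error, 1e-6)
  }
})

test_that("local assignment equals the exhaustive superposition oracle", {
  ab <- m32k25()
  set.seed(101)
  for (i in 1:100) {
    w <- build_fragment(c(runif(1, 60, 170), runif(1, 60, 170),
                          runif(1, -179, 180)), bond = 3.8) +
      matrix(rnorm(12, sd = 0.1), 4, 3)
    enc <- encode_local(w, ab)
    # independent route: full Kabsch superposition per letter
    errs <- vapply(ab$letters, function(l)
      superpose(ab$canonical[[l]], w)$crmsd, 0)
    expect_identical(enc$letters, names(which.min(errs)))
    expect_equal(enc$per_position_error, min(errs), tolerance = 1e-9)
  }
})

test_that("both encoders are invariant to rigid motion of the input", {
  ab <- m32k25()
  tr <- chain_from_letters("AQPUYSBX", ab)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- tr$coords %*% R + matrix(c(5, -3, 11), nrow(tr$coords), 3,
                                    byrow = TRUE)
  e1 <- encode_local(tr, ab)
  e2 <- encode_local(moved, ab)
  expect_identical(e1$letters, e2$letters)
  expect_equal(e1$per_position_error, e2$per_position_error, tolerance = 1e-9)
  r1 <- reconstruct_global(tr, ab, heap = 8)
  r2 <- reconstruct_global(moved, ab, heap = 8)
  expect_identical(r1$encoding$letters, r2$encoding$letters)
  expect_equal(r1$global_crmsd, r2$global_crmsd, tolerance = 1e-9)
})

test_that("noise-free synthetic chains reconstruct exactly", {
  ab <- m32k25()
  set.seed(111)
  for (i in 1:20) {
    s <- paste(sample(ab$letters, sample(4:25, 1), replace = TRUE),
               collapse = "")
    tr <- chain_from_letters(s, ab)
    rec <- reconstruct_global(tr, ab, heap = 8)
    expect_lt(rec$global_crmsd, 1e-6)
    expect_identical(paste(rec$encoding$letters, collapse = ""), s)
  }
})

test_that("global cRMSD is non-increasing in the beam width", {
  ab <- m32k25()
  set.seed(121)
  tr <- chain_from_letters("AQPUYSBXWT", ab)
  noisy <- tr$coords + matrix(rnorm(length(tr$coords), sd = 0.3),
                              nrow(tr$coords), 3)
  cr <- vapply(c(1, 4, 16, 64), function(h)
    reconstruct_global(noisy, ab, heap = h)$global_crmsd, 0)
  expect_true(all(diff(cr) <= 1e-9))
})

test_that("a full beam equals exhaustive search over all letter strings", {
  ab <- m32k25()
  sub <- structural_alphabet(ab$angles[c("A", "H", "P", "U", "X", "Y"), ],
                             letters = c("A", "H", "P", "U", "X", "Y"),
                             name = "sub6")
  set.seed(131)
  template <- chain_from_letters("PUX", sub)$coords +
    matrix(rnorm(18, sd = 0.25), 6, 3)
  # oracle: enumerate all 6^3 strings via the generative growth rule
  combos <- expand.grid(sub$letters, sub$letters, sub$letters,
                        stringsAsFactors = FALSE)
  best <- Inf
  best_s <- ""
  for (i in seq_len(nrow(combos))) {
    s <- paste(unlist(combos[i, ]), collapse = "")
    d <- crmsd(chain_from_letters(s, sub)$coords, template)
    if (d < best) { best <- d; best_s <- s }
  }
  rec <- reconstruct_global(template, sub, heap = 6^3)
  expect_equal(rec$global_crmsd, best, tolerance = 1e-9)
  expect_identical(paste(rec$encoding$letters, collapse = ""), best_s)
})

test_that("local encoding error never exceeds global encoding error", {
  # the global string is assembly-constrained, so its pooled per-window
  # letter-fit error is bounded below by the unconstrained local fit
  ab <- m32k25()
  set.seed(141)
  for (i in 1:10) {
    s <- paste(sample(ab$letters, 12, replace = TRUE), collapse = "")
    noisy <- chain_from_letters(s, ab)$coords +
      matrix(rnorm(45, sd = 0.2), 15, 3)
    loc <- encode_local(noisy, ab, break_range = NULL)
    rec <- reconstruct_global(noisy, ab, heap = 16, break_range = NULL)
    expect_lte(loc$protein_crmsd, rec$encoding$protein_crmsd + 1e-9)
    expect_true(all(loc$per_position_error <=
                      rec$encoding$per_position_error + 1e-9))
  }
})

test_that("AIC closed forms and ordering", {
  a <- aic_score(rep(1, 100), k = 1, base = exp(1))
  expect_equal(a$aic, 2)
  expect_equal(aic_score(rep(1, 100), k = 2, base = exp(1))$aic, 4)
  # lower RSS wins at equal k
  set.seed(151)
  r1 <- runif(50, 0.1, 0.3)
  r2 <- r1 * 1.5
  expect_lt(aic_score(r1, k = 10)$aic, aic_score(r2, k = 10)$aic)
  z <- aic_score(rep(0, 10), k = 3)
  expect_true(z$zero_rss)
  expect_identical(z$aic, -Inf)
  expect_equal(aic_score(rep(0.5, 1000), k = 25)$kbit,
               (50 + 1000 * log2(0.25)) / 1000)
})

test_that("alphabet ranking orders a coarsened alphabet below the original", {
  ab <- m32k25()
  set.seed(161)
  corpus <- lapply(1:4, function(i)
    chain_from_letters(paste(sample(ab$letters, 10, replace = TRUE),
                             collapse = ""), ab))
  coarse <- structural_alphabet(ab$angles[seq(1, 25, by = 4), ],
                                name = "coarse7")
  tab <- rank_alphabets(list(ab, coarse), corpus, heap = 8)
  expect_equal(tab$k, c(25, 7))
  expect_lt(tab$global_median[1], 1e-6)     # own corpus reconstructs exactly
  expect_gt(tab$global_median[2], tab$global_median[1])
  expect_lt(tab$aic_kbit[1], tab$aic_kbit[2])
  one <- rank_alphabets(list(ab), corpus[1], heap = 8)
  expect_equal(one$local_iqd, 0)            # single value: IQD 0
})

test_that("GA subset selection matches exhaustive search on a small pool", {
  ab <- m32k25()
  truth <- c("A", "P", "U", "X", "Y")
  pool_letters <- c(truth, "B", "C", "K", "S", "T", "V", "W")
  pool <- ab$angles[pool_letters, ]
  # 4-atom corpus traces are exact canonical fragments of the true letters,
  # so the optimum (fitness 0) requires selecting all five
  corpus <- lapply(truth, function(l) ca_trace(ab$canonical[[l]], id = l))
  ga <- ga_optimize(pool, target_size = 5, corpus = corpus, pop = 400,
                    gens = 20, seed = 3)
  expect_lt(attr(ga, "fitness"), 1e-6)
  expect_setequal(pool_letters[attr(ga, "pool_indices")], truth)
  # exhaustive oracle over all C(12, 5) subsets confirms the optimum
  best <- Inf
  for (sel in combn(12, 5, simplify = FALSE)) {
    sub <- structural_alphabet(pool[sel, , drop = FALSE], name = "s")
    fit <- mean(vapply(corpus, function(tr)
      encode_local(tr, sub)$protein_crmsd, 0))
    best <- min(best, fit)
  }
  expect_equal(attr(ga, "fitness"), best, tolerance = 1e-9)
  # determinism under a fixed seed
  ga2 <- ga_optimize(pool, target_size = 5, corpus = corpus, pop = 400,
                     gens = 20, seed = 3)
  expect_identical(ga$angles, ga2$angles)
  expect_error(ga_optimize(pool, target_size = 20, corpus = corpus), "pool")
})
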