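# Rank-sum maps, cluster formation, and the label-permutation test.

test_that("rank-sum Z and p match hand-derived values", {
  r <- ranksum_z(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$z, (0 - 4.5) / sqrt(5.25), tolerance = 1e-12)
  expect_equal(r$z, -1.964, tolerance = 1e-3)
  # exact two-sided p from full enumeration: 2/20
  expect_equal(ranksum_z(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p, 0.1)
  # antisymmetry under group swap
  a <- rnorm(5); b <- rnorm(4)
  expect_equal(ranksum_z(a, b)$z, -ranksum_z(b, a)$z)
  expect_equal(ranksum_z(a, b)$p, ranksum_z(b, a)$p)
  # degenerate: all values identical
  r0 <- ranksum_z(rep(1, 3), rep(1, 4))
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)
  expect_error(ranksum_z(1, c(2, 3)), "at least 2")
})

test_that("normal approximation agrees with wilcox.test without continuity", {
  set.seed(21)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(7) + 0.5
    ours <- ranksum_z(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(ours$u, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  # tie-corrected variance
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  expect_equal(ranksum_z(a, b)$p, ref$p.value, tolerance = 1e-10)
})

test_that("exact-mode p matches the enumeration oracle for all n, m <= 6", {
  chk <- ranksum_oracle_check(nmax = 6, reps = 4, seed = 13)
  expect_lt(chk$max_exact_err, 1e-12)
  # the normal approximation deviates at the smallest sizes (worst with
  # n = m = 2 and ties); it is only relied on at cohort sizes
  expect_lt(chk$max_approx_err, 0.45)
  expect_gt(chk$n_cases, 50)
})

test_that("thresholding yields a signed map honoring validity", {
  z <- array(c(2.5, -2.5, 0.5, 3), c(1, 2, 2))
  p <- array(c(0.01, 0.01, 0.5, 0.001), c(1, 2, 2))
  s <- threshold_map(z, p, 0.05)
  expect_equal(as.integer(s), c(1L, -1L, 0L, 1L))
  expect_equal(as.integer(threshold_map(z, p * 0 + 0.5, 0.05)),
               rep(0L, 4))
  valid <- array(c(TRUE, TRUE, TRUE, FALSE), c(1, 2, 2))
  expect_equal(as.integer(threshold_map(z, p, 0.05, valid)),
               c(1L, -1L, 0L, 0L))
  # degenerate threshold labels every valid site by sign
  s1 <- threshold_map(z, p, 1.0)
  expect_equal(as.integer(s1), c(1L, -1L, 1L, 1L))
})

test_that("clusters are signed connected components with summed mass", {
  # 1 channel, 3 freqs x 3 times
  z <- array(0, c(1, 3, 3))
  s <- array(0L, c(1, 3, 3))
  z[1, 1, 1:2] <- c(2.1, 2.3); s[1, 1, 1:2] <- 1L  # adjacent in time
  z[1, 3, 3] <- 2.8; s[1, 3, 3] <- 1L              # diagonal: separate
  cl <- find_clusters(s, z, neighbors = NULL, channels = "CZ")
  expect_length(cl, 2)
  expect_equal(cl[[1]]$mass, 4.4)
  expect_equal(cl[[1]]$n_sites, 2)
  expect_equal(cl[[2]]$mass, 2.8)
  # empty map
  expect_length(find_clusters(array(0L, c(1, 3, 3)), z, NULL, "CZ"), 0)
  # opposite signs never merge
  z2 <- z; z2[1, 1, 2] <- -2.3
  s2 <- s; s2[1, 1, 2] <- -1L
  cl2 <- find_clusters(s2, z2, NULL, "CZ")
  expect_length(cl2, 3)
})

test_that("cross-channel linking joins same-site clusters between neighbors", {
  z <- array(0, c(2, 2, 2)); s <- array(0L, c(2, 2, 2))
  z[1, 1, 1] <- 2; z[2, 1, 1] <- 2.5
  s[1, 1, 1] <- 1L; s[2, 1, 1] <- 1L
  nb <- list(A = "B", B = "A")
  cl <- find_clusters(s, z, nb, c("A", "B"))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$mass, 4.5)
  # tf_only splits them
  cl2 <- find_clusters(s, z, nb, c("A", "B"), tf_only = TRUE)
  expect_length(cl2, 2)
})

test_that("the permutation test is deterministic and label-order invariant", {
  set.seed(3)
  X <- array(rnorm(8 * 1 * 4 * 4), c(8, 1, 4, 4))
  X[1:4, 1, 1:2, 1:2] <- X[1:4, 1, 1:2, 1:2] + 5
  labels <- rep(c("A", "B"), each = 4)
  r1 <- permutation_test(X, labels, n_perm = 100, seed = 9, channels = "CZ")
  r2 <- permutation_test(X, labels, n_perm = 100, seed = 9, channels = "CZ")
  expect_identical(r1$clusters, r2$clusters)
  # permuting subject order leaves results identical
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  r3 <- permutation_test(X[perm, , , , drop = FALSE], labels[perm],
                         n_perm = 100, seed = 9, channels = "CZ")
  expect_equal(r1$z, r3$z)
  expect_equal(r1$clusters$mass, r3$clusters$mass)
})

test_that("null contrasts give no clusters; separation gives minimal p", {
  X0 <- array(0, c(6, 1, 3, 3))
  labels <- rep(c("A", "B"), each = 3)
  r0 <- permutation_test(X0, labels, n_perm = 50, seed = 1, channels = "CZ")
  expect_equal(nrow(r0$clusters), 0)
  set.seed(5)
  X <- array(rnorm(6 * 1 * 4 * 4, sd = 0.1), c(6, 1, 4, 4))
  X[1:3, 1, 2:4, 2:4] <- X[1:3, 1, 2:4, 2:4] + 10
  r <- permutation_test(X, labels, n_perm = 400, seed = 2, channels = "CZ")
  top <- r$clusters[1, ]
  expect_equal(top$n_sites, 9)
  # minimum attainable p with 3v3 labels: 2 of the 20 labelings reach the
  # observed mass (the true labeling and its swap)
  expect_lte(top$p_cluster, 0.2)
  expect_gte(top$p_cluster, 0.05)
})

test_that("Monte-Carlo cluster p matches the exhaustive-labeling oracle", {
  chk <- cluster_toy_check(n_perm = 600, seed = 4)
  expect_equal(chk$p_exact, 0.1)
  expect_lt(chk$abs_err, chk$binom_tol)
})

test_that("cluster p-values are monotone in effect amplitude", {
  set.seed(6)
  base <- array(rnorm(12 * 1 * 4 * 6, sd = 1), c(12, 1, 4, 6))
  labels <- rep(c("A", "B"), each = 6)
  ps <- sapply(c(1, 3, 8), function(amp) {
    X <- base
    X[1:6, 1, 2:3, 2:5] <- X[1:6, 1, 2:3, 2:5] + amp
    r <- permutation_test(X, labels, n_perm = 300, seed = 11,
                          channels = "CZ", plus_one = TRUE)
    if (nrow(r$clusters)) min(r$clusters$p_cluster) else 1
  })
  expect_true(all(diff(ps) <= 0))
})

test_that("cluster results serialize to JSON", {
  set.seed(5)
  X <- array(rnorm(6 * 1 * 4 * 4, sd = 0.1), c(6, 1, 4, 4))
  X[1:3, 1, 2:4, 2:4] <- X[1:3, 1, 2:4, 2:4] + 10
  r <- permutation_test(X, rep(c("A", "B"), each = 3), n_perm = 50,
                        seed = 2, channels = "CZ")
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_json(r, path)
  back <- jsonlite::read_json(path)
  expect_equal(length(back$clusters), nrow(r$clusters))
  expect_equal(back$clusters[[1]]$mass, r$clusters$mass[1])
})
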