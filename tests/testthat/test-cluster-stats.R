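test_that("trialwise correlation reproduces exact linear relations", {
  set.seed(2)
  data <- array(rnorm(3 * 6 * 40), c(3, 6, 40))
  s <- runif(40)
  data[1, 2, ] <- 2 * s        # perfect linear relation
  data[2, 4, ] <- -s           # perfect anti-correlation
  data[3, 5, ] <- 7            # zero variance
  e <- toy_epochs(data)
  r <- trialwise_correlation(e, s)
  expect_equal(unname(r[1, 2]), 1, tolerance = 1e-12)
  expect_equal(unname(r[2, 4]), -1, tolerance = 1e-12)
  expect_true(is.na(r[3, 5]))
  expect_true(all(abs(r) <= 1, na.rm = TRUE))
  # naive per-point textbook Pearson oracle
  expect_equal(unclass(r), oracle_pearson_map(e, s), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant regressor: everything missing, loudly
  expect_warning(r0 <- trialwise_correlation(e, rep(1, 40)),
                 "zero variance")
  expect_true(all(is.na(r0)))
  expect_error(trialwise_correlation(e, s[-1]), "does not match")
})

test_that("group t maps match the textbook formula with df = n - 1", {
  set.seed(5)
  maps <- lapply(1:6, function(i) matrix(rnorm(4 * 7), 4))
  tm <- group_t_map(maps)
  expect_equal(attr(tm, "df"), 5L)
  expect_equal(attr(tm, "kind"), "t_onesample")
  expect_equal(unclass(tm), oracle_t_map(maps), tolerance = 1e-12,
               ignore_attr = TRUE)
  # paired mode equals one-sample on differences
  maps_b <- lapply(1:6, function(i) matrix(rnorm(4 * 7), 4))
  tp <- group_t_map(maps, "paired", maps_b)
  expect_equal(attr(tp, "kind"), "t_paired")
  expect_equal(unclass(tp),
               oracle_t_map(Map(`-`, maps, maps_b)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # 18 subjects give the df the field reports
  maps18 <- lapply(1:18, function(i) matrix(rnorm(4), 2))
  expect_equal(attr(group_t_map(maps18), "df"), 17L)
  # degenerate variance is flagged as missing everywhere
  same <- lapply(1:5, function(i) matrix(0, 2, 3))
  expect_true(all(is.na(group_t_map(same))))
  expect_error(group_t_map(maps, "paired"), "maps_b")
  expect_error(group_t_map(list(maps[[1]], matrix(0, 2, 2))), "shapes")
})

test_that("adjacency graphs are symmetric, irreflexive distance neighbourhoods", {
  far <- data.frame(channel = c("a", "b"), x = c(0, 10), y = 0)
  g <- build_adjacency(far, radius = 5)  # farther apart than the threshold
  expect_false(any(g))
  m <- default_montage()
  adj <- build_adjacency(m)
  expect_true(isSymmetric(unclass(adj)))
  expect_false(any(diag(adj)))
  # brute-force pairwise distance recomputation
  thr <- attr(adj, "threshold")
  for (i in seq_len(nrow(m))) {
    d <- sqrt((m$x - m$x[i])^2 + (m$y - m$y[i])^2)
    expect_equal(which(adj[i, ]), setdiff(which(d <= thr), i),
                 ignore_attr = TRUE)
  }
  expect_error(build_adjacency(data.frame(channel = "a", x = 1, y = 1)),
               "at least 2")
  bad <- m; bad$x[3] <- NA
  expect_error(build_adjacency(bad), bad$channel[3])
})

test_that("cluster permutation p values equal exhaustive sign-flip enumeration", {
  set.seed(42)
  n <- 5; nch <- 3; nt <- 8
  montage <- data.frame(channel = c("a", "b", "c"), x = c(0, 1, 2), y = 0)
  adj <- build_adjacency(montage, radius = 1.1)
  # plant an effect on two adjacent channels so a valid cluster exists
  maps <- lapply(1:n, function(i) {
    m <- matrix(rnorm(nch * nt, 0, 1), nch)
    m[1:2, 3:5] <- m[1:2, 3:5] + 2.5
    m
  })
  cfg <- cluster_config(n_permutations = 1000, min_adjacent_channels = 2)
  res <- suppressMessages(
    cluster_permutation_test(maps, mode = "onesample", adjacency = adj,
                             config = cfg))
  expect_true(res$exhaustive)
  expect_message(cluster_permutation_test(maps, mode = "onesample",
                                          adjacency = adj, config = cfg),
                 "exhaustive")
  df <- n - 1
  tcrit <- qt(1 - cfg$cluster_forming_p / 2, df)
  oracle <- oracle_exhaustive(maps, tcrit, unclass(adj),
                              cfg$min_adjacent_channels)
  expect_equal(nrow(res$clusters), length(oracle$p))
  expect_equal(abs(res$clusters$cluster_sum), oracle$abs_sums,
               tolerance = 1e-10)
  expect_equal(res$clusters$p, oracle$p, tolerance = 1e-10)
  # p values live in [1/n_null, 1]
  expect_true(all(res$clusters$p >= 1 / 2^n & res$clusters$p <= 1))
})

test_that("paired permutation equals sign flips of within-subject differences", {
  set.seed(7)
  montage <- data.frame(channel = c("a", "b"), x = c(0, 1), y = 0)
  adj <- build_adjacency(montage, radius = 1.1)
  a <- lapply(1:5, function(i) matrix(rnorm(2 * 6), 2) + 1.5)
  b <- lapply(1:5, function(i) matrix(rnorm(2 * 6), 2))
  cfg <- cluster_config(n_permutations = 100)
  res <- suppressMessages(
    cluster_permutation_test(a, b, mode = "paired", adjacency = adj,
                             config = cfg))
  df <- 4
  tcrit <- qt(1 - cfg$cluster_forming_p / 2, df)
  oracle <- oracle_exhaustive(Map(`-`, a, b), tcrit, unclass(adj),
                              cfg$min_adjacent_channels)
  expect_equal(res$clusters$p, oracle$p, tolerance = 1e-10)
})

test_that("single-channel blobs are discarded regardless of their mass", {
  set.seed(9)
  montage <- data.frame(channel = c("a", "b", "c"), x = c(0, 5, 10), y = 0)
  adj <- build_adjacency(montage, radius = 1)  # no channel has neighbours
  maps <- lapply(1:6, function(i) {
    m <- matrix(rnorm(3 * 10, 0, 0.5), 3)
    m[2, 3:8] <- m[2, 3:8] + 10  # huge single-channel effect
    m
  })
  res <- suppressMessages(
    cluster_permutation_test(maps, mode = "onesample", adjacency = adj,
                             config = cluster_config(n_permutations = 64)))
  expect_equal(nrow(res$clusters), 0L)
  # with min_adjacent_channels = 1 the same blob is found and significant
  res1 <- suppressMessages(cluster_permutation_test(
    maps, mode = "onesample", adjacency = adj,
    config = cluster_config(n_permutations = 64,
                            min_adjacent_channels = 1)))
  expect_gt(nrow(res1$clusters), 0L)
  expect_true(any(res1$clusters$significant))
})

test_that("an unreachable cluster-forming threshold yields no clusters", {
  set.seed(3)
  montage <- data.frame(channel = c("a", "b"), x = c(0, 1), y = 0)
  adj <- build_adjacency(montage, radius = 1.1)
  maps <- lapply(1:6, function(i) matrix(rnorm(2 * 10), 2))
  res <- suppressMessages(cluster_permutation_test(
    maps, mode = "onesample", adjacency = adj,
    config = cluster_config(n_permutations = 64,
                            cluster_forming_p = 1e-9)))
  expect_equal(nrow(res$clusters), 0L)
  expect_true(all(res$null == 0))
})

test_that("permutation p values are invariant to channel relabelling", {
  set.seed(11)
  montage <- data.frame(channel = letters[1:4], x = c(0, 1, 2, 3), y = 0)
  adj <- build_adjacency(montage, radius = 1.1)
  maps <- lapply(1:5, function(i) matrix(rnorm(4 * 8), 4) +
                   c(1.5, 1.5, 0, 0))
  perm <- c(3, 1, 4, 2)
  adj_p <- build_adjacency(montage[perm, ], radius = 1.1)
  maps_p <- lapply(maps, function(m) m[perm, ])
  cfg <- cluster_config(n_permutations = 200)
  res <- suppressMessages(
    cluster_permutation_test(maps, mode = "onesample", adjacency = adj,
                             config = cfg))
  res_p <- suppressMessages(
    cluster_permutation_test(maps_p, mode = "onesample",
                             adjacency = adj_p, config = cfg))
  expect_equal(sort(res$clusters$p), sort(res_p$clusters$p))
  expect_equal(sort(abs(res$clusters$cluster_sum)),
               sort(abs(res_p$clusters$cluster_sum)), tolerance = 1e-10)
})

test_that("Fisher-z transforming r maps never flips a pointwise t sign", {
  set.seed(13)
  rmaps <- lapply(1:8, function(i)
    matrix(tanh(rnorm(3 * 9, 0.1, 0.4)), 3))
  t_raw <- group_t_map(rmaps)
  t_fz <- group_t_map(rmaps, fisher_z = TRUE)
  expect_true(all(sign(t_raw) == sign(t_fz), na.rm = TRUE))
})

test_that("the mean cluster-mass mode runs and controls its own cutoff", {
  set.seed(17)
  montage <- data.frame(channel = c("a", "b"), x = c(0, 1), y = 0)
  adj <- build_adjacency(montage, radius = 1.1)
  maps <- lapply(1:6, function(i) matrix(rnorm(2 * 12), 2) + 1)
  res <- suppressMessages(cluster_permutation_test(
    maps, mode = "onesample", adjacency = adj,
    config = cluster_config(n_permutations = 64, statistic = "mean")))
  expect_true(is.numeric(res$null_cutoff))
  expect_true(all(res$clusters$p >= 0 & res$clusters$p <= 1))
})

test_that("cluster_config validates its parameters", {
  expect_error(cluster_config(alpha = 1.5), "alpha")
  expect_error(cluster_config(n_permutations = 0), "n_permutations")
})
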