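test_that("hand-checkable distances come out exactly", {
  x <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  expect_equal(as.numeric(distance_matrix(x, "binary")), 2 / 3)
  expect_equal(as.numeric(distance_matrix(x, "manhattan")), 2)
  expect_equal(as.numeric(distance_matrix(x, "maximum")), 1)
  expect_equal(as.numeric(distance_matrix(x, "euclidean")), sqrt(2))

  same <- rbind(c(1, 0, 1), c(1, 0, 1))
  for (met in c("binary", "canberra", "correlation", "euclidean",
                "manhattan", "maximum", "minkowski", "uncentered"))
    expect_equal(as.numeric(distance_matrix(same, met)), 0, info = met)
})

test_that("every metric matches its literal formula on random binary matrices", {
  set.seed(11)
  for (rep in 1:5) {
    X <- matrix(rbinom(5 * 8, 1, 0.5), 5, 8)
    X[1, 1] <- 1                         # avoid all-zero rows for uncentered
    for (met in c("binary", "canberra", "correlation", "euclidean",
                  "manhattan", "maximum", "minkowski", "uncentered")) {
      ok <- if (met == "correlation") apply(X, 1, stats::sd) > 0 else TRUE
      if (!all(ok)) next
      D <- as.matrix(distance_matrix(X, met, minkowski_p = 3))
      for (i in 1:4) for (j in (i + 1):5)
        expect_equal(D[i, j], oracle_dist(X[i, ], X[j, ], met, p = 3),
                     tolerance = 1e-12, info = met)
    }
  }
})

test_that("constant rows under correlation metrics warn and use the 0/1 convention", {
  X <- rbind(c(1, 1, 1), c(1, 1, 1), c(1, 0, 0))
  expect_warning(D <- as.matrix(distance_matrix(X, "correlation")), "constant row")
  expect_equal(D[1, 2], 0)    # identical constant rows
  expect_equal(D[1, 3], 1)    # constant vs anything else
})

test_that("two points merge at their distance under every linkage", {
  d <- stats::dist(rbind(c(0, 0), c(3, 4)))
  for (lnk in c("upgma", "mcquitty", "median", "single", "complete",
                "centroid", "ward.D2"))
    expect_equal(agglomerate(d, lnk)$height, 5, info = lnk)
})

test_that("single and complete linkage match definition-level recomputation", {
  set.seed(21)
  for (rep in 1:10) {
    X <- matrix(runif(10), 5, 2)
    d <- stats::dist(X)
    for (method in c("single", "complete")) {
      h <- agglomerate(d, method)
      want <- oracle_linkage(d, method)
      expect_equal(h$height, want$heights, tolerance = 1e-12)
      for (k in 1:5) {
        got <- cut_dendrogram(h, k)
        oracle_part <- want$partitions[[5 - k + 1]]
        key <- function(p) sort(vapply(p, function(s) paste(sort(s), collapse = ","),
                                       character(1)))
        expect_identical(key(unname(split(seq_len(5), got))), key(oracle_part))
      }
    }
  }
})

test_that("dendrogram cuts behave at the extremes and refine with k", {
  net_support <- load_angiogenesis_fixture()$support
  d <- distance_matrix(net_support, "binary")
  h <- agglomerate(d, "upgma")
  expect_identical(as.integer(table(cut_dendrogram(h, 1))), 48L)
  expect_true(all(table(cut_dendrogram(h, 48)) == 1))
  expect_error(cut_dendrogram(h, 0), "between 1 and")
  expect_error(cut_dendrogram(h, 49), "between 1 and")

  for (k in c(2, 5, 10, 20)) {
    a <- cut_dendrogram(h, k)
    b <- cut_dendrogram(h, k + 1)
    # each finer cluster sits inside exactly one coarser cluster
    expect_true(all(tapply(a, b, function(v) length(unique(v))) == 1))
  }
})

test_that("silhouettes match the literal formula and the cluster package", {
  set.seed(31)
  X <- matrix(runif(40), 10, 4)
  d <- stats::dist(X)
  cl <- cut_dendrogram(agglomerate(d, "complete"), 4)
  s <- silhouette_widths(cl, d)
  expect_equal(s, oracle_silhouette(cl, d), tolerance = 1e-12)
  expect_true(all(s >= -1 & s <= 1))
  if (requireNamespace("cluster", quietly = TRUE)) {
    ref <- cluster::silhouette(cl, d)[, "sil_width"]
    expect_equal(unname(s), unname(ref), tolerance = 1e-12)
  }
})

test_that("silhouette edge cases follow the stated conventions", {
  # two well-separated blocks: within 0, between 1 -> all s = 1
  D <- matrix(1, 4, 4); D[1:2, 1:2] <- 0; D[3:4, 3:4] <- 0
  cl <- c(1, 1, 2, 2)
  expect_equal(silhouette_widths(cl, stats::as.dist(D)), rep(1, 4))

  # singleton cluster elements get 0
  cl2 <- c(1, 1, 2, 3)
  expect_equal(silhouette_widths(cl2, stats::as.dist(D))[4], 0)

  expect_error(silhouette_widths(rep(1, 4), stats::as.dist(D)), "single-cluster")
})

test_that("MSS satisfies the weighted-mean identity and singleton degeneracy", {
  fx <- load_angiogenesis_fixture()
  d <- distance_matrix(fx$support, "correlation")
  h <- agglomerate(d, "upgma")
  for (k in c(3, 7, 13)) {
    cl <- cut_dendrogram(h, k)
    mss <- mean_split_silhouette(cl, d)
    sizes <- table(cl)[names(mss$per_cluster)]
    expect_equal(mss$global,
                 sum(as.numeric(sizes) * mss$per_cluster) / length(cl),
                 tolerance = 1e-12)
    expect_true(mss$global >= -1 && mss$global <= 1)
  }
  # all singletons score exactly 0
  cl_all <- cut_dendrogram(h, 48)
  expect_equal(mean_split_silhouette(cl_all, d)$global, 0)
})

test_that("clustering statistics are invariant under row permutation", {
  fx <- load_angiogenesis_fixture()
  S <- fx$support
  set.seed(13)
  perm <- sample(nrow(S))
  d1 <- distance_matrix(S, "binary")
  d2 <- distance_matrix(S[perm, ], "binary")
  cl1 <- cut_dendrogram(agglomerate(d1, "upgma"), 11)
  cl2 <- cut_dendrogram(agglomerate(d2, "upgma"), 11)
  expect_identical(sort(as.integer(table(cl1))), sort(as.integer(table(cl2))))
  expect_equal(mean_split_silhouette(cl1, d1)$global,
               mean_split_silhouette(cl2, d2)$global, tolerance = 1e-12)
})

test_that("the evaluation grid composes the component operations", {
  fx <- load_angiogenesis_fixture()
  S <- fx$support[1:20, ]
  grid <- evaluate_grid(S, metrics = c("binary", "euclidean"),
                        linkages = c("upgma", "single"), k_range = 2:4)
  expect_identical(nrow(grid), 2L * 2L * 3L)
  for (i in seq_len(nrow(grid))) {
    d <- distance_matrix(S, grid$metric[i])
    cl <- cut_dendrogram(agglomerate(d, grid$linkage[i]), grid$k[i])
    expect_identical(grid$singletons[i], sum(table(cl) == 1L))
    expect_equal(grid$mss[i], mean_split_silhouette(cl, d)$global,
                 tolerance = 1e-12)
  }
})
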