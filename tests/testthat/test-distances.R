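test_that("identical trees give an all-zero distance matrix", {
  tr <- random_tree(8, seed = 3)
  coll <- tree_collection(rep(list(tr), 5))
  for (metric in c("kc", "rf", "path", "path_l1", "bs", "abouheif", "sumdd"))
    expect_equal(max(distance_matrix(coll, metric)$values), 0)
})

test_that("the documented two-tree KC distance is sqrt(2)", {
  coll <- tree_collection(list(ape::read.tree(text = "((A,B),C);"),
                               ape::read.tree(text = "((A,C),B);")))
  expect_equal(distance_matrix(coll, "kc")$values[1, 2], sqrt(2))
})

test_that("matrices equal the naive per-pair recomputation", {
  coll <- rand_collection(15, 10, seed = 61)
  vec_fun <- list(
    kc = function(t) kc_vector(t, 0.3)$entries,
    path = function(t) path_vector(t)$entries,
    abouheif = function(t) abouheif_vector(t)$entries,
    sumdd = function(t) sum_dd_vector(t)$entries)
  for (metric in names(vec_fun)) {
    D <- distance_matrix(coll, metric, lambda = 0.3)$values
    for (i in 1:14) for (j in (i + 1):15) {
      vi <- vec_fun[[metric]](coll$trees[[i]])
      vj <- vec_fun[[metric]](coll$trees[[j]])
      expect_equal(D[i, j], sqrt(sum((vi - vj)^2)), tolerance = 1e-9)
    }
  }
  Dl1 <- distance_matrix(coll, "path_l1")$values
  Drf <- distance_matrix(coll, "rf")$values
  for (i in 1:14) for (j in (i + 1):15) {
    expect_equal(Dl1[i, j],
                 sum(abs(path_vector(coll$trees[[i]])$entries -
                         path_vector(coll$trees[[j]])$entries)),
                 tolerance = 1e-9)
    expect_identical(Drf[i, j],
                     as.numeric(rf_distance(coll$trees[[i]],
                                            coll$trees[[j]])))
  }
})

test_that("RF distance counts the split symmetric difference", {
  a <- ape::read.tree(text = "((A,B),(C,D));")
  b <- ape::read.tree(text = "((A,C),(B,D));")
  expect_identical(rf_distance(a, a), 0L)
  expect_identical(rf_distance(a, b), 2L)
  expect_error(rf_distance(a, ape::read.tree(text = "((A,B),(C,E));")),
               class = "treeislands_input_error")
  set.seed(71)
  for (i in 1:30) {
    n <- sample(4:15, 1)
    t1 <- random_tree(n); t2 <- random_tree(n)
    rf <- rf_distance(t1, t2)
    expect_identical(rf, oracle_rf(t1, t2))
    expect_lte(rf, 2 * (n - 3))
    expect_equal(rf, as.numeric(phangorn::RF.dist(ape::unroot(t1),
                                                  ape::unroot(t2))))
  }
})

test_that("all metrics satisfy the metric axioms on random trees", {
  coll <- rand_collection(12, 10, seed = 81)
  for (metric in c("kc", "rf", "path", "path_l1", "bs", "abouheif", "sumdd")) {
    D <- distance_matrix(coll, metric, lambda = 0.5)$values
    expect_identical(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0))
    for (j in seq_len(nrow(D)))
      expect_true(all(outer(D[, j], D[j, ], `+`) - D >= -1e-9))
  }
})

test_that("KC lambda=0 distance is zero iff rooted topologies coincide", {
  set.seed(91)
  for (i in 1:50) {
    t1 <- random_tree(6)
    t2 <- if (i %% 2 == 0) {
      relab <- t1                      # same topology, new lengths
      relab$edge.length <- rexp(length(relab$edge.length))
      relab
    } else random_tree(6)
    d <- distance_matrix(tree_collection(list(t1, t2)), "kc")$values[1, 2]
    same <- identical(canonical_topology(t1), canonical_topology(t2))
    expect_identical(d == 0, same)
  }
})

test_that("distance matrices serialise to TSV and PHYLIP", {
  coll <- rand_collection(4, 6, seed = 95)
  dm <- distance_matrix(coll, "kc")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, f)
  back <- read.delim(f, check.names = FALSE)
  expect_identical(back$tree, coll$names)
  expect_equal(as.matrix(back[, -1]), dm$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  p <- withr::local_tempfile(fileext = ".dist")
  write_distance_matrix(dm, p, format = "phylip")
  expect_identical(as.integer(trimws(readLines(p)[1])), 4L)
})
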