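tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")

test_that("KC vectors blend root-to-MRCA depths and path lengths", {
  expect_equal(kc_vector(tr3, 0)$entries,
               c("A|B" = 1, "A|C" = 0, "B|C" = 0, A = 1, B = 1, C = 1))
  expect_equal(kc_vector(tr3, 1)$entries,
               c("A|B" = 1, "A|C" = 0, "B|C" = 0, A = 1, B = 1, C = 2))
  expect_equal(kc_vector(tr3, 0.5)$entries,
               c("A|B" = 1, "A|C" = 0, "B|C" = 0, A = 1, B = 1, C = 1.5))
})

test_that("KC preconditions: rootedness, lengths, lambda range", {
  star <- ape::read.tree(text = "(A,B,C);")
  expect_error(kc_vector(star, 0), class = "treeislands_precondition_error")
  topo <- ape::read.tree(text = "((A,B),C);")
  expect_silent(kc_vector(topo, 0))
  expect_error(kc_vector(topo, 0.5),
               class = "treeislands_precondition_error")
  expect_error(kc_vector(tr3, 1.5),
               class = "treeislands_precondition_error")
})

test_that("KC vector has length n(n-1)/2 + n and is scale-free at lambda 0", {
  for (n in c(2, 5, 17, 40)) {
    v <- kc_vector(random_tree(n, seed = n), 0)
    expect_length(v$entries, n * (n - 1) / 2 + n)
  }
  set.seed(7)
  for (i in 1:20) {
    tr <- random_tree(10)
    sc <- tr
    sc$edge.length <- sc$edge.length * runif(1, 0.01, 100)
    expect_identical(kc_vector(tr, 0)$entries, kc_vector(sc, 0)$entries)
  }
})

test_that("KC m and M entries match the ancestor-set MRCA oracle", {
  set.seed(21)
  for (i in 1:40) {
    tr <- random_tree(sample(4:20, 1))
    ref <- oracle_kc_mm(tr)
    m <- kc_vector(tr, 0)$entries
    M <- kc_vector(tr, 1)$entries
    expect_identical(names(m), ref$names)
    expect_equal(unname(m), ref$m, tolerance = 0)
    expect_equal(unname(M), ref$M, tolerance = 1e-12)
  }
})

test_that("path vectors count tip-to-tip edges", {
  expect_equal(path_vector(ape::read.tree(text = "((A,B),C);"))$entries,
               c("A|B" = 2, "A|C" = 3, "B|C" = 3))
  expect_equal(path_vector(ape::read.tree(text = "(A,B);"))$entries,
               c("A|B" = 2))
  caterpillar <- ape::read.tree(
    text = "(((((((A,B),C),D),E),F),G),H);")
  balanced <- ape::read.tree(
    text = "(((A,B),(C,D)),((E,F),(G,H)));")
  expect_false(identical(path_vector(caterpillar)$entries,
                         path_vector(balanced)$entries))
  set.seed(31)
  for (i in 1:25) {
    tr <- random_tree(sample(3:15, 1))
    expect_equal(path_vector(tr)$entries, oracle_path_counts(tr))
  }
})

test_that("branch-score vectors map splits to edge lengths", {
  coll <- tree_collection(list(tr3, tr3))
  expect_equal(distance_matrix(coll, "bs")$values[1, 2], 0)
  bumped <- tr3
  bumped$edge.length[2] <- bumped$edge.length[2] + 0.37
  expect_equal(
    distance_matrix(tree_collection(list(tr3, bumped)), "bs")$values[1, 2],
    0.37)
  topo <- ape::read.tree(text = "((A,B),C);")
  expect_error(branch_score_vector(topo),
               class = "treeislands_precondition_error")
})

test_that("branch-score distances equal split-union brute force and KF.dist", {
  set.seed(41)
  for (i in 1:15) {
    t1 <- random_tree(8); t2 <- random_tree(8)
    mine <- distance_matrix(tree_collection(list(t1, t2)), "bs")$values[1, 2]
    expect_equal(mine, oracle_bs_dist(t1, t2), tolerance = 1e-9)
    expect_equal(mine, as.numeric(phangorn::KF.dist(t1, t2)),
                 tolerance = 1e-9)
  }
})

test_that("direct-descendant vectors follow the tip-pair path walk", {
  expect_equal(abouheif_vector(ape::read.tree(text = "((A,B),C);"))$entries,
               c("A|B" = 2, "A|C" = 4, "B|C" = 4))
  star <- ape::read.tree(text = "(A,B,C);")
  expect_equal(unname(abouheif_vector(star)$entries), c(3, 3, 3))
  expect_equal(unname(sum_dd_vector(star)$entries), c(3, 3, 3))
  expect_equal(sum_dd_vector(ape::read.tree(text = "((A,B),C);"))$entries,
               oracle_dd(ape::read.tree(text = "((A,B),C);"), sum))
  expect_equal(unname(sum_dd_vector(ape::read.tree(text = "(A,B);"))$entries),
               2)
  set.seed(51)
  for (i in 1:20) {
    tr <- random_tree(sample(3:15, 1))
    expect_equal(abouheif_vector(tr)$entries, oracle_dd(tr, prod))
    expect_equal(sum_dd_vector(tr)$entries, oracle_dd(tr, sum))
    sc <- tr
    sc$edge.length <- sc$edge.length * 3.7
    expect_identical(abouheif_vector(tr)$entries,
                     abouheif_vector(sc)$entries)
  }
})
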