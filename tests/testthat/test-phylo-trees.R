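test_that("newick reading parses records and validates tip sets", {
  tf <- newick_file("(A:1,B:2);")
  trees <- read_newick_trees(tf)
  expect_length(trees, 1)
  expect_setequal(trees[[1]]$tip.label, c("A", "B"))
  expect_equal(sort(trees[[1]]$edge.length), c(1, 2))

  tf3 <- newick_file(c("(A:1,(B:1,C:1):1);", "((A:2,B:1):1,C:2);",
                       "(B:1,(A:1,C:1):2);"))
  expect_length(read_newick_trees(tf3), 3)

  expect_error(read_newick_trees(newick_file("((A:1,B:1;")),
               "record 1")
  expect_error(read_newick_trees(newick_file("(A:1,A:2);")),
               "duplicate tip labels")
  expect_error(
    read_newick_trees(newick_file(c("(A:1,B:2);", "(A:1,C:2);"))),
    "different tip set"
  )
  expect_error(read_newick_trees(tempfile()), "not found")
})

test_that("consensus of identical trees returns the input tree", {
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1,(D:2,E:1):0.25):1);")
  trees <- c(tr, tr, tr)
  cons <- majority_rule_consensus(trees)
  expect_true(ape::all.equal.phylo(cons, tr, use.edge.length = TRUE))
})

test_that("clades at or below the threshold frequency are excluded", {
  # {A,B} in 3 of 4 trees (0.75 > 0.5: kept); {C,D} in 2 of 4
  # (0.5, not > 0.5: dropped)
  t_ab_cd <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t_ab <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  t_other <- ape::read.tree(text = "(((A:1,C:1):1,B:1):1,D:1);")
  trees <- c(t_ab_cd, t_ab_cd, t_ab, t_other)
  cons <- majority_rule_consensus(trees, 0.5)
  clades <- oracle_clades(cons)
  expect_true("A|B" %in% clades)
  expect_false("C|D" %in% clades)
  expect_false("A|C" %in% clades)
})

test_that("consensus clades match the brute-force frequency filter exactly", {
  set.seed(42)
  for (rep in 1:8) {
    n_tips <- sample(5:8, 1)
    n_trees <- sample(4:10, 1)
    base <- ape::rtree(n_tips)
    trees <- c(list(base), lapply(seq_len(n_trees - 1), function(i) {
      phangorn::rNNI(base, moves = sample(0:2, 1))
    }))
    class(trees) <- "multiPhylo"
    for (thr in c(0.5, 0.7)) {
      cons <- majority_rule_consensus(trees, thr)
      expect_setequal(oracle_clades(cons), oracle_majority_clades(trees, thr))
    }
  }
})

test_that("consensus branch lengths average over supporting trees", {
  t1 <- ape::read.tree(text = "((A:1,B:1):2,C:1);")
  t2 <- ape::read.tree(text = "((A:3,B:2):4,C:2);")
  t3 <- ape::read.tree(text = "((A:2,C:1):1,B:3);")  # no {A,B} clade
  cons <- majority_rule_consensus(c(t1, t2, t3))
  # {A,B} in 2/3 trees; its edge averages 2 and 4; tips average all 3 trees
  bp <- bipartition_frequencies(c(t1, t2, t3))
  ab <- bp[vapply(bp$tips, function(x) identical(sort(x), c("A", "B")),
                  logical(1)), ]
  expect_equal(ab$frequency, 2 / 3)
  expect_equal(ab$mean_length, 3)
  d <- cons$edge.length[cons$edge[, 2] == which(cons$tip.label == "A")]
  expect_equal(d, mean(c(1, 3, 2)))
  internal <- cons$edge.length[cons$edge[, 2] > length(cons$tip.label)]
  expect_equal(internal, 3)
})

test_that("consensus is idempotent", {
  set.seed(7)
  base <- ape::rtree(6)
  trees <- c(list(base), lapply(1:5, function(i) phangorn::rNNI(base, 1)))
  class(trees) <- "multiPhylo"
  cons <- majority_rule_consensus(trees)
  cons2 <- majority_rule_consensus(structure(list(cons),
                                             class = "multiPhylo"))
  expect_true(ape::all.equal.phylo(cons, cons2, use.edge.length = TRUE))
})

test_that("consensus rejects empty or inconsistent inputs", {
  expect_error(majority_rule_consensus(structure(list(),
                                                 class = "multiPhylo")),
               "empty")
  t1 <- ape::read.tree(text = "(A:1,B:1);")
  expect_error(majority_rule_consensus(c(t1, t1), threshold = 1), "threshold")
  expect_error(majority_rule_consensus(c(t1, t1), threshold = 0.3),
               "threshold")
})

test_that("patristic distances are exact path sums", {
  tr <- ape::read.tree(text = "(A:1,B:2);")
  d <- patristic_distance_matrix(tr)
  expect_equal(d["A", "B"], 3)

  tr2 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d2 <- patristic_distance_matrix(tr2)
  expect_equal(d2["A", "B"], 2)
  expect_equal(d2["A", "C"], 4)
  expect_equal(d2["B", "C"], 4)

  expect_error(patristic_distance_matrix(ape::read.tree(text = "(A,B);")),
               "branch length")
})

test_that("patristic distances equal the naive path-sum oracle", {
  set.seed(11)
  for (rep in 1:20) {
    tr <- simulate_yule_tree(sample(4:30, 1))
    d <- patristic_distance_matrix(tr)
    expect_equal(d, oracle_patristic(tr), tolerance = 1e-12)
  }
})

test_that("patristic distances satisfy the four-point condition", {
  set.seed(3)
  tr <- simulate_yule_tree(10)
  d <- patristic_distance_matrix(tr)
  labs <- rownames(d)
  quads <- utils::combn(labs, 4)
  for (q in seq_len(ncol(quads))) {
    a <- quads[1, q]; b <- quads[2, q]; c <- quads[3, q]; e <- quads[4, q]
    sums <- sort(c(d[a, b] + d[c, e], d[a, c] + d[b, e],
                   d[a, e] + d[b, c]))
    expect_lt(sums[3] - sums[2], 1e-9)
  }
})

test_that("patristic distances are permutation-equivariant in tip order", {
  set.seed(5)
  tr <- simulate_yule_tree(8)
  d <- patristic_distance_matrix(tr)
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  d2 <- patristic_distance_matrix(rot)
  labs <- sort(tr$tip.label)
  expect_equal(d[labs, labs], d2[labs, labs], tolerance = 1e-12)
})
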