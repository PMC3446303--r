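caterpillar <- function() {
  # 1-D points forcing (((a,b),c),d) under complete linkage
  build_dendrogram(matrix(c(0, 1, 5, 30), ncol = 1,
                          dimnames = list(c("a", "b", "c", "d"), NULL)))
}

balanced4 <- function() {
  build_dendrogram(matrix(c(0, 1, 10, 11), ncol = 1,
                          dimnames = list(c("a", "b", "c", "d"), NULL)))
}

balanced8 <- function() {
  # pairs at distance 1, pairs-of-pairs at ~10, halves at ~100
  build_dendrogram(matrix(c(0, 1, 10, 11, 100, 101, 110, 111), ncol = 1,
                          dimnames = list(letters[1:8], NULL)))
}

test_that("two rows merge once at their Euclidean distance", {
  d <- build_dendrogram(matrix(c(0, 0, 3, 4), nrow = 2, byrow = TRUE,
                               dimnames = list(c("a", "b"), NULL)))
  expect_equal(nrow(d$merge), 1)
  expect_equal(d$height, 5)
  expect_error(build_dendrogram(matrix(1, 1, 1)), "2 rows")
  expect_error(build_dendrogram(matrix(c(1, NA), 2, 1)), "missing")
})

test_that("complete linkage merges by maximum pairwise distance", {
  d <- build_dendrogram(matrix(c(0, 1, 10), ncol = 1,
                               dimnames = list(c("a", "b", "c"), NULL)))
  expect_equal(d$height, c(1, 10))  # final merge at max(|0-10|,|1-10|)
})

test_that("dendrogram agrees with the naive O(n^3) oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:12, 1)
    x <- matrix(stats::rnorm(n * 3), nrow = n,
                dimnames = list(sprintf("g%02d", 1:n), NULL))
    d <- build_dendrogram(x)
    oracle <- oracle_complete_linkage(x)
    expect_equal(d$height, oracle$heights, tolerance = 1e-10)
    expect_equal(hclust_partitions(d), oracle$partitions)
  }
})

test_that("rootdist assigns depth 0 to the root and +1 per level", {
  d2 <- build_dendrogram(matrix(c(0, 1), ncol = 1,
                                dimnames = list(c("a", "b"), NULL)))
  expect_equal(rootdist(d2), 0L)
  d4 <- balanced4()
  rd <- rootdist(d4)
  expect_equal(rd[length(rd)], 0L)       # root merge
  expect_equal(sort(rd), c(0L, 1L, 1L))  # two child merges at depth 1
  cat_rd <- rootdist(caterpillar())
  # spine depths 0,1,2 from root to the deepest merge
  expect_equal(sort(cat_rd), c(0L, 1L, 2L))
})

test_that("rootdist cuts yield the contracted clusters", {
  expect_equal(cut_clusters(balanced4(), nesthc_params("rootdist", 1)),
               list(c("a", "b"), c("c", "d")))
  # cutlevel 0: one cluster of everything
  expect_equal(cut_clusters(balanced4(), nesthc_params("rootdist", 0)),
               list(c("a", "b", "c", "d")))
  # caterpillar at depth 1: {a,b,c} subtree, d detaches as a singleton
  expect_equal(cut_clusters(caterpillar(), nesthc_params("rootdist", 1)),
               list(c("a", "b", "c"), "d"))
  # cutting deeper than the tree leaves only singletons
  deep <- cut_clusters(balanced4(), nesthc_params("rootdist", 5))
  expect_true(all(lengths(deep) == 1))
})

test_that("height cuts straddle the root and the smallest merge", {
  d <- balanced4()
  top <- cut_clusters(d, nesthc_params("height", max(d$height) + 1))
  expect_equal(lengths(top), 4L)
  bottom <- cut_clusters(d, nesthc_params("height", min(d$height) / 2))
  expect_true(all(lengths(bottom) == 1))
  k <- cut_clusters(d, nesthc_params("height", cut_height_for_k(d, 2)))
  expect_equal(k, list(c("a", "b"), c("c", "d")))
})

test_that("cut_clusters is always a partition of the leaves", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:14, 1)
    x <- matrix(stats::rnorm(n * 2), nrow = n,
                dimnames = list(sprintf("g%02d", 1:n), NULL))
    d <- build_dendrogram(x)
    for (lev in 0:4) {
      cl <- cut_clusters(d, nesthc_params("rootdist", lev))
      all_members <- unlist(cl)
      expect_equal(sort(all_members), sort(d$labels))
      expect_false(anyDuplicated(all_members) > 0)
    }
    h <- stats::runif(1, 0, max(d$height) * 1.2)
    cl <- cut_clusters(d, nesthc_params("height", h))
    expect_equal(sort(unlist(cl)), sort(d$labels))
  }
})

test_that("nest_dendrogram mirrors cut_clusters at the outermost level", {
  g <- gen_modular_graph(m = 5, nmax = 30, seed = 4)
  am <- matrix(0, 30, 30, dimnames = list(leaf_ids(g), leaf_ids(g)))
  el <- edges(g)
  for (i in seq_len(nrow(el))) {
    am[el$u[i], el$v[i]] <- am[el$v[i], el$u[i]] <- 1
  }
  d <- build_dendrogram(am)
  params <- nesthc_params("rootdist", 3)
  res <- nest_dendrogram(g, d, params)
  cl <- cut_clusters(d, params)
  expected_containers <- sum(lengths(cl) >= 2)
  expect_equal(length(res$containers), expected_containers)
  # container memberships equal the non-singleton clusters
  got <- lapply(res$containers, function(id) leaf_descendants(res$graph, id))
  got <- got[order(vapply(got, min, character(1)))]
  want <- Filter(function(s) length(s) >= 2, cl)
  expect_equal(got, want)
  # singletons stay unnested
  singles <- unlist(Filter(function(s) length(s) == 1, cl))
  for (s in singles) {
    expect_equal(ancestors(res$graph, s), character(0))
  }
  expect_no_error(validate_graph(res$graph))
})

test_that("nlev = 2 nests child subtrees inside each outer module", {
  d <- balanced8()
  g <- add_node(hier_graph(), letters[1:8])
  res <- nest_dendrogram(g, d, nesthc_params("rootdist", 1, nlev = 2))
  top <- Filter(function(id) length(ancestors(res$graph, id)) == 0,
                res$containers)
  inner <- setdiff(res$containers, top)
  expect_equal(length(top), 2)
  expect_equal(length(inner), 4)
  for (id in inner) {
    expect_equal(length(children(res$graph, id)), 2)
    expect_true(ancestors(res$graph, id) %in% top)
  }
  for (leaf in letters[1:8]) {
    expect_equal(length(ancestors(res$graph, leaf)), 2)
  }
})

test_that("a cut deeper than the tree creates no containers", {
  d <- balanced4()
  g <- add_node(hier_graph(), c("a", "b", "c", "d"))
  res <- nest_dendrogram(g, d, nesthc_params("rootdist", 10))
  expect_equal(res$containers, character(0))
  expect_equal(sort(node_ids(res$graph)), c("a", "b", "c", "d"))
  expect_error(
    nest_dendrogram(add_node(hier_graph(), "zz"), d, nesthc_params()),
    "labels"
  )
})

test_that("linkage tables round-trip a dendrogram", {
  set.seed(9)
  x <- matrix(stats::rnorm(24), nrow = 8,
              dimnames = list(sprintf("g%d", 1:8), NULL))
  d <- build_dendrogram(x)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_linkage(d, path)
  d2 <- read_linkage(path)
  expect_equal(d2$merge, d$merge)
  expect_equal(d2$height, d$height)
  expect_equal(d2$labels, d$labels)
  expect_equal(d2$order, d$order)
  expect_equal(cut_clusters(d2, nesthc_params("rootdist", 2)),
               cut_clusters(d, nesthc_params("rootdist", 2)))
})
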