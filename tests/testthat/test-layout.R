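two_node_graph <- function() {
  g <- add_node(hier_graph(), c("a", "b"))
  add_edge(g, "a", "b")
}

test_that("initial placement is seed-deterministic", {
  g <- random_nested_graph(1)
  p <- force_params(seed = 42)
  s1 <- init_layout(g, p)
  s2 <- init_layout(g, p)
  expect_identical(s1$positions, s2$positions)
  s3 <- init_layout(g, force_params(seed = 43))
  expect_false(identical(s1$positions, s3$positions))
})

test_that("single node layout has a position and no radii", {
  g <- add_node(hier_graph(), "solo")
  s <- init_layout(g)
  expect_equal(nrow(s$positions), 1)
  expect_equal(length(s$radii), 0)
  res <- relax_step(g, s, force_params())
  expect_equal(res$max_displacement, 0)
  final <- relax(g)
  expect_equal(final$positions, init_layout(g)$positions)
})

test_that("a container starts at the centroid of its members", {
  g <- add_node(hier_graph(), c("a", "b", "c", "d"))
  g <- nest(g, c("a", "b", "c", "d"), "C")
  s <- init_layout(g, force_params(seed = 5))
  expect_equal(
    as.numeric(s$positions["C", ]),
    as.numeric(colMeans(s$positions[c("a", "b", "c", "d"), ]))
  )
  expect_true(s$radii[["C"]] > 0)
})

test_that("repulsion between two close siblings is equal and opposite", {
  g <- add_node(hier_graph(), c("a", "b"))
  s <- init_layout(g, force_params(seed = 1))
  s$positions["a", ] <- c(0, 0)
  s$positions["b", ] <- c(5, 0)  # well below the equilibrium spacing
  res <- relax_step(g, s, force_params())
  da <- res$state$positions["a", ] - c(0, 0)
  db <- res$state$positions["b", ] - c(5, 0)
  expect_equal(unname(da), unname(-db), tolerance = 1e-12)
  expect_true(da[["x"]] < 0 && db[["x"]] > 0)  # pushed apart on the axis
  expect_equal(da[["y"]], 0)
})

test_that("one relaxation step is translation equivariant", {
  g <- random_nested_graph(7)
  p <- force_params(seed = 3)
  s <- init_layout(g, p)
  shift <- c(137.25, -42.5)
  s2 <- s
  s2$positions <- sweep(s$positions, 2, -shift)
  r1 <- relax_step(g, s, p)
  r2 <- relax_step(g, s2, p)
  moved <- sweep(r1$state$positions, 2, -shift)
  expect_equal(r2$state$positions, moved, tolerance = 1e-9)
  expect_equal(r1$max_displacement, r2$max_displacement, tolerance = 1e-9)
})

test_that("two connected nodes settle at the closed-form equilibrium", {
  # attraction d^2/k balances repulsion k^2/d exactly at d = k
  for (seed in c(2, 9, 21)) {
    g <- two_node_graph()
    p <- force_params(rest_length = 30, seed = seed)
    s <- relax(g, p)
    d <- sqrt(sum((s$positions["a", ] - s$positions["b", ])^2))
    expect_lt(abs(d - 30) / 30, 0.05)
  }
})

test_that("relaxation is deterministic for identical inputs", {
  g <- nested_fixture()
  p <- force_params(seed = 11)
  s1 <- relax(g, p)
  s2 <- relax(g, p)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$iteration, s2$iteration)
})

test_that("temperature decreases strictly and caps displacement", {
  g <- nested_fixture()
  p <- force_params(seed = 2)
  s <- init_layout(g, p)
  temps <- s$temperature
  for (i in 1:25) {
    pre_temp <- s$temperature
    res <- relax_step(g, s, p)
    s <- res$state
    expect_lt(s$temperature, pre_temp)
    expect_lte(res$max_displacement, pre_temp + 1e-12)
    temps <- c(temps, s$temperature)
  }
  expect_true(all(diff(temps) < 0))
})

test_that("members end up inside their container circles", {
  bad_runs <- 0
  for (seed in 1:20) {
    g <- nested_fixture()
    s <- relax(g, force_params(seed = seed))
    if (nrow(containment_check(g, s)) > 0) bad_runs <- bad_runs + 1
  }
  expect_lte(bad_runs, 1)
})

test_that("containment_check flags exactly the displaced members", {
  g <- add_node(hier_graph(), c("a", "b"))
  g <- nest(g, c("a", "b"), "C")
  s <- init_layout(g, force_params(seed = 1))
  s$positions["a", ] <- s$positions["C", ]
  s$positions["b", ] <- s$positions["C", ]
  expect_equal(nrow(containment_check(g, s)), 0)
  s$positions["b", ] <- s$positions["C", ] + c(10 * s$radii[["C"]], 0)
  v <- containment_check(g, s)
  expect_equal(v$id, "b")
})

test_that("freezing all nodes yields zero displacement", {
  g <- nested_fixture()
  p <- force_params(seed = 4)
  s <- init_layout(g, p)
  res <- relax_step(g, s, p, movable = character())
  expect_equal(res$max_displacement, 0)
  expect_equal(res$state$positions, s$positions)
})

test_that("static layouts cover all nodes deterministically", {
  g <- nested_fixture()
  for (fn in list(layout_circle, layout_grid)) {
    s <- fn(g)
    expect_equal(sort(rownames(s$positions)), sort(node_ids(g)))
    expect_identical(s$positions, fn(g)$positions)
  }
})

test_that("layout tables round-trip through TSV", {
  g <- nested_fixture()
  s <- relax(g, force_params(seed = 6, max_iter = 40))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_layout(s, path)
  s2 <- read_layout(path)
  expect_equal(s2$positions[rownames(s$positions), ], s$positions,
               tolerance = 1e-6)
  expect_equal(sort(names(s2$radii)), sort(names(s$radii)))
})
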