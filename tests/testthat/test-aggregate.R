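bipartite_fixture <- function(cross_pairs) {
  # |A| = 2, |B| = 3; cross_pairs = list of c(a-side, b-side) edges
  g <- add_node(hier_graph(), c("a1", "a2", "b1", "b2", "b3"))
  g <- nest(g, c("a1", "a2"), "A")
  g <- nest(g, c("b1", "b2", "b3"), "B")
  for (p in cross_pairs) g <- add_edge(g, p[1], p[2])
  g
}

all_pairs <- list(c("a1", "b1"), c("a1", "b2"), c("a1", "b3"),
                  c("a2", "b1"), c("a2", "b2"), c("a2", "b3"))

test_that("module edge density is cross edges over possible pairs", {
  g <- bipartite_fixture(all_pairs)
  me <- module_edge_weight(g, "A", "B")
  expect_equal(me$count, 6)
  expect_equal(me$weight, 1.0)   # complete bipartite
  g0 <- bipartite_fixture(list())
  expect_equal(module_edge_weight(g0, "A", "B")$weight, 0.0)
  g3 <- bipartite_fixture(all_pairs[c(1, 4, 5)])
  expect_equal(module_edge_weight(g3, "A", "B")$weight, 0.5)
})

test_that("module edges reject nested or empty containers", {
  g <- bipartite_fixture(all_pairs)
  g <- nest(g, c("A", "B"), "Top")
  expect_error(module_edge_weight(g, "Top", "A"), "nested")
  expect_error(module_edge_weight(g, "A", "A"), "distinct")
  g2 <- add_node(bipartite_fixture(list()), "E", kind = "container")
  expect_error(module_edge_weight(g2, "A", "E"), "empty")
  expect_error(module_edge_weight(g2, "A", "a1"), "container")
})

test_that("aggregate_all matches exhaustive leaf-pair counting", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    m <- sample(3:5, 1)
    g <- gen_modular_graph(m = m, nmax = n, p_in = 0.4, p_out = 0.15,
                           seed = seed)
    labels <- node_attr(g, "module", leaf_ids(g))
    cids <- character()
    for (mod in unique(labels)) {
      cid <- new_container_id(g)
      g <- nest(g, names(labels)[labels == mod], cid)
      cids <- c(cids, cid)
    }
    agg <- aggregate_all(g, cids)
    expect_true(all(agg$weight >= 0 & agg$weight <= 1))
    total_cross <- 0
    for (i in seq_len(length(cids) - 1)) {
      for (j in (i + 1):length(cids)) {
        la <- leaf_descendants(g, cids[i])
        lb <- leaf_descendants(g, cids[j])
        want <- oracle_cross_count(g, la, lb)
        total_cross <- total_cross + want
        row <- agg[(agg$a == cids[i] & agg$b == cids[j]) |
                     (agg$a == cids[j] & agg$b == cids[i]), ]
        got <- if (nrow(row)) row$count else 0
        expect_equal(got, want)
        if (want > 0) {
          expect_equal(row$weight, want / (length(la) * length(lb)))
        }
      }
    }
    expect_equal(sum(agg$count), total_cross)
  }
})

test_that("aggregation is invariant under leaf relabeling", {
  g <- gen_modular_graph(m = 3, nmax = 12, p_in = 0.5, p_out = 0.1,
                         seed = 7)
  labels <- node_attr(g, "module", leaf_ids(g))
  for (mod in unique(labels)) {
    g <- nest(g, names(labels)[labels == mod], paste0("C_", mod))
  }
  base <- aggregate_all(g, paste0("C_", unique(labels)))
  set.seed(1)
  perm <- sample(leaf_ids(g))
  names(perm) <- leaf_ids(g)
  g2 <- hier_graph()
  for (mod in unique(labels)) {
    g2 <- add_node(g2, sort(unname(perm[names(labels)[labels == mod]])))
  }
  el <- edges(g)
  for (i in seq_len(nrow(el))) {
    g2 <- add_edge(g2, perm[[el$u[i]]], perm[[el$v[i]]], el$weight[i])
  }
  for (mod in unique(labels)) {
    g2 <- nest(g2, unname(perm[names(labels)[labels == mod]]),
               paste0("C_", mod))
  }
  got <- aggregate_all(g2, paste0("C_", unique(labels)))
  ord <- function(x) x[order(x$a, x$b), c("count", "possible", "weight")]
  a <- ord(base); b <- ord(got)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("weighted aggregation sums edge weights instead of counting", {
  g <- bipartite_fixture(list())
  g <- add_edge(g, "a1", "b1", weight = 0.25)
  g <- add_edge(g, "a2", "b2", weight = 0.5)
  expect_equal(module_edge_weight(g, "A", "B")$count, 2)
  expect_equal(module_edge_weight(g, "A", "B", weighted = TRUE)$count, 0.75)
})

test_that("diverging colors are symmetric about the neutral midpoint", {
  vals <- c(-2, -1, 0, 1, 2)
  cols <- style_diverging(vals)
  expect_equal(cols[3], "#F7F7F7")             # midpoint -> neutral
  expect_equal(cols[5], "#B2182B")             # +max -> positive endpoint
  expect_equal(cols[1], "#2166AC")             # -max -> negative endpoint
  # mirror: color(-x) uses the same interpolation fraction as color(+x)
  up <- grDevices::col2rgb(cols[4])
  dn <- grDevices::col2rgb(cols[2])
  neutral <- grDevices::col2rgb("#F7F7F7")
  pos <- grDevices::col2rgb("#B2182B")
  neg <- grDevices::col2rgb("#2166AC")
  expect_equal(as.numeric(up), as.numeric((neutral + pos) / 2),
               tolerance = 1)
  expect_equal(as.numeric(dn), as.numeric((neutral + neg) / 2),
               tolerance = 1)
  expect_equal(style_diverging(numeric()), character())
})

test_that("styling preserves (or inverts) value order", {
  set.seed(3)
  vals <- stats::rnorm(20)
  cols <- style_diverging(vals)
  # red channel increases with the value under blue-white-red
  reds <- grDevices::col2rgb(cols)["red", ]
  expect_true(all(diff(reds[order(vals)]) <= 0 + 255) &&
                cor(vals, as.numeric(reds)) > 0)
  d <- stats::rexp(20, 1 / 50)
  sizes <- style_size(d)
  expect_equal(cor(d, sizes, method = "spearman"), -1)
  expect_equal(sizes[which.min(d)], 20)  # nearest gene drawn largest
  expect_equal(sizes[which.max(d)], 5)
  mid <- style_size(c(0, 50, 100))
  expect_equal(mid[2], (5 + 20) / 2)     # linear interpolation
  expect_equal(style_size(rep(7, 3)), rep(12.5, 3))
  expect_error(style_size(c(-1, 2)), "nonnegative")
})
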