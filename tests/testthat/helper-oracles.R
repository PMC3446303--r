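# Independent oracles and fixture builders. These deliberately avoid the
# package's own traversal/clustering code paths.

# Connected components by boolean reachability closure over the adjacency
# matrix (matrix squaring until fixpoint).
oracle_components <- function(ids, edge_u, edge_v) {
  n <- length(ids)
  if (n == 0L) return(list())
  R <- diag(TRUE, n)
  dimnames(R) <- list(ids, ids)
  for (k in seq_along(edge_u)) {
    R[edge_u[k], edge_v[k]] <- TRUE
    R[edge_v[k], edge_u[k]] <- TRUE
  }
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  comps <- unique(apply(R, 1, function(row) paste(sort(ids[row]),
                                                  collapse = "\r")))
  lapply(comps, function(s) strsplit(s, "\r", fixed = TRUE)[[1]])
}

oracle_largest_component <- function(ids, edge_u, edge_v) {
  comps <- oracle_components(ids, edge_u, edge_v)
  if (!length(comps)) return(character())
  sizes <- lengths(comps)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    mins <- vapply(comps[best], min, character(1))
    best <- best[order(mins)][1L]
  }
  sort(comps[[best]])
}

# Naive O(n^3) agglomerative complete-linkage clustering on the rows of x.
# Returns merge heights and the partition (set of sets) after each merge.
oracle_complete_linkage <- function(x) {
  n <- nrow(x)
  D <- as.matrix(stats::dist(x))
  clusters <- lapply(seq_len(n), function(i) rownames(x)[i])
  heights <- numeric(0)
  partitions <- list()
  canon <- function(cl) {
    srt <- lapply(cl, sort)
    srt[order(vapply(srt, `[[`, "", 1L))]
  }
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) {
          best_h <- h
          best <- c(i, j)
        } else if (abs(h - best_h) <= 1e-12) {
          # tie: prefer the pair with lexicographically smallest minima
          cand <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
          cur <- sort(c(min(clusters[[best[1]]]), min(clusters[[best[2]]])))
          if (paste(cand, collapse = " ") < paste(cur, collapse = " ")) {
            best <- c(i, j)
          }
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    partitions[[length(partitions) + 1L]] <- canon(clusters)
  }
  list(heights = heights, partitions = partitions)
}

# Partitions implied by an hclust object after each successive merge.
hclust_partitions <- function(d) {
  n <- length(d$labels)
  canon <- function(cl) {
    srt <- lapply(cl, sort)
    srt[order(vapply(srt, `[[`, "", 1L))]
  }
  sets <- as.list(d$labels)
  live <- rep(TRUE, n)                    # leaves not yet merged
  merge_sets <- vector("list", n - 1L)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    pick <- function(ref) {
      if (ref < 0) {
        live[-ref] <<- FALSE
        d$labels[-ref]
      } else {
        merge_sets[[ref]]
      }
    }
    merge_sets[[i]] <- c(pick(d$merge[i, 1]), pick(d$merge[i, 2]))
    open <- Filter(Negate(is.null), merge_sets[seq_len(i)])
    # an earlier merge absorbed into a later one is no longer a cluster
    absorbed <- logical(i)
    for (j in seq_len(i)) {
      for (jj in seq_len(i)) {
        if (j != jj && all(merge_sets[[j]] %in% merge_sets[[jj]])) {
          absorbed[j] <- TRUE
        }
      }
    }
    cl <- c(merge_sets[seq_len(i)][!absorbed], as.list(d$labels[live]))
    out[[i]] <- canon(cl)
  }
  out
}

# Exhaustive leaf-pair cross-edge count between two leaf sets.
oracle_cross_count <- function(g, la, lb) {
  el <- edges(g)
  el <- el[el$layer == "leaf", , drop = FALSE]
  cnt <- 0L
  for (a in la) {
    for (b in lb) {
      u <- min(a, b); v <- max(a, b)
      cnt <- cnt + sum(el$u == u & el$v == v)
    }
  }
  cnt
}

# Random nested graph with attributes, for round-trip and layout tests.
random_nested_graph <- function(seed, n_leaves = NULL, p_edge = 0.15) {
  set.seed(seed)
  if (is.null(n_leaves)) n_leaves <- sample(3:15, 1)
  ids <- sprintf("n%02d", seq_len(n_leaves))
  g <- hier_graph()
  g <- add_node(g, ids)
  for (id in sample(ids, min(3, n_leaves))) {
    g <- set_node_attrs(g, id,
                        score = round(stats::rnorm(1), 4),
                        label = paste0("node ", id),
                        flagged = sample(c(TRUE, FALSE), 1))
  }
  if (n_leaves >= 2) {
    pairs <- utils::combn(ids, 2)
    for (k in which(stats::runif(ncol(pairs)) < p_edge)) {
      g <- add_edge(g, pairs[1, k], pairs[2, k],
                    weight = round(stats::runif(1, 0.1, 2), 4))
    }
  }
  # one or two nesting levels over random disjoint groups
  pool <- ids
  n_groups <- sample(0:3, 1)
  made <- character()
  for (i in seq_len(n_groups)) {
    if (length(pool) < 2) break
    size <- sample(2:min(4, length(pool)), 1)
    members <- sample(pool, size)
    pool <- setdiff(pool, members)
    cid <- new_container_id(g)
    g <- nest(g, members, cid)
    made <- c(made, cid)
  }
  if (length(made) >= 2 && stats::runif(1) < 0.5) {
    g <- nest(g, sample(made, 2), new_container_id(g))
  }
  g
}

# Structural equality of two hier_graphs (order-insensitive, numeric
# attributes compared with tolerance).
expect_graphs_equal <- function(a, b) {
  na <- a$nodes[order(a$nodes$id), , drop = FALSE]
  nb <- b$nodes[order(b$nodes$id), , drop = FALSE]
  rownames(na) <- rownames(nb) <- NULL
  expect_equal(na, nb)
  for (id in na$id) {
    aa <- a$attrs[[id]]
    bb <- b$attrs[[id]]
    if (length(aa) + length(bb) == 0) next
    expect_equal(aa[order(names(aa))], bb[order(names(bb))])
  }
  ea <- a$edges[order(a$edges$u, a$edges$v, a$edges$layer), , drop = FALSE]
  eb <- b$edges[order(b$edges$u, b$edges$v, b$edges$layer), , drop = FALSE]
  rownames(ea) <- rownames(eb) <- NULL
  expect_equal(ea, eb)
}

# Two sibling containers of three members each, joined by one cross edge.
nested_fixture <- function() {
  g <- hier_graph()
  g <- add_node(g, letters[1:6])
  g <- add_edge(g, "a", "b")
  g <- add_edge(g, "b", "c")
  g <- add_edge(g, "d", "e")
  g <- add_edge(g, "e", "f")
  g <- add_edge(g, "c", "d")
  g <- nest(g, c("a", "b", "c"), "A")
  g <- nest(g, c("d", "e", "f"), "B")
  g
}

# A random but valid sequence of graph operations; returns the graph.
random_op_sequence <- function(seed, n_ops = 20, max_nodes = 50) {
  set.seed(seed)
  g <- hier_graph()
  g <- add_node(g, sprintf("x%02d", 1:4))
  counter <- 4L
  for (k in seq_len(n_ops)) {
    op <- sample(c("add_leaf", "add_edge", "nest", "unnest"), 1,
                 prob = c(0.3, 0.3, 0.25, 0.15))
    if (op == "add_leaf" && length(node_ids(g)) < max_nodes) {
      counter <- counter + 1L
      g <- add_node(g, sprintf("x%02d", counter))
    } else if (op == "add_edge") {
      lv <- leaf_ids(g)
      if (length(lv) >= 2) {
        uv <- sample(lv, 2)
        g <- add_edge(g, uv[1], uv[2], weight = stats::runif(1))
      }
    } else if (op == "nest") {
      # candidates: nodes none of which is an ancestor of another
      cand <- sample(node_ids(g), min(length(node_ids(g)), sample(2:5, 1)))
      ok <- Filter(function(id) !any(ancestors(g, id) %in% cand), cand)
      if (length(ok) >= 2) g <- nest(g, ok)
    } else if (op == "unnest") {
      cc <- container_ids(g)
      if (length(cc)) g <- unnest(g, sample(cc, 1))
    }
  }
  g
}
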