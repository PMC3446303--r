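#' Co-expression module pipeline
#'
#' End-to-end nested co-expression analysis: (1) build the co-expression
#' graph, connecting genes i and j when `|Pearson r| >= corr_threshold`;
#' (2) cluster the expression rows with complete-linkage Euclidean
#' clustering; (3) superimpose the dendrogram onto the graph as nested
#' module containers; (4) aggregate inter-module connectivity into
#' density-weighted association edges; (5) style nodes — diverging color
#' by log2 fold-change, inverse size by kilobase distance to the nearest
#' binding site.
#'
#' @param expr Numeric matrix, genes (rows, named) x samples. Rows with
#'   zero variance are excluded from the correlation graph with a warning.
#' @param attrs Data frame with column `id` matching `rownames(expr)`;
#'   optional columns `logfc` and `kb_dist` drive the styling.
#' @param corr_threshold Absolute Pearson correlation threshold for
#'   drawing a co-expression edge.
#' @param params A [nesthc_params()] for the dendrogram cut; by default a
#'   height cut tuned to `k` clusters.
#' @param k Cluster count used when `params` is `NULL` (default 5).
#' @return List: `graph` (nested, styled `hier_graph` with aggregated
#'   association edges), `module_edges` (data frame), `containers`,
#'   `dendrogram`.
#' @export
coexpression_pipeline <- function(expr, attrs, corr_threshold = 0.7,
                                  params = NULL, k = 5) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr must have row names", call. = FALSE)
  if (!all(rownames(expr) %in% attrs$id)) {
    stop("attrs must cover all expression rows", call. = FALSE)
  }
  g <- hier_graph()
  for (id in rownames(expr)) {
    row <- attrs[attrs$id == id, , drop = FALSE]
    a <- list()
    for (nm in setdiff(names(row), "id")) a[[nm]] <- row[[nm]][1L]
    g <- add_node(g, id, attrs = a)
  }
  vars <- apply(expr, 1, stats::var)
  if (any(vars == 0)) {
    warning(sum(vars == 0), " zero-variance row(s) excluded from the ",
            "correlation graph", call. = FALSE)
  }
  keep <- rownames(expr)[vars > 0]
  if (length(keep) >= 2 && corr_threshold <= 1) {
    cc <- stats::cor(t(expr[keep, , drop = FALSE]))
    for (i in seq_len(length(keep) - 1L)) {
      for (j in (i + 1L):length(keep)) {
        r <- cc[i, j]
        if (is.finite(r) && abs(r) >= corr_threshold) {
          g <- add_edge(g, keep[i], keep[j], weight = abs(r))
        }
      }
    }
  }
  d <- build_dendrogram(expr)
  if (is.null(params)) {
    params <- nesthc_params(metric = "height",
                            cutlevel = cut_height_for_k(d, k))
  }
  nested <- nest_dendrogram(g, d, params)
  g <- nested$graph
  top <- nested$containers[vapply(nested$containers, function(id) {
    is.na(g$nodes$parent[match(id, g$nodes$id)])
  }, logical(1))]
  me <- aggregate_all(g, top)
  g <- add_module_edges(g, me)
  if ("logfc" %in% names(attrs)) {
    cols <- style_diverging(node_attr(g, "logfc", rownames(expr)))
    for (i in seq_along(rownames(expr))) {
      g <- set_node_attrs(g, rownames(expr)[i], color = cols[i])
    }
  }
  if ("kb_dist" %in% names(attrs)) {
    sizes <- style_size(node_attr(g, "kb_dist", rownames(expr)))
    for (i in seq_along(rownames(expr))) {
      g <- set_node_attrs(g, rownames(expr)[i], size = sizes[i])
    }
  }
  list(graph = g, module_edges = me, containers = nested$containers,
       dendrogram = d)
}

#' Fraction of genes whose container matches their planted module
#'
#' Assigns each top-level container its majority planted label; a gene
#' counts as recovered when its outermost container's majority label is
#' its own. Unnested genes count as not recovered.
#'
#' @param g A nested `hier_graph`.
#' @param labels Named character vector, gene id -> planted module label.
#' @return Fraction in [0, 1].
#' @export
module_recovery <- function(g, labels) {
  .check_hg(g)
  genes <- names(labels)
  top <- vapply(genes, function(id) {
    a <- ancestors(g, id)
    if (length(a)) a[[length(a)]] else NA_character_
  }, character(1))
  ok <- 0L
  for (ct in unique(stats::na.omit(top))) {
    members <- genes[!is.na(top) & top == ct]
    tab <- sort(table(labels[members]), decreasing = TRUE)
    maj <- names(tab)[1L]
    ok <- ok + sum(labels[members] == maj)
  }
  ok / length(genes)
}

#' Overlap counts of consecutive sets
#'
#' @param sets Ordered list (length >= 2) of id vectors, e.g. the members
#'   of the largest subnetwork at successive time points.
#' @return Integer vector of `|sets[i] intersect sets[i+1]|`, length
#'   `length(sets) - 1`.
#' @export
consecutive_overlap <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets", call. = FALSE)
  vapply(seq_len(length(sets) - 1L), function(i) {
    length(intersect(sets[[i]], sets[[i + 1L]]))
  }, integer(1))
}

#' Time-course subnetwork nesting pipeline
#'
#' For each time point t, selects the largest connected component L(t) of
#' the interactome subgraph induced by the DE set. Containers are chained
#' innermost-first: when `L(t)` is a subset of `L(t+1)` the container of t
#' is nested inside the container of t+1; otherwise the container of t is
#' placed alongside (members already claimed by a later container stay
#' there) and an association edge weighted by the overlap count links the
#' two. Nodes are colored by the log2 fold-change of the earliest time
#' point containing them.
#'
#' @param interactome A `hier_graph` (e.g. from [gen_scalefree()]).
#' @param de_sets Named list, ordered by time point, of data frames with
#'   columns `id` (interactome leaves) and `logfc`.
#' @return List: `graph` (interactome with chained containers),
#'   `containers` (named by time point; `NA` where skipped), `components`
#'   (the L(t) sets), `overlaps` (data frame `from`, `to`, `overlap`),
#'   `nested` (logical per consecutive pair).
#' @export
timecourse_pipeline <- function(interactome, de_sets) {
  .check_hg(interactome)
  if (length(de_sets) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (is.null(names(de_sets))) {
    names(de_sets) <- paste0("t", seq_along(de_sets))
  }
  tps <- names(de_sets)
  g <- interactome
  comps <- list()
  for (tp in tps) {
    s <- de_sets[[tp]]$id
    bad <- setdiff(s, leaf_ids(g))
    if (length(bad)) {
      stop("DE ids absent from the interactome: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    comps[[tp]] <- largest_connected_component(g, s)
  }
  containers <- stats::setNames(rep(NA_character_, length(tps)), tps)
  claimed <- character()
  nested <- stats::setNames(rep(NA, length(tps) - 1L), tps[-length(tps)])
  # outermost (last time point) first so inner nest() finds its parent
  for (i in rev(seq_along(tps))) {
    tp <- tps[i]
    L <- comps[[tp]]
    if (length(L) == 0L) {
      warning("empty largest component at ", tp, "; container skipped",
              call. = FALSE)
      next
    }
    if (i < length(tps)) {
      nxt <- comps[[tps[i + 1L]]]
      nested[[tp]] <- length(L) > 0 && all(L %in% nxt) &&
        !is.na(containers[[tps[i + 1L]]])
    }
    members <- if (i < length(tps) && isFALSE(nested[[tp]])) {
      setdiff(L, claimed)
    } else {
      L
    }
    if (length(members) == 0L) {
      warning("all members of ", tp, " already claimed; container skipped",
              call. = FALSE)
      next
    }
    id <- new_container_id(g, prefix = "T")
    g <- nest(g, members, id, attrs = list(timepoint = tp))
    containers[[tp]] <- id
    claimed <- union(claimed, members)
  }
  # association edges between consecutive non-nested containers
  for (i in seq_len(length(tps) - 1L)) {
    a <- containers[[tps[i]]]; b <- containers[[tps[i + 1L]]]
    if (!is.na(a) && !is.na(b) && isFALSE(nested[[tps[i]]])) {
      ov <- length(intersect(comps[[tps[i]]], comps[[tps[i + 1L]]]))
      if (ov > 0) g <- add_edge(g, a, b, weight = ov, layer = "association")
    }
  }
  # per-gene logfc from the earliest time point containing it
  lfc <- list()
  for (tp in rev(tps)) {
    s <- de_sets[[tp]]
    for (r in seq_len(nrow(s))) lfc[[s$id[r]]] <- s$logfc[r]
  }
  ids <- names(lfc)
  cols <- style_diverging(unlist(lfc))
  for (i in seq_along(ids)) {
    g <- set_node_attrs(g, ids[i], logfc = lfc[[ids[i]]], color = cols[i])
  }
  overlaps <- data.frame(
    from = tps[-length(tps)], to = tps[-1L],
    overlap = consecutive_overlap(comps), stringsAsFactors = FALSE
  )
  list(graph = g, containers = containers, components = comps,
       overlaps = overlaps, nested = nested)
}
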