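#' Complete-linkage Euclidean dendrogram
#'
#' Agglomerative clustering of the rows of a numeric matrix with Euclidean
#' distance and complete linkage (each step merges the pair of clusters
#' whose maximum pairwise distance is smallest). This is the clustering
#' used to superimpose module structure onto a network; any numeric matrix
#' works — an expression matrix (genes x samples) or a graph adjacency
#' matrix alike.
#'
#' @param x Numeric matrix with at least 2 rows and no missing values.
#'   Row names become the dendrogram leaf labels (defaults `L1..Ln`).
#' @return A `stats::hclust` object with `$labels` set.
#' @export
build_dendrogram <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to cluster", call. = FALSE)
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("L", seq_len(nrow(x)))
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "complete")
  hc$labels <- rownames(x)
  hc
}

#' Depth of each dendrogram merge from the root
#'
#' The final merge (the root) has depth 0; each merge's depth is its
#' parent's depth plus one. This is the `"rootdist"` metric used to cut a
#' dendrogram at a fixed number of branchings below the root.
#'
#' @param d An `hclust` object.
#' @return Integer vector of length `n_leaves - 1`, element `i` giving the
#'   root distance of merge step `i`.
#' @export
rootdist <- function(d) {
  .check_hclust(d)
  m <- nrow(d$merge)
  depth <- integer(m)
  depth[m] <- 0L
  if (m > 1L) {
    for (i in m:1) {
      for (ch in d$merge[i, ]) {
        if (ch > 0) depth[ch] <- depth[i] + 1L
      }
    }
  }
  depth
}

.check_hclust <- function(d) {
  if (!inherits(d, "hclust")) stop("expected an 'hclust' object", call. = FALSE)
  if (is.null(d$labels)) stop("dendrogram must carry leaf labels", call. = FALSE)
  invisible(d)
}

# Leaf labels under a merge reference (negative = leaf index, positive =
# merge step). Returns sorted labels.
.leaves_under <- function(d, node) {
  if (node < 0) return(d$labels[-node])
  out <- character()
  stack <- node
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    for (ch in d$merge[cur, ]) {
      if (ch < 0) out <- c(out, d$labels[-ch]) else stack <- c(stack, ch)
    }
  }
  sort(out)
}

#' Parameters for dendrogram-to-network superimposition
#'
#' @param metric `"rootdist"` (cut at an integer merge depth below the
#'   root) or `"height"` (sever merges above a height threshold).
#' @param cutlevel Nonnegative integer depth (`rootdist`) or real height
#'   threshold (`height`).
#' @param nlev Number of successive hierarchy levels to map as nested
#'   containers (>= 1).
#' @return A `nesthc_params` list.
#' @export
nesthc_params <- function(metric = c("rootdist", "height"), cutlevel = 3,
                          nlev = 1L) {
  metric <- match.arg(metric)
  if (metric == "rootdist") {
    if (cutlevel < 0 || cutlevel != round(cutlevel)) {
      stop("rootdist cutlevel must be a nonnegative integer", call. = FALSE)
    }
    cutlevel <- as.integer(cutlevel)
  }
  if (nlev < 1L) stop("nlev must be >= 1", call. = FALSE)
  structure(list(metric = metric, cutlevel = cutlevel,
                 nlev = as.integer(nlev)),
            class = "nesthc_params")
}

# Clusters together with their rooting merge node; list of
# list(node = merge index (or negative leaf index), members = labels).
.cluster_nodes <- function(d, params) {
  m <- nrow(d$merge)
  out <- list()
  if (params$metric == "rootdist") {
    walk <- function(node, depth) {
      if (node < 0) {
        out[[length(out) + 1L]] <<- list(node = node,
                                         members = d$labels[-node])
        return(invisible())
      }
      if (depth == params$cutlevel) {
        out[[length(out) + 1L]] <<- list(node = node,
                                         members = .leaves_under(d, node))
        return(invisible())
      }
      for (ch in d$merge[node, ]) walk(ch, depth + 1L)
    }
    walk(m, 0L)
  } else {
    memb <- stats::cutree(d, h = params$cutlevel)
    for (cl in split(names(memb), memb)) {
      cl <- sort(cl)
      if (length(cl) == 1L) {
        out[[length(out) + 1L]] <-
          list(node = -match(cl, d$labels), members = cl)
      } else {
        # rooting merge = the step at which the cluster is fully formed
        for (i in seq_len(m)) {
          lv <- .leaves_under(d, i)
          if (length(lv) == length(cl) && all(lv == cl)) {
            out[[length(out) + 1L]] <- list(node = i, members = cl)
            break
          }
        }
      }
    }
  }
  mins <- vapply(out, function(cl) min(cl$members), character(1))
  out[order(mins)]
}

#' Cut a dendrogram into clusters
#'
#' With `metric = "rootdist"`, clusters are the maximal subtrees whose root
#' merge sits exactly `cutlevel` branchings below the dendrogram root;
#' leaves that detach closer to the root become singletons, and a cutlevel
#' deeper than the tree yields all singletons. With `metric = "height"`,
#' all merges with height above `cutlevel` are severed (as
#' [stats::cutree()] with `h =`).
#'
#' @param d An `hclust` object with labels.
#' @param params A [nesthc_params()] object.
#' @return List of character vectors — a disjoint cover of all leaf
#'   labels, ordered by smallest member.
#' @export
cut_clusters <- function(d, params = nesthc_params()) {
  .check_hclust(d)
  lapply(.cluster_nodes(d, params), `[[`, "members")
}

#' Height threshold producing a given cluster count
#'
#' Convenience for "cut into k clusters": returns the midpoint between the
#' merge heights that separate k from k-1 clusters, for use as the
#' `cutlevel` of a `"height"` cut.
#'
#' @param d An `hclust` object.
#' @param k Desired number of clusters, `1 <= k <= n_leaves`.
#' @return A height threshold.
#' @export
cut_height_for_k <- function(d, k) {
  .check_hclust(d)
  n <- length(d$labels)
  if (k < 1 || k > n) stop("k out of range", call. = FALSE)
  hs <- sort(d$height)
  if (k == 1) return(hs[n - 1L] + 1)
  if (k == n) return(if (hs[1L] > 0) hs[1L] / 2 else -1)
  (hs[n - k] + hs[n - k + 1L]) / 2
}

#' Superimpose a dendrogram onto a network as nested containers
#'
#' Maps a hierarchical clustering onto the graph: each [cut_clusters()]
#' cluster with at least two members becomes a container holding its
#' leaves; for `nlev > 1`, each cluster's child subtrees (one more
#' branching down) are nested inside it, recursively. Singleton clusters
#' stay unnested. Any previous containment of the clustered leaves is
#' replaced.
#'
#' @param g A `hier_graph` whose leaves include all dendrogram labels.
#' @param d An `hclust` object with labels.
#' @param params A [nesthc_params()] object.
#' @return List with `graph` (the modified graph) and `containers`
#'   (character vector of created container ids, outermost first).
#' @export
nest_dendrogram <- function(g, d, params = nesthc_params()) {
  .check_hg(g)
  .check_hclust(d)
  labs <- d$labels
  bad <- setdiff(labs, leaf_ids(g))
  if (length(bad)) {
    stop("dendrogram labels not present as graph leaves: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cl <- .cluster_nodes(d, params)
  # replace existing containment of affected leaves
  g$nodes$parent[match(labs, g$nodes$id)] <- NA_character_
  created <- character()
  nest_rec <- function(node, members, level) {
    if (length(members) < 2L) return(invisible())
    id <- new_container_id(g)
    g <<- nest(g, members, id)
    created <<- c(created, id)
    if (level < params$nlev && node > 0) {
      for (ch in d$merge[node, ]) {
        chm <- if (ch < 0) d$labels[-ch] else .leaves_under(d, ch)
        nest_rec(ch, chm, level + 1L)
      }
    }
  }
  for (cli in cl) nest_rec(cli$node, cli$members, 1L)
  list(graph = g, containers = created)
}

#' Read and write dendrograms as linkage tables
#'
#' The linkage-table format is a TSV with columns `step`, `left`, `right`,
#' `height`: negative integers reference leaves (by position in the label
#' list), positive integers reference prior merge steps — the convention of
#' standard hierarchical-clustering merge tables. Leaf labels are carried
#' in header comment lines `#leaf <index> <label>`.
#'
#' @param d An `hclust` object with labels.
#' @param path File path.
#' @return `write_linkage()` returns `path` invisibly; `read_linkage()`
#'   returns an `hclust` object.
#' @export
write_linkage <- function(d, path) {
  .check_hclust(d)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(d$labels)) {
    cat(sprintf("#leaf\t%d\t%s\n", i, d$labels[i]), file = con)
  }
  cat("step\tleft\tright\theight\n", file = con)
  for (i in seq_len(nrow(d$merge))) {
    cat(sprintf("%d\t%d\t%d\t%s\n", i, d$merge[i, 1], d$merge[i, 2],
                format(d$height[i], digits = 17)), file = con)
  }
  invisible(path)
}

#' @rdname write_linkage
#' @export
read_linkage <- function(path) {
  lines <- readLines(path)
  leaf_lines <- grep("^#leaf\t", lines, value = TRUE)
  labs <- character()
  for (ln in leaf_lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    labs[as.integer(parts[2L])] <- parts[3L]
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"))
  need <- c("step", "left", "right", "height")
  if (!all(need %in% names(tab))) {
    stop("linkage table must have columns step, left, right, height",
         call. = FALSE)
  }
  tab <- tab[order(tab$step), , drop = FALSE]
  n <- nrow(tab) + 1L
  if (length(labs) == 0L) labs <- paste0("L", seq_len(n))
  if (length(labs) != n) stop("label count does not match merge count")
  merge <- cbind(as.integer(tab$left), as.integer(tab$right))
  hc <- list(merge = merge, height = as.double(tab$height),
             order = .hclust_order(merge, n), labels = labs,
             method = "complete", call = match.call(),
             dist.method = "euclidean")
  class(hc) <- "hclust"
  hc
}

# Left-to-right leaf order from a merge table (for plotting/cutree).
.hclust_order <- function(merge, n) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1L]), rec(merge[node, 2L]))
  }
  rec(n - 1L)
}
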