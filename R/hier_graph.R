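#' Create an empty hierarchical (compound) graph
#'
#' A `hier_graph` couples an undirected, weighted network on *leaf* nodes
#' with a containment forest of *container* nodes above them. Containers
#' may hold leaves and other containers, giving a tree of nesting levels
#' (each node has at most one parent). Edges live on two layers: `"leaf"`
#' edges connect two leaves; `"association"` edges are horizontal links
#' that may involve containers (e.g. aggregated module-module edges).
#'
#' @return An object of class `hier_graph` with zero nodes and edges.
#' @seealso [add_node()], [add_edge()], [nest()], [unnest()]
#' @export
#' @examples
#' g <- hier_graph()
#' g <- add_node(g, c("a", "b", "c"))
#' g <- add_edge(g, "a", "b", weight = 2)
#' g <- nest(g, c("a", "b"), "N1")
hier_graph <- function() {
  structure(
    list(
      nodes = data.frame(
        id = character(), kind = character(), parent = character(),
        stringsAsFactors = FALSE
      ),
      attrs = list(),
      edges = data.frame(
        u = character(), v = character(), weight = numeric(),
        layer = character(), stringsAsFactors = FALSE
      )
    ),
    class = "hier_graph"
  )
}

.check_hg <- function(g) {
  if (!inherits(g, "hier_graph")) {
    stop("expected a 'hier_graph' object", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.hier_graph <- function(x, ...) {
  nl <- sum(x$nodes$kind == "leaf")
  nc <- sum(x$nodes$kind == "container")
  ne <- nrow(x$edges)
  na <- sum(x$edges$layer == "association")
  cat(sprintf(
    "hier_graph: %d leaves, %d containers, %d edges (%d association)\n",
    nl, nc, ne, na
  ))
  invisible(x)
}

#' Node and edge accessors
#'
#' @param g A `hier_graph`.
#' @return `node_ids()`, `leaf_ids()` and `container_ids()` return character
#'   vectors of ids; `edges()` returns the canonical edge table with columns
#'   `u`, `v`, `weight`, `layer`.
#' @export
node_ids <- function(g) {
  .check_hg(g)
  g$nodes$id
}

#' @rdname node_ids
#' @export
leaf_ids <- function(g) {
  .check_hg(g)
  g$nodes$id[g$nodes$kind == "leaf"]
}

#' @rdname node_ids
#' @export
container_ids <- function(g) {
  .check_hg(g)
  g$nodes$id[g$nodes$kind == "container"]
}

#' @rdname node_ids
#' @export
edges <- function(g) {
  .check_hg(g)
  g$edges
}

#' Add nodes to a hierarchical graph
#'
#' @param g A `hier_graph`.
#' @param ids Character vector of new, unique node ids.
#' @param kind `"leaf"` (default) or `"container"`.
#' @param parent Optional id of an existing container the new nodes are
#'   placed in; `NA` (default) leaves them at the root level.
#' @param attrs Optional named list of scalar attributes applied to every
#'   added node (numeric values are stored as doubles).
#' @return The modified graph.
#' @export
add_node <- function(g, ids, kind = "leaf", parent = NA_character_,
                     attrs = list()) {
  .check_hg(g)
  kind <- match.arg(kind, c("leaf", "container"))
  ids <- as.character(ids)
  if (length(ids) == 0L) return(g)
  if (anyDuplicated(ids) || any(ids %in% g$nodes$id)) {
    stop("duplicate node id(s): ",
         paste(unique(ids[duplicated(ids) | ids %in% g$nodes$id]),
               collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(ids)) || anyNA(ids)) stop("node ids must be non-empty strings")
  if (!is.na(parent)) {
    if (!parent %in% container_ids(g)) {
      stop("parent '", parent, "' is not an existing container", call. = FALSE)
    }
  }
  g$nodes <- rbind(g$nodes, data.frame(
    id = ids, kind = kind, parent = rep(as.character(parent), length(ids)),
    stringsAsFactors = FALSE
  ))
  attrs <- .normalize_attrs(attrs)
  for (id in ids) g$attrs[[id]] <- attrs
  g
}

.normalize_attrs <- function(attrs) {
  if (length(attrs) == 0L) return(list())
  if (is.null(names(attrs)) || any(!nzchar(names(attrs)))) {
    stop("attributes must be a named list")
  }
  lapply(attrs, function(v) {
    if (length(v) != 1L) stop("attributes must be scalars")
    if (is.numeric(v)) as.double(v) else v
  })
}

#' Get or set node attributes
#'
#' @param g A `hier_graph`.
#' @param id A node id.
#' @param ... Named scalar attributes to set.
#' @return `node_attrs()` returns the named attribute list of one node;
#'   `set_node_attrs()` returns the modified graph; `node_attr()` returns a
#'   vector of one attribute across `ids` (`NA` where unset).
#' @export
node_attrs <- function(g, id) {
  .check_hg(g)
  if (!id %in% g$nodes$id) stop("unknown node id '", id, "'", call. = FALSE)
  a <- g$attrs[[id]]
  if (is.null(a)) list() else a
}

#' @rdname node_attrs
#' @export
set_node_attrs <- function(g, id, ...) {
  .check_hg(g)
  if (!id %in% g$nodes$id) stop("unknown node id '", id, "'", call. = FALSE)
  new <- .normalize_attrs(list(...))
  a <- g$attrs[[id]]
  if (is.null(a)) a <- list()
  a[names(new)] <- new
  g$attrs[[id]] <- a
  g
}

#' @rdname node_attrs
#' @param name Attribute name.
#' @param ids Node ids (defaults to all nodes).
#' @export
node_attr <- function(g, name, ids = node_ids(g)) {
  .check_hg(g)
  vals <- lapply(ids, function(id) {
    a <- g$attrs[[id]]
    if (is.null(a) || is.null(a[[name]])) NA else a[[name]]
  })
  out <- unlist(lapply(vals, function(v) if (all(is.na(v))) NA else v))
  names(out) <- ids
  out
}

#' Add or update an undirected edge
#'
#' Edges are stored canonically with `u < v` (lexicographic), so
#' `add_edge(g, "b", "a")` and `add_edge(g, "a", "b")` refer to the same
#' edge; re-adding an existing pair replaces its weight. The layer is
#' inferred: an edge between two leaves is a `"leaf"` edge, any edge
#' touching a container is an `"association"` edge. An explicit `layer`
#' overrides the inference (horizontal leaf-leaf associations external to
#' the hierarchy are permitted).
#'
#' @param g A `hier_graph`.
#' @param u,v Distinct existing node ids.
#' @param weight Nonnegative edge weight (default 1).
#' @param layer Optional `"leaf"` or `"association"`.
#' @return The modified graph.
#' @export
add_edge <- function(g, u, v, weight = 1, layer = NULL) {
  .check_hg(g)
  u <- as.character(u); v <- as.character(v)
  if (identical(u, v)) stop("self-loops are not allowed", call. = FALSE)
  miss <- setdiff(c(u, v), g$nodes$id)
  if (length(miss)) {
    stop("unknown node id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 0) {
    stop("weight must be a single nonnegative number", call. = FALSE)
  }
  kinds <- g$nodes$kind[match(c(u, v), g$nodes$id)]
  inferred <- if (all(kinds == "leaf")) "leaf" else "association"
  if (is.null(layer)) {
    layer <- inferred
  } else {
    layer <- match.arg(layer, c("leaf", "association"))
    if (layer == "leaf" && inferred != "leaf") {
      stop("a 'leaf' edge must connect two leaf nodes", call. = FALSE)
    }
  }
  if (u > v) { tmp <- u; u <- v; v <- tmp }
  hit <- which(g$edges$u == u & g$edges$v == v & g$edges$layer == layer)
  if (length(hit)) {
    g$edges$weight[hit] <- as.double(weight)
  } else {
    g$edges <- rbind(g$edges, data.frame(
      u = u, v = v, weight = as.double(weight), layer = layer,
      stringsAsFactors = FALSE
    ))
  }
  g
}

#' Ancestor chain of a node
#'
#' @param g A `hier_graph`.
#' @param id An existing node id.
#' @return Character vector of container ids on the path from the node's
#'   parent up to its root, nearest first; `character(0)` for a root node.
#'   Its length is the nesting depth of the node.
#' @export
ancestors <- function(g, id) {
  .check_hg(g)
  idx <- match(id, g$nodes$id)
  if (is.na(idx)) stop("unknown node id '", id, "'", call. = FALSE)
  out <- character()
  p <- g$nodes$parent[idx]
  while (!is.na(p)) {
    if (p %in% out) stop("containment cycle detected at '", p, "'")
    out <- c(out, p)
    p <- g$nodes$parent[match(p, g$nodes$id)]
  }
  out
}

#' Direct children of a container
#'
#' @param g A `hier_graph`.
#' @param id A container id (or any node; leaves have no children).
#' @return Character vector of child ids.
#' @export
children <- function(g, id) {
  .check_hg(g)
  g$nodes$id[!is.na(g$nodes$parent) & g$nodes$parent == id]
}

#' Leaf descendants of a node
#'
#' @param g A `hier_graph`.
#' @param id A node id; for a leaf the result is the leaf itself.
#' @return Character vector of all leaf ids contained (at any depth) in `id`.
#' @export
leaf_descendants <- function(g, id) {
  .check_hg(g)
  idx <- match(id, g$nodes$id)
  if (is.na(idx)) stop("unknown node id '", id, "'", call. = FALSE)
  if (g$nodes$kind[idx] == "leaf") return(id)
  out <- character()
  stack <- children(g, id)
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    if (g$nodes$kind[match(cur, g$nodes$id)] == "leaf") {
      out <- c(out, cur)
    } else {
      stack <- c(stack, children(g, cur))
    }
  }
  sort(out)
}

#' Generate a fresh container id
#'
#' @param g A `hier_graph`.
#' @param prefix Id prefix (default `"N"`).
#' @return The first id of the form `<prefix><k>`, `k = 1, 2, ...`, not yet
#'   used in the graph. Deterministic, so scripted pipelines are
#'   reproducible without a seed.
#' @export
new_container_id <- function(g, prefix = "N") {
  .check_hg(g)
  k <- 1L
  repeat {
    id <- paste0(prefix, k)
    if (!id %in% g$nodes$id) return(id)
    k <- k + 1L
  }
}

#' Nest a set of nodes inside a new container
#'
#' Creates a container holding `members` (leaves and/or containers). The
#' container itself is placed at the deepest common ancestor the members
#' had before the call (at the root if they had none), so repeated nesting
#' builds multiple hierarchy levels.
#'
#' @param g A `hier_graph`.
#' @param members Nonempty character vector of existing node ids. No member
#'   may be an ancestor of another member (that would create a containment
#'   cycle / overlapping containers).
#' @param container_id Id for the new container; must not already exist.
#'   Defaults to [new_container_id()].
#' @param attrs Optional named list of attributes for the container.
#' @return The modified graph; the container id is `container_id`.
#' @export
nest <- function(g, members, container_id = new_container_id(g),
                 attrs = list()) {
  .check_hg(g)
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("members must be nonempty", call. = FALSE)
  miss <- setdiff(members, g$nodes$id)
  if (length(miss)) {
    stop("unknown member id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (container_id %in% g$nodes$id) {
    stop("container id '", container_id, "' already exists", call. = FALSE)
  }
  anc <- lapply(members, function(m) ancestors(g, m))
  names(anc) <- members
  for (m in members) {
    if (any(anc[[m]] %in% members)) {
      stop("cannot nest '", m, "' together with one of its ancestors",
           call. = FALSE)
    }
  }
  common <- Reduce(intersect, anc)
  parent <- if (length(common)) common[[1L]] else NA_character_
  g <- add_node(g, container_id, kind = "container", parent = parent,
                attrs = attrs)
  g$nodes$parent[match(members, g$nodes$id)] <- container_id
  g
}

#' Dissolve a container, promoting its children
#'
#' The container's children are re-parented to the container's own parent
#' (or become root nodes), the container and any edges incident to it are
#' removed, and leaf-layer edges are untouched.
#'
#' @param g A `hier_graph`.
#' @param container_id An existing container id.
#' @return The modified graph.
#' @export
unnest <- function(g, container_id) {
  .check_hg(g)
  idx <- match(container_id, g$nodes$id)
  if (is.na(idx)) stop("unknown node id '", container_id, "'", call. = FALSE)
  if (g$nodes$kind[idx] != "container") {
    stop("'", container_id, "' is a leaf, not a container", call. = FALSE)
  }
  up <- g$nodes$parent[idx]
  kids <- children(g, container_id)
  g$nodes$parent[match(kids, g$nodes$id)] <- up
  g$nodes <- g$nodes[-idx, , drop = FALSE]
  rownames(g$nodes) <- NULL
  g$attrs[[container_id]] <- NULL
  keep <- g$edges$u != container_id & g$edges$v != container_id
  g$edges <- g$edges[keep, , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

#' Largest connected component of an induced leaf subgraph
#'
#' Considers only `"leaf"`-layer edges among the given subset of leaves and
#' returns the node set of the largest connected component; ties are broken
#' by the smallest lexicographic minimum member id.
#'
#' @param g A `hier_graph`.
#' @param subset Character vector of leaf ids (defaults to all leaves).
#' @return Sorted character vector (possibly empty).
#' @export
largest_connected_component <- function(g, subset = leaf_ids(g)) {
  .check_hg(g)
  subset <- unique(as.character(subset))
  bad <- setdiff(subset, leaf_ids(g))
  if (length(bad)) {
    stop("subset contains non-leaf or unknown id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(subset) == 0L) return(character())
  el <- g$edges[g$edges$layer == "leaf" &
                  g$edges$u %in% subset & g$edges$v %in% subset, ,
                drop = FALSE]
  adj <- split(c(el$v, el$u), c(el$u, el$v))
  comp <- rep(NA_integer_, length(subset))
  names(comp) <- subset
  k <- 0L
  for (start in subset) {
    if (!is.na(comp[[start]])) next
    k <- k + 1L
    queue <- start
    comp[[start]] <- k
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (nb in adj[[cur]]) {
        if (is.na(comp[[nb]])) {
          comp[[nb]] <- k
          queue <- c(queue, nb)
        }
      }
    }
  }
  comps <- split(names(comp), comp)
  sizes <- vapply(comps, length, integer(1))
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    mins <- vapply(comps[best], function(s) min(s), character(1))
    best <- best[order(mins)][1L]
  }
  sort(comps[[best]])
}

#' Validate a hierarchical graph
#'
#' Checks every structural invariant: unique ids, parents exist and are
#' containers, the containment relation is an acyclic forest, edges are
#' canonical (`u < v`), reference existing nodes, carry nonnegative weights,
#' have no self-loops or duplicate (pair, layer) entries, and leaf-layer
#' edges connect two leaves.
#'
#' @param g A `hier_graph`.
#' @return `g`, invisibly; stops with a message on the first violation.
#' @export
validate_graph <- function(g) {
  .check_hg(g)
  n <- g$nodes
  if (anyDuplicated(n$id)) stop("duplicate node ids")
  if (!all(n$kind %in% c("leaf", "container"))) stop("invalid node kind")
  hasp <- !is.na(n$parent)
  if (any(hasp)) {
    pk <- n$kind[match(n$parent[hasp], n$id)]
    if (anyNA(pk)) stop("parent refers to a missing node")
    if (!all(pk == "container")) stop("parent of a node must be a container")
  }
  for (id in n$id) ancestors(g, id)  # throws on cycles
  e <- g$edges
  if (nrow(e)) {
    if (any(e$u == e$v)) stop("self-loop present")
    if (!all(e$u < e$v)) stop("edge not stored canonically (u < v)")
    if (anyDuplicated(paste(e$u, e$v, e$layer))) stop("duplicate edge")
    if (!all(c(e$u, e$v) %in% n$id)) stop("edge references a missing node")
    if (any(e$weight < 0) || anyNA(e$weight)) stop("negative or NA edge weight")
    if (!all(e$layer %in% c("leaf", "association"))) stop("invalid edge layer")
    lf <- e$layer == "leaf"
    kindu <- n$kind[match(e$u, n$id)]
    kindv <- n$kind[match(e$v, n$id)]
    if (any(lf & (kindu != "leaf" | kindv != "leaf"))) {
      stop("leaf-layer edge touching a container")
    }
  }
  invisible(g)
}

# Depth of every node (root = 0); internal.
.depths <- function(g) {
  ids <- g$nodes$id
  d <- integer(length(ids))
  names(d) <- ids
  for (i in seq_along(ids)) d[[i]] <- length(ancestors(g, ids[[i]]))
  d
}
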