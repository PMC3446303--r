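# Attribute typing shared by GraphML and JSON writers.
.attr_type <- function(v) {
  if (is.logical(v)) "boolean" else if (is.numeric(v)) "double" else "string"
}

.attr_format <- function(v) {
  if (is.logical(v)) {
    if (v) "true" else "false"
  } else if (is.numeric(v)) {
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  } else {
    as.character(v)
  }
}

.attr_parse <- function(s, type) {
  switch(type,
         boolean = identical(s, "true"),
         double = as.double(s),
         s)
}

#' Write and read compound GraphML
#'
#' Serializes a `hier_graph` in the standard compound-graph GraphML
#' dialect: each container node element holds a nested `<graph>` element
#' with its children, to arbitrary depth; node attributes are keyed
#' `<data>` entries; all edges sit in the top-level graph with `weight`
#' and `layer` data. `read_graphml(write_graphml(g))` is structurally
#' identical to `g`.
#'
#' @param g A validated `hier_graph`.
#' @param path File path.
#' @return `write_graphml()` returns `path` invisibly; `read_graphml()`
#'   returns a validated `hier_graph` and rejects malformed files with the
#'   offending id in the message.
#' @export
write_graphml <- function(g, path) {
  validate_graph(g)
  # collect attribute keys with types
  keyinfo <- list()
  for (id in node_ids(g)) {
    a <- g$attrs[[id]]
    for (nm in names(a)) {
      ty <- .attr_type(a[[nm]])
      if (!is.null(keyinfo[[nm]]) && keyinfo[[nm]] != ty) {
        keyinfo[[nm]] <- "string"
      } else if (is.null(keyinfo[[nm]])) {
        keyinfo[[nm]] <- ty
      }
    }
  }
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  for (nm in sort(names(keyinfo))) {
    xml2::xml_add_child(doc, "key", id = paste0("a_", nm), `for` = "node",
                        attr.name = nm, attr.type = keyinfo[[nm]])
  }
  xml2::xml_add_child(doc, "key", id = "e_weight", `for` = "edge",
                      attr.name = "weight", attr.type = "double")
  xml2::xml_add_child(doc, "key", id = "e_layer", `for` = "edge",
                      attr.name = "layer", attr.type = "string")
  root_graph <- xml2::xml_add_child(doc, "graph", id = "G",
                                    edgedefault = "undirected")
  add_node_xml <- function(parent_xml, id) {
    nd <- xml2::xml_add_child(parent_xml, "node", id = id)
    a <- g$attrs[[id]]
    for (nm in names(a)) {
      d <- xml2::xml_add_child(nd, "data", key = paste0("a_", nm))
      xml2::xml_text(d) <- .attr_format(a[[nm]])
    }
    if (g$nodes$kind[match(id, g$nodes$id)] == "container") {
      sub <- xml2::xml_add_child(nd, "graph", id = paste0(id, ":g"),
                                 edgedefault = "undirected")
      for (ch in sort(children(g, id))) add_node_xml(sub, ch)
    }
  }
  roots <- g$nodes$id[is.na(g$nodes$parent)]
  for (id in sort(roots)) add_node_xml(root_graph, id)
  e <- g$edges
  if (nrow(e)) {
    e <- e[order(e$u, e$v, e$layer), , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      ed <- xml2::xml_add_child(root_graph, "edge", source = e$u[i],
                                target = e$v[i])
      d <- xml2::xml_add_child(ed, "data", key = "e_weight")
      xml2::xml_text(d) <- .attr_format(e$weight[i])
      d <- xml2::xml_add_child(ed, "data", key = "e_layer")
      xml2::xml_text(d) <- e$layer[i]
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, "./key")
  keymap <- list()
  for (k in keys) {
    keymap[[xml2::xml_attr(k, "id")]] <- list(
      name = xml2::xml_attr(k, "attr.name"),
      type = xml2::xml_attr(k, "attr.type")
    )
  }
  root_graph <- xml2::xml_find_first(doc, "./graph")
  if (inherits(root_graph, "xml_missing")) {
    stop("no <graph> element in '", path, "'", call. = FALSE)
  }
  g <- hier_graph()
  read_node <- function(nd, parent) {
    id <- xml2::xml_attr(nd, "id")
    if (is.na(id)) stop("node without id under parent '",
                        if (is.na(parent)) "<root>" else parent, "'",
                        call. = FALSE)
    sub <- xml2::xml_find_first(nd, "./graph")
    kind <- if (inherits(sub, "xml_missing")) "leaf" else "container"
    attrs <- list()
    for (d in xml2::xml_find_all(nd, "./data")) {
      ki <- keymap[[xml2::xml_attr(d, "key")]]
      if (is.null(ki)) next
      attrs[[ki$name]] <- .attr_parse(xml2::xml_text(d), ki$type)
    }
    g <<- add_node(g, id, kind = kind, parent = parent, attrs = attrs)
    if (kind == "container") {
      for (ch in xml2::xml_find_all(sub, "./node")) read_node(ch, id)
    }
  }
  for (nd in xml2::xml_find_all(root_graph, "./node")) {
    read_node(nd, NA_character_)
  }
  for (ed in xml2::xml_find_all(root_graph, ".//edge")) {
    u <- xml2::xml_attr(ed, "source")
    v <- xml2::xml_attr(ed, "target")
    for (end in c(u, v)) {
      if (is.na(end) || !end %in% node_ids(g)) {
        stop("edge references missing node id '", end, "'", call. = FALSE)
      }
    }
    weight <- 1
    layer <- NULL
    for (d in xml2::xml_find_all(ed, "./data")) {
      ki <- keymap[[xml2::xml_attr(d, "key")]]
      if (is.null(ki)) next
      if (ki$name == "weight") weight <- as.double(xml2::xml_text(d))
      if (ki$name == "layer") layer <- xml2::xml_text(d)
    }
    g <- add_edge(g, u, v, weight = weight, layer = layer)
  }
  validate_graph(g)
  g
}

#' Write and read a hierarchical graph as JSON
#'
#' Lossless round-trip including node kinds, parents and scalar
#' attributes. Nodes are recorded flat with a `parent` field.
#'
#' @param g A validated `hier_graph`.
#' @param path File path.
#' @return `write_json_graph()` returns `path` invisibly;
#'   `read_json_graph()` returns a validated `hier_graph`.
#' @export
write_json_graph <- function(g, path) {
  validate_graph(g)
  nodes <- lapply(seq_len(nrow(g$nodes)), function(i) {
    id <- g$nodes$id[i]
    rec <- list(id = id, kind = g$nodes$kind[i])
    if (!is.na(g$nodes$parent[i])) rec$parent <- g$nodes$parent[i]
    a <- g$attrs[[id]]
    if (length(a)) rec$attrs <- a
    rec
  })
  e <- g$edges
  e <- e[order(e$u, e$v, e$layer), , drop = FALSE]
  edges <- lapply(seq_len(nrow(e)), function(i) {
    list(u = e$u[i], v = e$v[i], weight = e$weight[i], layer = e$layer[i])
  })
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_json_graph
#' @export
read_json_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  g <- hier_graph()
  nodes <- obj$nodes
  # containers must exist before their children; insert parents first
  done <- character()
  byid <- stats::setNames(nodes, vapply(nodes, `[[`, "", "id"))
  insert <- function(rec) {
    id <- rec$id
    if (id %in% done) return(invisible())
    p <- rec$parent
    if (!is.null(p) && !(p %in% done)) {
      if (is.null(byid[[p]])) {
        stop("parent '", p, "' of node '", id, "' not defined",
             call. = FALSE)
      }
      insert(byid[[p]])
    }
    attrs <- if (is.null(rec$attrs)) list() else rec$attrs
    g <<- add_node(g, id, kind = if (is.null(rec$kind)) "leaf" else rec$kind,
                   parent = if (is.null(p)) NA_character_ else p,
                   attrs = attrs)
    done <<- c(done, id)
  }
  for (rec in nodes) insert(rec)
  for (e in obj$edges) {
    g <- add_edge(g, e$u, e$v,
                  weight = if (is.null(e$weight)) 1 else e$weight,
                  layer = e$layer)
  }
  validate_graph(g)
  g
}

#' Import an edge-list TSV
#'
#' Expects columns `source`, `target` and optionally `weight` (default 1)
#' and `layer`. Files are treated as undirected regardless of column
#' order: duplicate pairs (including reversed orientation) collapse to one
#' edge, keeping the last weight, with a warning when the two orientations
#' disagree. Unknown ids become leaf nodes.
#'
#' @param path File path.
#' @return A validated `hier_graph`.
#' @export
read_edgelist <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(tab))) {
    stop("edge list must have columns 'source' and 'target'", call. = FALSE)
  }
  if (!"weight" %in% names(tab)) tab$weight <- 1
  tab$weight[is.na(tab$weight)] <- 1
  g <- hier_graph()
  g <- add_node(g, unique(c(tab$source, tab$target)))
  key <- paste(pmin(tab$source, tab$target), pmax(tab$source, tab$target))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    w_by_key <- split(tab$weight, key)
    if (any(vapply(w_by_key, function(w) length(unique(w)) > 1,
                   logical(1)))) {
      warning("both orientations of an edge present with different ",
              "weights; keeping the last", call. = FALSE)
    }
  }
  for (i in seq_len(nrow(tab))) {
    layer <- if ("layer" %in% names(tab) && !is.na(tab$layer[i]) &&
                 nzchar(tab$layer[i])) tab$layer[i] else NULL
    g <- add_edge(g, tab$source[i], tab$target[i], weight = tab$weight[i],
                  layer = layer)
  }
  validate_graph(g)
  g
}

#' Export a graph's edges as an edge-list TSV
#'
#' @param g A `hier_graph`.
#' @param path File path.
#' @return `path`, invisibly. Columns: `source`, `target`, `weight`,
#'   `layer` (so aggregated association edges survive the round trip).
#' @export
write_edgelist <- function(g, path) {
  .check_hg(g)
  e <- g$edges[order(g$edges$u, g$edges$v, g$edges$layer), , drop = FALSE]
  tab <- data.frame(source = e$u, target = e$v, weight = e$weight,
                    layer = e$layer, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rendering options for SVG export
#'
#' @param width,height Canvas size in pixels.
#' @param node_size Default node diameter (used when a node has no `size`
#'   attribute).
#' @param node_color Default node fill (hex), overridden by a node's
#'   `color` attribute.
#' @param container_stroke Stroke color of container circles.
#' @param edge_width_scale Stroke width of an association edge of density
#'   1; widths scale linearly with edge weight.
#' @param flip_y If `TRUE` (default), Cartesian layout coordinates are
#'   flipped so that the y axis points down, the SVG screen convention.
#' @return A `render_spec` list.
#' @export
render_spec <- function(width = 800, height = 800, node_size = 10,
                        node_color = "#BBBBBB",
                        container_stroke = "#555555",
                        edge_width_scale = 8, flip_y = TRUE) {
  stopifnot(width > 0, height > 0, node_size > 0, edge_width_scale > 0)
  structure(list(width = width, height = height, node_size = node_size,
                 node_color = node_color,
                 container_stroke = container_stroke,
                 edge_width_scale = edge_width_scale, flip_y = flip_y),
            class = "render_spec")
}

.fmt <- function(x) sprintf("%.3f", x)

#' Render a laid-out nested network to SVG
#'
#' Containers are drawn as circles beneath their members (outermost
#' first), then leaf-layer edges as lines, association edges with width
#' proportional to their weight, and finally leaf glyphs filled and sized
#' from the `color` and `size` node attributes. Output bytes are
#' deterministic for fixed inputs.
#'
#' @param g A validated `hier_graph`.
#' @param state A `layout_state` covering all nodes.
#' @param spec A [render_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_svg <- function(g, state, spec = render_spec(), path) {
  validate_graph(g)
  ids <- node_ids(g)
  missing_pos <- setdiff(ids, rownames(state$positions))
  if (length(missing_pos)) {
    stop("layout lacks coordinates for: ",
         paste(missing_pos, collapse = ", "), call. = FALSE)
  }
  pos <- state$positions[ids, , drop = FALSE]
  radii <- state$radii
  pad <- 0.05 * min(spec$width, spec$height)
  # fit layout (including container extents) into the canvas
  ext <- cbind(
    lo = apply(pos, 2, min), hi = apply(pos, 2, max)
  )
  for (id in names(radii)) {
    ext["x", "lo"] <- min(ext["x", "lo"], pos[id, 1] - radii[[id]])
    ext["x", "hi"] <- max(ext["x", "hi"], pos[id, 1] + radii[[id]])
    ext["y", "lo"] <- min(ext["y", "lo"], pos[id, 2] - radii[[id]])
    ext["y", "hi"] <- max(ext["y", "hi"], pos[id, 2] + radii[[id]])
  }
  span <- max(ext[, "hi"] - ext[, "lo"], 1e-9)
  scl <- min(spec$width - 2 * pad, spec$height - 2 * pad) / span
  px <- function(id) pad + (pos[id, 1] - ext["x", "lo"]) * scl
  py <- function(id) {
    y <- pad + (pos[id, 2] - ext["y", "lo"]) * scl
    if (spec$flip_y) spec$height - y else y
  }
  lines <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
           'height="%d" viewBox="0 0 %d %d">'),
    spec$width, spec$height, spec$width, spec$height
  ))
  depths <- .depths(g)
  # containers, outermost (shallowest) first, id as tiebreak
  cc <- container_ids(g)
  cc <- cc[order(depths[cc], cc)]
  for (id in cc) {
    lines <- c(lines, sprintf(
      '<circle class="container" id="%s" cx="%s" cy="%s" r="%s" fill="none" stroke="%s" stroke-dasharray="4,3"/>',
      id, .fmt(px(id)), .fmt(py(id)), .fmt(radii[[id]] * scl),
      spec$container_stroke
    ))
  }
  e <- g$edges[order(g$edges$layer, g$edges$u, g$edges$v), , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    if (e$layer[i] == "association") {
      w <- max(0.5, e$weight[i] * spec$edge_width_scale)
      lines <- c(lines, sprintf(
        '<line class="association" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#777777" stroke-width="%s"/>',
        .fmt(px(e$u[i])), .fmt(py(e$u[i])), .fmt(px(e$v[i])),
        .fmt(py(e$v[i])), .fmt(w)
      ))
    } else {
      lines <- c(lines, sprintf(
        '<line class="leaf-edge" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#AAAAAA" stroke-width="1"/>',
        .fmt(px(e$u[i])), .fmt(py(e$u[i])), .fmt(px(e$v[i])),
        .fmt(py(e$v[i]))
      ))
    }
  }
  for (id in sort(leaf_ids(g))) {
    a <- g$attrs[[id]]
    col <- if (!is.null(a$color)) a$color else spec$node_color
    size <- if (!is.null(a$size)) a$size else spec$node_size
    lines <- c(lines, sprintf(
      '<circle class="node" id="%s" cx="%s" cy="%s" r="%s" fill="%s" stroke="#333333"/>',
      id, .fmt(px(id)), .fmt(py(id)), .fmt(size / 2), col
    ))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
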