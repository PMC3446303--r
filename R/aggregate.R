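#' Aggregated connectivity between two containers
#'
#' Counts the leaf-layer edges running between the leaf descendants of two
#' containers and normalizes by the number of possible cross pairs
#' (|leaves(a)| x |leaves(b)|), giving a module-module edge density in
#' [0, 1] — the quantity drawn as out-edge width between module containers.
#'
#' @param g A `hier_graph`.
#' @param a,b Distinct container ids, neither an ancestor of the other,
#'   each with at least one leaf descendant.
#' @param weighted If `TRUE`, sum the weights of cross edges instead of
#'   counting them (the normalized value may then exceed 1 if weights do).
#' @return A list of class `module_edge` with fields `a`, `b`, `count`
#'   (cross-edge count, or weight sum if `weighted`), `possible` and
#'   `weight` (= count / possible).
#' @export
module_edge_weight <- function(g, a, b, weighted = FALSE) {
  .check_hg(g)
  for (id in c(a, b)) {
    if (!id %in% container_ids(g)) {
      stop("'", id, "' is not a container", call. = FALSE)
    }
  }
  if (identical(a, b)) stop("containers must be distinct", call. = FALSE)
  if (a %in% ancestors(g, b) || b %in% ancestors(g, a)) {
    stop("containers must not be nested in one another", call. = FALSE)
  }
  la <- leaf_descendants(g, a)
  lb <- leaf_descendants(g, b)
  if (length(la) == 0L || length(lb) == 0L) {
    stop("empty container: no leaf descendants", call. = FALSE)
  }
  el <- g$edges[g$edges$layer == "leaf", , drop = FALSE]
  cross <- (el$u %in% la & el$v %in% lb) | (el$u %in% lb & el$v %in% la)
  count <- if (weighted) sum(el$weight[cross]) else sum(cross)
  possible <- length(la) * length(lb)
  structure(
    list(a = min(a, b), b = max(a, b), count = count, possible = possible,
         weight = count / possible),
    class = "module_edge"
  )
}

#' @export
print.module_edge <- function(x, ...) {
  cat(sprintf("module edge %s -- %s: %g / %d cross pairs (density %.3f)\n",
              x$a, x$b, x$count, x$possible, x$weight))
  invisible(x)
}

#' Aggregate all pairwise module edges
#'
#' @param g A `hier_graph`.
#' @param containers Character vector of pairwise non-nested container ids
#'   (defaults to all top-level containers).
#' @param weighted Passed to [module_edge_weight()].
#' @return Data frame with one row per unordered pair having `count > 0`:
#'   columns `a`, `b`, `count`, `possible`, `weight`.
#' @export
aggregate_all <- function(g, containers = NULL, weighted = FALSE) {
  .check_hg(g)
  if (is.null(containers)) {
    cc <- container_ids(g)
    containers <- cc[is.na(g$nodes$parent[match(cc, g$nodes$id)])]
  }
  containers <- sort(unique(as.character(containers)))
  out <- data.frame(a = character(), b = character(), count = numeric(),
                    possible = integer(), weight = numeric(),
                    stringsAsFactors = FALSE)
  if (length(containers) < 2L) return(out)
  for (i in seq_len(length(containers) - 1L)) {
    for (j in (i + 1L):length(containers)) {
      me <- module_edge_weight(g, containers[i], containers[j],
                               weighted = weighted)
      if (me$count > 0) {
        out <- rbind(out, data.frame(
          a = me$a, b = me$b, count = me$count, possible = me$possible,
          weight = me$weight, stringsAsFactors = FALSE
        ))
      }
    }
  }
  out
}

#' Attach aggregated module edges to the graph
#'
#' Adds each row of an [aggregate_all()] table as an association-layer
#' edge between the two containers, weighted by the density.
#'
#' @param g A `hier_graph`.
#' @param module_edges Data frame from [aggregate_all()].
#' @return The modified graph.
#' @export
add_module_edges <- function(g, module_edges) {
  .check_hg(g)
  for (i in seq_len(nrow(module_edges))) {
    g <- add_edge(g, module_edges$a[i], module_edges$b[i],
                  weight = module_edges$weight[i], layer = "association")
  }
  g
}

#' Visual attribute scales
#'
#' A `style_scale` maps numeric values linearly onto an output range —
#' colors for [style_diverging()], sizes for [style_size()].
#'
#' @param domain Numeric `c(lo, hi)` with `lo < hi`, or `NULL` to derive
#'   from the data.
#' @param range For colors: character vector `c(negative, neutral,
#'   positive)`; for sizes: numeric `c(min, max)`.
#' @param midpoint Neutral point of a diverging scale (default 0).
#' @param inverse If `TRUE`, the mapping is reversed (small values map to
#'   the large end of the range).
#' @return A `style_scale` list.
#' @export
style_scale <- function(domain = NULL, range, midpoint = 0,
                        inverse = FALSE) {
  if (!is.null(domain)) {
    if (length(domain) != 2L || !(domain[1] < domain[2])) {
      stop("domain must be c(lo, hi) with lo < hi", call. = FALSE)
    }
  }
  structure(list(domain = domain, range = range, midpoint = midpoint,
                 inverse = inverse),
            class = "style_scale")
}

.mix_color <- function(from, to, t) {
  ramp <- grDevices::colorRamp(c(from, to))
  v <- ramp(max(0, min(1, t)))
  grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255)
}

#' Diverging color mapping for signed values
#'
#' Maps values (typically log2 fold-changes) onto a symmetric diverging
#' palette: the midpoint maps to the neutral center color, the domain
#' endpoints to the extreme colors, with linear interpolation in between
#' and clamping outside the domain. The default domain is symmetric about
#' 0 at the maximum absolute value, so `color(-x)` mirrors `color(+x)`.
#'
#' @param values Numeric vector.
#' @param scale A [style_scale()] whose `range` holds the
#'   (negative, neutral, positive) colors; default blue-white-red.
#' @return Character vector of hex RGB colors, same length as `values`.
#' @export
style_diverging <- function(values,
                            scale = style_scale(
                              range = c("#2166AC", "#F7F7F7", "#B2182B"))) {
  if (length(values) == 0L) return(character())
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  mid <- scale$midpoint
  dom <- scale$domain
  if (is.null(dom)) {
    m <- max(abs(values - mid))
    dom <- c(mid - m, mid + m)
  }
  cols <- scale$range
  if (length(cols) != 3L) stop("diverging scale needs 3 colors")
  vapply(values, function(v) {
    if (v >= mid) {
      span <- dom[2] - mid
      t <- if (span <= 0) 0 else (v - mid) / span
      .mix_color(cols[2], cols[3], t)
    } else {
      span <- mid - dom[1]
      t <- if (span <= 0) 0 else (mid - v) / span
      .mix_color(cols[2], cols[1], t)
    }
  }, character(1))
}

#' Inverse linear size mapping for distances
#'
#' Maps nonnegative distances (e.g. kilobases from a transcription start
#' site to the nearest binding site) onto node sizes. With the default
#' `inverse = TRUE`, the minimum distance maps to the maximum size and the
#' maximum distance to the minimum size (near things drawn big); constant
#' input maps everything to the midrange size.
#'
#' @param values Nonnegative numeric vector.
#' @param scale A [style_scale()] with numeric `range = c(min_size,
#'   max_size)`; default sizes 5-20 with `inverse = TRUE`.
#' @return Numeric vector of sizes.
#' @export
style_size <- function(values,
                       scale = style_scale(range = c(5, 20),
                                           inverse = TRUE)) {
  if (length(values) == 0L) return(numeric())
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  if (any(values < 0)) stop("distances must be nonnegative", call. = FALSE)
  dom <- scale$domain
  if (is.null(dom)) dom <- range(values)
  rng <- scale$range
  if (dom[1] == dom[2]) {
    return(rep(mean(rng), length(values)))
  }
  t <- (values - dom[1]) / (dom[2] - dom[1])
  t <- pmax(0, pmin(1, t))
  if (isTRUE(scale$inverse)) t <- 1 - t
  rng[1] + t * (rng[2] - rng[1])
}
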