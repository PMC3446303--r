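# Internal force constants calibrated against the layout contracts
# (two-node equilibrium at rest_length; members held inside the padded
# container circle at termination). Not user-tunable.
.STEP_GAIN <- 0.1        # displacement = gain * force, capped by temperature
.CONTAIN_STIFF <- 10     # linear restoring force per unit overshoot
.CONTAIN_MARGIN <- 0.8   # restoring engages beyond this fraction of radius
.MIN_RADIUS <- 1e-3

#' Force-directed layout parameters
#'
#' @param rest_length Target edge length in layout units; also the length
#'   scale `k` of the force law (attraction `d^2/k`, repulsion
#'   `repulsion * k^2/d`).
#' @param repulsion Multiplier on the repulsive charge term.
#' @param container_padding Multiplicative margin on container radii;
#'   radius = `padding * sqrt(n_leaves) * rest_length / 2`.
#' @param cooling Per-iteration temperature decay factor in (0, 1).
#' @param max_iter Iteration cap for [relax()].
#' @param tol Convergence threshold on the maximum node displacement.
#' @param seed RNG seed for the initial placement.
#' @return A `force_params` list.
#' @export
force_params <- function(rest_length = 30, repulsion = 1,
                         container_padding = 1.5, cooling = 0.95,
                         max_iter = 300L, tol = 0.05, seed = 1L) {
  stopifnot(rest_length > 0, repulsion > 0, container_padding > 0,
            cooling > 0, cooling < 1, max_iter >= 1, tol > 0)
  structure(list(rest_length = rest_length, repulsion = repulsion,
                 container_padding = container_padding, cooling = cooling,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "force_params")
}

# Run code with a private, seeded RNG stream, restoring the caller's state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.container_radii <- function(g, params) {
  cc <- container_ids(g)
  r <- vapply(cc, function(id) {
    n <- length(leaf_descendants(g, id))
    max(.MIN_RADIUS,
        params$container_padding * sqrt(max(n, 1)) * params$rest_length / 2)
  }, numeric(1))
  names(r) <- cc
  r
}

# Recompute container centers as the centroid of their children,
# deepest containers first so parents see updated child positions.
.recenter_containers <- function(g, pos, depths) {
  cc <- container_ids(g)
  if (!length(cc)) return(pos)
  for (id in cc[order(depths[cc], decreasing = TRUE)]) {
    kids <- children(g, id)
    if (length(kids)) {
      pos[id, ] <- colMeans(pos[kids, , drop = FALSE])
    }
  }
  pos
}

#' Initialize a nested layout
#'
#' Leaves (and childless containers) are placed uniformly at random in a
#' square whose side grows with `sqrt(n)`; container positions are the
#' centroids of their members; container radii scale with the square root
#' of their leaf count. The placement is fully determined by
#' `params$seed`.
#'
#' @param g A validated `hier_graph`.
#' @param params A [force_params()] object.
#' @return A `layout_state` list: `positions` (n x 2 matrix, rownames =
#'   node ids), `radii` (named vector over containers), `temperature`,
#'   `iteration`.
#' @export
init_layout <- function(g, params = force_params()) {
  .check_hg(g)
  ids <- node_ids(g)
  pos <- matrix(0, nrow = length(ids), ncol = 2,
                dimnames = list(ids, c("x", "y")))
  free <- ids[g$nodes$kind == "leaf" |
                vapply(ids, function(i) length(children(g, i)) == 0L,
                       logical(1))]
  side <- max(1, sqrt(length(free))) * params$rest_length
  if (length(free)) {
    coords <- .with_seed(params$seed,
                         matrix(stats::runif(2 * length(free), 0, side),
                                ncol = 2))
    pos[free, ] <- coords
  }
  depths <- .depths(g)
  pos <- .recenter_containers(g, pos, depths)
  structure(
    list(positions = pos, radii = .container_radii(g, params),
         temperature = side / 5, iteration = 0L),
    class = "layout_state"
  )
}

# Representatives of an edge's endpoints in their deepest common frame:
# climb the two ancestor chains until both sides share the same parent.
# Returns c(rep_u, rep_v), or NULL when one endpoint contains the other.
.edge_reps <- function(chain_u, chain_v, parent_of) {
  if (chain_u[1L] %in% chain_v || chain_v[1L] %in% chain_u) return(NULL)
  for (a in chain_u) {
    pa <- parent_of[[a]]
    for (b in chain_v) {
      if (a != b && identical(pa, parent_of[[b]])) return(c(a, b))
    }
  }
  NULL
}

#' One synchronous relaxation step
#'
#' Applies, per sibling frame (nodes sharing a parent; containers act as
#' super-nodes at their own level): spring attraction along edges between
#' siblings, pairwise repulsion among siblings, and a linear restoring
#' force that pulls a member back inside its parent's padded circle. An
#' edge whose endpoints live in different containers exerts its spring on
#' the two enclosing representatives, not on the hidden members, so each
#' nest reaches a local equilibrium independently of other levels. Each
#' node's displacement is capped by the current temperature; moving a
#' container translates everything inside it; the temperature is then
#' multiplied by the cooling factor.
#'
#' @param g A `hier_graph`.
#' @param state A `layout_state` from [init_layout()] or a previous step.
#' @param params A [force_params()] object.
#' @param movable Optional character vector restricting which nodes may
#'   move (used for per-container local re-relaxation); default all.
#' @return List with `state` (updated) and `max_displacement`, the largest
#'   force-driven (own-frame) displacement of any node in this step —
#'   always bounded by the pre-step temperature.
#' @export
relax_step <- function(g, state, params = force_params(), movable = NULL) {
  .check_hg(g)
  ids <- node_ids(g)
  pos <- state$positions[ids, , drop = FALSE]
  k <- params$rest_length
  n <- length(ids)
  Fx <- stats::setNames(numeric(n), ids)
  Fy <- stats::setNames(numeric(n), ids)

  parent_of <- as.list(stats::setNames(g$nodes$parent, ids))
  frames <- split(ids, vapply(parent_of, function(p) {
    if (is.na(p)) "" else p
  }, character(1)))

  # pairwise repulsion among siblings
  for (frame in frames) {
    m <- length(frame)
    if (m < 2L) next
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        a <- frame[i]; b <- frame[j]
        dx <- pos[a, 1] - pos[b, 1]
        dy <- pos[a, 2] - pos[b, 2]
        d <- sqrt(dx * dx + dy * dy)
        if (d < 1e-9) {
          # deterministic symmetry breaking for coincident nodes
          dx <- 1e-6 * if (a < b) 1 else -1
          dy <- 0
          d <- 1e-6
        }
        f <- params$repulsion * k * k / d
        Fx[a] <- Fx[a] + dx / d * f; Fy[a] <- Fy[a] + dy / d * f
        Fx[b] <- Fx[b] - dx / d * f; Fy[b] <- Fy[b] - dy / d * f
      }
    }
  }

  # spring attraction along edges, applied to same-frame representatives
  chains <- lapply(stats::setNames(ids, ids),
                   function(i) c(i, ancestors(g, i)))
  el <- g$edges
  for (e in seq_len(nrow(el))) {
    reps <- .edge_reps(chains[[el$u[e]]], chains[[el$v[e]]], parent_of)
    if (is.null(reps)) next
    a <- reps[1L]; b <- reps[2L]
    dx <- pos[a, 1] - pos[b, 1]
    dy <- pos[a, 2] - pos[b, 2]
    d <- sqrt(dx * dx + dy * dy)
    if (d < 1e-9) next
    f <- d * d / k
    Fx[a] <- Fx[a] - dx / d * f; Fy[a] <- Fy[a] - dy / d * f
    Fx[b] <- Fx[b] + dx / d * f; Fy[b] <- Fy[b] + dy / d * f
  }

  # containment: restore members that drift past the padded boundary
  for (id in ids) {
    p <- parent_of[[id]]
    if (is.na(p)) next
    dx <- pos[id, 1] - pos[p, 1]
    dy <- pos[id, 2] - pos[p, 2]
    d <- sqrt(dx * dx + dy * dy)
    b <- .CONTAIN_MARGIN * state$radii[[p]]
    if (d > b) {
      f <- .CONTAIN_STIFF * (d - b)
      Fx[id] <- Fx[id] - dx / d * f
      Fy[id] <- Fy[id] - dy / d * f
    }
  }

  # local displacements: gain-scaled force, capped by temperature
  Dx <- Fx * .STEP_GAIN
  Dy <- Fy * .STEP_GAIN
  norm <- sqrt(Dx * Dx + Dy * Dy)
  over <- norm > state$temperature & norm > 0
  if (any(over)) {
    scl <- state$temperature / norm[over]
    Dx[over] <- Dx[over] * scl
    Dy[over] <- Dy[over] * scl
  }
  if (!is.null(movable)) {
    fixed <- setdiff(ids, movable)
    Dx[fixed] <- 0; Dy[fixed] <- 0
  }

  # total displacement = own + ancestors' (containers carry their members);
  # the temperature cap applies to each node's own force displacement,
  # rigid carriage by a moving container comes on top
  depths <- .depths(g)
  ord <- ids[order(depths[ids])]
  Tx <- Dx; Ty <- Dy
  for (id in ord) {
    p <- parent_of[[id]]
    if (!is.na(p)) {
      Tx[id] <- Tx[id] + Tx[[p]]
      Ty[id] <- Ty[id] + Ty[[p]]
    }
  }
  pos[, 1] <- pos[, 1] + Tx[ids]
  pos[, 2] <- pos[, 2] + Ty[ids]
  pos <- .recenter_containers(g, pos, depths)

  state$positions <- pos
  state$temperature <- state$temperature * params$cooling
  state$iteration <- state$iteration + 1L
  list(state = state, max_displacement = max(sqrt(Dx^2 + Dy^2), 0))
}

#' Relax a nested layout to equilibrium
#'
#' Iterates [relax_step()] until the maximum displacement drops below
#' `params$tol` or `params$max_iter` is reached. Identical
#' (graph, params) input yields a bit-identical layout.
#'
#' @param g A validated `hier_graph`.
#' @param params A [force_params()] object.
#' @param state Optional starting `layout_state` (default
#'   [init_layout()]); pass a previous state to continue a relaxation.
#' @param movable Optional character vector of nodes allowed to move.
#' @return The final `layout_state`, with `$converged` set; non-convergence
#'   at `max_iter` is reported with a message, not an error.
#' @export
relax <- function(g, params = force_params(), state = NULL, movable = NULL) {
  .check_hg(g)
  if (is.null(state)) state <- init_layout(g, params)
  disp <- Inf
  while (state$iteration < params$max_iter) {
    step <- relax_step(g, state, params, movable = movable)
    state <- step$state
    disp <- step$max_displacement
    if (disp < params$tol) break
  }
  state$converged <- disp < params$tol
  if (!state$converged) {
    message("layout did not converge within ", params$max_iter,
            " iterations (last displacement ", format(disp, digits = 3), ")")
  }
  state
}

#' List containment violations of a layout
#'
#' @param g A `hier_graph`.
#' @param state A `layout_state` covering all nodes.
#' @return Data frame with one row per node lying outside its parent's
#'   circle: columns `id`, `parent`, `distance`, `radius`. Empty when the
#'   nesting is respected.
#' @export
containment_check <- function(g, state) {
  .check_hg(g)
  out <- data.frame(id = character(), parent = character(),
                    distance = numeric(), radius = numeric(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g$nodes))) {
    id <- g$nodes$id[i]
    p <- g$nodes$parent[i]
    if (is.na(p)) next
    d <- sqrt(sum((state$positions[id, ] - state$positions[p, ])^2))
    r <- state$radii[[p]]
    if (d > r + 1e-9) {
      out <- rbind(out, data.frame(id = id, parent = p, distance = d,
                                   radius = r, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Static circle and grid layouts
#'
#' Trivial deterministic placements (no force simulation), useful as
#' starting points or for quick rendering.
#'
#' @param g A `hier_graph`.
#' @param params A [force_params()] (used for length scale and radii).
#' @return A `layout_state`.
#' @export
layout_circle <- function(g, params = force_params()) {
  .check_hg(g)
  ids <- node_ids(g)
  lv <- leaf_ids(g)
  n <- max(length(lv), 1L)
  r <- params$rest_length * n / (2 * pi) + params$rest_length
  theta <- 2 * pi * (seq_along(lv) - 1L) / n
  pos <- matrix(0, nrow = length(ids), ncol = 2,
                dimnames = list(ids, c("x", "y")))
  pos[lv, 1] <- r * cos(theta)
  pos[lv, 2] <- r * sin(theta)
  pos <- .recenter_containers(g, pos, .depths(g))
  structure(list(positions = pos, radii = .container_radii(g, params),
                 temperature = 0, iteration = 0L),
            class = "layout_state")
}

#' @rdname layout_circle
#' @export
layout_grid <- function(g, params = force_params()) {
  .check_hg(g)
  ids <- node_ids(g)
  lv <- leaf_ids(g)
  ncol_ <- max(1L, ceiling(sqrt(length(lv))))
  pos <- matrix(0, nrow = length(ids), ncol = 2,
                dimnames = list(ids, c("x", "y")))
  for (i in seq_along(lv)) {
    pos[lv[i], 1] <- ((i - 1L) %% ncol_) * params$rest_length
    pos[lv[i], 2] <- ((i - 1L) %/% ncol_) * params$rest_length
  }
  pos <- .recenter_containers(g, pos, .depths(g))
  structure(list(positions = pos, radii = .container_radii(g, params),
                 temperature = 0, iteration = 0L),
            class = "layout_state")
}

#' Read and write layout tables
#'
#' TSV with columns `id`, `x`, `y`, `radius` (radius is set for containers
#' only, `NA` for leaves).
#'
#' @param state A `layout_state`.
#' @param path File path.
#' @return `write_layout()` returns `path` invisibly; `read_layout()`
#'   returns a `layout_state` (temperature 0).
#' @export
write_layout <- function(state, path) {
  ids <- rownames(state$positions)
  rad <- rep(NA_real_, length(ids))
  hit <- ids %in% names(state$radii)
  rad[hit] <- state$radii[ids[hit]]
  tab <- data.frame(id = ids, x = state$positions[, 1],
                    y = state$positions[, 2], radius = rad,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y")
  if (!all(need %in% names(tab))) {
    stop("layout table must have columns id, x, y", call. = FALSE)
  }
  pos <- as.matrix(tab[, c("x", "y")])
  rownames(pos) <- tab$id
  radii <- numeric(0)
  if ("radius" %in% names(tab)) {
    hit <- !is.na(tab$radius)
    radii <- stats::setNames(tab$radius[hit], tab$id[hit])
  }
  structure(list(positions = pos, radii = radii, temperature = 0,
                 iteration = 0L),
            class = "layout_state")
}
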