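# Deterministic near-even assignment of n genes to m modules; shared by
# gen_modular_graph and gen_expression so the two agree without RNG.
.module_assignment <- function(m, n) {
  sort(rep_len(seq_len(m), n))
}

.gene_ids <- function(n) sprintf("g%02d", seq_len(n))

#' Modular toy graph generator
#'
#' Planted-partition graph: up to `nmax` leaves are split near-evenly into
#' `m` modules; each intra-module pair is edged with probability `p_in`,
#' each inter-module pair with `p_out`. The planted module is stored as
#' node attribute `"module"` (`"M1"`..`"Mm"`) — nesting the modules as
#' containers is left to the analysis pipeline.
#'
#' @param m Module count (>= 1).
#' @param nmax Node count (>= m).
#' @param p_in,p_out Edge probabilities, `0 <= p_out <= p_in <= 1`. The
#'   defaults (0.3, 0.01) make the modules statistically separable at
#'   `nmax = 30`.
#' @param seed RNG seed; identical arguments give an identical graph.
#' @return A `hier_graph` of leaves with planted `"module"` attributes.
#' @export
gen_modular_graph <- function(m = 5, nmax = 30, p_in = 0.3, p_out = 0.01,
                              seed = 1L) {
  stopifnot(m >= 1, nmax >= m, p_out >= 0, p_in >= p_out, p_in <= 1)
  n <- nmax
  ids <- .gene_ids(n)
  mod <- .module_assignment(m, n)
  g <- hier_graph()
  for (i in seq_len(n)) {
    g <- add_node(g, ids[i], attrs = list(module = paste0("M", mod[i])))
  }
  if (n > 1L) {
    pairs <- utils::combn(n, 2)
    p <- ifelse(mod[pairs[1, ]] == mod[pairs[2, ]], p_in, p_out)
    draw <- .with_seed(seed, stats::runif(ncol(pairs)))
    for (k in which(draw < p)) {
      g <- add_edge(g, ids[pairs[1, k]], ids[pairs[2, k]], weight = 1)
    }
  }
  g
}

#' Step-model scale-free graph generator
#'
#' Preferential-attachment step model: the first step creates a single
#' vertex and no edge; each subsequent step adds one vertex linked to an
#' existing vertex chosen with probability proportional to degree + 1
#' (the +1 bootstraps attachment to degree-zero vertices). A graph of `n`
#' vertices therefore has exactly `n - 1` edges and is connected, with a
#' right-skewed degree distribution.
#'
#' @param n Vertex count (>= 1).
#' @param seed RNG seed.
#' @return A `hier_graph` of leaves `v1..vn`.
#' @export
gen_scalefree <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  ids <- sprintf("v%0*d", max(nchar(n), 1L), seq_len(n))
  g <- hier_graph()
  g <- add_node(g, ids)
  if (n > 1L) {
    deg <- integer(n)
    targets <- .with_seed(seed, {
      t <- integer(n - 1L)
      for (i in 2:n) {
        w <- deg[seq_len(i - 1L)] + 1
        j <- sample.int(i - 1L, 1L, prob = w)
        t[i - 1L] <- j
        deg[j] <- deg[j] + 1L
        deg[i] <- deg[i] + 1L
      }
      t
    })
    for (i in 2:n) g <- add_edge(g, ids[targets[i - 1L]], ids[i])
  }
  g
}

#' Synthetic modular expression matrix with gene annotations
#'
#' Emulates the statistical shape of a module-structured gene expression
#' experiment: genes of the same planted module share a latent sample
#' profile scaled by `effect`, plus i.i.d. Gaussian noise. The companion
#' attribute table carries a simulated per-gene log2 fold-change (a
#' module-level mean plus gene scatter) and a heavy-tailed, nonnegative
#' simulated kilobase distance to the nearest binding site, drawn from an
#' exponential calibrated so that about one-third of genes fall within
#' 50 kb.
#'
#' @param m,nmax Module structure, as in [gen_modular_graph()].
#' @param n_samples Number of sample columns.
#' @param effect Scale of the shared module profile (signal).
#' @param noise Standard deviation of the per-gene noise.
#' @param seed RNG seed.
#' @return List with `expr` (genes x samples matrix, rownames = gene ids)
#'   and `attrs` (data frame `id`, `module`, `logfc`, `kb_dist`).
#' @export
gen_expression <- function(m = 5, nmax = 30, n_samples = 10, effect = 4,
                           noise = 1, seed = 1L) {
  stopifnot(m >= 1, nmax >= m, n_samples >= 2, effect >= 0, noise > 0)
  n <- nmax
  ids <- .gene_ids(n)
  mod <- .module_assignment(m, n)
  out <- .with_seed(seed, {
    latent <- matrix(stats::rnorm(m * n_samples), nrow = m)
    expr <- effect * latent[mod, , drop = FALSE] +
      matrix(stats::rnorm(n * n_samples, sd = noise), nrow = n)
    mod_lfc <- stats::rnorm(m, sd = 1.5)
    logfc <- mod_lfc[mod] + stats::rnorm(n, sd = 0.3)
    kb <- stats::rexp(n, rate = log(1.5) / 50)
    list(expr = expr, logfc = logfc, kb = kb)
  })
  expr <- out$expr
  rownames(expr) <- ids
  colnames(expr) <- sprintf("s%02d", seq_len(n_samples))
  attrs <- data.frame(
    id = ids, module = paste0("M", mod), logfc = out$logfc,
    kb_dist = out$kb, stringsAsFactors = FALSE
  )
  list(expr = expr, attrs = attrs)
}

#' Specification of a synthetic time-course experiment
#'
#' @param interactome_size Vertex count of the scale-free interactome.
#' @param timepoints Ordered labels of the treatment time points.
#' @param set_sizes Per-timepoint differentially-expressed (DE) set sizes,
#'   non-decreasing, each at most `interactome_size`.
#' @param nested_fraction Probability that a DE gene of one time point
#'   persists in the next set (1 = fully nested sets).
#' @param logfc_scale Standard deviation of the simulated log2
#'   fold-changes.
#' @param seed RNG seed.
#' @return A `timecourse_spec` list.
#' @export
timecourse_spec <- function(interactome_size = 200,
                            timepoints = c("3h", "6h", "12h"),
                            set_sizes = c(10, 20, 40),
                            nested_fraction = 0.8, logfc_scale = 1,
                            seed = 1L) {
  stopifnot(length(timepoints) >= 2,
            length(set_sizes) == length(timepoints),
            all(set_sizes >= 1), all(diff(set_sizes) >= 0),
            all(set_sizes <= interactome_size),
            nested_fraction >= 0, nested_fraction <= 1, logfc_scale > 0)
  structure(list(interactome_size = interactome_size,
                 timepoints = timepoints, set_sizes = set_sizes,
                 nested_fraction = nested_fraction,
                 logfc_scale = logfc_scale, seed = as.integer(seed)),
            class = "timecourse_spec")
}

# Snowball sample: grow a connected set from a degree-biased seed vertex
# by repeatedly absorbing a random frontier neighbor.
.snowball <- function(adj, deg, size) {
  start <- sample.int(length(deg), 1L, prob = deg + 1)
  set <- start
  while (length(set) < size) {
    frontier <- setdiff(unique(unlist(adj[set])), set)
    if (length(frontier) == 0L) {
      frontier <- setdiff(seq_along(deg), set)
    }
    set <- c(set, frontier[sample.int(length(frontier), 1L)])
  }
  set
}

#' Synthetic time-course DE sets mapped on a scale-free interactome
#'
#' The interactome is a [gen_scalefree()] graph. The first DE set is a
#' connected snowball sample (a perturbed neighborhood); each later set
#' keeps every current member independently with `nested_fraction` and is
#' topped up to its target size with genes drawn uniformly from the rest
#' of the interactome. With `nested_fraction = 1` the sets are strictly
#' nested, emulating a growing subnetwork with a stable core. Each gene
#' gets a per-timepoint simulated log2 fold-change.
#'
#' @param spec A [timecourse_spec()].
#' @return List with `interactome` (a `hier_graph`) and `de_sets` (named
#'   list, one data frame `id`, `logfc` per time point).
#' @export
gen_timecourse <- function(spec = timecourse_spec()) {
  if (!inherits(spec, "timecourse_spec")) {
    stop("expected a 'timecourse_spec'", call. = FALSE)
  }
  g <- gen_scalefree(spec$interactome_size, seed = spec$seed)
  ids <- leaf_ids(g)
  n <- length(ids)
  el <- g$edges
  iu <- match(el$u, ids); iv <- match(el$v, ids)
  adj <- lapply(seq_len(n), function(i) integer())
  for (e in seq_along(iu)) {
    adj[[iu[e]]] <- c(adj[[iu[e]]], iv[e])
    adj[[iv[e]]] <- c(adj[[iv[e]]], iu[e])
  }
  deg <- lengths(adj)
  de <- .with_seed(spec$seed + 1L, {
    sets <- vector("list", length(spec$timepoints))
    cur <- sort(.snowball(adj, deg, spec$set_sizes[1L]))
    sets[[1L]] <- cur
    for (t in seq_along(spec$timepoints)[-1L]) {
      keep <- cur[stats::runif(length(cur)) < spec$nested_fraction]
      need <- spec$set_sizes[t] - length(keep)
      pool <- setdiff(seq_len(n), keep)
      if (need > length(pool)) stop("DE set size exceeds interactome")
      fresh <- if (need > 0) pool[sample.int(length(pool), need)] else integer()
      cur <- sort(c(keep, fresh))
      sets[[t]] <- cur
    }
    lfc <- lapply(sets, function(s) {
      stats::rnorm(length(s), sd = spec$logfc_scale)
    })
    list(sets = sets, lfc = lfc)
  })
  de_sets <- lapply(seq_along(spec$timepoints), function(t) {
    data.frame(id = ids[de$sets[[t]]], logfc = de$lfc[[t]],
               stringsAsFactors = FALSE)
  })
  names(de_sets) <- spec$timepoints
  list(interactome = g, de_sets = de_sets)
}
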