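#' Skeletonize a binary matrix mask
#'
#' Topology-preserving thinning (Zhang-Suen parallel thinning) reducing the
#' segmented hyaluronan mask to one-pixel-wide centerlines, the "HA cables"
#' whose lengths are compared across conditions. Thinning preserves the
#' 8-connected component count: in the degenerate case where a tiny blob
#' would be erased entirely, its most central pixel is retained.
#'
#' @param mask A non-empty [binary_mask()].
#' @return A [binary_mask()] holding the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$pixels)) stop("cannot skeletonize an empty mask", call. = FALSE)
  p <- mask$pixels
  lab_in <- label_components_8(p)
  p <- thin_zhang_suen(p)
  # guard: every input component keeps at least one skeleton pixel
  for (comp in seq_len(max(lab_in))) {
    sel <- lab_in == comp
    if (!any(p[sel])) {
      idx <- which(sel, arr.ind = TRUE)
      ctr <- colMeans(idx)
      keep <- which.min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
      p[idx[keep, 1], idx[keep, 2]] <- TRUE
    }
  }
  binary_mask(p, mask$pixel_size_um)
}

# one pass of Zhang-Suen; sub = 1 or 2 selects the sub-iteration conditions
zs_pass <- function(p, sub) {
  n2 <- shift_mat(p, 1, 0);  n3 <- shift_mat(p, 1, -1)
  n4 <- shift_mat(p, 0, -1); n5 <- shift_mat(p, -1, -1)
  n6 <- shift_mat(p, -1, 0); n7 <- shift_mat(p, -1, 1)
  n8 <- shift_mat(p, 0, 1);  n9 <- shift_mat(p, 1, 1)
  b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
  seqs <- list(n2, n3, n4, n5, n6, n7, n8, n9, n2)
  a <- 0
  for (k in 1:8) a <- a + (!seqs[[k]] & seqs[[k + 1]])
  if (sub == 1) {
    cond <- !(n2 & n4 & n6) & !(n4 & n6 & n8)
  } else {
    cond <- !(n2 & n4 & n8) & !(n2 & n6 & n8)
  }
  del <- p & b >= 2 & b <= 6 & a == 1 & cond
  p & !del
}

thin_zhang_suen <- function(px) {
  p <- px != 0
  repeat {
    p1 <- zs_pass(p, 1)
    p2 <- zs_pass(p1, 2)
    if (identical(p2, p)) break
    p <- p2
  }
  p
}

#' Build the weighted pixel graph of a skeleton
#'
#' One node per skeleton pixel; one edge per 8-adjacent pixel pair, weighted
#' by the calibrated Euclidean step: `pixel_size_um` for orthogonal steps
#' and `sqrt(2) * pixel_size_um` for diagonal steps (the AnalyzeSkeleton
#' convention). Connected components are labelled on construction.
#'
#' @param skeleton A [binary_mask()] holding a thin (1-px) skeleton.
#' @return A `skeleton_graph` object.
#' @export
build_graph <- function(skeleton) {
  stopifnot(inherits(skeleton, "binary_mask"))
  px <- skeleton$pixels
  if (!any(px)) stop("cannot build a graph from an empty skeleton", call. = FALSE)
  s <- skeleton$pixel_size_um
  nr <- nrow(px)
  id <- matrix(0L, nr, ncol(px))
  on <- which(px)
  id[on] <- seq_along(on)
  coords <- which(px, arr.ind = TRUE)
  edges <- list()
  dirs <- list(c(0L, 1L, s), c(1L, 0L, s),
               c(1L, 1L, s * sqrt(2)), c(1L, -1L, s * sqrt(2)))
  for (d in dirs) {
    nb <- shift_mat(id, -d[1], -d[2], fill = 0L) # id of pixel at (i+dr, j+dc)
    sel <- px & nb > 0L
    if (any(sel)) {
      edges[[length(edges) + 1L]] <-
        tibble::tibble(from = id[sel], to = nb[sel], weight_um = d[3])
    }
  }
  edges <- if (length(edges) > 0) dplyr::bind_rows(edges) else
    tibble::tibble(from = integer(0), to = integer(0), weight_um = numeric(0))
  skeleton_graph(edges, n_nodes = length(on), pixel_size_um = s,
                 coords = tibble::tibble(node = seq_along(on),
                                         row = coords[, 1], col = coords[, 2]))
}

#' Construct a skeleton graph from an edge table
#'
#' Mostly used internally by [build_graph()], but exposed so that skeleton
#' graphs can also be built directly from known geometry (e.g. synthetic
#' trees used as oracles).
#'
#' @param edges Data frame with columns `from`, `to`, `weight_um`.
#' @param n_nodes Number of nodes (isolated nodes allowed).
#' @param pixel_size_um Calibration carried for reporting.
#' @param coords Optional tibble with `node`, `row`, `col`.
#' @return A `skeleton_graph`: node/edge tables, an igraph representation,
#'   a per-node component id and per-node degree.
#' @export
skeleton_graph <- function(edges, n_nodes, pixel_size_um = 1, coords = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "weight_um") %in% names(edges)))
  n_nodes <- as.integer(n_nodes)
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
    igraph::E(g)$weight <- edges$weight_um
  }
  comp <- igraph::components(g)$membership
  structure(
    list(edges = edges, n_nodes = n_nodes, pixel_size_um = pixel_size_um,
         coords = coords, graph = g, component = as.integer(comp),
         degree = as.integer(igraph::degree(g))),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d edges, %d component(s)\n",
              x$n_nodes, nrow(x$edges), max(x$component)))
  invisible(x)
}

#' Longest shortest path (geodesic diameter) of a skeleton component
#'
#' The maximum over node pairs of the weighted shortest-path distance within
#' one connected component -- the proxy for hyaluronan cable length. For
#' components with at least two endpoints (degree-1 nodes) the search is
#' restricted to endpoint pairs, which equals the all-pairs maximum on
#' trees; components with fewer than two endpoints (isolated pixels, pure
#' loops) fall back to the all-pairs maximum.
#'
#' @param graph A `skeleton_graph`.
#' @param component Component id.
#' @return Geodesic diameter in micrometres.
#' @export
longest_shortest_path <- function(graph, component) {
  stopifnot(inherits(graph, "skeleton_graph"))
  nodes <- which(graph$component == component)
  if (length(nodes) == 0L) {
    stop("unknown component id: ", component, call. = FALSE)
  }
  if (length(nodes) == 1L) return(0)
  eps <- nodes[graph$degree[nodes] == 1L]
  targets <- if (length(eps) >= 2L) eps else nodes
  d <- igraph::distances(graph$graph, v = targets, to = targets,
                         weights = igraph::E(graph$graph)$weight)
  max(d[is.finite(d)])
}

#' Per-component skeleton summaries
#'
#' Skeletonizes a matrix mask, builds the weighted pixel graph and reports,
#' per connected skeleton: pixel count, endpoints (exactly one neighbour),
#' junctions (three or more neighbours), branch count (maximal paths between
#' endpoint/junction nodes; a pure cycle counts as one branch) and the
#' longest shortest path in micrometres. Components of fewer than 3 pixels
#' are kept but flagged `small`, so any downstream filtering is explicit.
#'
#' @param mask A non-empty [binary_mask()] (segmented HABP signal).
#' @return A tibble with one row per skeleton component, ordered by
#'   component id.
#' @examples
#' sc <- make_fiber_scene(5, length_um = 6, image_size = 256, seed = 7)
#' seg <- segment_matrix(sc$channels$HABP)
#' summarize_skeletons(seg$mask)
#' @export
summarize_skeletons <- function(mask) {
  skel <- skeletonize(mask)
  g <- build_graph(skel)
  purrr::map_dfr(seq_len(max(g$component)), function(comp) {
    nodes <- which(g$component == comp)
    deg <- g$degree[nodes]
    tibble::tibble(
      component = comp,
      n_pixels = length(nodes),
      n_endpoints = sum(deg == 1L),
      n_junctions = sum(deg >= 3L),
      n_branches = count_branches(g, nodes),
      lsp_um = longest_shortest_path(g, comp),
      small = length(nodes) < 3L
    )
  })
}

# Number of maximal degree-2 chains between special (deg != 2) nodes; a
# component that is a pure cycle counts as a single branch. Mutually
# adjacent junction pixels (a frequent artifact of 8-connected crossings)
# are merged into one junction cluster first, so a plus-shaped crossing
# yields 4 branches rather than one per junction pixel.
count_branches <- function(g, nodes) {
  deg <- g$degree[nodes]
  if (length(nodes) == 1L) return(0L)
  special <- nodes[deg != 2L]
  if (length(special) == 0L) return(1L) # pure cycle
  cluster <- integer(g$n_nodes)
  junctions <- nodes[deg >= 3L]
  if (length(junctions) > 0L) {
    sub <- igraph::induced_subgraph(g$graph, junctions)
    memb <- igraph::components(sub)$membership
    cluster[junctions] <- memb
  }
  endpoints <- nodes[deg <= 1L]
  cluster[endpoints] <- max(cluster) + seq_along(endpoints)
  special_set <- rep(FALSE, g$n_nodes)
  special_set[special] <- TRUE
  adj <- igraph::adjacent_vertices(g$graph, special)
  traversals <- 0L
  for (k in seq_along(special)) {
    u <- special[k]
    for (v in as.integer(adj[[k]])) {
      if (special_set[v] && cluster[v] == cluster[u]) next # intra-cluster
      prev <- u; cur <- v
      while (!special_set[cur]) {
        nxt <- as.integer(igraph::neighbors(g$graph, cur))
        nxt <- nxt[nxt != prev]
        if (length(nxt) == 0L) break
        prev <- cur; cur <- nxt[1]
      }
      traversals <- traversals + 1L
    }
  }
  as.integer(traversals / 2L)
}

#' Empirical cumulative distribution of cable lengths
#'
#' Right-continuous ECDF as a step table: one row per distinct value with
#' the cumulative fraction of observations at or below it (reaching exactly
#' 1). This is the representation behind cumulative-distribution
#' comparisons of skeleton lengths across conditions.
#'
#' @param values Non-empty numeric vector (lengths in um).
#' @return A tibble with columns `value` and `fraction`.
#' @export
ecdf_table <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("ecdf of an empty sample", call. = FALSE)
  if (anyNA(values)) stop("ecdf values must not be NA", call. = FALSE)
  v <- sort(unique(values))
  tibble::tibble(value = v,
                 fraction = cumsum(tabulate(match(sort(values), v))) / length(values))
}
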