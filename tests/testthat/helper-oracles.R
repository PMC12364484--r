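# Shared fixtures and independent oracles, built in code at test time.

# random tree as an edge table: node k+1 attaches to a uniformly chosen
# earlier node; weights are calibrated orthogonal/diagonal steps
random_tree_edges <- function(n_nodes, s = 0.09) {
  if (n_nodes < 2L) {
    return(tibble::tibble(from = integer(0), to = integer(0),
                          weight_um = numeric(0)))
  }
  to <- 2:n_nodes
  from <- vapply(to, function(k) sample.int(k - 1L, 1L), integer(1))
  tibble::tibble(from = from, to = to,
                 weight_um = sample(c(s, s * sqrt(2)), n_nodes - 1L,
                                    replace = TRUE))
}

# brute-force all-pairs shortest-path maximum (Floyd-Warshall),
# independent of the igraph-based implementation under test
fw_max_distance <- function(edges, n_nodes) {
  d <- matrix(Inf, n_nodes, n_nodes)
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges$from[r]; j <- edges$to[r]; w <- edges$weight_um[r]
    d[i, j] <- min(d[i, j], w)
    d[j, i] <- min(d[j, i], w)
  }
  for (k in seq_len(n_nodes)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  max(d[is.finite(d)])
}

# hand implementation of the tie-corrected Kruskal-Wallis H from mid-ranks,
# used as a dual-route check on the packaged wrapper
kw_h_by_ranks <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# label map holding one filled disk of radius r px
disk_label_map <- function(radius_px, size_px, pixel_size_um = 0.09,
                           center = NULL) {
  if (is.null(center)) center <- c((size_px + 1) / 2, (size_px + 1) / 2)
  rr <- matrix(seq_len(size_px), size_px, size_px)
  cc <- matrix(seq_len(size_px), size_px, size_px, byrow = TRUE)
  d <- sqrt((rr - center[1])^2 + (cc - center[2])^2)
  label_map((d <= radius_px) * 1L, pixel_size_um)
}

# 90-degree rotation of a matrix
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
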