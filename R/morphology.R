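# Low-level grid morphology shared across stages. All neighbourhood logic in
# the package is 8-connected, matching the conventions of the original
# FIJI-based analysis.

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-connected component labelling built on EBImage's 4-connected bwlabel:
# diagonal-touching 4-labels are merged through a label-level graph.
label_components_8 <- function(px) {
  px <- px != 0
  lab4 <- EBImage::bwlabel(EBImage::Image(px * 1))
  lab4 <- matrix(as.integer(EBImage::imageData(lab4)), nrow(px), ncol(px))
  k <- max(lab4)
  if (k <= 1L) return(lab4)
  pairs <- list()
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab4
    b <- shift_mat(lab4, d[1], d[2], fill = 0L)
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs[[length(pairs) + 1L]] <- cbind(a[sel], b[sel])
  }
  if (length(pairs) == 0L) return(lab4)
  ed <- unique(do.call(rbind, pairs))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed[, 1]), to = as.character(ed[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(k)))
  )
  comp <- igraph::components(g)$membership
  remap <- as.integer(comp[as.character(seq_len(k))])
  out <- lab4
  out[out > 0L] <- remap[out[out > 0L]]
  relabel_contiguous(out)
}

# number of 8-connected components of a logical matrix
count_components_8 <- function(px) max(label_components_8(px))

# drop 8-connected components smaller than min_px pixels
remove_small_components <- function(px, min_px) {
  if (min_px <= 1L) return(px != 0)
  lab <- label_components_8(px)
  if (max(lab) == 0L) return(px != 0)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_px)
  out <- matrix(lab %in% keep, nrow(px), ncol(px))
  out
}

# Euclidean distance of every pixel to the nearest TRUE pixel of `target`
# (0 inside the target). Wraps EBImage::distmap on the complement.
distance_to_region <- function(target) {
  if (!any(target)) return(matrix(Inf, nrow(target), ncol(target)))
  d <- EBImage::distmap(EBImage::Image((!target) * 1), metric = "euclidean")
  matrix(as.numeric(EBImage::imageData(d)), nrow(target), ncol(target))
}

# fill holes of a logical matrix (wrapper keeping plain-matrix semantics)
fill_mask_holes <- function(px) {
  f <- EBImage::fillHull(EBImage::Image(px * 1))
  matrix(as.numeric(EBImage::imageData(f)) != 0, nrow(px), ncol(px))
}
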