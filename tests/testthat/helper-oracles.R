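# igraph-based connected-components oracle for cluster labelling
igraph_cluster_sizes <- function(values, threshold, connectivity) {
  dims <- dim(values)
  idx <- which(values > threshold)
  if (length(idx) == 0) return(integer(0))
  coords <- arrayInd(idx, dims)
  off <- modfilt:::connectivity_offsets(connectivity)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lookup <- stats::setNames(seq_along(idx), key(coords))
  edges <- NULL
  for (k in seq_len(nrow(off))) {
    nb <- sweep(coords, 2, off[k, ], "+")
    hit <- lookup[key(nb)]
    ok <- !is.na(hit)
    if (any(ok)) edges <- rbind(edges, cbind(which(ok), hit[ok]))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(0), 0, 2) else edges,
    directed = FALSE)
  g <- igraph::add_vertices(g,
    max(0, length(idx) - igraph::vcount(g)))
  sort(as.integer(igraph::components(g)$csize), decreasing = TRUE)
}
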