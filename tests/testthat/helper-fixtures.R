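# Shared fixtures, all generated in code.

# mask holding the first n voxels of a small grid (canonical ordering)
flat_mask <- function(n, shape = c(4, 4, 4), voxel_size = 3) {
  stopifnot(n <= prod(shape))
  brain_mask(array(c(rep(TRUE, n), rep(FALSE, prod(shape) - n)), dim = shape),
             image_grid(shape, voxel_size))
}

# random voxel_matrix fixture
random_vm <- function(n, Tn, seed, shape = c(5, 5, 5)) {
  set.seed(seed)
  voxel_matrix(matrix(rnorm(n * Tn), n, Tn), flat_mask(n, shape))
}

# dense-matrix degree-centrality oracle (full correlation matrix)
dc_oracle <- function(X, r0, mode = "weighted_positive") {
  C <- cor(t(X))
  diag(C) <- 0
  if (mode == "weighted_positive") rowSums(C * (C > r0)) else rowSums(C > r0)
}

# dense eigen-solver oracle for the shifted correlation matrix
ec_oracle <- function(X) {
  A <- (cor(t(X)) + 1) / 2
  ev <- eigen(A, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v) < 0) v <- -v
  list(vector = v, lambda = ev$values[1])
}

# connected-component oracle via igraph over an explicit offset neighborhood
component_oracle <- function(coords, offsets) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  idx <- stats::setNames(seq_len(n), key(coords))
  edges <- c()
  for (o in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2, -offsets[o, ])
    hit <- idx[key(nb)]
    ok <- !is.na(hit)
    edges <- c(edges, rbind(which(ok), hit[ok]))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}
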