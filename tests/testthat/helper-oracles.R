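# independent oracle for RWR: direct linear solve of the stationary equation
# p = r (I - (1-r) M)^{-1} p0, dangling columns redirected to the restart
rwr_solve <- function(g, seeds, r) {
  cn <- column_normalize(g)
  n <- nrow(cn$P)
  p0 <- stats::setNames(numeric(n), rownames(cn$P))
  p0[seeds] <- 1 / length(seeds)
  M <- as.matrix(cn$P)
  if (length(cn$dangling)) M[, cn$dangling] <- p0
  solve(diag(n) - (1 - r) * M, r * p0)
}

# random connected graph with named vertices, at most n_max nodes
random_connected_graph <- function(seed, n_max = 50) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(sample(5:n_max, 1), 0.15)
  })
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership ==
                                           which.max(comp$csize)))
  igraph::set_vertex_attr(g, "name",
                          value = sprintf("n%03d", seq_len(igraph::vcount(g))))
}
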