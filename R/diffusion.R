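#' Column-normalized transition matrix of an unweighted network
#'
#' The undirected graph is walked as a doubly-directed graph: the binary
#' adjacency matrix is normalized so that every nonzero column sums to 1.
#' Zero-degree (dangling) columns are left at zero and reported; [rwr()]
#' redirects their mass to the restart distribution.
#'
#' @param network an igraph graph.
#' @return list with `P` (sparse transition matrix, columns are sources) and
#'   `dangling` (names of zero-degree nodes).
#' @export
column_normalize <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty graph")
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  A <- (A > 0) * 1
  deg <- Matrix::colSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  P <- A %*% Matrix::Diagonal(x = inv)
  dimnames(P) <- dimnames(A)
  list(P = P, dangling = rownames(A)[deg == 0])
}

#' Random walk with restart
#'
#' Iterates `p_{t+1} = (1 - r) A' p_t + r p_0` with `A'` the
#' column-normalized adjacency and `p_0` uniform over the seed nodes, until
#' the L1 difference between successive iterates drops below `tol`. Mass
#' landing on dangling nodes is redirected to the restart distribution so
#' that the scores stay a probability vector. The steady state scores each
#' node's proximity to the seeds.
#'
#' @param network igraph graph.
#' @param seeds nonempty character vector of seed node names (here typically
#'   the one-hot phenotype indicator nodes).
#' @param r restart rate in (0, 1].
#' @param tol L1 termination tolerance.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return list of class `relevance_ranking`: `scores` (named, sums to 1),
#'   `seeds`, `r`, `iterations`, `residual`.
#' @export
rwr <- function(network, seeds, r = 0.5, tol = 1e-4, max_iter = 10000) {
  if (length(seeds) == 0) stop("empty seed set")
  nodes <- igraph::V(network)$name
  missing <- setdiff(seeds, nodes)
  if (length(missing)) stop("seed(s) not in graph: ", paste(missing, collapse = ", "))
  if (r <= 0 || r > 1) stop("restart rate must lie in (0, 1]")
  cn <- column_normalize(network)
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)
  dang <- cn$dangling
  p <- p0
  for (it in seq_len(max_iter)) {
    lost <- if (length(dang)) sum(p[dang]) else 0
    pn <- (1 - r) * (as.vector(cn$P %*% p) + lost * p0) + r * p0
    names(pn) <- nodes
    res <- sum(abs(pn - p))
    p <- pn
    if (res < tol) {
      return(structure(list(scores = p, seeds = seeds, r = r,
                            iterations = it, residual = res),
                       class = "relevance_ranking"))
    }
  }
  stop(sprintf("RWR did not converge in %d iterations (L1 residual %.3g)",
               max_iter, res))
}

#' Top-N feature subnetwork from a relevance ranking
#'
#' Nodes of excluded kinds (phenotype, covariate) are removed before the
#' ranking cut; ties in score are broken by lexicographic node ID. The
#' induced subgraph over the selected feature nodes is attached.
#'
#' @param network igraph graph the ranking was computed on.
#' @param ranking a `relevance_ranking` from [rwr()].
#' @param N number of features to keep (N exceeding the available feature
#'   nodes returns all of them with a warning).
#' @param include_kinds node kinds eligible for the cut.
#' @return list of class `subnetwork`: `nodes` (data.frame node/kind/score in
#'   rank order) and `graph` (induced igraph subgraph).
#' @export
top_n_features <- function(network, ranking, N,
                           include_kinds = c("protein", "metabolite")) {
  stopifnot(N >= 1)
  kind <- stats::setNames(igraph::V(network)$kind, igraph::V(network)$name)
  feats <- names(kind)[kind %in% include_kinds]
  sc <- ranking$scores[feats]
  ord <- feats[order(-sc, feats)]
  if (N > length(ord)) {
    warning("N = ", N, " exceeds the ", length(ord),
            " available feature nodes; returning all")
    N <- length(ord)
  }
  top <- ord[seq_len(N)]
  structure(list(nodes = data.frame(node = top, kind = unname(kind[top]),
                                    score = unname(ranking$scores[top]),
                                    stringsAsFactors = FALSE),
                 graph = igraph::induced_subgraph(network, top)),
            class = "subnetwork")
}
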