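#' Threshold an association matrix to its k largest edges
#'
#' Keeps the `k` largest off-diagonal weights at their original values and
#' zeroes everything else (proportional thresholding: the threshold is a
#' number of edges, not a weight cutoff). Ties at the k-th weight are
#' broken deterministically by lexicographic (row, column) order of the
#' upper-triangle pair. Idempotent for fixed `k`.
#'
#' @param M symmetric nonnegative matrix (diagonal ignored).
#' @param k number of undirected edges to retain,
#'   `1 <= k <= n(n-1)/2`. The study default is 90.
#' @return object of class `weighted_network`: list with `weights`
#'   (symmetric matrix with exactly `k` positive upper-triangle entries),
#'   `k`, and `labels`.
#' @export
threshold_topk <- function(M, k = 90) {
  n <- nrow(M)
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-10)))
    stop("matrix must be symmetric")
  kmax <- n * (n - 1) / 2
  if (k < 1 || k > kmax)
    stop("k must be between 1 and n(n-1)/2 = ", kmax)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  w <- M[ut]
  if (anyNA(w)) stop("association matrix contains missing pairs")
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(k)]
  W <- matrix(0, n, n, dimnames = dimnames(M))
  W[ut[keep, , drop = FALSE]] <- w[keep]
  W <- W + t(W)
  structure(list(weights = W, k = as.integer(k),
                 labels = rownames(M)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d nodes, k = %d edges, max weight %.4g\n",
              nrow(x$weights), x$k, max(x$weights)))
  invisible(x)
}

as_weight_matrix <- function(W) {
  if (inherits(W, "weighted_network")) W$weights else W
}

weights_to_graph <- function(W) {
  W <- as_weight_matrix(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

#' Weighted nodal clustering coefficient
#'
#' Onnela geometric-mean form with weights scaled by the largest weight in
#' the network: for node `i` with degree `k_i >= 2`,
#' `C_i = sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1))` with
#' `w' = w / max(w)`. Nodes of degree < 2 get 0. An arithmetic-mean
#' variant is available for sensitivity checks.
#'
#' @param W a `weighted_network` or symmetric nonnegative matrix.
#' @param variant `"onnela"` (default) or `"arithmetic"` (Barrat-style
#'   average of the two incident scaled weights per triangle).
#' @return numeric vector of per-node clustering coefficients.
#' @export
nodal_clustering <- function(W, variant = c("onnela", "arithmetic")) {
  variant <- match.arg(variant)
  W <- as_weight_matrix(W)
  mx <- max(W)
  if (mx == 0) return(stats::setNames(rep(0, nrow(W)), rownames(W)))
  Ws <- W / mx
  deg <- rowSums(Ws > 0)
  if (variant == "onnela") {
    A3 <- Ws^(1 / 3)
    tri <- diag(A3 %*% A3 %*% A3)
  } else {
    # arithmetic mean of the three scaled triangle weights
    A <- (Ws > 0) + 0
    tri <- diag(Ws %*% A %*% A + A %*% Ws %*% A + A %*% A %*% Ws) / 3
  }
  ci <- ifelse(deg >= 2, tri / (deg * (deg - 1)), 0)
  stats::setNames(as.numeric(ci), rownames(W))
}

#' Global clustering coefficient
#'
#' Arithmetic mean of the nodal clustering coefficients over ALL nodes
#' (zero-degree nodes contribute 0).
#'
#' @param nodal numeric vector from [nodal_clustering()], or a
#'   `weighted_network` (nodal values are computed first).
#' @return scalar mean clustering.
#' @export
global_clustering <- function(nodal) {
  if (inherits(nodal, "weighted_network") || is.matrix(nodal))
    nodal <- nodal_clustering(nodal)
  if (length(nodal) == 0) stop("empty input")
  mean(nodal)
}

#' Shortest path lengths with reciprocal-weight edge lengths
#'
#' Edge length is `1/weight` for every retained edge; entries are the
#' minimal path-length sums, `Inf` for unreachable pairs, 0 on the
#' diagonal.
#'
#' @param W a `weighted_network` or symmetric nonnegative matrix.
#' @return node x node numeric matrix of shortest path lengths.
#' @export
shortest_path_lengths <- function(W) {
  g <- weights_to_graph(W)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(D) <- dimnames(as_weight_matrix(W))
  D
}

#' Characteristic path length
#'
#' Mean of the shortest path lengths over all unordered REACHABLE node
#' pairs; the number of unreachable pairs is reported alongside rather
#' than being substituted, so a disconnected top-k network still yields a
#' finite L with a transparent flag.
#'
#' @param D distance matrix from [shortest_path_lengths()], or a
#'   `weighted_network`.
#' @return list with `L` (mean over reachable pairs; `NA` if none) and
#'   `n_unreachable` (count of unreachable unordered pairs).
#' @export
char_path_length <- function(D) {
  if (inherits(D, "weighted_network")) D <- shortest_path_lengths(D)
  d <- D[upper.tri(D)]
  unreach <- sum(is.infinite(d))
  reach <- d[is.finite(d)]
  list(L = if (length(reach)) mean(reach) else NA_real_,
       n_unreachable = unreach)
}

#' Weighted betweenness centrality
#'
#' For each node `i`, the sum over unordered pairs `(j, k)`, `j != k != i`,
#' of the fraction of shortest paths between `j` and `k` (reciprocal-weight
#' lengths, all minimal paths counted with multiplicity) that pass through
#' `i`. Unnormalised; unreachable pairs contribute 0; degree-0 and
#' degree-1 nodes score 0.
#'
#' @param W a `weighted_network` or symmetric nonnegative matrix.
#' @return named numeric vector of betweenness values.
#' @export
node_betweenness <- function(W) {
  g <- weights_to_graph(W)
  b <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight,
                           normalized = FALSE)
  stats::setNames(as.numeric(b), rownames(as_weight_matrix(W)))
}

#' Random surrogate ensemble statistics
#'
#' Generates `n_nets` size-matched random surrogates of a weighted
#' network: the topology is randomised by degree-preserving double-edge
#' swaps (Maslov-Sneppen rewiring) and the original multiset of edge
#' weights is then randomly permuted onto the rewired edges. Node count,
#' edge count, degree sequence and the weight multiset are all conserved.
#' If rewiring is infeasible (pathological degree sequences) the surrogate
#' falls back to an Erdos-Renyi graph with the same edge count, with a
#' message. A pure Erdos-Renyi null is also selectable.
#'
#' @param W a `weighted_network` or symmetric nonnegative matrix.
#' @param n_nets ensemble size (default 20).
#' @param seed integer seed.
#' @param null `"degree"` (default, Maslov-Sneppen) or `"er"`
#'   (Erdos-Renyi with matched node and edge counts).
#' @return list with `c_rand`, `l_rand` (ensemble means of global
#'   clustering and characteristic path length) and `surrogates` (list of
#'   surrogate weight matrices).
#' @export
random_ensemble <- function(W, n_nets = 20, seed = 1L,
                            null = c("degree", "er")) {
  null <- match.arg(null)
  if (n_nets < 1) stop("n_nets must be at least 1")
  Wm <- as_weight_matrix(W)
  n <- nrow(Wm)
  ew <- Wm[upper.tri(Wm)]
  ew <- ew[ew > 0]
  m <- length(ew)
  g0 <- weights_to_graph(Wm)
  with_seed(seed, {
    surr <- lapply(seq_len(n_nets), function(i) {
      gr <- NULL
      if (null == "degree") {
        gr <- tryCatch(
          igraph::rewire(g0, igraph::keeping_degseq(niter = 20 * m)),
          error = function(e) NULL)
      }
      if (is.null(gr)) {
        if (null == "degree")
          message("degree-preserving rewiring failed; ",
                  "falling back to Erdos-Renyi surrogate")
        gr <- igraph::sample_gnm(n, m)
      }
      el <- igraph::as_edgelist(gr, names = FALSE)
      S <- matrix(0, n, n, dimnames = dimnames(Wm))
      S[el] <- sample(ew)
      S + t(S)
    })
    cs <- vapply(surr, function(S) global_clustering(nodal_clustering(S)),
                 numeric(1))
    ls <- vapply(surr, function(S) char_path_length(
      shortest_path_lengths(S))$L, numeric(1))
    list(c_rand = mean(cs), l_rand = mean(ls), surrogates = surr)
  })
}

#' Small-worldness index
#'
#' `sigma = (C / C_rand) / (L / L_rand)`: the clustering ratio over the
#' path-length ratio against the random ensemble. Values above 1 indicate
#' small-world organisation.
#'
#' @param c,l global clustering and characteristic path length of the
#'   network.
#' @param c_rand,l_rand ensemble means from [random_ensemble()].
#' @return scalar sigma, or `NA` (with a warning) if any input is
#'   nonpositive or missing.
#' @export
small_worldness <- function(c, l, c_rand, l_rand) {
  vals <- c(c, l, c_rand, l_rand)
  if (anyNA(vals) || any(vals <= 0)) {
    warning("small-worldness undefined: nonpositive or missing input")
    return(NA_real_)
  }
  (c / c_rand) / (l / l_rand)
}

#' All network metrics of one thresholded network
#'
#' Convenience wrapper computing the nodal (clustering, betweenness) and
#' global (C, L, sigma) parameters in one call.
#'
#' @param W a `weighted_network` (see [threshold_topk()]).
#' @param n_rand surrogate ensemble size for sigma (default 20).
#' @param seed seed for the ensemble.
#' @return object of class `network_metrics`: list with
#'   `nodal_clustering`, `nodal_betweenness`, `global_clustering`,
#'   `char_path_length`, `n_unreachable_pairs`, `c_rand`, `l_rand`,
#'   `sigma`.
#' @export
network_metrics <- function(W, n_rand = 20, seed = 1L) {
  nc <- nodal_clustering(W)
  C <- global_clustering(nc)
  cp <- char_path_length(shortest_path_lengths(W))
  bt <- node_betweenness(W)
  ens <- random_ensemble(W, n_nets = n_rand, seed = seed)
  sig <- small_worldness(C, cp$L, ens$c_rand, ens$l_rand)
  structure(list(nodal_clustering = nc, nodal_betweenness = bt,
                 global_clustering = C, char_path_length = cp$L,
                 n_unreachable_pairs = cp$n_unreachable,
                 c_rand = ens$c_rand, l_rand = ens$l_rand, sigma = sig),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("<network_metrics> C = %.4f  L = %.4f  sigma = %.4f",
                     "  (%d unreachable pairs)\n"),
              x$global_clustering, x$char_path_length, x$sigma,
              x$n_unreachable_pairs))
  invisible(x)
}
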