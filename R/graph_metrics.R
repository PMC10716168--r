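#' Weighted shortest-path distance matrix
#'
#' Edge lengths are the reciprocal of the edge weight (stronger connections
#' are "closer"); distances are Dijkstra shortest paths, `Inf` for
#' disconnected pairs and 0 on the diagonal.
#'
#' @param x a [connectome()] or a weights matrix.
#' @return R x R numeric distance matrix.
#' @export
shortest_paths_matrix <- function(x) {
  W <- weights_of(x)
  g <- graph_from_weights(W)
  wts <- igraph::E(g)$weight
  d <- igraph::distances(g, weights = if (length(wts)) 1 / wts else NULL,
                         algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

weights_of <- function(x) {
  if (inherits(x, "connectome")) x$weights else as.matrix(x)
}

graph_from_weights <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Global efficiency (harmonic mean of inverse distances)
#' @param x a [connectome()] or weights matrix.
#' @return scalar; mean over ordered node pairs of 1/d_ij, with 1/Inf = 0.
#' @export
global_efficiency <- function(x) {
  mean(nodal_efficiency(x))
}

#' Nodal efficiency
#'
#' Per-region mean inverse shortest-path distance to all other regions,
#' i.e. the region's contribution to whole-network communication efficiency.
#'
#' @inheritParams global_efficiency
#' @return length-R numeric vector.
#' @export
nodal_efficiency <- function(x) {
  d <- shortest_paths_matrix(x)
  N <- nrow(d)
  if (N < 2) stop("need at least 2 regions")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (N - 1)
}

#' Nodal and mean local efficiency
#'
#' The local efficiency of node i is the global efficiency of the subgraph
#' induced by its neighbours (node i removed, original weights); it measures
#' fault tolerance of communication around i. Nodes with fewer than two
#' neighbours get 0.
#'
#' @inheritParams global_efficiency
#' @return length-R numeric vector ([nodal_local_efficiency()]) or its mean
#'   ([local_efficiency()]).
#' @export
nodal_local_efficiency <- function(x) {
  W <- weights_of(x)
  R <- nrow(W)
  out <- numeric(R)
  for (i in seq_len(R)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    sub <- W[nb, nb, drop = FALSE]
    if (all(sub == 0)) next
    out[i] <- global_efficiency(sub)
  }
  out
}

#' @rdname nodal_local_efficiency
#' @export
local_efficiency <- function(x) mean(nodal_local_efficiency(x))

#' Characteristic path length
#'
#' Mean shortest-path distance over connected ordered pairs. If any pair is
#' disconnected the mean is restricted to finite pairs and the result carries
#' attribute `disconnected = TRUE`.
#'
#' @inheritParams global_efficiency
#' @return scalar with optional `disconnected` attribute.
#' @export
characteristic_path_length <- function(x) {
  d <- shortest_paths_matrix(x)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0) stop("no connected node pair")
  out <- mean(fin)
  if (length(fin) < length(off)) attr(out, "disconnected") <- TRUE
  out
}

#' Nodal degree strength and network strength
#'
#' Degree strength k_i is the summed weight of edges at node i; network
#' strength S_p is its mean across nodes.
#'
#' @inheritParams global_efficiency
#' @return length-R vector ([degree_strength()]) or scalar ([network_strength()]).
#' @export
degree_strength <- function(x) rowSums(weights_of(x))

#' @rdname degree_strength
#' @export
network_strength <- function(x) mean(degree_strength(x))

#' Weighted clustering coefficient (Onnela)
#'
#' Weights are scaled by the largest weight in the network; the coefficient
#' of node i is the sum of geometric means of triangle weights at i divided
#' by k_i (k_i - 1) with k_i the binary degree. Isolated and degree-1 nodes
#' get 0.
#'
#' @inheritParams global_efficiency
#' @return list with `nodal` (length-R vector) and `mean` (scalar C_p).
#' @export
clustering_coefficient <- function(x) {
  W <- weights_of(x)
  R <- nrow(W)
  mx <- max(W)
  nodal <- numeric(R)
  if (mx > 0) {
    Wb <- (W / mx)^(1 / 3)
    num <- diag(Wb %*% Wb %*% Wb)  # ordered triangle walks = 2 * triangles
    k <- rowSums(W > 0)
    ok <- k > 1
    nodal[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  }
  list(nodal = nodal, mean = mean(nodal))
}

#' Nodal betweenness centrality
#'
#' Fraction of shortest paths between other node pairs passing through each
#' node, summed over ordered pairs and normalised by (n-1)(n-2) so values lie
#' in \[0, 1\]. Tied shortest paths split credit by multiplicity.
#'
#' @inheritParams global_efficiency
#' @return length-R numeric vector.
#' @export
betweenness_centrality <- function(x) {
  W <- weights_of(x)
  R <- nrow(W)
  if (R < 3) stop("betweenness needs at least 3 regions")
  g <- graph_from_weights(W)
  wts <- igraph::E(g)$weight
  b <- igraph::betweenness(g, weights = if (length(wts)) 1 / wts else NULL,
                           directed = FALSE)
  as.numeric(2 * b / ((R - 1) * (R - 2)))
}

#' All global network properties
#'
#' @inheritParams global_efficiency
#' @param ensemble optional list of null connectomes from [random_ensemble()];
#'   when supplied, gamma/lambda/sigma small-world ratios are included.
#' @return named list: `e_glob`, `e_loc`, `l_p`, `s_p`, `c_p`, and with an
#'   ensemble also `gamma`, `lambda`, `sigma`.
#' @export
global_metrics <- function(x, ensemble = NULL) {
  out <- list(
    e_glob = global_efficiency(x),
    e_loc = local_efficiency(x),
    l_p = as.numeric(characteristic_path_length(x)),
    s_p = network_strength(x),
    c_p = clustering_coefficient(x)$mean
  )
  if (!is.null(ensemble)) {
    sw <- small_worldness(x, ensemble)
    out <- c(out, sw)
  }
  out
}

#' All nodal network properties
#' @inheritParams global_efficiency
#' @return data.frame with columns `region`, `n_eglob`, `n_eloc`,
#'   `degree_strength`, `betweenness`.
#' @export
nodal_metrics <- function(x) {
  data.frame(
    region = seq_len(nrow(weights_of(x))),
    n_eglob = nodal_efficiency(x),
    n_eloc = nodal_local_efficiency(x),
    degree_strength = degree_strength(x),
    betweenness = betweenness_centrality(x)
  )
}

#' Matched random networks
#'
#' Degree-preserving nulls: the binary topology is rewired by Maslov-Sneppen
#' double-edge swaps (10x the edge count attempted swaps), preserving the
#' binary degree sequence exactly, and the observed multiset of weights is
#' then randomly permuted onto the rewired edges. Reproducible from `seed`.
#'
#' @param x a [connectome()] or weights matrix.
#' @param n number of null networks.
#' @param seed integer seed.
#' @param swap_factor attempted swaps per edge.
#' @return list of `n` [connectome()] objects.
#' @export
random_ensemble <- function(x, n = 5000, seed = 1L, swap_factor = 10) {
  W <- weights_of(x)
  edge_w <- W[upper.tri(W)]
  edge_w <- edge_w[edge_w > 0]
  if (length(edge_w) < 2) stop("need at least 2 edges to rewire")
  g <- graph_from_weights(W)
  niter <- ceiling(swap_factor * igraph::ecount(g))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
    el <- igraph::as_edgelist(gr, names = FALSE)
    w <- sample(edge_w)
    Wn <- matrix(0, nrow(W), ncol(W))
    Wn[el] <- w
    Wn[el[, c(2, 1)]] <- w
    connectome(Wn)
  })
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

#' Small-world ratios against a null ensemble
#'
#' gamma = C_p / mean null C_p, lambda = L_p / mean null L_p,
#' sigma = gamma / lambda; sigma > 1 indicates small-world topology.
#'
#' @param x a [connectome()] or weights matrix.
#' @param ensemble list of null connectomes ([random_ensemble()]).
#' @return named list with `gamma`, `lambda`, `sigma`.
#' @export
small_worldness <- function(x, ensemble) {
  cp <- clustering_coefficient(x)$mean
  lp <- as.numeric(characteristic_path_length(x))
  cp_null <- mean(vapply(ensemble, function(e) clustering_coefficient(e)$mean, 0))
  lp_null <- mean(vapply(ensemble, function(e) as.numeric(characteristic_path_length(e)), 0))
  if (cp_null == 0 || lp_null == 0) stop("null ensemble metric mean is zero")
  gamma <- cp / cp_null
  lambda <- lp / lp_null
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}
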