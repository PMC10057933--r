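# Global graph measures and small-world normalization against
# degree-preserving randomized reference graphs.

asIgraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net@adjacency, mode = "undirected")
}

fromIgraph <- function(g) {
  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  new("BinaryNetwork",
      adjacency = methods::as(a, "generalMatrix"),
      rThreshold = NA_real_, qValue = NA_real_)
}

#' Clustering coefficient
#'
#' Per-node clustering coefficient \eqn{C_i = 2 t_i / (k_i (k_i - 1))},
#' where \eqn{t_i} is the number of edges among the neighbors of node i
#' and \eqn{k_i} its degree; nodes with degree < 2 contribute
#' \eqn{C_i = 0}. The mean is taken over all nodes (a segregation
#' measure: the tendency of a node's neighbors to be interconnected).
#'
#' @param net a \linkS4class{BinaryNetwork}.
#' @return list with \code{perNode} (numeric vector) and \code{mean}.
#' @export
clusteringCoefficient <- function(net) {
  stopifnot(is(net, "BinaryNetwork"))
  g <- asIgraph(net)
  ci <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  ci[!is.finite(ci)] <- 0
  list(perNode = ci, mean = mean(ci))
}

#' Characteristic path length
#'
#' Mean shortest-path distance (breadth-first search on the unweighted
#' graph) over all ordered pairs of distinct nodes within the largest
#' connected component (an integration measure). For disconnected graphs
#' the measure is restricted to that component by default; the
#' \code{"harmonic"} method instead uses all node pairs and returns the
#' reciprocal of the mean inverse distance (efficiency-style), which
#' tolerates unreachable pairs.
#'
#' @param net a \linkS4class{BinaryNetwork} with >= 2 nodes.
#' @param method \code{"component"} (default) or \code{"harmonic"}.
#' @return list with \code{L}, \code{componentSize} and
#'   \code{componentFraction}.
#' @export
characteristicPathLength <- function(net,
                                     method = c("component", "harmonic")) {
  stopifnot(is(net, "BinaryNetwork"))
  method <- match.arg(method)
  n <- nNodes(net)
  if (n < 2L) stop("at least 2 nodes are required")
  if (nEdges(net) == 0L)
    stop("undefined path length: the network has no edges")
  g <- asIgraph(net)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  csize <- comp$csize[big]
  if (method == "component") {
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    L <- igraph::mean_distance(sub, directed = FALSE)
  } else {
    D <- igraph::distances(g)
    inv <- 1 / D[upper.tri(D)]
    inv[!is.finite(inv)] <- 0
    L <- 1 / mean(inv)
  }
  list(L = L, componentSize = as.integer(csize),
       componentFraction = csize / n)
}

#' Degree-preserving network randomization
#'
#' Randomizes a network by repeated double-edge swaps (Maslov-Sneppen
#' rewiring): two edges (a,b), (c,d) are replaced by (a,d), (c,b) when
#' that introduces no self-loop or multi-edge. Every node's degree (and
#' hence the degree sequence and edge count) is preserved exactly. The
#' number of attempted swaps is \code{nSwapsPerEdge * nEdges}.
#' Deterministic given \code{seed}.
#'
#' @param net a \linkS4class{BinaryNetwork}.
#' @param nSwapsPerEdge attempted swaps per edge (default 10).
#' @param seed integer seed.
#' @return a randomized \linkS4class{BinaryNetwork}; networks with fewer
#'   than 2 edges are returned unchanged with a warning.
#' @export
randomizeNetwork <- function(net, nSwapsPerEdge = 10, seed = 1) {
  stopifnot(is(net, "BinaryNetwork"))
  m <- nEdges(net)
  if (m < 2L) {
    warning("network too small to rewire; returning it unchanged")
    return(net)
  }
  g <- asIgraph(net)
  rg <- withSeed(seed,
    igraph::rewire(g, igraph::keeping_degseq(niter = nSwapsPerEdge * m)))
  fromIgraph(rg)
}

#' Small-world properties of a binary network
#'
#' Computes the mean clustering coefficient C and characteristic path
#' length L of the network, the means of the same measures over
#' \code{nRandom} degree-preserving randomized reference networks
#' (default 5), and the normalized quantities: normalized clustering
#' \eqn{\gamma = C / C_{rand}}, normalized path length
#' \eqn{\lambda = L / L_{rand}}, and small-world coefficient
#' \eqn{\sigma = \gamma / \lambda}. A network is considered small-world
#' when \eqn{\gamma > 1}, \eqn{\lambda \approx 1} and \eqn{\sigma > 1}.
#'
#' The master seed fans out deterministically to one child seed per
#' reference network. A warning is issued when the largest connected
#' component holds less than 90\% of the nodes, since L is then computed
#' on a reduced node set.
#'
#' @param net a \linkS4class{BinaryNetwork}.
#' @param nRandom number of randomized references (>= 1, default 5).
#' @param seed integer master seed.
#' @param nSwapsPerEdge attempted swaps per edge during rewiring.
#' @param pathMethod passed to [characteristicPathLength()].
#' @return a \linkS4class{NetworkProperties} object.
#' @examples
#' sim <- buildSimilarityMatrix(extractCubes(
#'   simulateVolume(shape = c(15, 15, 15), fwhm = 8, seed = 2)))
#' net <- fdrBinarize(sim)
#' smallWorldProperties(net, seed = 1)
#' @export
smallWorldProperties <- function(net, nRandom = 5, seed = 1,
                                 nSwapsPerEdge = 10,
                                 pathMethod = c("component", "harmonic")) {
  stopifnot(is(net, "BinaryNetwork"), nRandom >= 1)
  pathMethod <- match.arg(pathMethod)
  C <- clusteringCoefficient(net)$mean
  pl <- characteristicPathLength(net, method = pathMethod)
  if (pl$componentFraction < 0.9)
    warning(sprintf(
      "largest connected component holds only %.0f%% of nodes",
      100 * pl$componentFraction))
  Cr <- Lr <- numeric(nRandom)
  for (i in seq_len(nRandom)) {
    rn <- randomizeNetwork(net, nSwapsPerEdge = nSwapsPerEdge,
                           seed = childSeed(seed, i))
    Cr[i] <- clusteringCoefficient(rn)$mean
    Lr[i] <- characteristicPathLength(rn, method = pathMethod)$L
  }
  CRand <- mean(Cr)
  LRand <- mean(Lr)
  if (CRand <= 0)
    stop("degenerate reference: randomized networks have zero clustering")
  gamma <- C / CRand
  lambda <- pl$L / LRand
  new("NetworkProperties",
      clusteringC = C, pathLengthL = pl$L, CRand = CRand, LRand = LRand,
      gamma = gamma, lambda = lambda, sigma = gamma / lambda,
      nRandom = as.integer(nRandom),
      componentFraction = pl$componentFraction)
}
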