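#' Pairwise Pearson functional-connectivity network
#'
#' Builds a symmetric weighted functional network whose edge weights are the
#' Pearson correlation coefficients between activity traces. The diagonal is
#' forced to zero (no self-edges).
#'
#' @param traces Numeric matrix, one row per node (neuron or region), equal
#'   length series in columns (length >= 3).
#' @param nodes Optional node names; defaults to rownames or `V1...Vn`.
#' @param level `"neuron"` or `"region"` tag carried on the network.
#' @return An object of class `functional_network`: list with `w` (symmetric
#'   weight matrix, weights in `[-1, 1]`, zero diagonal), `nodes`, `level`.
#' @examples
#' net <- connectivity_matrix(rbind(a = c(1, 2, 3), b = c(2, 4, 6)))
#' net$w
#' @export
connectivity_matrix <- function(traces, nodes = NULL,
                                level = c("neuron", "region")) {
  level <- match.arg(level)
  traces <- as.matrix(traces)
  if (nrow(traces) < 2) stop("need at least 2 series")
  if (ncol(traces) < 3) stop("series must have length >= 3")
  v <- apply(traces, 1, stats::var)
  if (any(v == 0)) {
    bad <- if (!is.null(rownames(traces))) rownames(traces)[v == 0] else
      which(v == 0)
    stop("zero-variance series for node(s): ",
         paste(bad, collapse = ", "))
  }
  w <- stats::cor(t(traces))
  w <- (w + t(w)) / 2            # enforce exact symmetry
  diag(w) <- 0
  if (is.null(nodes))
    nodes <- rownames(traces) %||% paste0("V", seq_len(nrow(traces)))
  dimnames(w) <- list(nodes, nodes)
  structure(list(w = w, nodes = nodes, level = level),
            class = "functional_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean functional connectivity
#'
#' Mean of the raw signed weights over the strict upper triangle.
#'
#' @param net A `functional_network`.
#' @return Scalar mean connectivity.
#' @export
mean_connectivity <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  if (nrow(net$w) < 2) stop("network has fewer than 2 nodes")
  mean(net$w[upper.tri(net$w)])
}

#' Strong-connection ratio
#'
#' Fraction of node pairs whose correlation strictly exceeds the threshold,
#' relative to all existing (off-diagonal) pairs.
#'
#' @param net A `functional_network`.
#' @param threshold Correlation cutoff (default 0.8); ties are not counted.
#' @return Fraction in `[0, 1]`.
#' @export
strong_ratio <- function(net, threshold = 0.8) {
  stopifnot(inherits(net, "functional_network"))
  w <- net$w[upper.tri(net$w)]
  if (length(w) == 0) stop("network has no pairs")
  mean(w > threshold)
}

#' Region-level functional network
#'
#' Averages traces of the neurons within each brain region to a per-region
#' response trace, then correlates the region averages. Regions containing
#' no included neurons are dropped and reported.
#'
#' @param dataset A `calcium_dataset`.
#' @param regions Optional `region_map`; defaults to the dataset's map.
#' @param responsive_only If `TRUE`, restrict to the responsive union of
#'   `rset`.
#' @param rset A [detect_responsive()] result (required when
#'   `responsive_only = TRUE`).
#' @return A `functional_network` at region level, with attribute
#'   `dropped_regions` (names of regions without included neurons).
#' @export
region_network <- function(dataset, regions = dataset$region_map,
                           responsive_only = FALSE, rset = NULL) {
  stopifnot(inherits(regions, "region_map"))
  include <- rep(TRUE, nrow(dataset$traces))
  if (responsive_only) {
    if (is.null(rset)) stop("responsive_only = TRUE requires rset")
    include <- rset$union
  }
  ids <- regions$rects$id
  mean_traces <- lapply(ids, function(r) {
    sel <- include & dataset$region == r
    if (!any(sel)) return(NULL)
    colMeans(dataset$traces[sel, , drop = FALSE])
  })
  keep <- !vapply(mean_traces, is.null, logical(1))
  if (sum(keep) < 2) stop("fewer than 2 populated regions")
  m <- do.call(rbind, mean_traces[keep])
  rownames(m) <- regions$rects$name[keep]
  net <- connectivity_matrix(m, level = "region")
  attr(net, "dropped_regions") <- regions$rects$name[!keep]
  net
}

#' Negative-weight policy and modularity parameters
#'
#' Modularity and weighted degree are defined for nonnegative weights; the
#' policy states how signed correlations are handled before those metrics:
#' `"clip"` sets negatives to zero (default), `"abs"` takes absolute values,
#' `"error"` refuses signed input.
#'
#' @param gamma Resolution parameter (> 0, default 1).
#' @param negative Negative-weight policy.
#' @return A list of class `modularity_params`.
#' @export
modularity_params <- function(gamma = 1,
                              negative = c("clip", "abs", "error")) {
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(gamma = gamma, negative = match.arg(negative)),
            class = "modularity_params")
}

apply_negative_policy <- function(w, policy) {
  switch(policy,
         clip = pmax(w, 0),
         abs = abs(w),
         error = if (any(w < 0))
           stop("negative weights present; choose a clip/abs policy") else w)
}

#' Spectral partition of a functional network
#'
#' Normalized spectral clustering of the correlation network: weights are
#' mapped to affinities `(w + 1) / 2` in `[0, 1]`, the top-k eigenvectors of
#' the symmetric-normalized affinity are row-normalized and k-means
#' clustered. Deterministic given the seed; retries with fresh k-means
#' starts if a community comes back empty.
#'
#' @param net A `functional_network`.
#' @param k Number of communities (default 3, <= node count).
#' @param seed Integer seed for k-means initialization.
#' @return An object of class `network_partition`: list with `membership`
#'   (0-based contiguous community id per node, named) and `k`.
#' @export
spectral_partition <- function(net, k = 3L, seed = 1L) {
  stopifnot(inherits(net, "functional_network"))
  n <- nrow(net$w)
  if (k > n) stop("k must be <= node count")
  if (k == n) {
    memb <- seq_len(n) - 1L
    names(memb) <- net$nodes
    return(structure(list(membership = memb, k = as.integer(k)),
                     class = "network_partition"))
  }
  aff <- (net$w + 1) / 2
  diag(aff) <- 1
  d <- rowSums(aff)
  d[d == 0] <- 1
  s <- 1 / sqrt(d)
  L <- aff * tcrossprod(s)        # D^-1/2 A D^-1/2
  e <- eigen(L, symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  set.seed(seed)
  for (attempt in 1:20) {
    km <- stats::kmeans(U, centers = k, nstart = 10)
    if (all(tabulate(km$cluster, k) > 0)) {
      # contiguous ids in order of first appearance
      memb <- as.integer(factor(km$cluster, levels = unique(km$cluster))) - 1L
      names(memb) <- net$nodes
      return(structure(list(membership = memb, k = as.integer(k)),
                       class = "network_partition"))
    }
  }
  stop("spectral partition produced an empty community repeatedly")
}

#' Network modularity
#'
#' Modularity of a weighted network under a given community partition:
#' `Q = (1 / 2m) * sum_ij (A_ij - gamma * k_i * k_j / 2m) * delta(c_i, c_j)`
#' over ordered node pairs, where `A` is the (policy-transformed) weight
#' matrix, `k_i` its row sums, `m` half the total weight, and `gamma` the
#' resolution parameter. With one community and `gamma = 1`, `Q = 0`
#' identically.
#'
#' @param net A `functional_network`.
#' @param partition A [spectral_partition()] result (or compatible list with
#'   a 0-based `membership` vector).
#' @param params A [modularity_params()] object.
#' @return Scalar modularity `Q`.
#' @export
network_modularity <- function(net, partition,
                               params = modularity_params()) {
  stopifnot(inherits(net, "functional_network"),
            inherits(params, "modularity_params"))
  memb <- partition$membership
  if (length(memb) != nrow(net$w)) stop("partition does not cover all nodes")
  A <- apply_negative_policy(net$w, params$negative)
  k <- rowSums(A)
  two_m <- sum(A)
  if (two_m <= 0) stop("total edge weight is zero after negative policy")
  same <- outer(memb, memb, `==`)
  sum((A - params$gamma * tcrossprod(k) / two_m) * same) / two_m
}

#' Weighted degree centrality
#'
#' Sum of (policy-transformed) connection weights incident to each node; in
#' binary mode, the count of connections exceeding a threshold.
#'
#' @param net A `functional_network`.
#' @param params A [modularity_params()] object (negative-weight policy).
#' @param binary If `TRUE`, count edges with weight strictly above
#'   `threshold` instead of summing weights.
#' @param threshold Edge cutoff for binary mode (default 0.8).
#' @return Named numeric vector, one value per node.
#' @export
degree_centrality <- function(net, params = modularity_params(),
                              binary = FALSE, threshold = 0.8) {
  stopifnot(inherits(net, "functional_network"))
  A <- apply_negative_policy(net$w, params$negative)
  out <- if (binary) rowSums(A > threshold) else rowSums(A)
  stats::setNames(out, net$nodes)
}

#' Greedy modularity-maximizing partition
#'
#' Agglomerative (Clauset-Newman-Moore style) community detection: starts
#' from singleton communities and repeatedly merges the pair of communities
#' giving the largest modularity gain, stopping when no merge improves `Q`.
#' Used as the per-day alternative to carrying a fixed day-1 partition
#' forward.
#'
#' @param net A `functional_network`.
#' @param params A [modularity_params()] object.
#' @return A `network_partition`.
#' @export
greedy_partition <- function(net, params = modularity_params()) {
  stopifnot(inherits(net, "functional_network"))
  A <- apply_negative_policy(net$w, params$negative)
  n <- nrow(A)
  memb <- seq_len(n) - 1L
  q_of <- function(m) {
    network_modularity(net, list(membership = m), params)
  }
  repeat {
    comms <- unique(memb)
    if (length(comms) == 1) break
    best <- list(gain = 0, m = NULL)
    q0 <- q_of(memb)
    for (i in seq_along(comms)) for (j in seq_along(comms)) {
      if (i >= j) next
      m2 <- memb
      m2[m2 == comms[j]] <- comms[i]
      g <- q_of(m2) - q0
      if (g > best$gain + 1e-12) best <- list(gain = g, m = m2)
    }
    if (is.null(best$m)) break
    memb <- best$m
  }
  memb <- as.integer(factor(memb, levels = unique(memb))) - 1L
  names(memb) <- net$nodes
  structure(list(membership = memb, k = length(unique(memb))),
            class = "network_partition")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %d %s nodes, mean |w| = %.3f\n",
              nrow(x$w), x$level, mean(abs(x$w[upper.tri(x$w)]))))
  invisible(x)
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d communities over %d nodes\n",
              x$k, length(x$membership)))
  invisible(x)
}
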