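## Nodal topology of binary networks: the four metrics used to contrast EZ
## and NEZ nodes, plus the EZ/NEZ sub-network density decomposition.
## All metrics are computed on the whole network first; EZ/NEZ labels are
## applied only afterwards, so that differing node counts between the two
## classes cannot bias the per-node values.

adjacency_of <- function(net) {
  if (inherits(net, "ez_network")) net$adjacency else {
    a <- as.matrix(net)
    if (!isSymmetric(unname(a)) || any(a != 0 & a != 1) || any(diag(a) != 0))
      stopf("adjacency must be binary, symmetric, hollow")
    a
  }
}

#' Node degree
#'
#' Number of edges attached to each node: `nd_i = sum_j a_ij`.
#'
#' @param net An `ez_network` or binary adjacency matrix.
#' @return Named integer vector, one value per node.
#' @export
node_degree <- function(net) {
  a <- adjacency_of(net)
  stats::setNames(as.integer(rowSums(a)), rownames(a))
}

#' Clustering coefficient
#'
#' Density of connections among each node's neighbours:
#' `c_i = 2 e_i / (k_i (k_i - 1))`, where `e_i` counts edges between
#' neighbours of `i`. Nodes with fewer than two neighbours get 0.
#'
#' @inheritParams node_degree
#' @return Named numeric vector in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  a <- adjacency_of(net)
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e_i <- sum(a[nb, nb]) / 2
    out[i] <- 2 * e_i / (k * (k - 1))
  }
  stats::setNames(out, rownames(a))
}

# Level-synchronous BFS distances from every node of a binary adjacency.
# Returns the n x n geodesic matrix with Inf for unreachable pairs.
bfs_distances <- function(a) {
  n <- nrow(a)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) == 1
  step <- 0
  repeat {
    step <- step + 1
    nxt <- ((reach %*% a) > 0) & !reach
    if (!any(nxt)) break
    D[nxt] <- step
    reach <- reach | nxt
  }
  D
}

#' Betweenness centrality
#'
#' Fraction of shortest paths passing through each node, accumulated over
#' unordered pairs `s < t` with `s != i != t` (Brandes' algorithm on the
#' unweighted graph). Pairs in different components contribute nothing.
#' Unnormalized by default -- within-sample EZ-vs-NEZ contrasts cancel any
#' normalization; `normalize = TRUE` divides by `(N-1)(N-2)/2`.
#'
#' @inheritParams node_degree
#' @param normalize Divide by the number of possible pairs?
#' @return Named numeric vector of non-negative centralities.
#' @export
betweenness_centrality <- function(net, normalize = FALSE) {
  a <- adjacency_of(net)
  n <- nrow(a)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    d <- rep(-1L, n)
    sigma <- numeric(n)
    d[s] <- 0L
    sigma[s] <- 1
    levels <- list(s)
    frontier <- s
    while (length(frontier) > 0) {
      af <- a[frontier, , drop = FALSE]
      reachable <- which(colSums(af) > 0 & d < 0)
      if (length(reachable) == 0) break
      sigma[reachable] <- as.numeric(
        crossprod(af[, reachable, drop = FALSE], sigma[frontier]))
      d[reachable] <- d[frontier[1]] + 1L
      levels[[length(levels) + 1L]] <- reachable
      frontier <- reachable
    }
    delta <- numeric(n)
    if (length(levels) > 1) {
      for (lev in rev(seq_along(levels))[-length(levels)]) {
        w <- levels[[lev]]
        v <- levels[[lev - 1L]]
        coef <- (1 + delta[w]) / sigma[w]
        delta[v] <- delta[v] +
          sigma[v] * as.numeric(a[v, w, drop = FALSE] %*% coef)
      }
    }
    delta[s] <- 0
    bc <- bc + delta
  }
  bc <- bc / 2  # unordered pairs
  if (normalize && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  stats::setNames(bc, rownames(a))
}

#' Local efficiency
#'
#' Communication efficiency among each node's neighbours after the node is
#' removed: the subgraph induced by the neighbours of `i` is extracted and
#' `le_i = (1 / (k_i (k_i - 1))) * sum_{j != h} 1 / d_jh`, with geodesics
#' `d_jh` measured inside that subgraph and unreachable pairs contributing
#' zero. Nodes with fewer than two neighbours get 0.
#'
#' @inheritParams node_degree
#' @return Named numeric vector in \[0, 1\].
#' @export
local_efficiency <- function(net) {
  a <- adjacency_of(net)
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    sub <- a[nb, nb, drop = FALSE]
    D <- bfs_distances(sub)
    inv <- 1 / D
    diag(inv) <- 0
    out[i] <- sum(inv[is.finite(inv)]) / (k * (k - 1))
  }
  stats::setNames(out, rownames(a))
}

#' All four nodal metrics of one network
#'
#' @inheritParams node_degree
#' @return data.frame with columns `node`, `bc`, `c`, `le`, `nd`.
#' @export
nodal_metrics <- function(net) {
  a <- adjacency_of(net)
  data.frame(node = rownames(a) %||% paste0("CH", seq_len(nrow(a))),
             bc = unname(betweenness_centrality(net)),
             c = unname(clustering_coefficient(net)),
             le = unname(local_efficiency(net)),
             nd = unname(node_degree(net)),
             stringsAsFactors = FALSE)
}

#' Band x metric nodal feature table
#'
#' Computes the four nodal metrics on each banded network and assembles the
#' per-node feature matrix with columns named `{band}_{metric}` -- with the
#' default seven bands, 28 features per node. Labels, patient and state
#' metadata are carried from the networks.
#'
#' @param networks Named list of `ez_network` (one per band) sharing node
#'   labels, e.g. built by [network_features()].
#' @return data.frame: `patient_id`, `node`, `state`, `modality`,
#'   `ez_label`, then one column per band x metric.
#' @export
nodal_feature_table <- function(networks) {
  if (length(networks) == 0L) stopf("no networks supplied")
  labs <- lapply(networks, function(n) n$labels)
  if (length(unique(vapply(labs, paste, "", collapse = "\r"))) != 1L)
    stopf("networks must share identical node labels")
  first <- networks[[1]]
  meta <- data.frame(
    patient_id = first$patient_id %||% NA_character_,
    node = first$labels,
    state = first$state %||% NA_character_,
    modality = first$modality %||% NA_character_,
    ez_label = if (!is.null(first$ez_mask))
      ifelse(first$ez_mask, "EZ", "NEZ") else NA_character_,
    stringsAsFactors = FALSE
  )
  feats <- lapply(names(networks), function(b) {
    m <- nodal_metrics(networks[[b]])
    m <- m[, c("bc", "c", "le", "nd")]
    names(m) <- paste0(b, "_", names(m))
    m
  })
  cbind(meta, do.call(cbind, feats))
}

#' EZ/NEZ sub-network densities
#'
#' Partitions the network into the EZ and NEZ modules and reports the
#' internal density of each (observed / possible edges within the module)
#' and the interaction density bridging them (observed / `n_ez * n_nez`).
#' A module with fewer than two nodes has no defined internal density and
#' is reported as `NA` rather than zero.
#'
#' @param net An `ez_network`.
#' @param ez_mask Logical EZ indicator per node; defaults to the mask stored
#'   in the network.
#' @return A one-row data.frame: `d_ez`, `d_nez`, `d_cross`, the edge and
#'   pair counts behind each, plus band/state metadata.
#' @export
subnetwork_densities <- function(net, ez_mask = NULL) {
  a <- adjacency_of(net)
  ez_mask <- ez_mask %||% net$ez_mask
  if (is.null(ez_mask)) stopf("no EZ mask available")
  ez_mask <- as.logical(ez_mask)
  if (length(ez_mask) != nrow(a))
    stopf("ez_mask length %d != node count %d", length(ez_mask), nrow(a))
  n1 <- sum(ez_mask)
  n2 <- sum(!ez_mask)
  e_ez <- sum(a[ez_mask, ez_mask]) / 2
  e_nez <- sum(a[!ez_mask, !ez_mask]) / 2
  e_cross <- sum(a[ez_mask, !ez_mask])
  data.frame(
    patient_id = net$patient_id %||% NA_character_,
    band = net$band %||% NA_character_,
    state = net$state %||% NA_character_,
    d_ez = if (n1 >= 2) e_ez / choose(n1, 2) else NA_real_,
    d_nez = if (n2 >= 2) e_nez / choose(n2, 2) else NA_real_,
    d_cross = if (n1 >= 1 && n2 >= 1) e_cross / (n1 * n2) else NA_real_,
    e_ez = e_ez, e_nez = e_nez, e_cross = e_cross,
    n_ez = n1, n_nez = n2,
    stringsAsFactors = FALSE
  )
}
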