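# SKATER regionalization: the patch adjacency graph is reduced to a minimum
# spanning tree (Prim), which is then pruned greedily -- at each step the
# single edge removal (over all current trees) that minimizes the total
# intracluster square deviation is committed -- until the requested number of
# trees (superpixels) exists.

#' Minimum spanning tree of a patch graph
#'
#' Prim's algorithm per connected component, with a deterministic tie-break:
#' among candidate edges crossing the cut, the lowest
#' `(cost, min node id, max node id)` triple wins. Components are started at
#' their lowest unvisited node id, so the result is a forest when the graph
#' is disconnected. The returned edges carry ids `1..m` assigned in
#' `(from, to)` order; SKATER uses these ids to break ties.
#'
#' @param g a [build_patch_graph()] result.
#' @return a `patch_graph` whose `edges` form the MST forest (columns `from`,
#'   `to`, `cost`, `id`), plus `n_components`.
#' @export
minimum_spanning_tree <- function(g) {
  stopifnot(inherits(g, "patch_graph"))
  e <- g$edges
  n <- g$n
  if (n == 1L || nrow(e) == 0L) {
    out <- structure(list(n = n,
                          edges = cbind(e[0, ], id = integer(0)),
                          n_components = n),
                     class = c("patch_mst", "patch_graph"))
    return(out)
  }
  ord <- order(e$cost, e$from, e$to)
  ef <- e$from[ord]; et <- e$to[ord]; ec <- e$cost[ord]
  in_tree <- rep(FALSE, n)
  keep <- logical(length(ord))
  n_comp <- 0L
  visited <- 0L
  while (visited < n) {
    start <- which(!in_tree)[1L]
    in_tree[start] <- TRUE
    visited <- visited + 1L
    n_comp <- n_comp + 1L
    repeat {
      cross <- !keep & xor(in_tree[ef + 1L], in_tree[et + 1L])
      pick <- which.max(cross)          # first TRUE in (cost, from, to) order
      if (!cross[pick]) break
      keep[pick] <- TRUE
      in_tree[ef[pick] + 1L] <- TRUE
      in_tree[et[pick] + 1L] <- TRUE
      visited <- visited + 1L
    }
  }
  sel <- which(keep)
  edges <- data.frame(from = ef[sel], to = et[sel], cost = ec[sel])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  edges$id <- seq_len(nrow(edges))
  rownames(edges) <- NULL
  structure(list(n = n, edges = edges, n_components = n_comp),
            class = c("patch_mst", "patch_graph"))
}

# Tree bookkeeping for the greedy pruning. A tree is a set of 0-based node
# ids plus the rows of the MST edge table that join them. evaluate_tree()
# roots the tree at its lowest node, runs one preorder DFS, accumulates
# subtree aggregates, and scores every single-edge removal.
#
# SSD modes (per tree with member features x_j, weights w_j):
#   literal : (1/n) * sum_j ||x_j - mean(x)||^2, n = patch count, unweighted
#             mean -- the normalized form of the pruning objective.
#   weighted: sum_j w_j ||x_j - wmean(x)||^2 -- the classic within-cluster
#             sum of squares with pixel-count weights.
ssd_value <- function(S1, S2, W, n, weighted) {
  if (n <= 1L) return(0)
  ss <- S2 - sum(S1^2) / W
  if (weighted) max(ss, 0) else max(ss, 0) / n
}

evaluate_tree <- function(nodes, edges, features, weights, weighted) {
  m <- length(nodes)
  if (m == 1L)
    return(list(ssd = 0, best_total = Inf, best_edge = NA_integer_))
  loc <- integer(max(nodes) + 1L)
  loc[nodes + 1L] <- seq_len(m)
  x <- features[nodes + 1L, , drop = FALSE]
  w <- weights[nodes + 1L]
  ef <- loc[edges$from + 1L]; et <- loc[edges$to + 1L]
  adj <- vector("list", m)
  for (i in seq_along(ef)) {
    adj[[ef[i]]] <- c(adj[[ef[i]]], i)
    adj[[et[i]]] <- c(adj[[et[i]]], i)
  }
  root <- which.min(nodes)
  parent <- integer(m); parent_edge <- integer(m)
  order_ <- integer(m); pos <- integer(m)
  stack <- root; parent[root] <- 0L
  np <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    np <- np + 1L; order_[np] <- v; pos[v] <- np
    for (ei in adj[[v]]) {
      u <- if (ef[ei] == v) et[ei] else ef[ei]
      if (u == parent[v]) next
      parent[u] <- v; parent_edge[u] <- ei
      stack <- c(stack, u)
    }
  }
  # subtree aggregates by reverse preorder accumulation
  W_ <- w; S1 <- w * x; S2 <- w * rowSums(x^2); cnt <- rep(1L, m)
  for (i in m:2) {
    v <- order_[i]; p <- parent[v]
    W_[p] <- W_[p] + W_[v]
    S1[p, ] <- S1[p, ] + S1[v, ]
    S2[p] <- S2[p] + S2[v]
    cnt[p] <- cnt[p] + cnt[v]
  }
  tot_W <- W_[root]; tot_S1 <- S1[root, ]; tot_S2 <- S2[root]
  ssd_full <- ssd_value(tot_S1, tot_S2, tot_W, m, weighted)
  best_total <- Inf; best_edge <- NA_integer_; best_v <- NA_integer_
  for (i in 2:m) {
    v <- order_[i]
    tot <- ssd_value(S1[v, ], S2[v], W_[v], cnt[v], weighted) +
           ssd_value(tot_S1 - S1[v, ], tot_S2 - S2[v], tot_W - W_[v],
                     m - cnt[v], weighted)
    eid <- edges$id[parent_edge[v]]
    if (tot < best_total - 1e-12 ||
        (abs(tot - best_total) <= 1e-12 && !is.na(best_edge) &&
         eid < best_edge)) {
      best_total <- tot; best_edge <- eid; best_v <- v
    }
  }
  # nodes of the committed subtree: contiguous preorder block under best_v
  sub_nodes <- nodes[order_[pos[best_v]:(pos[best_v] + cnt[best_v] - 1L)]]
  list(ssd = ssd_full, best_total = best_total, best_edge = best_edge,
       sub_nodes = sub_nodes)
}

#' SKATER partition of a minimum spanning tree
#'
#' Greedy best-first pruning. Starting from the MST forest, until `k` trees
#' exist: for every current tree, every single-edge removal is scored by the
#' total intracluster square deviation of the two resulting subtrees; the one
#' removal (across all trees) minimizing the forest-wide total is committed,
#' ties broken by lowest edge id. Candidate evaluation is exhaustive per tree
#' via incremental subtree statistics, so each greedy step is exactly the
#' best available single split.
#'
#' @param tree a [minimum_spanning_tree()] result.
#' @param features `J x C` patch feature matrix ([patch_means()]).
#' @param k requested number of superpixels, between the number of forest
#'   components and J.
#' @param sizes per-patch pixel counts (used only when `weighted = TRUE`).
#' @param weighted `FALSE` (default) scores trees by the patch-count-
#'   normalized deviation around the unweighted patch mean; `TRUE` uses the
#'   classic pixel-count-weighted within-cluster sum of squares.
#' @return an object of class `skater_result`: `assignment` (length-J,
#'   0-based superpixel per patch, trees numbered by lowest member patch id),
#'   `k`, `ssd` (per-superpixel), `total_ssd`, `n_patches` (per-superpixel),
#'   `removed_edges` (ids, in removal order).
#' @export
skater_partition <- function(tree, features, k, sizes = NULL,
                             weighted = FALSE) {
  stopifnot(inherits(tree, "patch_graph"))
  J <- tree$n
  k <- as.integer(k)
  features <- as.matrix(features)
  stopifnot(nrow(features) == J)
  weights <- if (weighted) {
    stopifnot(!is.null(sizes), length(sizes) == J)
    as.numeric(sizes)
  } else rep(1, J)
  edges <- tree$edges
  # initial forest components
  comp <- rep(NA_integer_, J)
  if (nrow(edges)) {
    g <- igraph::graph_from_edgelist(cbind(edges$from, edges$to) + 1L,
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, J - igraph::gorder(g)))
    comp <- igraph::components(g)$membership
  } else comp <- seq_len(J)
  n0 <- max(comp)
  if (k < n0 || k > J)
    stop(sprintf("k must be between the number of components (%d) and the number of patches (%d)",
                 n0, J))
  trees <- vector("list", n0)
  for (tci in seq_len(n0)) {
    nodes <- which(comp == tci) - 1L
    sub <- edges[edges$from %in% nodes, , drop = FALSE]
    trees[[tci]] <- list(nodes = nodes, edges = sub)
    trees[[tci]]$eval <- evaluate_tree(nodes, sub, features, weights,
                                       weighted)
  }
  removed <- integer(0)
  while (length(trees) < k) {
    red <- vapply(trees, function(tr) tr$eval$best_total - tr$eval$ssd,
                  numeric(1))
    eid <- vapply(trees, function(tr)
      if (is.na(tr$eval$best_edge)) Inf else tr$eval$best_edge, numeric(1))
    if (all(!is.finite(red))) stop("no splittable tree left")
    best <- min(red)
    cand <- which(red <= best + 1e-12)
    pick <- cand[which.min(eid[cand])]
    tr <- trees[[pick]]
    removed <- c(removed, tr$eval$best_edge)
    sub_nodes <- tr$eval$sub_nodes
    rest_nodes <- setdiff(tr$nodes, sub_nodes)
    e <- tr$edges[tr$edges$id != tr$eval$best_edge, , drop = FALSE]
    e_sub <- e[e$from %in% sub_nodes, , drop = FALSE]
    e_rest <- e[e$from %in% rest_nodes, , drop = FALSE]
    t1 <- list(nodes = sub_nodes, edges = e_sub,
               eval = evaluate_tree(sub_nodes, e_sub, features, weights,
                                    weighted))
    t2 <- list(nodes = rest_nodes, edges = e_rest,
               eval = evaluate_tree(rest_nodes, e_rest, features, weights,
                                    weighted))
    trees[[pick]] <- t1
    trees[[length(trees) + 1L]] <- t2
  }
  # number superpixels by lowest member patch id
  mins <- vapply(trees, function(tr) min(tr$nodes), numeric(1))
  ord <- order(mins)
  assignment <- integer(J)
  ssd <- numeric(length(trees)); npat <- integer(length(trees))
  for (s in seq_along(ord)) {
    tr <- trees[[ord[s]]]
    assignment[tr$nodes + 1L] <- s - 1L
    ssd[s] <- tr$eval$ssd
    npat[s] <- length(tr$nodes)
  }
  structure(list(assignment = assignment, k = k, ssd = ssd,
                 total_ssd = sum(ssd), n_patches = npat,
                 removed_edges = removed),
            class = "skater_result")
}

#' @export
print.skater_result <- function(x, ...) {
  cat(sprintf("<skater_result> k=%d, total SSD=%.4g\n", x$k, x$total_ssd))
  invisible(x)
}
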