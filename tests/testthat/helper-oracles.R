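# Independent brute-force oracles. These deliberately share no code with the
# package implementation they check.

# MST total weight by Kruskal with union-find
oracle_kruskal_weight <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  total <- 0
  for (i in order(edges$cost)) {
    a <- find(edges$from[i] + 1L)
    b <- find(edges$to[i] + 1L)
    if (a != b) {
      parent[a] <- b
      total <- total + edges$cost[i]
    }
  }
  total
}

# connected-component labelling by explicit BFS flood fill
oracle_flood_fill <- function(lab, connectivity = 4L) {
  H <- nrow(lab); W <- ncol(lab)
  out <- matrix(-1L, H, W)
  deltas <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    deltas <- c(deltas, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  comp <- 0L
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (lab[r, cc] < 0L || out[r, cc] >= 0L) next
    queue <- list(c(r, cc))
    out[r, cc] <- comp
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in deltas) {
        rr <- p[1] + d[1]; c2 <- p[2] + d[2]
        if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= W &&
            out[rr, c2] < 0L && lab[rr, c2] == lab[p[1], p[2]]) {
          out[rr, c2] <- comp
          queue <- c(queue, list(c(rr, c2)))
        }
      }
    }
    comp <- comp + 1L
  }
  out
}

# are two labelings the same partition?
same_partition <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  all(tapply(b, a, function(x) length(unique(x))) == 1L) &&
    all(tapply(a, b, function(x) length(unique(x))) == 1L)
}

# adjusted Rand index by explicit pair counting
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(ifelse(sij == maxi, 1, 0))
  (sij - expected) / (maxi - expected)
}

# Savitzky-Golay by per-position local polynomial regression (lm)
oracle_sg <- function(y, window, order) {
  Tn <- length(y)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(Tn), function(t) {
    idx <- max(1L, t - h):min(Tn, t + h)
    deg <- min(order, length(idx) - 1L)
    x <- idx - t
    fit <- stats::lm(y[idx] ~ stats::poly(x, degree = deg, raw = TRUE))
    unname(stats::coef(fit)[1L])     # fitted value at x = 0
  }, numeric(1))
}

# literal SSD of a node set: patch-count-normalized squared deviation around
# the unweighted mean feature vector
oracle_ssd <- function(X) {
  if (nrow(X) <= 1L) return(0)
  ctr <- colMeans(X)
  sum(sweep(X, 2L, ctr)^2) / nrow(X)
}

# components of a forest given an edge subset (0-based nodes)
oracle_components <- function(nodes, edges) {
  comp <- as.list(nodes)
  find_comp <- function(v) which(vapply(comp, function(s) v %in% s,
                                        logical(1)))
  for (i in seq_len(nrow(edges))) {
    a <- find_comp(edges$from[i]); b <- find_comp(edges$to[i])
    if (a != b) {
      comp[[a]] <- c(comp[[a]], comp[[b]])
      comp[[b]] <- NULL
    }
  }
  comp
}

# fully exhaustive greedy SKATER: at each step enumerate every tree x edge,
# recompute both sides' SSD from scratch, commit the global best (ties to
# the lowest edge id); returns the final 0-based assignment
oracle_skater <- function(n, edges, X, k) {
  trees <- lapply(oracle_components(0:(n - 1L), edges), identity)
  tree_edges <- lapply(trees, function(nd)
    edges[edges$from %in% nd & edges$to %in% nd, , drop = FALSE])
  while (length(trees) < k) {
    best <- list(total = Inf, id = Inf)
    for (ti in seq_along(trees)) {
      e <- tree_edges[[ti]]
      if (!nrow(e)) next
      others <- sum(vapply(seq_along(trees)[-ti], function(tj)
        oracle_ssd(X[trees[[tj]] + 1L, , drop = FALSE]), numeric(1)))
      for (i in seq_len(nrow(e))) {
        parts <- oracle_components(trees[[ti]], e[-i, , drop = FALSE])
        tot <- others + sum(vapply(parts, function(nd)
          oracle_ssd(X[nd + 1L, , drop = FALSE]), numeric(1)))
        if (tot < best$total - 1e-12 ||
            (abs(tot - best$total) <= 1e-12 && e$id[i] < best$id)) {
          best <- list(total = tot, id = e$id[i], ti = ti, i = i)
        }
      }
    }
    stopifnot(is.finite(best$total))
    e <- tree_edges[[best$ti]]
    parts <- oracle_components(trees[[best$ti]], e[-best$i, , drop = FALSE])
    keep_e <- e[-best$i, , drop = FALSE]
    trees[[best$ti]] <- parts[[1]]
    tree_edges[[best$ti]] <- keep_e[keep_e$from %in% parts[[1]], ,
                                    drop = FALSE]
    trees[[length(trees) + 1L]] <- parts[[2]]
    tree_edges[[length(tree_edges) + 1L]] <-
      keep_e[keep_e$from %in% parts[[2]], , drop = FALSE]
  }
  assignment <- integer(n)
  for (s in seq_along(trees)) assignment[trees[[s]] + 1L] <- s - 1L
  assignment
}

# random spanning tree over n nodes shaped like a patch_mst: each node
# attaches to a random earlier node; edge ids follow (from, to) order
random_tree <- function(n, seed) {
  set.seed(seed)
  from <- integer(0); to <- integer(0)
  for (v in seq_len(n - 1L)) {
    u <- sample.int(v, 1L) - 1L
    from <- c(from, min(u, v)); to <- c(to, max(u, v))
  }
  e <- data.frame(from = from, to = to, cost = stats::runif(n - 1L))
  e <- e[order(e$from, e$to), , drop = FALSE]
  e$id <- seq_len(nrow(e))
  rownames(e) <- NULL
  structure(list(n = n, edges = e, n_components = 1L),
            class = c("patch_mst", "patch_graph"))
}

# random connected weighted graph (0-based nodes)
random_graph <- function(n, seed, p_extra = 0.4) {
  set.seed(seed)
  from <- integer(0); to <- integer(0)
  for (v in seq_len(n - 1L)) {
    u <- sample.int(v, 1L) - 1L
    from <- c(from, min(u, v)); to <- c(to, max(u, v))
  }
  all_pairs <- t(combn(0:(n - 1L), 2L))
  have <- paste(from, to)
  extra <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have) &
                       stats::runif(nrow(all_pairs)) < p_extra, ,
                     drop = FALSE]
  e <- data.frame(from = c(from, extra[, 1]), to = c(to, extra[, 2]))
  e$cost <- round(stats::runif(nrow(e)), 3)   # rounding provokes cost ties
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(n = n, edges = e), class = "patch_graph")
}
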