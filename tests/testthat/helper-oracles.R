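# Independent oracles used by the property tests. These deliberately use a
# different formulation than the package code paths they check.

# Exhaustive-permutation two-sided p for the two-sample rank test, computed
# from the Mann-Whitney U statistic (count of x>y pairs) over all labelings.
oracle_perm_p <- function(x, y) {
  v <- c(x, y)
  m <- length(x); n <- length(y)
  u_stat <- function(xi) {
    xs <- v[xi]; ys <- v[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(seq_len(m))
  mu <- m * n / 2
  splits <- utils::combn(m + n, m)
  us <- apply(splits, 2, u_stat)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Connected components of an undirected edge list by breadth-first search.
oracle_components <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    adj[[edges$a[k]]] <- c(adj[[edges$a[k]]], edges$b[k])
    adj[[edges$b[k]]] <- c(adj[[edges$b[k]]], edges$a[k])
  }
  seen <- character(0)
  comps <- list()
  for (v in nodes) {
    if (v %in% seen) next
    queue <- v; comp <- character(0)
    while (length(queue)) {
      w <- queue[1]; queue <- queue[-1]
      if (w %in% comp) next
      comp <- c(comp, w)
      queue <- c(queue, setdiff(adj[[w]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, character(1)))]
}

# Canonical form of a partition (list of member vectors) for comparison.
canonical_partition <- function(groups) {
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, min, character(1)))])
}

# Random disjoint-clique graph on <= max_n nodes with uniform edge weights.
random_clique_graph <- function(seed, max_n = 12L, weight = 90) {
  set.seed(seed)
  n <- sample(4:max_n, 1)
  nodes <- sprintf("n%02d", seq_len(n))
  sizes <- c()
  left <- n
  while (left > 0L) {
    s <- sample(seq_len(min(4L, left)), 1)
    sizes <- c(sizes, s)
    left <- left - s
  }
  member <- rep(seq_along(sizes), sizes)
  member <- sample(member)  # scatter clique membership over node ids
  edges <- list()
  for (cl in unique(member)) {
    ns <- nodes[member == cl]
    if (length(ns) >= 2L) {
      pairs <- utils::combn(ns, 2)
      edges[[length(edges) + 1L]] <- data.frame(
        a = pairs[1, ], b = pairs[2, ], percent_identity = weight,
        stringsAsFactors = FALSE)
    }
  }
  list(nodes = nodes,
       edges = if (length(edges)) do.call(rbind, edges)
       else data.frame(a = character(0), b = character(0),
                       percent_identity = numeric(0)))
}
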