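## Synthetic nesting trees built from parent tables.

## caterpillar: d terminal loops joining a running composite one at a time
caterpillar_tree <- function(d, areas = rep(1, d)) {
  n <- 2 * d - 1
  par <- rep(NA_integer_, n)
  par[1] <- d + 1; par[2] <- d + 1
  if (d > 2) {
    for (k in 2:(d - 1)) {
      par[k + 1] <- d + k       # next leaf joins
      par[d + k - 1] <- d + k   # previous composite joins
    }
  }
  as_nesting_tree(data.frame(
    id = 1:n, parent = par,
    area = c(areas, rep(NA, d - 1)),
    h = c(rep(NA, d), seq_len(d - 1))
  ))
}

## complete binary tree with 2^depth leaves
balanced_tree <- function(depth, leaf_area = 1) {
  nl <- 2^depth
  par <- rep(NA_integer_, 2 * nl - 1)
  lvl <- 1:nl
  nxt <- nl
  h <- 0
  hval <- rep(NA_real_, 2 * nl - 1)
  while (length(lvl) > 1) {
    h <- h + 1
    newlvl <- integer(0)
    for (k in seq(1, length(lvl), by = 2)) {
      nxt <- nxt + 1
      par[lvl[k]] <- nxt
      par[lvl[k + 1]] <- nxt
      hval[nxt] <- h
      newlvl <- c(newlvl, nxt)
    }
    lvl <- newlvl
  }
  as_nesting_tree(data.frame(
    id = seq_len(2 * nl - 1), parent = par,
    area = c(rep(leaf_area, nl), rep(NA, nl - 1)), h = hval
  ))
}

## random full binary tree over n leaves: merge two uniformly chosen roots
random_full_tree <- function(n_leaves, seed) {
  set.seed(seed)
  n <- 2 * n_leaves - 1
  par <- rep(NA_integer_, n)
  roots <- 1:n_leaves
  nxt <- n_leaves
  while (length(roots) > 1) {
    pick <- sample(length(roots), 2)
    nxt <- nxt + 1
    par[roots[pick]] <- nxt
    roots <- c(roots[-pick], nxt)
  }
  as_nesting_tree(data.frame(
    id = 1:n, parent = par,
    area = c(runif(n_leaves, 0.5, 2), rep(NA, n_leaves - 1)),
    h = c(rep(NA, n_leaves), seq_len(n_leaves - 1))
  ))
}

## naive metric recomputation straight from the definitions (per node,
## no shared bottom-up pass)
naive_subtree_asymmetry <- function(t, node) {
  nd <- t$nodes
  desc <- function(i) {
    if (is.na(nd$child1[i])) return(i)
    c(i, desc(nd$child1[i]), desc(nd$child2[i]))
  }
  leaves_below <- function(i) sum(is.na(nd$child1[desc(i)]))
  ids <- desc(node)
  ints <- ids[!is.na(nd$child1[ids])]
  qs <- vapply(ints, function(j) {
    r <- leaves_below(nd$child1[j])
    s <- leaves_below(nd$child2[j])
    if (r + s > 2) abs(r - s) / (r + s - 2) else 0
  }, numeric(1))
  mean(qs)
}

naive_strahler <- function(t, node = nrow(t$nodes)) {
  nd <- t$nodes
  rec <- function(i) {
    if (is.na(nd$child1[i])) return(1L)
    o1 <- rec(nd$child1[i]); o2 <- rec(nd$child2[i])
    if (o1 == o2) o1 + 1L else max(o1, o2)
  }
  vapply(seq_len(nrow(nd)), rec, integer(1))
}

naive_stream_counts <- function(t) {
  ord <- naive_strahler(t)
  nd <- t$nodes
  ## count maximal same-order paths by walking up from every node
  heads <- vapply(seq_len(nrow(nd)), function(i) {
    p <- nd$parent[i]
    is.na(p) || ord[p] != ord[i]
  }, logical(1))
  tab <- table(ord[heads])
  as.integer(tab[order(as.integer(names(tab)))])
}
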