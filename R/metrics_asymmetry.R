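#' Subtree degree
#'
#' The degree of a (sub)tree is the number of its leaf nodes (terminal
#' segments); a leaf has degree 1. Exterior and phantom leaves count.
#'
#' @param t A [nesting_tree].
#' @param node Node id (default: root).
#' @return Integer leaf count.
#' @export
subtree_degree <- function(t, node = NULL) {
  nd <- t$nodes
  if (is.null(node)) node <- nrow(nd)
  if (!node %in% nd$id) abort("node not in tree")
  nd$degree[node]
}

#' Partition asymmetry of a bifurcation
#'
#' For a bifurcation whose two subtrees have degrees `r` and `s`, the
#' partition asymmetry is `q = |r - s| / (r + s - 2)`, with `q = 0` for the
#' degenerate partition `(1, 1)`. Symmetric partitions give 0, a terminal
#' loop joining a large subtree gives 1. Vectorized and symmetric in
#' `(r, s)`.
#'
#' @param r,s Positive integer subtree degrees.
#' @return Asymmetry values in `[0, 1]`.
#' @examples
#' partition_asymmetry(4, 2)  # 0.5
#' @export
partition_asymmetry <- function(r, s) {
  if (any(r < 1) || any(s < 1)) abort("subtree degrees must be positive")
  q <- ifelse(r + s > 2, abs(r - s) / (r + s - 2), 0)
  as.numeric(q)
}

## per-node table of partition asymmetry q and subtree asymmetry A
## (uniform weights), computed bottom-up in one pass
node_asymmetries <- function(t) {
  nd <- t$nodes
  n <- nrow(nd)
  leaf <- is.na(nd$child1)
  q <- rep(NA_real_, n)
  sumq <- numeric(n)
  cnt <- integer(n)
  for (i in which(!leaf)) {
    c1 <- nd$child1[i]; c2 <- nd$child2[i]
    q[i] <- partition_asymmetry(nd$degree[c1], nd$degree[c2])
    sumq[i] <- q[i] + sumq[c1] + sumq[c2]
    cnt[i] <- 1L + cnt[c1] + cnt[c2]
  }
  tibble::tibble(
    id = nd$id, degree = nd$degree, exterior = nd$exterior,
    is_leaf = leaf, q = q,
    asymmetry = ifelse(cnt > 0, sumq / pmax(cnt, 1L), NA_real_)
  )
}

#' Subtree asymmetry
#'
#' The asymmetry `A(n)` of the subtree rooted at `node` is the weighted
#' average of the partition asymmetry over all bifurcating vertices of the
#' subtree, normalized by the total weight. The default weighting window
#' includes every node of the subtree with unit weight.
#'
#' @param t A [nesting_tree].
#' @param node Node id of an internal node (default: root).
#' @param weight_fn `NULL` for uniform weights (the default), or a function
#'   receiving the tibble of the subtree's internal nodes (columns `id`,
#'   `degree`, `q`) and returning one non-negative weight per row. Use
#'   `function(d) as.numeric(d$id == node)` style weights for no averaging.
#' @return Asymmetry in `[0, 1]`. A degree-1 node (a leaf) is an error.
#' @examples
#' t <- loop_decompose(assign_model_weights(triangular_lattice_hex(2),
#'                                          "gradient", seed = 1))
#' subtree_asymmetry(t)
#' @export
subtree_asymmetry <- function(t, node = NULL, weight_fn = NULL) {
  nd <- t$nodes
  if (is.null(node)) node <- nrow(nd)
  if (nd$degree[node] < 2) abort("asymmetry is undefined for a degree-1 node")
  if (is.null(weight_fn)) {
    return(node_asymmetries(t)$asymmetry[node])
  }
  ids <- subtree_ids(nd, node)
  qtab <- node_asymmetries(t)[ids, ]
  qtab <- qtab[!qtab$is_leaf, c("id", "degree", "q")]
  w <- weight_fn(qtab)
  if (length(w) != nrow(qtab) || any(w < 0)) abort("invalid partition weights")
  sum(w * qtab$q) / sum(w)
}

#' Averaged asymmetry at a given degree
#'
#' The averaged asymmetry `Lambda(d)` is the arithmetic mean of the subtree
#' asymmetry `A(n)` over all internal nodes whose degree lies within
#' `window` of `d` on the base-2 logarithmic axis.
#'
#' @param t A [nesting_tree].
#' @param d Target degree (may be fractional; the window is log2-based).
#' @param window Half-width of the averaging window in log2-degree units.
#' @param include_exterior Include subtrees containing exterior leaves
#'   (default `TRUE`: the asymmetry is a topological metric).
#' @return The mean asymmetry, or `NA` when no node falls in the window.
#' @export
averaged_asymmetry <- function(t, d, window = 0.5, include_exterior = TRUE) {
  na <- node_asymmetries(t)
  na <- na[!na$is_leaf, ]
  if (!include_exterior) na <- na[!na$exterior, ]
  sel <- abs(log2(na$degree) - log2(d)) <= window
  if (!any(sel)) return(NA_real_)
  mean(na$asymmetry[sel])
}

#' Asymmetry profile over degrees
#'
#' Evaluates the averaged asymmetry on a grid of degrees, together with the
#' underlying `(log2 degree, asymmetry)` scatter of all internal nodes (for
#' density plots).
#'
#' @inheritParams averaged_asymmetry
#' @param at Degrees at which to evaluate; default: `2^k` for integer and
#'   half-integer `k` spanning the tree's degrees.
#' @return A tibble with columns `d`, `log2_d`, `lambda` (mean asymmetry in
#'   the window) and `n_nodes`; the node scatter is attached as attribute
#'   `"scatter"`.
#' @export
asymmetry_profile <- function(t, at = NULL, window = 0.5,
                              include_exterior = TRUE) {
  na <- node_asymmetries(t)
  na <- na[!na$is_leaf, ]
  if (!include_exterior) na <- na[!na$exterior, ]
  if (is.null(at)) {
    lmax <- log2(max(na$degree))
    at <- 2^seq(1, lmax, by = 0.5)
  }
  ld <- log2(na$degree)
  out <- purrr::map_dfr(at, function(d) {
    sel <- abs(ld - log2(d)) <= window
    tibble::tibble(
      d = d, log2_d = log2(d),
      lambda = if (any(sel)) mean(na$asymmetry[sel]) else NA_real_,
      n_nodes = sum(sel)
    )
  })
  attr(out, "scatter") <- tibble::tibble(log2_d = ld, asymmetry = na$asymmetry)
  out
}
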