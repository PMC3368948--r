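#' Nesting trees
#'
#' A `nesting_tree` records the merge history of a hierarchical loop
#' decomposition as a full binary tree. Leaves are the original loops of the
#' graph (plus one exterior leaf, or several phantom boundary leaves);
#' every internal node is a merge event carrying the strength `h` of the
#' removed edge, the composite loop area, the subtree degree (number of
#' leaf descendants) and an exterior flag that propagates upward from
#' exterior leaves.
#'
#' The node table is kept in topological order: every child id is smaller
#' than its parent's id, leaves come first, and the last row is the root.
#'
#' @name nesting_tree
#' @rdname nesting_tree
NULL

new_nesting_tree <- function(nodes, mode = "single_exterior",
                             strength_rule = "min", seed = NA_integer_,
                             n_discarded = 0L) {
  ## children are an unordered pair; store them canonically
  c1 <- pmin(nodes$child1, nodes$child2)
  nodes$child2 <- pmax(nodes$child1, nodes$child2)
  nodes$child1 <- c1
  t <- structure(
    list(nodes = tibble::as_tibble(nodes), mode = mode,
         strength_rule = strength_rule, seed = seed,
         n_discarded = n_discarded),
    class = "nesting_tree"
  )
  validate_nesting_tree(t)
  t
}

#' Validate the structural invariants of a nesting tree
#'
#' Checks that the tree is full binary (internal nodes have exactly two
#' children), that ids are topologically ordered, that degrees add up, and
#' that every node's area is the sum of its children's (exterior leaves
#' carry area 0).
#'
#' @param t A `nesting_tree`.
#' @param tol Relative tolerance of the area conservation check.
#' @return `t`, invisibly.
#' @export
validate_nesting_tree <- function(t, tol = 1e-9) {
  nd <- t$nodes
  req <- c("id", "parent", "child1", "child2", "h", "area", "degree",
           "exterior", "face")
  if (!all(req %in% names(nd))) abort("missing nesting tree columns")
  if (!identical(nd$id, seq_len(nrow(nd)))) abort("ids must be 1..n in order")
  leaf <- is.na(nd$child1)
  if (any(is.na(nd$child2) != leaf)) abort("internal nodes need two children")
  if (sum(is.na(nd$parent)) != 1) abort("tree must have exactly one root")
  int <- which(!leaf)
  if (length(int)) {
    if (any(nd$child1[int] >= nd$id[int] | nd$child2[int] >= nd$id[int])) {
      abort("children must precede parents (topological id order)")
    }
    dsum <- nd$degree[nd$child1[int]] + nd$degree[nd$child2[int]]
    if (any(dsum != nd$degree[int])) abort("degree is not additive")
    asum <- nd$area[nd$child1[int]] + nd$area[nd$child2[int]]
    rel <- abs(asum - nd$area[int]) / pmax(nd$area[int], .Machine$double.eps)
    if (any(rel > tol)) abort("area is not conserved at a merge")
  }
  if (sum(leaf) != length(int) + 1L) abort("not a full binary tree")
  invisible(t)
}

#' @export
print.nesting_tree <- function(x, ...) {
  nd <- x$nodes
  leaf <- is.na(nd$child1)
  cat(sprintf("<nesting_tree> %d leaves (%d exterior), %d merges, mode = %s\n",
              sum(leaf), sum(leaf & nd$exterior), sum(!leaf), x$mode))
  h <- nd$h[!leaf]
  if (length(h)) {
    cat(sprintf("  strength rule = %s; h in [%.4g, %.4g]; total area = %.6g\n",
                x$strength_rule, min(h), max(h), nd$area[nrow(nd)]))
  }
  if (x$n_discarded > 0) {
    cat(sprintf("  %d disconnecting edge removal(s) discarded\n", x$n_discarded))
  }
  invisible(x)
}

#' Build a nesting tree from a node table
#'
#' Construct a [nesting_tree] from a data frame describing the tree by
#' parent pointers, e.g. when assembling synthetic trees or reading
#' serialized ones. Internal degrees and areas are (re)computed from the
#' leaves; nodes are renumbered into topological order if necessary.
#'
#' @param df A data frame with columns `id`, `parent` (`NA` for the root),
#'   and optionally `h` (merge strength, internal nodes), `area` (leaf
#'   areas), `exterior` (leaf flags) and `face` (leaf face ids).
#' @param mode,strength_rule,seed Provenance fields, stored as-is.
#' @return A [nesting_tree].
#' @examples
#' # a single bifurcation over two unit-area loops and an exterior leaf
#' df <- data.frame(id = 1:5, parent = c(4, 4, 5, 5, NA),
#'                  area = c(1, 1, 0, NA, NA),
#'                  exterior = c(FALSE, FALSE, TRUE, NA, NA),
#'                  h = c(NA, NA, NA, 1, 2))
#' as_nesting_tree(df)
#' @export
as_nesting_tree <- function(df, mode = "single_exterior",
                            strength_rule = "min", seed = NA_integer_) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("id", "parent") %in% names(df)))
  df <- df[order(df$id), ]
  n <- nrow(df)
  id <- df$id
  parent <- match(df$parent, id)            # as row indices
  is_leaf <- !(seq_len(n) %in% parent)
  ## ids that are already 1..n in topological order are kept verbatim, so
  ## serialization round trips preserve the merge-order numbering
  if (identical(as.integer(id), seq_len(n)) &&
      all(is.na(parent) | parent > seq_len(n))) {
    return(build_nesting_tree_ordered(df, parent, is_leaf, mode,
                                      strength_rule, seed))
  }
  ## topological renumbering: repeatedly emit nodes whose children are done
  order_out <- integer(n)
  emitted <- logical(n)
  k <- 0L
  for (i in which(is_leaf)) {
    k <- k + 1L
    order_out[k] <- i
    emitted[i] <- TRUE
  }
  nchild_done <- integer(n)
  queue <- which(is_leaf)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    p <- parent[i]
    if (is.na(p)) next
    nchild_done[p] <- nchild_done[p] + 1L
    if (nchild_done[p] == 2L && !emitted[p]) {
      k <- k + 1L
      order_out[k] <- p
      emitted[p] <- TRUE
      queue <- c(queue, p)
    }
  }
  if (k != n) abort("node table does not describe a binary tree")
  new_pos <- integer(n)
  new_pos[order_out] <- seq_len(n)

  h <- if ("h" %in% names(df)) df$h else rep(NA_real_, n)
  area <- if ("area" %in% names(df)) df$area else rep(1, n)
  exterior <- if ("exterior" %in% names(df)) df$exterior else rep(FALSE, n)
  face <- if ("face" %in% names(df)) df$face else ifelse(is_leaf, id, NA)
  exterior[is.na(exterior)] <- FALSE

  nd <- tibble::tibble(
    id = seq_len(n),
    parent = new_pos[parent[order_out]],
    child1 = NA_integer_, child2 = NA_integer_,
    h = as.numeric(h[order_out]),
    area = as.numeric(area[order_out]),
    degree = NA_integer_,
    exterior = as.logical(exterior[order_out]),
    face = as.integer(face[order_out])
  )
  nd$parent[is.na(df$parent)[order_out]] <- NA_integer_
  for (i in seq_len(n)) {
    p <- nd$parent[i]
    if (is.na(p)) next
    if (is.na(nd$child1[p])) nd$child1[p] <- i else nd$child2[p] <- i
  }
  leaf <- is.na(nd$child1)
  nd$degree[leaf] <- 1L
  nd$area[leaf & nd$exterior] <- 0
  nd$area[leaf & is.na(nd$area)] <- 1
  nd$face[!leaf] <- NA_integer_
  for (i in which(!leaf)) {
    nd$degree[i] <- nd$degree[nd$child1[i]] + nd$degree[nd$child2[i]]
    nd$area[i] <- nd$area[nd$child1[i]] + nd$area[nd$child2[i]]
    nd$exterior[i] <- nd$exterior[nd$child1[i]] || nd$exterior[nd$child2[i]]
  }
  new_nesting_tree(nd, mode = mode, strength_rule = strength_rule, seed = seed)
}

## assemble a nesting tree from rows already in topological id order
build_nesting_tree_ordered <- function(df, parent, is_leaf, mode,
                                       strength_rule, seed) {
  n <- nrow(df)
  grab <- function(col, default) {
    if (col %in% names(df)) df[[col]] else rep(default, length.out = n)
  }
  exterior <- grab("exterior", FALSE)
  exterior[is.na(exterior)] <- FALSE
  nd <- tibble::tibble(
    id = seq_len(n),
    parent = as.integer(parent),
    child1 = NA_integer_, child2 = NA_integer_,
    h = as.numeric(grab("h", NA_real_)),
    area = as.numeric(grab("area", 1)),
    degree = NA_integer_,
    exterior = as.logical(exterior),
    face = as.integer(grab("face", ifelse(is_leaf, df$id, NA)))
  )
  for (i in seq_len(n)) {
    p <- nd$parent[i]
    if (is.na(p)) next
    if (is.na(nd$child1[p])) nd$child1[p] <- i else nd$child2[p] <- i
  }
  leaf <- is.na(nd$child1)
  nd$degree[leaf] <- 1L
  nd$area[leaf & nd$exterior & is.na(nd$area)] <- 0
  nd$area[leaf & is.na(nd$area)] <- 1
  nd$face[!leaf] <- NA_integer_
  for (i in which(!leaf)) {
    nd$degree[i] <- nd$degree[nd$child1[i]] + nd$degree[nd$child2[i]]
    nd$area[i] <- nd$area[nd$child1[i]] + nd$area[nd$child2[i]]
    nd$exterior[i] <- nd$exterior[nd$child1[i]] || nd$exterior[nd$child2[i]]
  }
  new_nesting_tree(nd, mode = mode, strength_rule = strength_rule, seed = seed)
}

#' @describeIn nesting_tree Tidy the node table of a nesting tree.
#' @param x A `nesting_tree`.
#' @param ... Unused.
#' @method tidy nesting_tree
#' @export
tidy.nesting_tree <- function(x, ...) {
  nd <- x$nodes
  nd$is_leaf <- is.na(nd$child1)
  nd
}

#' @describeIn nesting_tree One-row summary: leaf/merge counts, strength
#'   range, root subtree asymmetry and Strahler bifurcation ratio.
#' @method glance nesting_tree
#' @export
glance.nesting_tree <- function(x, ...) {
  nd <- x$nodes
  leaf <- is.na(nd$child1)
  rb <- tryCatch(bifurcation_ratio(x), error = function(e) NULL)
  tibble::tibble(
    n_leaves = sum(leaf),
    n_exterior_leaves = sum(leaf & nd$exterior),
    n_merges = sum(!leaf),
    n_discarded = x$n_discarded,
    h_min = suppressWarnings(min(nd$h, na.rm = TRUE)),
    h_max = suppressWarnings(max(nd$h[is.finite(nd$h)], na.rm = TRUE)),
    total_area = nd$area[nrow(nd)],
    asymmetry = subtree_asymmetry(x),
    r_b = if (is.null(rb)) NA_real_ else rb$r_b,
    mode = x$mode,
    strength_rule = x$strength_rule,
    seed = x$seed
  )
}

## row indices of all nodes in the subtree rooted at `node`
subtree_ids <- function(nd, node) {
  sel <- logical(nrow(nd))
  stack <- node
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    sel[i] <- TRUE
    if (!is.na(nd$child1[i])) stack <- c(stack, nd$child1[i], nd$child2[i])
  }
  which(sel)
}
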