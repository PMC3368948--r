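#' Segment a graph into major sectors via its nesting tree
#'
#' High-level nodes of the nesting tree correspond to the major loops of
#' the graph; cutting the tree below them yields a natural segmentation of
#' the terminal faces into connected sectors.
#'
#' Two cut criteria are supported: `k` splits off the `k` disjoint subtrees
#' obtained by opening the `k - 1` highest (non-exterior-strength) merges
#' from the root down; `h_cutoff` takes the maximal subtrees whose root
#' merge strength is below the cutoff (leaves whose parent merge is above
#' the cutoff become singleton segments).
#'
#' @param t A [nesting_tree].
#' @param k Number of segments.
#' @param h_cutoff Strength cutoff (alternative to `k`).
#' @return A tibble mapping `face` (terminal face id) to `segment` (1-based
#'   segment index); exterior/phantom leaves are omitted.
#' @export
segment_tree <- function(t, k = NULL, h_cutoff = NULL) {
  nd <- t$nodes
  if (is.null(k) == is.null(h_cutoff)) {
    abort("supply exactly one of `k` or `h_cutoff`")
  }
  leaf <- is.na(nd$child1)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1 || k > sum(leaf)) abort("k out of range")
    if (k == 1) {
      roots <- nrow(nd)
    } else {
      ## scan strength cutoffs; at each, the segments are the maximal
      ## subtrees below the cutoff. Choose the cutoff whose k-th largest
      ## segment (by terminal face count) is largest -- the k major
      ## sectors -- and keep only those k subtrees. Late spurious merges
      ## (strong minor loops) then fall outside every segment.
      n_faces_below <- as.integer(leaf & !nd$exterior & !is.na(nd$face))
      for (i in which(!leaf)) {
        n_faces_below[i] <- n_faces_below[nd$child1[i]] +
          n_faces_below[nd$child2[i]]
      }
      cand <- sort(unique(nd$h[!leaf]))
      best <- NULL; best_score <- -1
      for (cut in cand) {
        below <- !leaf & nd$h < cut
        parent_below <- below[nd$parent]
        parent_below[is.na(parent_below)] <- FALSE
        root_seg <- (below | leaf) & !parent_below
        sizes <- sort(n_faces_below[root_seg], decreasing = TRUE)
        score <- if (length(sizes) >= k) sizes[k] else -1
        if (score >= best_score) {       # ties: prefer the larger cutoff
          best_score <- score
          best <- which(root_seg)
        }
      }
      roots <- best[order(-n_faces_below[best])][seq_len(k)]
    }
  } else {
    ## maximal subtrees whose root merge strength < cutoff: a node starts a
    ## segment when it is below the cutoff (or a leaf) while its parent is not
    below <- !leaf & nd$h < h_cutoff
    is_seg_root <- (below | leaf) & vapply(seq_len(nrow(nd)), function(i) {
      p <- nd$parent[i]
      is.na(p) || !below[p]
    }, logical(1))
    roots <- which(is_seg_root)
    if (!length(roots)) roots <- nrow(nd)
  }
  out <- purrr::map_dfr(seq_along(roots), function(s) {
    ids <- subtree_ids(nd, roots[s])
    keep <- ids[!is.na(nd$face[ids]) & !nd$exterior[ids]]
    tibble::tibble(face = nd$face[keep], segment = s)
  })
  out <- dplyr::arrange(out, .data$face)
  ## segments whose subtree contains an exterior/phantom leaf: their region
  ## touches the unbounded outside
  attr(out, "exterior_segments") <- which(nd$exterior[roots])
  out
}

#' Histogram of partition asymmetry with a suggested cleaning threshold
#'
#' Histograms the partition asymmetry `q` over the internal nodes of the
#' tree. In digitized natural networks, spurious strong minor loops produce
#' an excess of `q = 1` partitions; the location of the last interior local
#' minimum of the (moving-average smoothed) histogram below the `q = 1` end
#' is suggested as a natural data-cleaning cutoff.
#'
#' @param t A [nesting_tree].
#' @param bins Number of equal-width bins on `[0, 1]`.
#' @param smooth_window Moving-average window (bins) applied before the
#'   minimum search.
#' @return A list with `histogram` (tibble: `mid`, `count`, `smoothed`) and
#'   `threshold` (bin midpoint of the last interior local minimum, or `NA`
#'   when no robust minimum exists).
#' @export
q_histogram <- function(t, bins = 20, smooth_window = 3) {
  q <- node_asymmetries(t)
  q <- q$q[!q$is_leaf]
  br <- seq(0, 1, length.out = bins + 1)
  cnt <- tabulate(pmin(findInterval(q, br, rightmost.closed = TRUE), bins),
                  nbins = bins)
  sm <- stats::filter(cnt, rep(1 / smooth_window, smooth_window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- cnt[is.na(sm)]
  mid <- (br[-1] + br[-length(br)]) / 2
  ## interior local minima of the smoothed histogram; a minimum is robust
  ## only if its valley is well below the flanking maxima (depth < 1/2)
  lmin <- which(diff(sign(diff(sm))) > 0) + 1
  lmin <- lmin[lmin > 1 & lmin < bins]
  robust <- vapply(lmin, function(i) {
    flank <- min(max(sm[1:(i - 1)]), max(sm[(i + 1):bins]))
    flank > 0 && sm[i] < 0.5 * flank
  }, logical(1))
  lmin <- lmin[robust]
  threshold <- if (length(lmin)) mid[max(lmin)] else NA_real_
  list(histogram = tibble::tibble(mid = mid, count = cnt, smoothed = sm),
       threshold = threshold)
}

#' Clean a nesting tree of high-asymmetry partitions
#'
#' Spurious data (e.g. non-uniform staining of a leaf specimen) shows up as
#' strong minor loops that join the hierarchy through extremely asymmetric
#' partitions. Cleaning marks every internal node with partition asymmetry
#' `q` above the threshold and removes the smaller-degree child subtree of
#' each marked node, then contracts the marked node onto its surviving
#' child and recomputes degrees and areas.
#'
#' @param t A [nesting_tree].
#' @param q_threshold Partitions with `q` strictly above this are removed
#'   (default 0.97).
#' @return A list with `tree` (the cleaned [nesting_tree]) and
#'   `removed_faces` (terminal face ids of the removed subtrees).
#' @export
clean_tree <- function(t, q_threshold = 0.97) {
  if (q_threshold <= 0 || q_threshold > 1) abort("q_threshold must be in (0, 1]")
  nd <- t$nodes
  na <- node_asymmetries(t)
  marked <- which(!na$is_leaf & na$q > q_threshold)
  if (!length(marked)) return(list(tree = t, removed_faces = integer(0)))

  drop <- logical(nrow(nd))     # nodes whose whole subtree is removed
  contract <- logical(nrow(nd)) # marked nodes replaced by surviving child
  ## process from the root down so nested marks inside removed subtrees
  ## are irrelevant
  for (i in rev(marked)) {
    if (drop[i]) next
    c1 <- nd$child1[i]; c2 <- nd$child2[i]
    ## remove the smaller-degree child (ties: smaller area, then lower id);
    ## never remove the child carrying all exterior leaves of the pair if
    ## that would orphan the exterior -- the minor chain is the target
    minor <- if (nd$degree[c1] < nd$degree[c2]) c1
    else if (nd$degree[c2] < nd$degree[c1]) c2
    else if (nd$area[c1] != nd$area[c2]) c(c1, c2)[which.min(nd$area[c(c1, c2)])]
    else min(c1, c2)
    drop[subtree_ids(nd, minor)] <- TRUE
    contract[i] <- TRUE
  }
  keep_leaves <- which(is.na(nd$child1) & !drop)
  if (!length(keep_leaves)) abort("cleaning would empty the tree")

  ## rebuild parent pointers skipping contracted nodes
  new_parent <- function(i) {
    p <- nd$parent[i]
    while (!is.na(p) && (contract[p] || drop[p])) p <- nd$parent[p]
    p
  }
  keep <- !drop & !contract
  ## a contracted root: its surviving child becomes the root
  df <- tibble::tibble(
    id = nd$id[keep],
    parent = vapply(nd$id[keep], new_parent, numeric(1)),
    h = nd$h[keep],
    area = ifelse(is.na(nd$child1[keep]), nd$area[keep], NA_real_),
    exterior = ifelse(is.na(nd$child1[keep]), nd$exterior[keep], NA),
    face = nd$face[keep]
  )
  removed <- nd$face[drop & !is.na(nd$face)]
  cleaned <- as_nesting_tree(df, mode = t$mode,
                             strength_rule = t$strength_rule, seed = t$seed)
  list(tree = cleaned, removed_faces = sort(removed))
}
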