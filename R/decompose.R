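#' Reassign weights of disconnecting (bridge) links
#'
#' A bridge is a link whose removal disconnects the graph; during the
#' decomposition its deletion would split a loop from the rest instead of
#' merging two loops. Such events are avoided up-front by raising every
#' bridge weight just above the maximum link weight of the loopy component
#' it would disconnect, so the component is fully merged before the bridge
#' could be removed (it is then pruned as a dangling edge instead).
#'
#' @param g A pruned [planar_graph()].
#' @return The graph with bridge weights reassigned; bridge-free graphs are
#'   returned unchanged.
#' @export
reassign_bridge_weights <- function(g) {
  gi <- as_igraph(g)
  br <- igraph::bridges(gi)
  if (!length(br)) return(g)
  ends <- igraph::ends(gi, br, names = TRUE)
  li <- g$links
  key <- paste(pmin(li$from, li$to), pmax(li$from, li$to))
  brow <- match(paste(pmin(as.integer(ends[, 1]), as.integer(ends[, 2])),
                      pmax(as.integer(ends[, 1]), as.integer(ends[, 2]))), key)
  ## component maxima are computed over non-bridge links only
  gi_nb <- igraph::delete_edges(gi, br)
  comp <- igraph::components(gi_nb)$membership
  wmax <- tapply(
    c(li$weight[-brow], li$weight[-brow]),
    comp[as.character(c(li$from[-brow], li$to[-brow]))],
    max
  )
  for (k in seq_along(brow)) {
    c1 <- comp[as.character(li$from[brow[k]])]
    c2 <- comp[as.character(li$to[brow[k]])]
    m1 <- if (as.character(c1) %in% names(wmax)) wmax[[as.character(c1)]] else -Inf
    m2 <- if (as.character(c2) %in% names(wmax)) wmax[[as.character(c2)]] else -Inf
    ## the side that finishes merging first sets the bridge's removal time
    m <- min(m1, m2)
    if (!is.finite(m)) m <- max(m1, m2)
    g$links$weight[brow[k]] <- m * (1 + 1e-9)
  }
  g
}

#' Surround the graph with phantom boundary loops
#'
#' Fragments the exterior region into one phantom loop per perimeter
#' junction, preserving neighbourhood information for loops that would
#' otherwise all merge into a single undifferentiated exterior. An enclosing
#' polygon (the outer boundary scaled about its centroid) is added, plus one
#' connector link per perimeter junction vertex; all added links carry
#' infinite weight, so they are never removed during the decomposition.
#'
#' @param g A pruned, connected [planar_graph()] with a simple perimeter.
#' @param scale Scale factor of the enclosing polygon about the perimeter
#'   centroid.
#' @return The augmented graph. Vertices and links added here have `phantom
#'   = TRUE`; calling the function twice is an error.
#' @export
add_phantom_boundary <- function(g, scale = 1.2) {
  if (any(is.infinite(g$links$weight))) {
    abort("graph already has a phantom boundary")
  }
  fs <- face_structure(g)
  cyc <- fs$cycle[[fs$outer]]            # vertex indices, outer face walk
  deg <- vertex_degrees(g)
  on_perim <- unique(cyc)
  if (length(on_perim) != length(cyc)) abort("perimeter is not a simple cycle")
  is_junc <- deg[as.character(g$nodes$id[cyc])] >= 3
  if (!any(is_junc)) is_junc[] <- TRUE   # degenerate: a bare cycle
  ## the enclosing polygon follows the whole perimeter; connectors attach
  ## only at the junction vertices, defining one phantom loop per junction
  p <- g$nodes[cyc, ]
  cx <- mean(p$x); cy <- mean(p$y)
  new_id <- max(g$nodes$id) + seq_along(cyc)
  ring <- tibble::tibble(
    id = new_id,
    x = cx + scale * (p$x - cx),
    y = cy + scale * (p$y - cy),
    phantom = TRUE
  )
  nseg <- length(cyc)
  connectors <- tibble::tibble(from = p$id[is_junc], to = new_id[is_junc],
                               weight = Inf, phantom = TRUE)
  ring_links <- tibble::tibble(from = new_id,
                               to = new_id[c(2:nseg, 1)],
                               weight = Inf, phantom = TRUE)
  if (!"phantom" %in% names(g$nodes)) g$nodes$phantom <- FALSE
  if (!"phantom" %in% names(g$links)) g$links$phantom <- FALSE
  g$nodes <- dplyr::bind_rows(g$nodes, ring)
  g$links <- dplyr::bind_rows(g$links, connectors, ring_links)
  g
}

#' Hierarchically decompose a loopy planar graph into a nesting tree
#'
#' The core algorithm: after pruning tree-like components, reassigning
#' bridge weights and (optionally) adding phantom boundary loops, links are
#' collapsed into edge chains and the globally weakest chain is removed
#' iteratively. Each removal that separates two distinct loops merges them
#' into a new node of a full binary *nesting tree* whose height is the
#' strength of the removed edge; chains meeting at a junction whose degree
#' drops to 2 are re-collapsed and their strength re-aggregated. The
#' procedure runs until a single loop remains.
#'
#' @param g A connected [planar_graph()] with at least one cycle.
#' @param mode `"single_exterior"`: the unbounded region is one zero-area
#'   exterior leaf. `"phantom_boundary"`: the exterior is fragmented into
#'   one phantom loop per perimeter junction (see [add_phantom_boundary()]).
#' @param strength_rule Chain strength aggregation: `"min"` (weakest link,
#'   default), `"median"`, `"max"`.
#' @param seed Integer seed for the deterministic tie-breaking perturbation.
#' @param phantom_scale Scale of the enclosing phantom polygon.
#' @return A [nesting_tree] object.
#' @examples
#' g <- assign_model_weights(triangular_lattice_hex(2), "gradient", seed = 1)
#' t <- loop_decompose(g)
#' t
#' @export
loop_decompose <- function(g,
                           mode = c("single_exterior", "phantom_boundary"),
                           strength_rule = c("min", "median", "max"),
                           seed = 1L,
                           phantom_scale = 1.2) {
  mode <- match.arg(mode)
  strength_rule <- match.arg(strength_rule)
  if (!graph_is_connected(g)) abort("graph must be connected")
  g <- prune_tree_components(g)
  g <- perturb_weights(g, seed = seed)
  g <- reassign_bridge_weights(g)
  if (mode == "phantom_boundary") g <- add_phantom_boundary(g, phantom_scale)

  fs <- face_structure(g)
  ch <- walk_chains(g, rule = strength_rule)
  nch <- nrow(ch)
  m <- fs$m

  ## sides of each chain: the two faces bordering its first member link
  first_link <- vapply(ch$links, `[`, integer(1), 1)
  cf1 <- fs$dart_face[first_link]
  cf2 <- fs$dart_face[m + first_link]

  n_faces <- fs$n_faces
  outer <- fs$outer
  area <- abs(fs$signed_area)

  ## identify phantom faces (phantom mode): faces bordered by any phantom link
  is_phantom_face <- logical(n_faces)
  if (mode == "phantom_boundary") {
    ph_links <- which(g$links$phantom)
    ph_faces <- unique(fs$dart_face[c(ph_links, m + ph_links)])
    is_phantom_face[setdiff(ph_faces, outer)] <- TRUE
  }

  ## leaves of the nesting tree: internal faces, then exterior leaves
  internal <- setdiff(which(!is_phantom_face), outer)
  exterior_leaves <- if (mode == "single_exterior") outer else
    which(is_phantom_face)
  leaf_faces <- c(internal, exterior_leaves)
  n_leaf <- length(leaf_faces)
  if (length(internal) < 1) abort("empty loop set after pruning")

  n_nodes_max <- 2L * n_leaf - 1L
  nd_parent <- rep(NA_integer_, n_nodes_max)
  nd_child1 <- rep(NA_integer_, n_nodes_max)
  nd_child2 <- rep(NA_integer_, n_nodes_max)
  nd_h <- rep(NA_real_, n_nodes_max)
  nd_area <- numeric(n_nodes_max)
  nd_degree <- integer(n_nodes_max)
  nd_ext <- logical(n_nodes_max)
  nd_face <- rep(NA_integer_, n_nodes_max)

  nd_area[seq_len(n_leaf)] <- ifelse(leaf_faces %in% internal,
                                     area[leaf_faces], 0)
  nd_degree[seq_len(n_leaf)] <- 1L
  nd_ext[seq_len(n_leaf)] <- leaf_faces %in% exterior_leaves
  nd_face[seq_len(n_leaf)] <- leaf_faces

  ## union-find over faces; loopnode maps a face root to its tree node
  uf <- seq_len(n_faces)
  uf_find <- function(i) {
    while (uf[i] != i) {
      uf[i] <<- uf[uf[i]]
      i <- uf[i]
    }
    i
  }
  loopnode <- integer(n_faces)
  loopnode[leaf_faces] <- seq_len(n_leaf)
  ## in phantom mode the true outer face never participates
  if (mode == "phantom_boundary") loopnode[outer] <- NA_integer_

  ## chain state (parallel vectors; list-column of weights)
  cs <- ch$strength
  alive <- rep(TRUE, nch)
  cv1 <- match(ch$v1, g$nodes$id)
  cv2 <- match(ch$v2, g$nodes$id)
  cw <- ch$weights

  inc <- vector("list", nrow(g$nodes))
  for (cc in seq_len(nch)) {
    inc[[cv1[cc]]] <- c(inc[[cv1[cc]]], cc)
    inc[[cv2[cc]]] <- c(inc[[cv2[cc]]], cc)
  }

  kill_chain <- function(cc) {
    alive[cc] <<- FALSE
    inc[[cv1[cc]]] <<- drop_once(inc[[cv1[cc]]], cc)
    inc[[cv2[cc]]] <<- drop_once(inc[[cv2[cc]]], cc)
  }

  ## re-collapse chains around a vertex whose degree dropped to 2, prune
  ## dangling chains at degree-1 vertices
  cleanup <- function(v) {
    repeat {
      ii <- inc[[v]]
      if (length(ii) == 2L && ii[1] != ii[2]) {
        a <- ii[1]; b <- ii[2]
        ua <- if (cv1[a] == v) cv2[a] else cv1[a]
        ub <- if (cv1[b] == v) cv2[b] else cv1[b]
        cw[[a]] <<- c(cw[[a]], cw[[b]])
        cs[a] <<- chain_strength(cw[[a]], strength_rule)
        cv1[a] <<- ua
        cv2[a] <<- ub
        alive[b] <<- FALSE
        inc[[ub]] <<- c(drop_once(inc[[ub]], b), a)
        inc[[v]] <<- integer(0)
        ## sides: keep a's (they border the same pair of loops as b's)
        v <- NULL
        return(invisible())
      } else if (length(ii) == 1L) {
        a <- ii[1]
        u <- if (cv1[a] == v) cv2[a] else cv1[a]
        alive[a] <<- FALSE
        inc[[v]] <<- integer(0)
        inc[[u]] <<- drop_once(inc[[u]], a)
        v <- u
      } else {
        return(invisible())
      }
    }
  }

  next_node <- n_leaf
  merges <- 0L
  discards <- 0L
  h_seq <- numeric(0)

  repeat {
    s <- ifelse(alive & is.finite(cs), cs, Inf)
    cc <- which.min(s)
    if (!length(cc) || s[cc] == Inf) break
    f1 <- uf_find(cf1[cc])
    f2 <- uf_find(cf2[cc])
    l1 <- loopnode[f1]
    l2 <- loopnode[f2]
    va <- cv1[cc]; vb <- cv2[cc]
    kill_chain(cc)
    if (f1 != f2 && !is.na(l1) && !is.na(l2)) {
      next_node <- next_node + 1L
      nd_child1[next_node] <- l1
      nd_child2[next_node] <- l2
      nd_parent[l1] <- next_node
      nd_parent[l2] <- next_node
      nd_h[next_node] <- cs[cc]
      nd_area[next_node] <- nd_area[l1] + nd_area[l2]
      nd_degree[next_node] <- nd_degree[l1] + nd_degree[l2]
      nd_ext[next_node] <- nd_ext[l1] || nd_ext[l2]
      uf[f1] <- f2
      loopnode[f2] <- next_node
      merges <- merges + 1L
      h_seq <- c(h_seq, cs[cc])
    } else {
      ## the chain bordered the same loop on both sides: its removal would
      ## disconnect the graph; the event is discarded (no merge)
      discards <- discards + 1L
    }
    cleanup(va)
    if (vb != va) cleanup(vb)
  }

  if (merges != n_leaf - 1L) {
    abort(sprintf("decomposition ended with %d merges for %d leaves",
                  merges, n_leaf))
  }

  nodes <- tibble::tibble(
    id = seq_len(next_node),
    parent = nd_parent[seq_len(next_node)],
    child1 = nd_child1[seq_len(next_node)],
    child2 = nd_child2[seq_len(next_node)],
    h = nd_h[seq_len(next_node)],
    area = nd_area[seq_len(next_node)],
    degree = nd_degree[seq_len(next_node)],
    exterior = nd_ext[seq_len(next_node)],
    face = nd_face[seq_len(next_node)]
  )
  new_nesting_tree(nodes, mode = mode, strength_rule = strength_rule,
                   seed = seed, n_discarded = discards)
}

drop_once <- function(x, v) {
  i <- match(v, x)
  if (is.na(i)) x else x[-i]
}
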