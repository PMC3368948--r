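## Aggregate a chain's member link weights into its edge strength.
chain_strength <- function(weights, rule = c("min", "median", "max")) {
  rule <- match.arg(rule)
  switch(rule, min = min(weights), median = median(weights), max = max(weights))
}

#' Collapse links into maximal edge chains
#'
#' An *edge* of the decomposition is a maximal chain of links whose interior
#' vertices have degree exactly 2. Each chain carries an aggregate strength:
#' by default the weight of its weakest link (alternatives: median, max).
#'
#' @param g A pruned [planar_graph()].
#' @param rule Strength aggregation rule: `"min"` (default), `"median"`, `"max"`.
#' @return A tibble with one row per chain: endpoint vertex ids `v1`, `v2`,
#'   `n_links`, `strength`, `closed` (a cycle all of whose vertices have
#'   degree 2, anchored at one vertex), and list-columns `links` (row indices
#'   into `g$links`) and `weights`.
#' @examples
#' g <- planar_graph(
#'   nodes = data.frame(id = 1:3, x = c(0, 1, 2), y = c(0, 1, 0)),
#'   links = data.frame(from = c(1, 2), to = c(2, 3), weight = c(3, 5))
#' )
#' # not pruned (it is a path), but chain walking itself:
#' loopnest:::walk_chains(g, rule = "min")
#' @export
collapse_chains <- function(g, rule = c("min", "median", "max")) {
  rule <- match.arg(rule)
  walk_chains(g, rule)
}

walk_chains <- function(g, rule = "min") {
  li <- g$links
  m <- nrow(li)
  ids <- g$nodes$id
  from_i <- match(li$from, ids)
  to_i <- match(li$to, ids)
  ## adjacency: for each vertex, incident link rows
  adj <- vector("list", length(ids))
  for (l in seq_len(m)) {
    adj[[from_i[l]]] <- c(adj[[from_i[l]]], l)
    adj[[to_i[l]]] <- c(adj[[to_i[l]]], l)
  }
  deg <- lengths(adj)
  visited <- logical(m)
  res_v1 <- integer(0); res_v2 <- integer(0); res_links <- list()
  res_closed <- logical(0)

  walk_from <- function(v, l) {
    ## walk from junction vertex v through link l to the next junction
    chain <- l
    prev <- v
    cur <- if (from_i[l] == v) to_i[l] else from_i[l]
    while (deg[cur] == 2 && cur != v) {
      ls <- adj[[cur]]
      l <- if (ls[1] == chain[length(chain)]) ls[2] else ls[1]
      chain <- c(chain, l)
      nxt <- if (from_i[l] == cur) to_i[l] else from_i[l]
      prev <- cur
      cur <- nxt
    }
    list(links = chain, end = cur)
  }

  junctions <- which(deg != 2)
  for (v in junctions) {
    for (l in adj[[v]]) {
      if (visited[l]) next
      w <- walk_from(v, l)
      ## a chain between junctions may be traversed from both ends; claim it once
      visited[w$links] <- TRUE
      res_v1 <- c(res_v1, v)
      res_v2 <- c(res_v2, w$end)
      res_links[[length(res_links) + 1]] <- w$links
      res_closed <- c(res_closed, FALSE)
    }
  }
  ## leftover links form closed all-degree-2 cycles; anchor each at its
  ## lowest-index vertex and flag it degenerate (one loop around one face)
  for (l0 in seq_len(m)) {
    if (m == 0 || visited[l0]) next
    anchor <- min(from_i[l0], to_i[l0])
    w <- walk_from(anchor, l0)
    visited[w$links] <- TRUE
    res_v1 <- c(res_v1, anchor)
    res_v2 <- c(res_v2, anchor)
    res_links[[length(res_links) + 1]] <- w$links
    res_closed <- c(res_closed, TRUE)
  }
  weights <- lapply(res_links, function(ls) li$weight[ls])
  tibble::tibble(
    chain = seq_along(res_v1),
    v1 = ids[res_v1],
    v2 = ids[res_v2],
    n_links = lengths(res_links),
    strength = vapply(weights, chain_strength, numeric(1), rule = rule),
    closed = res_closed,
    links = res_links,
    weights = weights
  )
}
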