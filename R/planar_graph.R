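#' Construct an embedded weighted planar graph
#'
#' A `planar_graph` is the substrate of the hierarchical loop decomposition:
#' vertices with 2-D coordinates and links (the elementary graph elements)
#' with strictly positive weights, interpreted as vessel or vein widths.
#'
#' @param nodes A data frame with columns `id` (unique integer), `x`, `y`
#'   (planar coordinates, arbitrary length units).
#' @param links A data frame with columns `from`, `to` (vertex ids) and
#'   `weight` (positive width). Multi-links and self-loops are rejected.
#' @param validate_embedding If `TRUE`, check that no two links cross except
#'   at shared endpoints (quadratic in the number of links).
#'
#' @return An object of class `planar_graph`: a list with tibbles `nodes` and
#'   `links`.
#' @examples
#' g <- planar_graph(
#'   nodes = data.frame(id = 1:3, x = c(0, 1, 0.5), y = c(0, 0, 1)),
#'   links = data.frame(from = c(1, 2, 3), to = c(2, 3, 1), weight = c(1, 2, 3))
#' )
#' g
#' @export
planar_graph <- function(nodes, links, validate_embedding = FALSE) {
  nodes <- tibble::as_tibble(nodes)
  links <- tibble::as_tibble(links)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("from", "to", "weight") %in% names(links)))
  nodes$id <- as.integer(nodes$id)
  links$from <- as.integer(links$from)
  links$to <- as.integer(links$to)
  links$weight <- as.numeric(links$weight)
  if (anyDuplicated(nodes$id)) abort("duplicate vertex ids")
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y))) {
    abort("missing or non-finite vertex coordinates")
  }
  if (nrow(links)) {
    if (any(links$from == links$to)) abort("self-loops are not allowed")
    if (!all(links$from %in% nodes$id) || !all(links$to %in% nodes$id)) {
      abort("link endpoint not among vertex ids")
    }
    key <- paste(pmin(links$from, links$to), pmax(links$from, links$to))
    if (anyDuplicated(key)) abort("duplicate links between the same vertex pair")
    bad <- !is.finite(links$weight) & !is.infinite(links$weight)
    if (any(bad) || any(links$weight <= 0)) {
      abort("link weights must be strictly positive")
    }
  }
  g <- structure(list(nodes = nodes, links = links), class = "planar_graph")
  if (validate_embedding) validate_embedding(g)
  g
}

#' @export
print.planar_graph <- function(x, ...) {
  cat(sprintf("<planar_graph> %d vertices, %d links\n",
              nrow(x$nodes), nrow(x$links)))
  if (nrow(x$links)) {
    w <- x$links$weight[is.finite(x$links$weight)]
    if (length(w)) {
      cat(sprintf("  weights: [%.4g, %.4g]", min(w), max(w)))
    }
    if (any(is.infinite(x$links$weight))) cat("  (+ phantom links)")
    cat("\n")
  }
  invisible(x)
}

## degree of every vertex, named by id
vertex_degrees <- function(g) {
  ids <- g$nodes$id
  d <- tabulate(match(c(g$links$from, g$links$to), ids), nbins = length(ids))
  setNames(d, ids)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g$links[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = data.frame(name = g$nodes$id)
  )
}

graph_is_connected <- function(g) {
  if (nrow(g$nodes) <= 1) return(TRUE)
  igraph::is_connected(as_igraph(g))
}

#' Check that the straight-line embedding is non-crossing
#'
#' Errors with `"not a planar embedding"` if any two links intersect away
#' from shared endpoints.
#'
#' @param g A [planar_graph()].
#' @return `g`, invisibly.
#' @export
validate_embedding <- function(g) {
  li <- g$links
  n <- nrow(li)
  if (n < 2) return(invisible(g))
  xy <- g$nodes[match(c(li$from, li$to), g$nodes$id), c("x", "y")]
  x1 <- xy$x[1:n]; y1 <- xy$y[1:n]
  x2 <- xy$x[(n + 1):(2 * n)]; y2 <- xy$y[(n + 1):(2 * n)]
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    ## segments sharing an endpoint are allowed
    shared <- li$from[i] == li$from[j] | li$from[i] == li$to[j] |
      li$to[i] == li$from[j] | li$to[i] == li$to[j]
    d1 <- cross2(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
    d2 <- cross2(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
    d3 <- cross2(x1[j], y1[j], x2[j], y2[j], x1[i], y1[i])
    d4 <- cross2(x1[j], y1[j], x2[j], y2[j], x2[i], y2[i])
    crossing <- !shared & (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(crossing)) abort("not a planar embedding")
  }
  invisible(g)
}

#' Break weight ties by deterministic infinitesimal perturbation
#'
#' The decomposition requires a strict ordering of edge weights. Equal
#' weights are separated by seed-controlled perturbations of magnitude at
#' most `rel` times the smallest finite weight, leaving the ordering of
#' already-distinct weights untouched.
#'
#' @param g A [planar_graph()].
#' @param seed Integer seed controlling the perturbation.
#' @param rel Relative perturbation magnitude.
#' @return The graph with pairwise-distinct finite link weights.
#' @export
perturb_weights <- function(g, seed = 1L, rel = 1e-9) {
  w <- g$links$weight
  fin <- is.finite(w)
  if (!any(fin) || !anyDuplicated(w[fin])) return(g)
  eps <- rel * min(w[fin])
  u <- with_local_seed(seed, runif(sum(fin), min = 0, max = 1))
  ## rank-preserving: identical weights get distinct offsets < eps
  w[fin] <- w[fin] + u * eps
  if (anyDuplicated(w[fin])) {
    ## astronomically unlikely; nudge by rank
    w[fin] <- w[fin] + rank(w[fin], ties.method = "first") * eps * 1e-3
  }
  g$links$weight <- w
  g
}

## evaluate expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Prune tree-like components
#'
#' Iteratively removes degree-1 vertices and their links until every
#' remaining vertex has degree at least 2, leaving the loopy backbone on
#' which every edge either separates or connects two loops.
#'
#' @param g A connected [planar_graph()].
#' @return The pruned graph. Errors with `"no loopy backbone"` when the
#'   input contains no cycle.
#' @export
prune_tree_components <- function(g) {
  repeat {
    deg <- vertex_degrees(g)
    drop <- names(deg)[deg <= 1]
    if (!length(drop)) break
    drop <- as.integer(drop)
    g$nodes <- g$nodes[!(g$nodes$id %in% drop), ]
    g$links <- g$links[!(g$links$from %in% drop | g$links$to %in% drop), ]
  }
  if (!nrow(g$links)) abort("no loopy backbone")
  g
}
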