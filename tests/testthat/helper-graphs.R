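## Small fixture graphs built in code. Weights are chosen pairwise distinct
## so the decomposition order is unambiguous.

pg <- function(nodes, links) {
  planar_graph(as.data.frame(nodes), as.data.frame(links))
}

## unit square with one diagonal: 2 faces of area 0.5
square_diag <- function(w = c(1, 2, 3, 4, 5)) {
  pg(list(id = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
     list(from = c(1, 2, 3, 4, 1), to = c(2, 3, 4, 1, 3), weight = w))
}

## two triangles sharing one edge
two_triangles <- function(w = c(5, 4, 1, 3, 2)) {
  ## shared edge 1-2 has weight w[1]
  pg(list(id = 1:4, x = c(0, 1, 0.5, 0.5), y = c(0, 0, 1, -1)),
     list(from = c(1, 2, 1, 1, 2), to = c(2, 3, 3, 4, 4),
          weight = w))
}

## two triangles joined by a bridge link
two_triangles_bridge <- function(wl = c(3, 4, 5), wr = c(7, 8, 9), wb = 1) {
  pg(list(id = 1:6,
          x = c(0, 1, 0.5, 2.5, 3.5, 3), y = c(0, 0, 1, 0, 0, 1)),
     list(from = c(1, 2, 1, 2, 4, 5, 4),
          to   = c(2, 3, 3, 4, 5, 6, 6),
          weight = c(wl[1], wl[2], wl[3], wb, wr[1], wr[2], wr[3])))
}

## 2 x 2 grid of unit squares: 4 faces
grid2x2 <- function(weights = 1:12) {
  xy <- expand.grid(x = 0:2, y = 0:2)
  id <- seq_len(9)
  idx <- function(x, y) id[xy$x == x & xy$y == y]
  hor <- do.call(rbind, lapply(0:2, function(y)
    cbind(sapply(0:1, idx, y = y), sapply(1:2, idx, y = y))))
  ver <- do.call(rbind, lapply(0:2, function(x)
    cbind(sapply(0:1, function(y) idx(x, y)), sapply(1:2, function(y) idx(x, y)))))
  e <- rbind(hor, ver)
  pg(list(id = id, x = xy$x, y = xy$y),
     list(from = e[, 1], to = e[, 2], weight = weights))
}

## triangle with a pendant path attached at vertex 1
triangle_with_tail <- function() {
  pg(list(id = 1:6, x = c(0, 1, 0.5, -1, -2, -3), y = c(0, 0, 1, 0, 0, 0)),
     list(from = c(1, 2, 1, 1, 4, 5), to = c(2, 3, 3, 4, 5, 6),
          weight = c(2, 3, 4, 1, 1.5, 2.5)))
}

## theta graph: two junction vertices joined by three chains
theta_graph <- function(w = c(1, 2, 3, 4, 5, 6)) {
  pg(list(id = 1:5, x = c(0, 2, 1, 1, 1), y = c(0, 0, 1, 0, -1)),
     list(from = c(1, 3, 1, 4, 1, 5), to = c(3, 2, 4, 2, 5, 2),
          weight = w))
}

## a 1-ring hexagonal lattice with seeded random distinct weights
hex1_random <- function(seed = 1) {
  g <- triangular_lattice_hex(1)
  g$links$weight <- with_seed_local(seed, sample(seq_len(nrow(g$links))))
  g
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
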