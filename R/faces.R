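## Face extraction by half-edge (dart) traversal of the straight-line
## embedding. Link i yields darts i (from -> to) and m + i (to -> from).
## The successor of a dart arriving at v is the dart leaving v that is the
## clockwise neighbour of the reversed dart in the angular order around v;
## with this convention internal faces come out counter-clockwise (positive
## shoelace area) and the outer face clockwise (negative area).
face_structure <- function(g) {
  nodes <- g$nodes
  li <- g$links
  m <- nrow(li)
  if (!m) abort("graph has no links")
  vidx <- match(c(li$from, li$to), nodes$id)
  tail_v <- c(vidx[1:m], vidx[(m + 1):(2 * m)])     # dart tails
  head_v <- c(vidx[(m + 1):(2 * m)], vidx[1:m])     # dart heads
  rev_d <- c((m + 1):(2 * m), 1:m)
  ang <- atan2(nodes$y[head_v] - nodes$y[tail_v],
               nodes$x[head_v] - nodes$x[tail_v])

  ## darts grouped by tail vertex, each group sorted counter-clockwise
  ord <- order(tail_v, ang)
  grp_start <- which(!duplicated(tail_v[ord]))
  grp_of <- integer(nrow(nodes))
  grp_of[tail_v[ord][grp_start]] <- grp_start
  grp_size <- tabulate(tail_v, nbins = nrow(nodes))
  pos_in_grp <- integer(2 * m)
  pos_in_grp[ord] <- sequence(rle(tail_v[ord])$lengths)

  ## next dart after d: clockwise predecessor of rev(d) around head(d)
  nxt <- integer(2 * m)
  for (d in seq_len(2 * m)) {
    v <- head_v[d]
    r <- rev_d[d]
    p <- pos_in_grp[r] - 1L
    if (p < 1L) p <- grp_size[v]
    nxt[d] <- ord[grp_of[v] + p - 1L]
  }

  face_of <- integer(2 * m)
  areas <- numeric(0)
  cycles <- list()
  f <- 0L
  for (d0 in seq_len(2 * m)) {
    if (face_of[d0]) next
    f <- f + 1L
    d <- d0
    a <- 0
    vs <- integer(0)
    repeat {
      face_of[d] <- f
      vs <- c(vs, tail_v[d])
      a <- a + nodes$x[tail_v[d]] * nodes$y[head_v[d]] -
        nodes$x[head_v[d]] * nodes$y[tail_v[d]]
      d <- nxt[d]
      if (d == d0) break
    }
    areas[f] <- a / 2
    cycles[[f]] <- vs
  }
  outer <- which.max(abs(areas))
  list(
    n_faces = f,
    signed_area = areas,
    outer = outer,
    cycle = cycles,                      # vertex indices into nodes
    dart_face = face_of,                 # length 2m; link i: sides face_of[i], face_of[m+i]
    m = m
  )
}

#' Extract the internal faces of a pruned planar graph
#'
#' Traverses the straight-line embedding and returns the elementary loops
#' (faces) of the graph. The face with the largest absolute signed area is
#' taken to be the unbounded outer face and is excluded.
#'
#' @param g A pruned, connected [planar_graph()].
#' @param validate If `TRUE`, first check the embedding is non-crossing.
#' @return A tibble with one row per internal face: `face` (id), `area`
#'   (shoelace polygon area, coordinate units squared) and `vertices`
#'   (list-column of vertex ids in counter-clockwise order). The number of
#'   faces equals `L - V + 1` (Euler's formula).
#' @examples
#' g <- triangular_lattice_hex(1)
#' extract_faces(g)
#' @export
extract_faces <- function(g, validate = FALSE) {
  if (validate) validate_embedding(g)
  if (!graph_is_connected(g)) abort("graph must be connected")
  fs <- face_structure(g)
  keep <- setdiff(seq_len(fs$n_faces), fs$outer)
  tibble::tibble(
    face = seq_along(keep),
    area = abs(fs$signed_area[keep]),
    vertices = lapply(keep, function(f) g$nodes$id[fs$cycle[[f]]])
  )
}
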