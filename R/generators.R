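#' Hexagonal patch of the triangular lattice
#'
#' Builds the common substrate of all generated model networks: a central
#' vertex surrounded by `rings` concentric hexagonal rings of the
#' triangular lattice at unit spacing. The patch has `1 + 3 n (n + 1)`
#' vertices, `9 n^2 + 3 n` links and `6 n^2` internal faces (`n = rings`);
#' 16 rings give the 817-vertex lattice on which the architectural models
#' are defined.
#'
#' Links carry `family` (1-3, the three directions of parallel lattice
#' lines) and `line` (signed line index within the family) columns used by
#' the line-based weight models; initial weights are 1.
#'
#' @param rings Number of rings, at least 1.
#' @param spacing Lattice constant (length units).
#' @return A [planar_graph()] with attribute `rings`.
#' @examples
#' g <- triangular_lattice_hex(2)
#' nrow(g$nodes)  # 19
#' @export
triangular_lattice_hex <- function(rings, spacing = 1) {
  n <- as.integer(rings)
  if (n < 1) abort("rings must be at least 1")
  qr <- expand.grid(q = -n:n, r = -n:n)
  qr <- qr[abs(qr$q + qr$r) <= n, ]
  nodes <- tibble::tibble(
    id = seq_len(nrow(qr)),
    x = spacing * (qr$q + qr$r / 2),
    y = spacing * qr$r * sqrt(3) / 2
  )
  key <- paste(qr$q, qr$r)
  idx <- function(q, r) match(paste(q, r), key)
  ## three positive directions; family line indices: E: r, NE: q, NW: q + r
  dirs <- list(c(1L, 0L), c(0L, 1L), c(-1L, 1L))
  links <- purrr::map_dfr(seq_along(dirs), function(f) {
    dq <- dirs[[f]][1]; dr <- dirs[[f]][2]
    to <- idx(qr$q + dq, qr$r + dr)
    ok <- !is.na(to)
    tibble::tibble(
      from = seq_len(nrow(qr))[ok],
      to = to[ok],
      weight = 1,
      family = f,
      line = switch(f, qr$r[ok], qr$q[ok], qr$q[ok] + qr$r[ok])
    )
  })
  g <- planar_graph(nodes, links[, c("from", "to", "weight")])
  g$links$family <- links$family
  g$links$line <- as.integer(links$line)
  attr(g, "rings") <- n
  attr(g, "spacing") <- spacing
  g
}

## recursive bisection order of line indices -n..n: boundaries and centre
## are order 0, bisectors of order-k spans order k+1; the lower of two
## candidate midpoints wins for odd spans
lattice_line_orders <- function(n) {
  ord <- rep(NA_integer_, 2 * n + 1)   # index i + n + 1 for line i
  at <- function(i) i + n + 1L
  ord[at(c(-n, 0L, n))] <- 0L
  bisect <- function(a, b, k) {
    if (b - a < 2) return()
    mid <- a + (b - a) %/% 2           # lower midpoint on ties
    ord[at(mid)] <<- k
    bisect(a, mid, k + 1L)
    bisect(mid, b, k + 1L)
  }
  bisect(-n, 0L, 1L)
  bisect(0L, n, 1L)
  tibble::tibble(line = -n:n, order = ord)
}

## table of all 3 * (2n + 1) lattice lines in nested (bisection) order
nested_line_sequence <- function(n) {
  lo <- lattice_line_orders(n)
  lines <- tidyr::expand_grid(family = 1:3, line = -n:n)
  lines$order <- lo$order[match(lines$line, lo$line)]
  lines[order(lines$order, lines$family, lines$line), ]
}

#' Assign an architectural weight model to a lattice
#'
#' Distributes the weight multiset `1..L` (or a custom positive multiset)
#' bijectively over the `L` links of a hexagonal triangular-lattice patch
#' according to one of the architectural models. All models share the same
#' multiset; only its spatial arrangement differs:
#'
#' * `gradient`: weights descend with the link midpoint's Euclidean
#'   distance from the left-most vertex (the nearest link gets the maximum
#'   weight), producing a smooth weight gradient and an additive,
#'   caterpillar-like nesting tree.
#' * `random_links`: seeded uniform permutation of the weights over links;
#'   no long-range order.
#' * `nested`: lattice lines are ordered by recursive bisection (boundary
#'   and central lines first) and the descending weights are dealt line by
#'   line, so thick links occupy low-order lines -- a self-similar,
#'   multiplicative hierarchy.
#' * `nested5` / `nested10` (or `nested_swap` with `swaps`): the nested
#'   arrangement after randomly permuting the positions of 5 / 10 randomly
#'   chosen lines, interpolating toward line-level disorder.
#' * `random_lines`: a full seeded permutation of the line order.
#' * `peaks`: weights grow with distance to the nearest of `n_peaks`
#'   equidistant peak points (the patch centre plus 6 points at half
#'   radius), so each peak seeds a radially growing basin of the
#'   decomposition; the basins join at a characteristic scale where the
#'   asymmetry changes monotonicity.
#'
#' @param g A lattice from [triangular_lattice_hex()] (line-based models
#'   require its `family`/`line` columns).
#' @param model One of `"gradient"`, `"random_links"`, `"nested"`,
#'   `"nested5"`, `"nested10"`, `"nested_swap"`, `"random_lines"`,
#'   `"peaks"`.
#' @param seed Integer seed for the stochastic models.
#' @param swaps Number of lines to shuffle for `nested_swap`.
#' @param n_peaks Number of peaks (default 7; the first is the centre, the
#'   rest are placed on a half-radius hexagon).
#' @param peak_points Optional two-column matrix of peak coordinates
#'   overriding the default placement.
#' @param weights Optional custom positive weight multiset of length `L`.
#' @return The graph with model weights assigned.
#' @examples
#' g <- assign_model_weights(triangular_lattice_hex(4), "nested", seed = 1)
#' @export
assign_model_weights <- function(g, model = c("gradient", "random_links",
                                              "nested", "nested5", "nested10",
                                              "nested_swap", "random_lines",
                                              "peaks"),
                                 seed = 1L, swaps = NULL, n_peaks = 7,
                                 peak_points = NULL, weights = NULL) {
  model <- match.arg(model)
  L <- nrow(g$links)
  if (is.null(weights)) weights <- as.numeric(seq_len(L))
  if (length(weights) != L || any(weights <= 0)) {
    abort("weights must be a positive multiset with one value per link")
  }
  w_desc <- sort(weights, decreasing = TRUE)
  mid_x <- (g$nodes$x[match(g$links$from, g$nodes$id)] +
              g$nodes$x[match(g$links$to, g$nodes$id)]) / 2
  mid_y <- (g$nodes$y[match(g$links$from, g$nodes$id)] +
              g$nodes$y[match(g$links$to, g$nodes$id)]) / 2

  needs_lines <- model %in% c("nested", "nested5", "nested10", "nested_swap",
                              "random_lines")
  if (needs_lines && !all(c("family", "line") %in% names(g$links))) {
    abort("line-based models require a triangular_lattice_hex() input")
  }

  if (model == "gradient") {
    left <- which.min(g$nodes$x + 1e-12 * g$nodes$y)
    d <- sqrt((mid_x - g$nodes$x[left])^2 + (mid_y - g$nodes$y[left])^2)
    ord <- order(d, g$links$from, g$links$to)
    g$links$weight[ord] <- w_desc
  } else if (model == "random_links") {
    perm <- with_local_seed(seed, sample.int(L))
    g$links$weight <- weights[perm]
  } else if (model == "peaks") {
    if (is.null(peak_points)) {
      rings <- attr(g, "rings")
      if (is.null(rings)) abort("peaks model requires a lattice input")
      R <- rings / 2 * (attr(g, "spacing") %||% 1)
      th <- (0:5) * pi / 3
      peak_points <- rbind(c(0, 0), cbind(R * cos(th), R * sin(th)))
      peak_points <- peak_points[seq_len(min(n_peaks, 7)), , drop = FALSE]
    }
    d <- apply(peak_points, 1, function(p) {
      sqrt((mid_x - p[1])^2 + (mid_y - p[2])^2)
    })
    dmin <- do.call(pmin, as.data.frame(d))
    ord <- order(dmin, g$links$from, g$links$to)
    ## nearest links are weakest: the decomposition then grows one basin
    ## out of every peak, as in the single-source gradient model
    g$links$weight[ord] <- rev(w_desc)
  } else {
    n <- attr(g, "rings")
    seq_tab <- nested_line_sequence(n)
    nl <- nrow(seq_tab)
    pos <- seq_len(nl)
    if (model == "random_lines") {
      pos <- with_local_seed(seed, sample.int(nl))
    } else if (model %in% c("nested5", "nested10", "nested_swap")) {
      k <- switch(model, nested5 = 5L, nested10 = 10L,
                  nested_swap = as.integer(swaps))
      if (is.na(k) || k < 1) abort("nested_swap requires `swaps`")
      if (2 * k > nl) abort("lattice has too few lines for that many swaps")
      ## swap the sequence positions of k disjoint random line pairs
      ch <- with_local_seed(seed, sample.int(nl, 2L * k))
      for (j in seq_len(k)) {
        a <- ch[2 * j - 1L]; b <- ch[2 * j]
        tmp <- pos[a]; pos[a] <- pos[b]; pos[b] <- tmp
      }
    }
    seq_tab <- seq_tab[order(pos), ]
    ## deal descending weights line by line; within a line by position
    lkey <- paste(g$links$family, g$links$line)
    skey <- paste(seq_tab$family, seq_tab$line)
    line_rank <- match(lkey, skey)
    ord <- order(line_rank, mid_x, mid_y)
    g$links$weight[ord] <- w_desc
  }
  attr(g, "model") <- model
  attr(g, "model_seed") <- seed
  g
}

#' Generate a complete model network in one call
#'
#' Convenience wrapper: [triangular_lattice_hex()] followed by
#' [assign_model_weights()].
#'
#' @inheritParams triangular_lattice_hex
#' @inheritParams assign_model_weights
#' @param ... Passed to [assign_model_weights()].
#' @return A weighted [planar_graph()].
#' @export
model_network <- function(rings, model, seed = 1L, spacing = 1, ...) {
  assign_model_weights(triangular_lattice_hex(rings, spacing), model,
                       seed = seed, ...)
}

#' Plant spurious strong minor loops along the major lines
#'
#' Emulates the digitization artifact seen in non-uniformly stained
#' specimens: small loops with spuriously strong boundary links
#' concentrated around the major veins. Randomly chosen faces adjacent to
#' the order-0 (major) lattice lines have all their boundary links raised
#' above the maximum weight, so they persist to the very end of the
#' decomposition and join through maximally asymmetric partitions --
#' exactly the signature the partition-asymmetry cleaning removes.
#'
#' @param g A weighted lattice (e.g. the nested model from
#'   [assign_model_weights()]).
#' @param n_spurious Number of faces to contaminate.
#' @param seed Seed for the face choice.
#' @param boost Multiple of the maximum weight given to the contaminated
#'   boundary links.
#' @return The contaminated graph, with the chosen face ids (as they
#'   appear in the `face` column of the nesting tree's leaves) in attribute
#'   `"spurious_faces"`.
#' @export
contaminate_nested <- function(g, n_spurious = 12, seed = 1L, boost = 2) {
  if (!all(c("family", "line") %in% names(g$links))) {
    abort("contamination requires a lattice input")
  }
  n <- attr(g, "rings")
  lo <- lattice_line_orders(n)
  major <- lo$line[lo$order == 0]
  fs <- face_structure(g)
  m <- fs$m
  cand_links <- which(g$links$line %in% major)
  cand_faces <- setdiff(unique(fs$dart_face[c(cand_links, m + cand_links)]),
                        fs$outer)
  picked <- with_local_seed(seed, sample(cand_faces,
                                         min(n_spurious, length(cand_faces))))
  wmax <- max(g$links$weight)
  bump <- 0
  for (f in picked) {
    darts <- which(fs$dart_face == f)
    links <- ifelse(darts > m, darts - m, darts)
    bump <- bump + 1
    g$links$weight[links] <- wmax * boost + bump + seq_along(links) / 10
  }
  attr(g, "spurious_faces") <- picked
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
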