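## Brute-force decomposition oracle: after every removal the faces and chain
## strengths are recomputed from scratch on the current graph -- no
## incremental bookkeeping. Loops are identified across steps by which
## original face centroids their polygon contains (ray casting), so the
## oracle shares no state with the package's merge machinery.

## -- naive face walk (standalone copy kept deliberately simple) ------------
oracle_faces <- function(nodes, links) {
  m <- nrow(links)
  vi <- match(c(links$from, links$to), nodes$id)
  tl <- c(vi[1:m], vi[(m + 1):(2 * m)])
  hd <- c(vi[(m + 1):(2 * m)], vi[1:m])
  rev_d <- c((m + 1):(2 * m), 1:m)
  ang <- atan2(nodes$y[hd] - nodes$y[tl], nodes$x[hd] - nodes$x[tl])
  nxt <- integer(2 * m)
  for (d in seq_len(2 * m)) {
    v <- hd[d]
    cand <- which(tl == v)
    cand <- cand[order(ang[cand])]
    i <- which(cand == rev_d[d])
    nxt[d] <- cand[if (i == 1) length(cand) else i - 1]
  }
  seen <- logical(2 * m)
  out <- list()
  for (d0 in seq_len(2 * m)) {
    if (seen[d0]) next
    d <- d0; vs <- integer(0); a <- 0
    repeat {
      seen[d] <- TRUE
      vs <- c(vs, tl[d])
      a <- a + nodes$x[tl[d]] * nodes$y[hd[d]] - nodes$x[hd[d]] * nodes$y[tl[d]]
      d <- nxt[d]
      if (d == d0) break
    }
    out[[length(out) + 1]] <- list(v = vs, area = a / 2)
  }
  outer <- which.max(abs(vapply(out, `[[`, numeric(1), "area")))
  list(faces = out, outer = outer)
}

point_in_poly <- function(px, py, x, y) {
  n <- length(x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py) &&
        px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

## chains recomputed from scratch: maximal degree-2 paths between junctions
oracle_chains <- function(nodes, links, rule = "min") {
  deg <- table(factor(c(links$from, links$to), levels = nodes$id))
  adj <- split(rep(seq_len(nrow(links)), 2), c(links$from, links$to))
  other <- function(l, v) if (links$from[l] == v) links$to[l] else links$from[l]
  visited <- logical(nrow(links))
  chains <- list()
  junctions <- nodes$id[deg[as.character(nodes$id)] != 2]
  for (v in junctions) {
    for (l in adj[[as.character(v)]]) {
      if (visited[l]) next
      ls <- l
      prev <- v
      cur <- other(l, v)
      while (deg[as.character(cur)] == 2 && cur != v) {
        nx <- setdiff(adj[[as.character(cur)]], ls[length(ls)])
        ls <- c(ls, nx)
        prev <- cur
        cur <- other(nx, cur)
      }
      visited[ls] <- TRUE
      chains[[length(chains) + 1]] <- ls
    }
  }
  for (l0 in seq_len(nrow(links))) {      # closed all-degree-2 cycles
    if (visited[l0]) next
    ls <- l0
    v <- links$from[l0]
    cur <- links$to[l0]
    while (cur != v) {
      nx <- setdiff(adj[[as.character(cur)]], ls[length(ls)])
      ls <- c(ls, nx)
      cur <- other(nx, cur)
    }
    visited[ls] <- TRUE
    chains[[length(chains) + 1]] <- ls
  }
  strengths <- vapply(chains, function(ls) {
    w <- links$weight[ls]
    switch(rule, min = min(w), median = median(w), max = max(w))
  }, numeric(1))
  list(chains = chains, strengths = strengths)
}

## full oracle: returns merge events as list(h, members1, members2) where
## members are sets of original face labels ("F<i>" or "EXT")
oracle_decompose <- function(g, rule = "min") {
  g <- prune_tree_components(g)
  g <- reassign_bridge_weights(g)
  nodes <- as.data.frame(g$nodes)
  links <- as.data.frame(g$links)

  f0 <- oracle_faces(nodes, links)
  int0 <- setdiff(seq_along(f0$faces), f0$outer)
  ## interior reference points of the original faces
  refs <- lapply(int0, function(i) {
    vs <- f0$faces[[i]]$v
    c(mean(nodes$x[vs]), mean(nodes$y[vs]))
  })
  labels <- paste0("F", seq_along(int0))

  current_partition <- function(nodes, links) {
    ## map each original face label to a loop key from the current faces
    if (!nrow(links)) {
      return(setNames(rep("EXT", length(labels)), labels))
    }
    fc <- oracle_faces(nodes, links)
    assign <- rep("EXT", length(labels))
    ## internal faces are the counter-clockwise (positive-area) cycles; this
    ## stays correct even if a discarded removal disconnects the graph
    ints <- which(vapply(fc$faces, `[[`, numeric(1), "area") > 1e-12)
    for (k in seq_along(ints)) {
      vs <- fc$faces[[ints[k]]]$v
      for (j in seq_along(refs)) {
        if (point_in_poly(refs[[j]][1], refs[[j]][2],
                          nodes$x[vs], nodes$y[vs])) {
          assign[j] <- paste0("L", k)
        }
      }
    }
    setNames(assign, labels)
  }

  part <- current_partition(nodes, links)
  blocks <- function(part) {
    fin <- part != "EXT"
    c(unname(split(names(part)[fin], part[fin])),
      list(c("EXT", names(part)[!fin])))
  }
  events <- list()

  repeat {
    ch <- oracle_chains(nodes, links, rule)
    fin <- is.finite(ch$strengths)
    if (!any(fin)) break
    k <- which(fin)[which.min(ch$strengths[fin])]
    h <- ch$strengths[k]
    before <- blocks(part)
    ## delete the chain's links, then prune dangling vertices
    links <- links[-ch$chains[[k]], , drop = FALSE]
    repeat {
      deg <- table(factor(c(links$from, links$to), levels = nodes$id))
      dangling <- nodes$id[deg[as.character(nodes$id)] <= 1]
      if (!length(dangling)) break
      nodes <- nodes[!(nodes$id %in% dangling), , drop = FALSE]
      links <- links[!(links$from %in% dangling | links$to %in% dangling), ,
                     drop = FALSE]
      if (!nrow(links)) break
    }
    part <- current_partition(nodes, links)
    after <- blocks(part)
    ## detect a merge: two old blocks now share a key
    merged <- NULL
    for (b in after) {
      parents <- Filter(function(ob) any(ob %in% b), before)
      if (length(parents) == 2) merged <- parents
      if (length(parents) > 2) stop("oracle: more than two loops merged")
    }
    if (!is.null(merged)) {
      events[[length(events) + 1]] <- list(
        h = h,
        m1 = sort(merged[[1]]),
        m2 = sort(merged[[2]])
      )
    }
    if (!nrow(links)) break
  }
  events
}

## the same canonical event list extracted from a package nesting tree;
## face ids are mapped to the oracle's "F<i>" labels via face vertex sets
tree_events <- function(t, g) {
  g2 <- prune_tree_components(g)
  g2 <- reassign_bridge_weights(g2)
  fs <- loopnest:::face_structure(g2)
  f0 <- oracle_faces(as.data.frame(g2$nodes), as.data.frame(g2$links))
  int_pkg <- setdiff(seq_len(fs$n_faces), fs$outer)
  int_or <- setdiff(seq_along(f0$faces), f0$outer)
  keyify <- function(vs) paste(sort(unique(vs)), collapse = "-")
  pkg_keys <- vapply(int_pkg, function(f) keyify(g2$nodes$id[fs$cycle[[f]]]),
                     character(1))
  or_keys <- vapply(int_or, function(i) keyify(g2$nodes$id[f0$faces[[i]]$v]),
                    character(1))
  ## package face id -> oracle label
  lab_of <- setNames(paste0("F", match(pkg_keys, or_keys)), int_pkg)

  nd <- t$nodes
  leaf_labels <- ifelse(nd$exterior & !is.na(nd$face), "EXT",
                        lab_of[as.character(nd$face)])
  members <- vector("list", nrow(nd))
  for (i in seq_len(nrow(nd))) {
    members[[i]] <- if (is.na(nd$child1[i])) {
      if (nd$exterior[i]) "EXT" else leaf_labels[i]
    } else {
      c(members[[nd$child1[i]]], members[[nd$child2[i]]])
    }
  }
  int <- which(!is.na(nd$child1))
  lapply(int, function(i) {
    m1 <- sort(unique(members[[nd$child1[i]]]))
    m2 <- sort(unique(members[[nd$child2[i]]]))
    list(h = nd$h[i], m1 = m1, m2 = m2)
  })
}

## canonical comparable form: unordered pair of member sets + h
canon_events <- function(evts) {
  lapply(evts, function(e) {
    pair <- list(sort(unique(e$m1)), sort(unique(e$m2)))
    pair <- pair[order(vapply(pair, paste, character(1), collapse = ","))]
    list(h = round(e$h, 9), members = pair)
  })
}
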