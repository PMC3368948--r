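#' Read a weighted planar network from disk
#'
#' Two plain-text dialects are supported:
#'
#' * **edge-list TSV** -- a `#nodes` section (`id<TAB>x<TAB>y`) followed by a
#'   `#links` section (`a<TAB>b<TAB>weight`);
#' * **GraphML** -- an XML graph whose nodes carry `x`/`y` attributes and
#'   whose edges carry a `weight` attribute.
#'
#' Weights are tie-perturbed on load (see [perturb_weights()]) so the
#' decomposition's strict ordering is well defined and reproducible.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"graphml"`.
#' @param validate Check the straight-line embedding is non-crossing
#'   (disable for noisy digitizations).
#' @param largest_component Keep only the largest connected component
#'   instead of erroring on disconnected input.
#' @param perturb_seed Seed of the tie-breaking perturbation (`NULL` to
#'   skip).
#' @return A [planar_graph()].
#' @examples
#' path <- system.file("extdata", "hex1.tsv", package = "loopnest")
#' read_network(path)
#' @export
read_network <- function(path, format = c("auto", "tsv", "graphml"),
                         validate = TRUE, largest_component = FALSE,
                         perturb_seed = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$|\\.xml$", path, ignore.case = TRUE)) {
      "graphml"
    } else "tsv"
  }
  g <- if (format == "tsv") read_network_tsv(path) else read_network_graphml(path)
  if (any(g$links$weight <= 0)) abort("non-positive link weight in input")
  if (!graph_is_connected(g)) {
    if (!largest_component) abort("input graph is disconnected")
    gi <- as_igraph(g)
    comp <- igraph::components(gi)
    keep <- as.integer(names(comp$membership)[comp$membership ==
                                                which.max(comp$csize)])
    g$nodes <- g$nodes[g$nodes$id %in% keep, ]
    g$links <- g$links[g$links$from %in% keep & g$links$to %in% keep, ]
  }
  if (validate) validate_embedding(g)
  if (!is.null(perturb_seed)) g <- perturb_weights(g, seed = perturb_seed)
  g
}

read_network_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  sec <- cumsum(grepl("^#", lines))
  hdr <- tolower(sub("^#\\s*", "", lines[grepl("^#", lines)]))
  if (!all(c("nodes", "links") %in% hdr)) {
    abort("TSV must contain '#nodes' and '#links' sections")
  }
  parse_sec <- function(name, cols) {
    which_hdr <- which(hdr == name)
    body <- lines[sec == which_hdr & !grepl("^#", lines) & nzchar(lines)]
    m <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    if (is.null(m) || ncol(m) < length(cols)) {
      abort(sprintf("malformed '#%s' section", name))
    }
    df <- as.data.frame(m[, seq_along(cols), drop = FALSE],
                        stringsAsFactors = FALSE)
    names(df) <- cols
    df[] <- lapply(df, as.numeric)
    if (anyNA(df)) abort(sprintf("non-numeric value in '#%s' section", name))
    df
  }
  nodes <- parse_sec("nodes", c("id", "x", "y"))
  links <- parse_sec("links", c("from", "to", "weight"))
  planar_graph(nodes, links)
}

read_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_map <- setNames(xml2::xml_attr(keys, "attr.name"),
                      xml2::xml_attr(keys, "id"))
  get_data <- function(el, name) {
    data <- xml2::xml_find_all(el, "./data")
    kid <- xml2::xml_attr(data, "key")
    vals <- xml2::xml_text(data)
    nm <- ifelse(kid %in% names(key_map), key_map[kid], kid)
    v <- vals[nm == name]
    if (length(v)) as.numeric(v[1]) else NA_real_
  }
  node_el <- xml2::xml_find_all(doc, ".//node")
  edge_el <- xml2::xml_find_all(doc, ".//edge")
  nid <- xml2::xml_attr(node_el, "id")
  nodes <- tibble::tibble(
    id = seq_along(nid),
    x = vapply(node_el, get_data, numeric(1), "x"),
    y = vapply(node_el, get_data, numeric(1), "y")
  )
  if (anyNA(nodes$x) || anyNA(nodes$y)) abort("GraphML nodes need x and y")
  links <- tibble::tibble(
    from = match(xml2::xml_attr(edge_el, "source"), nid),
    to = match(xml2::xml_attr(edge_el, "target"), nid),
    weight = vapply(edge_el, get_data, numeric(1), "weight")
  )
  if (anyNA(links$weight)) abort("GraphML edges need a weight attribute")
  planar_graph(nodes, links)
}

#' Write a planar network to disk
#'
#' @param g A [planar_graph()].
#' @param path Output file.
#' @param format `"tsv"` or `"graphml"` (see [read_network()] for the
#'   dialects).
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#nodes", con)
    writeLines(sprintf("%d\t%.17g\t%.17g", g$nodes$id, g$nodes$x, g$nodes$y),
               con)
    writeLines("#links", con)
    writeLines(sprintf("%d\t%d\t%.17g", g$links$from, g$links$to,
                       g$links$weight), con)
  } else {
    doc <- xml2::xml_new_root("graphml")
    for (k in list(c("kx", "node", "x"), c("ky", "node", "y"),
                   c("kw", "edge", "weight"))) {
      xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                          `attr.name` = k[3], `attr.type` = "double")
    }
    gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
    for (i in seq_len(nrow(g$nodes))) {
      nel <- xml2::xml_add_child(gr, "node", id = as.character(g$nodes$id[i]))
      xml2::xml_add_child(nel, "data", sprintf("%.17g", g$nodes$x[i]), key = "kx")
      xml2::xml_add_child(nel, "data", sprintf("%.17g", g$nodes$y[i]), key = "ky")
    }
    for (i in seq_len(nrow(g$links))) {
      eel <- xml2::xml_add_child(gr, "edge",
                                 source = as.character(g$links$from[i]),
                                 target = as.character(g$links$to[i]))
      xml2::xml_add_child(eel, "data", sprintf("%.17g", g$links$weight[i]),
                          key = "kw")
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Serialize a nesting tree
#'
#' `"newick"` writes an annotated Newick string: every node carries an
#' NHX-style comment block `[&&LNT:A=...:d=...:h=...:ext=...]` with its
#' area, degree, merge strength and exterior flag. `"json"` writes the node
#' table plus provenance. [read_nesting_tree()] reproduces topology and
#' attributes exactly.
#'
#' @param t A [nesting_tree].
#' @param path Output file.
#' @param format `"newick"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_nesting_tree <- function(t, path, format = c("newick", "json")) {
  format <- match.arg(format)
  nd <- t$nodes
  if (format == "json") {
    jsonlite::write_json(
      list(mode = t$mode, strength_rule = t$strength_rule, seed = t$seed,
           n_discarded = t$n_discarded, nodes = nd),
      path, auto_unbox = TRUE, digits = NA, na = "null"
    )
    return(invisible(path))
  }
  ann <- function(i) {
    sprintf("[&&LNT:A=%.17g:d=%d:h=%s:ext=%d:face=%s]",
            nd$area[i], nd$degree[i],
            if (is.na(nd$h[i])) "NA" else sprintf("%.17g", nd$h[i]),
            as.integer(nd$exterior[i]),
            if (is.na(nd$face[i])) "NA" else as.character(nd$face[i]))
  }
  rec <- function(i) {
    if (is.na(nd$child1[i])) {
      paste0("n", i, ann(i))
    } else {
      paste0("(", rec(nd$child1[i]), ",", rec(nd$child2[i]), ")n", i, ann(i))
    }
  }
  writeLines(paste0(rec(nrow(nd)), ";"), path)
  invisible(path)
}

#' Read a serialized nesting tree
#'
#' @param path File written by [write_nesting_tree()].
#' @param format `"auto"` (by extension), `"newick"` or `"json"`.
#' @return A [nesting_tree].
#' @export
read_nesting_tree <- function(path, format = c("auto", "newick", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "newick"
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nd <- tibble::as_tibble(obj$nodes)
    nd$parent <- as.integer(nd$parent)
    nd$h <- as.numeric(nd$h)
    return(as_nesting_tree(
      nd[, c("id", "parent", "h", "area", "exterior", "face")],
      mode = obj$mode, strength_rule = obj$strength_rule,
      seed = obj$seed %||% NA_integer_
    ))
  }
  s <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick_tree(s)
}

## recursive-descent parser for the annotated Newick dialect above
parse_newick_tree <- function(s) {
  s <- sub(";\\s*$", "", trimws(s))
  rows <- list()
  pos <- 1L
  nchar_s <- nchar(s)
  peek <- function() substr(s, pos, pos)
  parse_node <- function(parent_tmp) {
    kids <- integer(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- c(kids, parse_node(NA))
      if (peek() != ",") abort("malformed newick: expected ','")
      pos <<- pos + 1L
      kids <- c(kids, parse_node(NA))
      if (peek() != ")") abort("malformed newick: expected ')'")
      pos <<- pos + 1L
    }
    ## label
    m <- regexpr("^[^(),\\[;]*", substr(s, pos, nchar_s))
    label <- regmatches(substr(s, pos, nchar_s), m)
    pos <<- pos + attr(m, "match.length")
    ## annotation block
    attrs <- list(A = NA_real_, d = NA, h = NA_real_, ext = 0, face = NA)
    if (peek() == "[") {
      close_b <- regexpr("]", substr(s, pos, nchar_s), fixed = TRUE)
      block <- substr(s, pos + 1L, pos + close_b - 2L)
      pos <<- pos + close_b
      block <- sub("^&&LNT:", "", block)
      for (kv in strsplit(block, ":", fixed = TRUE)[[1]]) {
        p <- strsplit(kv, "=", fixed = TRUE)[[1]]
        attrs[[p[1]]] <- p[2]
      }
    }
    id <- length(rows) + 1L
    rows[[id]] <<- list(tmp_id = id, label = label, kids = kids,
                        A = as.numeric(attrs$A),
                        h = suppressWarnings(as.numeric(attrs$h)),
                        ext = as.integer(attrs$ext),
                        face = suppressWarnings(as.integer(attrs$face)))
    id
  }
  root <- parse_node(NA)
  n <- length(rows)
  parent <- rep(NA_integer_, n)
  for (r in rows) for (k in r$kids) parent[k] <- r$tmp_id
  ## labels of the form n<i> restore the original merge-order numbering
  labels <- vapply(rows, `[[`, character(1), "label")
  ids <- vapply(rows, `[[`, integer(1), "tmp_id")
  if (all(grepl("^n[0-9]+$", labels))) {
    lab_ids <- as.integer(sub("^n", "", labels))
    if (!anyDuplicated(lab_ids)) {
      parent <- lab_ids[parent]
      ids <- lab_ids
    }
  }
  df <- tibble::tibble(
    id = ids,
    parent = parent,
    h = vapply(rows, `[[`, numeric(1), "h"),
    area = vapply(rows, `[[`, numeric(1), "A"),
    exterior = vapply(rows, `[[`, integer(1), "ext") == 1L,
    face = vapply(rows, function(r) r$face %||% NA_integer_, integer(1))
  )
  as_nesting_tree(df)
}
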