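test_that("bridge weights are raised above their detached component", {
  g <- two_triangles_bridge(wl = c(3, 4, 5), wr = c(7, 8, 9), wb = 1)
  g2 <- reassign_bridge_weights(prune_tree_components(g))
  wb <- g2$links$weight[g2$links$from == 2 & g2$links$to == 4]
  expect_gt(wb, 5)          # above the left triangle's maximum
  expect_lt(wb, 5.001)      # but only infinitesimally
  ## all other weights untouched
  expect_equal(sort(g2$links$weight[-4]), c(3, 4, 5, 7, 8, 9))
  ## identity on bridge-free input
  h <- triangular_lattice_hex(1)
  expect_identical(reassign_bridge_weights(h)$links$weight, h$links$weight)
})

test_that("chained bridges each get their local component maximum", {
  ## three triangles in a row joined by two bridges
  g <- pg(list(id = 1:9,
               x = c(0, 1, 0.5, 2.5, 3.5, 3, 5, 6, 5.5),
               y = c(0, 0, 1, 0, 0, 1, 0, 0, 1)),
          list(from = c(1, 2, 1, 2, 4, 5, 4, 5, 7, 8, 7),
               to   = c(2, 3, 3, 4, 5, 6, 6, 7, 8, 9, 9),
               weight = c(3, 4, 5, 1, 11, 12, 13, 2, 7, 8, 9)))
  g2 <- reassign_bridge_weights(prune_tree_components(g))
  b1 <- g2$links$weight[g2$links$from == 2 & g2$links$to == 4]
  b2 <- g2$links$weight[g2$links$from == 5 & g2$links$to == 7]
  expect_equal(b1, 5 * (1 + 1e-9))    # left triangle max
  expect_equal(b2, 9 * (1 + 1e-9))    # right triangle max
})

test_that("phantom boundary adds one phantom loop per perimeter junction", {
  g <- triangular_lattice_hex(1)
  ga <- add_phantom_boundary(g)
  expect_equal(nrow(ga$nodes), 7 + 6)
  expect_equal(nrow(ga$links), 12 + 12)
  expect_equal(sum(is.infinite(ga$links$weight)), 12)
  ## faces: 6 internal + 6 phantom + outer
  f <- loopnest:::face_structure(ga)
  expect_equal(f$n_faces, 13)
  expect_error(add_phantom_boundary(ga), "already has")
})

test_that("a bare triangle gets three phantom loops", {
  tri <- pg(list(id = 1:3, x = c(0, 1, 0.5), y = c(0, 0, 1)),
            list(from = c(1, 2, 3), to = c(2, 3, 1), weight = c(3, 1, 2)))
  ga <- add_phantom_boundary(tri)
  f <- loopnest:::face_structure(ga)
  expect_equal(f$n_faces, 1 + 3 + 1)
})

test_that("single-loop graph decomposes to one merge with the exterior", {
  tri <- pg(list(id = 1:3, x = c(0, 1, 0.5), y = c(0, 0, 1)),
            list(from = c(1, 2, 3), to = c(2, 3, 1), weight = c(3, 1, 2)))
  t <- loop_decompose(tri)
  nd <- t$nodes
  expect_equal(nrow(nd), 3)              # face + exterior + root
  expect_equal(sum(is.na(nd$child1)), 2)
  expect_equal(nd$h[3], 1)               # weakest perimeter link
  expect_true(nd$exterior[3])
  expect_equal(nd$area[3], 0.5, tolerance = 1e-12)
})

test_that("two faces sharing a weak edge merge with each other first", {
  g <- two_triangles(w = c(1, 5, 4, 3, 2))  # shared edge weight 1
  t <- loop_decompose(g)
  nd <- t$nodes
  first_merge <- nd[4, ]                    # first internal node
  expect_equal(first_merge$h, 1)
  expect_false(first_merge$exterior)        # joins the two faces, not outside
  expect_equal(first_merge$degree, 2L)
  expect_equal(nd$h[5], 2)                  # then the weakest perimeter edge
})

test_that("decomposition invariants hold across graphs and modes", {
  graphs <- list(
    square_diag(), two_triangles(), grid2x2(), theta_graph(),
    hex1_random(1), hex1_random(2),
    assign_model_weights(triangular_lattice_hex(3), "random_links", seed = 3)
  )
  for (g in graphs) {
    for (mode in c("single_exterior", "phantom_boundary")) {
      t <- loop_decompose(g, mode = mode, seed = 1)
      nd <- t$nodes
      leaf <- is.na(nd$child1)
      ## merge count = leaves - 1
      expect_equal(sum(!leaf), sum(leaf) - 1L)
      ## area conservation and degree additivity (validator re-checks)
      expect_silent(validate_nesting_tree(t))
      ## removal strengths non-decreasing under the min rule
      h <- nd$h[!leaf]
      h <- h[is.finite(h)]
      expect_true(all(diff(h) >= -1e-12))
      ## leaves cover all internal faces exactly once
      f <- extract_faces(prune_tree_components(g))
      expect_equal(sum(leaf & !nd$exterior), nrow(f))
      expect_equal(sum(nd$area[leaf]), sum(f$area), tolerance = 1e-9)
    }
  }
})

test_that("single and phantom modes agree on the internal subtree of the nested model", {
  g <- assign_model_weights(triangular_lattice_hex(3), "nested", seed = 1)
  ts <- loop_decompose(g, mode = "single_exterior", seed = 1)
  tp <- loop_decompose(g, mode = "phantom_boundary", seed = 1)
  ## restriction to internal-face leaves: compare the partition each merge
  ## induces on internal faces, for merges not involving the exterior
  internal_merge_sets <- function(t) {
    nd <- t$nodes
    mem <- vector("list", nrow(nd))
    for (i in seq_len(nrow(nd))) {
      mem[[i]] <- if (is.na(nd$child1[i])) {
        if (nd$exterior[i]) integer(0) else nd$face[i]
      } else c(mem[[nd$child1[i]]], mem[[nd$child2[i]]])
    }
    int <- which(!is.na(nd$child1) &
                   !nd$exterior[nd$child1[seq_len(nrow(nd))]] &
                   !nd$exterior[nd$child2[seq_len(nrow(nd))]])
    sets <- lapply(int, function(i) sort(mem[[i]]))
    ## face ids are mode-specific; compare via sorted area multisets instead
    areas <- lapply(int, function(i) sort(round(nd$area[subtree_ids(nd, i)[
      is.na(nd$child1[subtree_ids(nd, i)])]], 9)))
    areas
  }
  s1 <- internal_merge_sets(ts)
  s2 <- internal_merge_sets(tp)
  ## every fully-internal merge of the single-exterior tree appears in the
  ## phantom tree (boundary loops merge through phantoms, not among them)
  key <- function(x) paste(x, collapse = ",")
  expect_true(all(vapply(s1, key, "") %in% vapply(s2, key, "")))
})

test_that("gradient-weighted lattice yields a caterpillar decomposition", {
  g <- assign_model_weights(triangular_lattice_hex(2), "gradient", seed = 1)
  t <- loop_decompose(g)
  nd <- t$nodes
  int <- which(!is.na(nd$child1))
  minor <- pmin(nd$degree[nd$child1[int]], nd$degree[nd$child2[int]])
  ## additive nestedness: every merge joins one terminal loop
  expect_true(all(minor == 1))
})

test_that("brute-force oracle reproduces topology and h sequence", {
  graphs <- list(
    square_diag(), two_triangles(), grid2x2(), theta_graph(),
    two_triangles_bridge(),
    hex1_random(1), hex1_random(2), hex1_random(3),
    grid2x2(weights = with_seed_local(5, sample(1:12))),
    two_triangles(w = c(2, 5, 4, 1, 3))
  )
  for (g in graphs) {
    t <- loop_decompose(g, seed = 1)
    got <- canon_events(tree_events(t, g))
    want <- canon_events(oracle_decompose(g))
    expect_equal(length(got), length(want))
    expect_equal(vapply(got, `[[`, numeric(1), "h"),
                 vapply(want, `[[`, numeric(1), "h"), tolerance = 1e-9)
    expect_equal(lapply(got, `[[`, "members"),
                 lapply(want, `[[`, "members"))
  }
})

test_that("median strength rule changes chain priorities accordingly", {
  t_min <- loop_decompose(theta_graph(w = c(3, 5, 2, 6, 4, 7)),
                          strength_rule = "min")
  t_med <- loop_decompose(theta_graph(w = c(3, 5, 2, 6, 4, 7)),
                          strength_rule = "median")
  ## min rule: first removal at strength 2; median rule: at 4
  expect_equal(min(t_min$nodes$h, na.rm = TRUE), 2)
  expect_equal(min(t_med$nodes$h, na.rm = TRUE), 4)
})

test_that("decomposition requires a cycle and connectivity", {
  tree <- pg(list(id = 1:3, x = 0:2, y = c(0, 0, 0)),
             list(from = c(1, 2), to = c(2, 3), weight = c(1, 2)))
  expect_error(loop_decompose(tree), "no loopy backbone")
  disc <- pg(list(id = 1:6, x = c(0, 1, 0.5, 10, 11, 10.5), y = c(0, 0, 1, 0, 0, 1)),
             list(from = c(1, 2, 3, 4, 5, 6), to = c(2, 3, 1, 5, 6, 4),
                  weight = 1:6))
  expect_error(loop_decompose(disc), "connected")
})
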