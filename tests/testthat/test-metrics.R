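test_that("partition asymmetry matches its definition and is symmetric", {
  expect_equal(partition_asymmetry(1, 1), 0)
  expect_equal(partition_asymmetry(3, 3), 0)
  expect_equal(partition_asymmetry(4, 2), 0.5)
  ## exhaustive check against the closed form for all r, s <= 6
  for (r in 1:6) for (s in 1:6) {
    q <- partition_asymmetry(r, s)
    expect_equal(q, partition_asymmetry(s, r))
    expect_true(q >= 0 && q <= 1)
    if (r + s > 2) expect_equal(q, abs(r - s) / (r + s - 2))
  }
  expect_error(partition_asymmetry(0, 3), "positive")
})

test_that("subtree degree counts leaves, including exterior leaves", {
  t <- loop_decompose(hex1_random(1))
  expect_equal(subtree_degree(t), 7L)      # 6 faces + 1 exterior leaf
  nd <- t$nodes
  leafs <- which(is.na(nd$child1))
  expect_true(all(vapply(leafs, function(i) subtree_degree(t, i), integer(1)) == 1L))
  int <- which(!is.na(nd$child1))
  for (i in int) {
    expect_equal(subtree_degree(t, i),
                 subtree_degree(t, nd$child1[i]) + subtree_degree(t, nd$child2[i]))
  }
})

test_that("caterpillar asymmetry follows (d-2)/(d-1) exactly", {
  for (d in c(2, 3, 4, 8, 16, 64)) {
    t <- caterpillar_tree(d)
    expect_equal(subtree_asymmetry(t), if (d == 2) 0 else (d - 2) / (d - 1))
  }
  ## complete binary trees are perfectly symmetric at every partition
  for (depth in 1:5) {
    expect_equal(subtree_asymmetry(balanced_tree(depth)), 0)
  }
  expect_error(subtree_asymmetry(caterpillar_tree(4), node = 1), "degree-1")
})

test_that("asymmetry, orders and stream counts agree with naive recomputation", {
  for (seed in 1:6) {
    t <- random_full_tree(12, seed)
    na <- loopnest:::node_asymmetries(t)
    int <- which(!na$is_leaf)
    for (i in int[c(1, length(int) %/% 2, length(int))]) {
      expect_equal(na$asymmetry[i], naive_subtree_asymmetry(t, i))
    }
    expect_equal(strahler_orders(t)$order, naive_strahler(t))
    sc <- stream_counts(t)
    expect_equal(sc$n_streams, naive_stream_counts(t))
    expect_equal(sc$n_streams[1], 12L)   # N_1 = leaf count
    ## bounds
    expect_true(all(na$q[int] >= 0 & na$q[int] <= 1))
    expect_true(all(na$asymmetry[int] >= 0 & na$asymmetry[int] <= 1))
  }
})

test_that("averaged asymmetry windows on the log2 degree axis", {
  t <- caterpillar_tree(8)
  ## window containing only the root (degree 8; degree 7 sits 0.19 away)
  expect_equal(averaged_asymmetry(t, 8, window = 0.1), 6 / 7)
  ## widening to 0.4 pulls in the degree-7 node
  expect_equal(averaged_asymmetry(t, 8, window = 0.4), mean(c(5 / 6, 6 / 7)))
  ## a single bifurcation has asymmetry 0
  expect_equal(averaged_asymmetry(caterpillar_tree(2), 2), 0)
  ## empty window is a missing value, not an error
  expect_true(is.na(averaged_asymmetry(t, 1024, window = 0.1)))
  ## gradient-model caterpillar: lambda increases with degree
  g <- assign_model_weights(triangular_lattice_hex(2), "gradient", seed = 1)
  td <- loop_decompose(g)
  prof <- asymmetry_profile(td, at = 2^(1:4), window = 0.4)
  expect_true(all(diff(prof$lambda) > 0, na.rm = TRUE))
})

test_that("custom partition weight functions are honoured", {
  t <- caterpillar_tree(4)
  ## uniform weights = default
  expect_equal(subtree_asymmetry(t, weight_fn = function(df) rep(1, nrow(df))),
               subtree_asymmetry(t))
  ## no averaging: weight only the root partition (q = 1 for (3,1))
  root <- nrow(t$nodes)
  expect_equal(
    subtree_asymmetry(t, weight_fn = function(df) as.numeric(df$id == root)),
    1
  )
})

test_that("cumulative size distribution counts exceedance over all areas", {
  t <- caterpillar_tree(4, areas = rep(0.25, 4))
  s <- cumulative_size_distribution(t)
  ## node areas: 4 x 0.25, then 0.5, 0.75, 1.0
  expect_equal(s$a, c(0.25, 0.5, 0.75, 1))
  expect_equal(s$p, c(3 / 7, 2 / 7, 1 / 7, 0))
  ## P(A > a) just below the smallest area is 1
  expect_true(all(s$p <= 1) && all(diff(s$p) <= 0))
  idx <- findInterval(0.3, s$a)
  expect_equal(s$p[idx], 3 / 7)    # P(A > 0.3)
})

test_that("exterior leaves are excluded from the CSD", {
  t <- loop_decompose(hex1_random(1))
  s <- cumulative_size_distribution(t)
  expect_equal(max(s$a), 1)                  # total area normalized
  expect_equal(s$p[length(s$p)], 0)
  ## 6 leaves + 6 composites (the exterior leaf contributes no area, and
  ## composites repeat areas only by coincidence)
  areas <- t$nodes$area[t$nodes$area > 0]
  expect_equal(length(areas), 12)
})

test_that("adjusted CSD flattens exact power laws", {
  s <- tibble::tibble(a = 10^seq(-3, 0, by = 0.1), p = 0.01 / 10^seq(-3, 0, by = 0.1))
  adj <- adjusted_csd(s)
  expect_equal(adj$p_adj, rep(0.01, nrow(s)))
  fit <- fit_slope(adj, axes = "loglog")
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$stderr, 0, tolerance = 1e-12)
})

test_that("fit_slope recovers exact lines and power-law exponents", {
  x <- 1:20
  fit <- fit_slope(data.frame(x = x, y = 3 - 0.5 * x), axes = "linear")
  expect_equal(fit$slope, -0.5)
  expect_equal(fit$stderr, 0, tolerance = 1e-12)
  fit2 <- fit_slope(data.frame(a = x, p = 2 * x^(-1.7)), axes = "loglog")
  expect_equal(fit2$slope, -1.7, tolerance = 1e-9)
  ## range restriction
  fit3 <- fit_slope(data.frame(x = x, y = c(rep(9, 10), 3 - 0.5 * x[11:20])),
                    range = c(11, 20), axes = "linear")
  expect_equal(fit3$slope, -0.5)
  expect_error(fit_slope(data.frame(x = 1, y = 1)), "two points")
})

test_that("Strahler orders follow the recursive rule on known shapes", {
  expect_equal(max(strahler_orders(caterpillar_tree(16))$order), 2L)
  expect_equal(max(strahler_orders(balanced_tree(3))$order), 4L)
  t1 <- as_nesting_tree(data.frame(id = 1, parent = NA, area = 1))
  expect_equal(strahler_orders(t1)$order, 1L)
})

test_that("stream counts on known shapes", {
  expect_equal(stream_counts(balanced_tree(3))$n_streams, c(8L, 4L, 2L, 1L))
  sc <- stream_counts(caterpillar_tree(16))
  expect_equal(sc$n_streams, c(16L, 1L))   # all order-2 nodes chain into one
  expect_equal(stream_counts(caterpillar_tree(2))$n_streams, c(2L, 1L))
})

test_that("bifurcation ratio: constrained fit and two-point fallback", {
  rb <- bifurcation_ratio(balanced_tree(3))
  expect_equal(rb$r_b, 2)
  expect_equal(rb$stderr, 0, tolerance = 1e-12)
  expect_equal(rb$method, "constrained_fit")
  ## exact geometric progression with ratio 5, via a synthetic tree is hard;
  ## caterpillar falls back to the two-point ratio
  rb2 <- bifurcation_ratio(caterpillar_tree(16))
  expect_equal(rb2$method, "two_point")
  expect_equal(rb2$r_b, 16)
  ## stream numbers decay for every generated model decomposition
  for (m in c("gradient", "nested", "random_links")) {
    t <- loop_decompose(model_network(4, m, seed = 2), seed = 2)
    sc <- stream_counts(t)
    expect_true(all(diff(sc$n_streams) < 0))
    rb <- bifurcation_ratio(t)
    expect_true(is.finite(rb$r_b) && rb$r_b > 1)
  }
})
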