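#' Horton-Strahler orders of nesting-tree nodes
#'
#' Leaves have order 1; a node whose children have orders `(w1, w2)` gets
#' `max(w1, w2)` when they differ and `w1 + 1` when equal.
#'
#' @param t A [nesting_tree].
#' @return A tibble with columns `id` and `order`.
#' @export
strahler_orders <- function(t) {
  nd <- t$nodes
  n <- nrow(nd)
  ord <- integer(n)
  leaf <- is.na(nd$child1)
  ord[leaf] <- 1L
  for (i in which(!leaf)) {
    o1 <- ord[nd$child1[i]]
    o2 <- ord[nd$child2[i]]
    ord[i] <- if (o1 == o2) o1 + 1L else max(o1, o2)
  }
  tibble::tibble(id = nd$id, order = ord)
}

#' Strahler stream counts
#'
#' A stream is a maximal path of same-order nodes ending in a node of
#' higher order (or the root). `N_1` equals the leaf count.
#'
#' @param t A [nesting_tree].
#' @return A tibble with columns `order` and `n_streams`.
#' @export
stream_counts <- function(t) {
  nd <- t$nodes
  ord <- strahler_orders(t)$order
  ## the head of each stream: a node whose parent has a different order
  parent_ord <- ifelse(is.na(nd$parent), NA_integer_, ord[nd$parent])
  is_head <- is.na(parent_ord) | parent_ord != ord
  tab <- table(ord[is_head])
  tibble::tibble(order = as.integer(names(tab)),
                 n_streams = as.integer(tab))
}

#' Strahler bifurcation ratio
#'
#' Fits the law of stream numbers: `log N_w` versus order `w` is fitted by
#' least squares with the line constrained to pass through `(1, log N_1)`
#' (`N_1` is the number of terminal loops); the highest-order point is
#' discarded as noise-sensitive. The bifurcation ratio is `R_B =
#' exp(-slope)` (base-free). With fewer than three distinct orders the
#' two-point ratio `N_1 / N_2` is reported and flagged.
#'
#' @param t A [nesting_tree].
#' @return A one-row tibble: `r_b`, `stderr` (standard error of the fitted
#'   log-ratio), `n_orders`, and `method` (`"constrained_fit"` or
#'   `"two_point"`).
#' @export
bifurcation_ratio <- function(t) {
  sc <- stream_counts(t)
  sc <- sc[order(sc$order), ]
  K <- nrow(sc)
  if (K < 2) abort("tree has a single Strahler order; no ratio defined")
  y <- log(sc$n_streams)
  if (K < 3) {
    return(tibble::tibble(r_b = sc$n_streams[1] / sc$n_streams[2],
                          stderr = NA_real_, n_orders = K,
                          method = "two_point"))
  }
  ## constrained through (1, y1); drop the highest order
  use <- 2:(K - 1)
  xs <- sc$order[use] - 1
  ys <- y[1] - y[use]
  b <- sum(xs * ys) / sum(xs^2)
  res <- ys - b * xs
  se <- if (length(use) > 1) {
    sqrt(sum(res^2) / (length(use) - 1) / sum(xs^2))
  } else 0
  tibble::tibble(r_b = exp(b), stderr = se, n_orders = K,
                 method = "constrained_fit")
}
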