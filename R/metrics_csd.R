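#' Cumulative size distribution of nesting-tree loop areas
#'
#' The probability `P(A > a)` that the area of a loop drawn at random from
#' the nodes of the nesting tree (terminal loops and composites alike)
#' exceeds `a`. Zero-area nodes (the exterior and phantom leaves) are
#' excluded; areas are normalized so the total graph area is 1.
#'
#' @param t A [nesting_tree].
#' @param normalize Normalize areas by the total (root) area (default).
#' @return A tibble with columns `a` (distinct areas, ascending) and `p`
#'   (`P(A > a)`, right-continuous and non-increasing; `p = 0` at the
#'   largest area).
#' @examples
#' t <- loop_decompose(assign_model_weights(triangular_lattice_hex(2),
#'                                          "gradient", seed = 1))
#' cumulative_size_distribution(t)
#' @export
cumulative_size_distribution <- function(t, normalize = TRUE) {
  nd <- t$nodes
  areas <- nd$area[nd$area > 0]
  if (!length(areas)) abort("tree has no non-exterior node")
  if (normalize) areas <- areas / nd$area[nrow(nd)]
  a <- sort(unique(areas))
  n <- length(areas)
  ## P(A > a) at each distinct a
  p <- vapply(a, function(x) sum(areas > x), numeric(1)) / n
  tibble::tibble(a = a, p = p)
}

#' Adjusted cumulative size distribution
#'
#' Multiplies the cumulative size distribution by the area:
#' `P~(a) = a * P(A > a)`. For self-similar architectures `P(A > a)` is
#' inversely proportional to `a`, so the adjusted distribution fluctuates
#' about a constant; deviations and periodicities reveal the architectural
#' unit.
#'
#' @param x A [nesting_tree] or a tibble as returned by
#'   [cumulative_size_distribution()].
#' @param ... Passed to [cumulative_size_distribution()] when `x` is a tree.
#' @return A tibble with columns `a` and `p_adj`.
#' @export
adjusted_csd <- function(x, ...) {
  s <- if (inherits(x, "nesting_tree")) cumulative_size_distribution(x, ...) else x
  tibble::tibble(a = s$a, p_adj = s$a * s$p)
}

#' Fit a straight line to a metric series
#'
#' Ordinary least squares on linear or log-log axes, restricted to an
#' abscissa range. Realizes slope measurements on cumulative size
#' distributions (e.g. the slope-1/2 signature of additive architectures on
#' linear axes, or slope-0 of the adjusted distribution of self-similar
#' ones on log-log axes).
#'
#' @param series A two-column data frame (abscissa, ordinate).
#' @param range Abscissa interval `c(lo, hi)` to fit over (inclusive).
#' @param axes `"linear"` or `"loglog"`.
#' @return A one-row tibble: `slope`, `intercept`, `stderr`, `n`.
#' @export
fit_slope <- function(series, range = NULL, axes = c("linear", "loglog")) {
  axes <- match.arg(axes)
  x <- series[[1]]
  y <- series[[2]]
  if (!is.null(range)) {
    sel <- x >= range[1] & x <= range[2]
    x <- x[sel]; y <- y[sel]
  }
  if (axes == "loglog") {
    keep <- x > 0 & y > 0
    x <- log10(x[keep]); y <- log10(y[keep])
  }
  if (length(x) < 2) abort("need at least two points in the fit range")
  fit <- lm(y ~ x)
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["x", "Std. Error"]),
    error = function(e) NA_real_
  )
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    stderr = if (is.nan(se)) 0 else se,
    n = length(x)
  )
}
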