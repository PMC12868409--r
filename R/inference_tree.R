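# Conditional-inference recursive partitioning of ordination scores by
# exposure year. At each node a permutation test of independence between
# the scores and the year factor is carried out: the linear statistic is
# the vector of per-year score sums, standardized by its exact permutation
# moments (Strasser-Weber), and summarised as a quadratic form referred to
# a chi-squared distribution with (levels - 1) degrees of freedom. Only
# when the test rejects is a binary split made, so split selection is
# unbiased in the conditional-inference sense.

# Exact permutation moments of per-level sums of y under free permutation.
node_independence_test <- function(y, g) {
  g <- droplevels(g)
  L <- nlevels(g)
  if (L < 2) return(list(stat = NA_real_, p = 1, levels = L))
  n <- length(y)
  nv <- as.numeric(table(g))
  Tv <- as.numeric(tapply(y, g, sum))
  mu <- nv * mean(y)
  s2 <- sum((y - mean(y))^2) / n
  Sigma <- s2 / (n - 1) * (n * diag(nv) - outer(nv, nv))
  stat <- as.numeric(t(Tv - mu) %*% MASS::ginv(Sigma) %*% (Tv - mu))
  list(stat = stat, p = pchisq(stat, df = L - 1, lower.tail = FALSE),
       levels = L)
}

# Standardized two-sample statistic for a candidate left/right partition.
split_statistic <- function(y, left) {
  n <- length(y)
  nl <- sum(left)
  s2 <- sum((y - mean(y))^2) / n
  v <- nl * (n - nl) / (n - 1) * s2
  if (v <= 0) return(0)
  abs(sum(y[left]) - nl * mean(y)) / sqrt(v)
}

grow_node <- function(y, g, alpha, min_leaf, mode) {
  g <- droplevels(g)
  yrs <- as.numeric(levels(g))
  leaf <- function() {
    list(type = "leaf", years = yrs, n = length(y), mean_score = mean(y))
  }
  if (nlevels(g) < 2 || length(y) < 2 * min_leaf) return(leaf())
  test <- node_independence_test(y, g)
  if (is.na(test$stat) || test$p > alpha) return(leaf())
  # candidate partitions of the year levels
  cands <- if (mode == "ordered") {
    lapply(yrs[-length(yrs)], function(cut) yrs[yrs <= cut])
  } else {
    # all bipartitions: left sets contain the first level, never all levels
    L <- length(yrs)
    lapply(0:(2^(L - 1) - 2), function(code) {
      bits <- as.logical(intToBits(code))[seq_len(L - 1)]
      yrs[c(TRUE, bits)]
    })
  }
  stats <- vapply(cands, function(ly) {
    left <- as.numeric(as.character(g)) %in% ly
    if (sum(left) < min_leaf || sum(!left) < min_leaf) return(-Inf)
    split_statistic(y, left)
  }, numeric(1))
  if (all(!is.finite(stats))) return(leaf())
  best <- cands[[which.max(stats)]]
  left <- as.numeric(as.character(g)) %in% best
  list(type = "split", years = yrs, n = length(y), p = test$p,
       statistic = test$stat, left_years = sort(best),
       cut = if (mode == "ordered") max(best) else NA_real_,
       left = grow_node(y[left], g[left], alpha, min_leaf, mode),
       right = grow_node(y[!left], g[!left], alpha, min_leaf, mode))
}

#' Conditional inference tree of ordination scores over exposure years
#'
#' Recursively partitions first-axis ordination scores by exposure year
#' (treated as a factor). A node is split only if a permutation-moment
#' independence test between scores and years rejects at `alpha`; the
#' split maximises the standardized two-sample statistic over candidate
#' partitions respecting `min_leaf`. By default year levels are treated as
#' ordered, so candidate splits are cutpoints and the resulting groups are
#' contiguous year ranges; `mode = "unordered"` searches all level
#' bipartitions.
#'
#' @param scores Numeric vector (e.g. first NMDS axis), one per site.
#' @param year Exposure year per site (coerced to a factor with
#'   numerically ordered levels).
#' @param alpha Significance level required to split (default 0.05).
#' @param min_leaf Minimum sites per child node (default 7).
#' @param mode `"ordered"` (cutpoint splits, default) or `"unordered"`.
#' @return Object of class `split_tree` (nested list of `split` and
#'   `leaf` nodes).
#' @export
inference_tree <- function(scores, year, alpha = 0.05, min_leaf = 7,
                           mode = c("ordered", "unordered")) {
  mode <- match.arg(mode)
  stop_if_not(length(scores) == length(year),
              "scores and year must have equal length")
  yn <- as.numeric(as.character(year))
  stop_if_not(!any(is.na(yn)), "year must be numeric or a numeric factor")
  g <- factor(yn, levels = sort(unique(yn)))
  stop_if_not(min_leaf >= 1, "min_leaf must be >= 1")
  stop_if_not(min_leaf <= length(scores), "min_leaf larger than node size")
  node <- grow_node(scores, g, alpha, min_leaf, mode)
  structure(list(root = node, alpha = alpha, min_leaf = min_leaf,
                 mode = mode),
            class = "split_tree")
}

#' Year groups at the leaves of a split tree
#'
#' @param x A `split_tree`.
#' @return List of numeric year vectors, one per leaf, partitioning the
#'   observed years, ordered by mean leaf score position in the tree.
#' @export
leaf_groups <- function(x) {
  walk <- function(node) {
    if (node$type == "leaf") return(list(node$years))
    c(walk(node$left), walk(node$right))
  }
  walk(x$root)
}

format_node <- function(node, indent = 0) {
  pad <- strrep("  ", indent)
  if (node$type == "leaf") {
    return(sprintf("%sleaf: years {%s}, n = %d, mean score = %.3f",
                   pad, paste(node$years, collapse = ","), node$n,
                   node$mean_score))
  }
  c(sprintf("%ssplit: years {%s} vs rest (p = %.3g, n = %d)",
            pad, paste(node$left_years, collapse = ","), node$p, node$n),
    format_node(node$left, indent + 1),
    format_node(node$right, indent + 1))
}

#' @export
print.split_tree <- function(x, ...) {
  cat(sprintf("Conditional inference tree (alpha = %g, min_leaf = %d, %s years)\n",
              x$alpha, x$min_leaf, x$mode))
  cat(format_node(x$root), sep = "\n")
  invisible(x)
}

#' Serialise a split tree to JSON
#' @param x A `split_tree`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @export
split_tree_to_json <- function(x, path = NULL) {
  if (is.null(path)) {
    jsonlite::toJSON(x[c("root", "alpha", "min_leaf", "mode")],
                     auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(x[c("root", "alpha", "min_leaf", "mode")], path,
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
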