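#' Bray-Curtis dissimilarity between assemblages
#'
#' `d_ij = sum |x_i - x_j| / sum (x_i + x_j)` over species, in [0, 1]
#' (computed with [vegan::vegdist()]).
#'
#' @param mat Site-by-species count matrix; non-negative, no all-zero row.
#' @return A `dist` object.
#' @export
bray_curtis <- function(mat) {
  stop_if_not(all(mat >= 0), "counts must be non-negative")
  stop_if_not(all(rowSums(mat) > 0), "all-zero row: no dissimilarity defined")
  vegan::vegdist(mat, method = "bray")
}

#' Non-metric multidimensional scaling with principal-axis rotation
#'
#' Iterative stress minimisation over `n_starts` random initialisations
#' ([vegan::metaMDS()] on a precomputed dissimilarity; no automatic data
#' transformation), with the final configuration centred and rotated to
#' its principal axes so the first axis carries the greatest variance
#' among assemblages.
#'
#' @param d Symmetric dissimilarity (`dist` or matrix).
#' @param k Number of dimensions (default 2).
#' @param n_starts Random starts (default 20).
#' @param seed Integer seed.
#' @return Object of class `nmds_ordination`: list with `scores` (sites x
#'   k), `stress`, `converged`, `n_starts`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1) {
  d <- as.dist(d)
  fit <- with_seed(seed, vegan::metaMDS(d, k = k, try = n_starts,
                                        trymax = n_starts,
                                        autotransform = FALSE,
                                        wascores = FALSE, trace = 0))
  if (!isTRUE(fit$converged)) {
    warning("NMDS did not converge across random starts; best solution kept")
  }
  sc <- vegan::scores(fit, display = "sites")
  structure(list(scores = sc, stress = fit$stress,
                 converged = isTRUE(fit$converged), n_starts = n_starts,
                 engine = fit),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f, %sconverged (%d starts)\n",
              ncol(x$scores), x$stress, if (x$converged) "" else "NOT ",
              x$n_starts))
  invisible(x)
}

#' Permutational multivariate analysis of variance
#'
#' Sequential (type-I) decomposition of a dissimilarity matrix over the
#' supplied factors in the given order, with pseudo-F and permutation
#' p-values under free row permutation ([vegan::adonis2()] with
#' `by = "terms"`). `R2 = SS_term / SS_total`; term plus residual R2 sums
#' to one; the smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param d Dissimilarity (`dist`).
#' @param terms Data frame of factors, one row per site, in the order the
#'   sequential decomposition should use (e.g. tree species, then year).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Data frame of class `permanova_result`: `term`, `df`, `ss`,
#'   `r2`, `f`, `p` (residual and total rows included).
#' @export
permanova <- function(d, terms, n_perm = 999, seed = 1) {
  d <- as.dist(d)
  terms <- as.data.frame(terms)
  stop_if_not(nrow(terms) == attr(d, "Size"),
              "terms must have one row per site")
  for (nm in names(terms)) {
    terms[[nm]] <- factor(terms[[nm]])
    stop_if_not(nlevels(terms[[nm]]) >= 2,
                paste("term constant across sites:", nm))
  }
  form <- stats::reformulate(names(terms), response = quote(d))
  environment(form) <- environment()
  tab <- with_seed(seed, vegan::adonis2(form, data = terms,
                                        permutations = n_perm,
                                        by = "terms"))
  out <- data.frame(term = rownames(tab), df = tab$Df, ss = tab$SumOfSqs,
                    r2 = tab$R2, f = tab$F, p = tab$`Pr(>F)`,
                    row.names = NULL)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("permanova_result", "data.frame")
  out
}
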