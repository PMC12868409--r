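#' Blend functional and phylogenetic distance matrices
#'
#' The functional-phylogenetic distance of a species pair combines its
#' (max-rescaled) phylogenetic distance P and functional distance F as
#' \deqn{(a P^p + (1 - a) F^p)^{1/p}.}
#' `a = 0` reproduces the rescaled functional matrix exactly and `a = 1`
#' the rescaled phylogenetic matrix; intermediate values mix both. Each
#' source matrix is divided by its own maximum before blending so the two
#' scales are commensurable; the rescaling and parameters are recorded in
#' attributes.
#'
#' @param func_matrix Functional (e.g. Gower) distance matrix.
#' @param phylo_matrix Phylogenetic (cophenetic) distance matrix over the
#'   same species set (any order; aligned by dimnames).
#' @param a Phylogenetic weight in [0, 1].
#' @param p Blend exponent (> 0); the canonical quadratic blend is `p = 2`.
#' @param rescale Divide each source by its maximum first (default TRUE).
#' @return Matrix of class `blended_distance` with attributes `a`, `p`,
#'   `rescaled`.
#' @export
blend_distances <- function(func_matrix, phylo_matrix, a, p = 2,
                            rescale = TRUE) {
  stop_if_not(a >= 0 && a <= 1, "a must lie in [0, 1]")
  stop_if_not(p > 0, "p must be > 0")
  fn <- rownames(func_matrix)
  pn <- rownames(phylo_matrix)
  stop_if_not(!is.null(fn) && !is.null(pn) && setequal(fn, pn),
              "functional and phylogenetic matrices must cover the same species")
  phylo_matrix <- phylo_matrix[fn, fn]
  if (rescale) {
    stop_if_not(max(func_matrix) > 0, "all-zero functional matrix")
    stop_if_not(max(phylo_matrix) > 0, "all-zero phylogenetic matrix")
    func_matrix <- func_matrix / max(func_matrix)
    phylo_matrix <- phylo_matrix / max(phylo_matrix)
  }
  out <- (a * phylo_matrix^p + (1 - a) * func_matrix^p)^(1 / p)
  structure(out, a = a, p = p, rescaled = rescale,
            class = c("blended_distance", "matrix"))
}

#' Mean pairwise distance of an assemblage
#'
#' Mean over all unordered pairs of distinct species present in the
#' assemblage. Assemblages with fewer than two species have no pairs and
#' yield `NA`.
#'
#' @param species Character vector of species present.
#' @param distance Distance matrix covering (at least) these species.
#' @return Scalar mean pairwise distance, or `NA` if fewer than 2 species.
#' @export
mean_pairwise_distance <- function(species, distance) {
  species <- unique(species)
  unknown <- setdiff(species, rownames(distance))
  stop_if_not(length(unknown) == 0,
              paste("species not in distance matrix:",
                    paste(unknown, collapse = ", ")))
  if (length(species) < 2) return(NA_real_)
  d <- distance[species, species]
  mean(d[lower.tri(d)])
}

#' Standardized effect size of mean pairwise distance (tip-shuffling null)
#'
#' For each assemblage (row of a site-by-species matrix), computes the
#' observed mean pairwise distance and compares it with a null
#' distribution obtained by shuffling the species labels of the distance
#' matrix over the full species pool (all species in `distance`), keeping
#' assemblage memberships fixed. `SES = (obs - null mean) / null sd`;
#' negative values indicate clustering (habitat filtering). Assemblages
#' with fewer than two species, or a degenerate null (sd = 0, e.g. an
#' assemblage equal to the whole pool), yield `NA` SES.
#'
#' @param asm Site-by-species matrix (counts or presences; presence-based
#'   MPD is used unless `abundance_weighted = TRUE`). Row metadata in an
#'   attribute `"sites"` (as produced by [assemblage_matrix()]) is carried
#'   through to the result.
#' @param distance Distance matrix over the species pool; must cover every
#'   species in `asm`.
#' @param n_rand Number of label shuffles (default 999).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param perms Optional integer matrix (`n_rand` x pool size) of
#'   pre-drawn label permutations, e.g. to share one null across a
#'   parameter scan; overrides `n_rand`/`seed`.
#' @param abundance_weighted If `TRUE`, pairwise distances are weighted by
#'   the product of the two species' abundances.
#' @return Data frame of class `ses_result`: one row per assemblage with
#'   `n_species`, `mpd_obs`, `null_mean`, `null_sd`, `ses`, `n_rand`, plus
#'   any site metadata columns.
#' @export
ses_mpd <- function(asm, distance, n_rand = 999, seed = 1, perms = NULL,
                    abundance_weighted = FALSE) {
  pool <- rownames(distance)
  stop_if_not(!is.null(pool), "distance matrix needs species dimnames")
  unknown <- setdiff(colnames(asm), pool)
  stop_if_not(length(unknown) == 0,
              paste("assemblage species missing from the distance matrix:",
                    paste(unknown, collapse = ", ")))
  S <- length(pool)
  W <- matrix(0, nrow = nrow(asm), ncol = S,
              dimnames = list(rownames(asm), pool))
  W[, colnames(asm)] <- as.matrix(asm)
  if (!abundance_weighted) W <- (W > 0) * 1
  pair_stats <- function(D) {
    num <- rowSums((W %*% D) * W)      # sum over ordered pairs (diag zero)
    den <- rowSums(W)^2 - rowSums(W^2) # matching pair-weight total
    ifelse(den > 0, num / den, NA_real_)
  }
  obs <- pair_stats(distance)
  if (is.null(perms)) {
    stop_if_not(n_rand >= 1, "n_rand must be >= 1")
    perms <- with_seed(seed, t(replicate(n_rand, sample.int(S))))
  } else {
    perms <- as.matrix(perms)
    stop_if_not(ncol(perms) == S, "perms must have one column per pool species")
    n_rand <- nrow(perms)
  }
  null <- matrix(NA_real_, nrow = n_rand, ncol = nrow(asm))
  for (r in seq_len(n_rand)) {
    idx <- perms[r, ]
    null[r, ] <- pair_stats(distance[idx, idx])
  }
  null_mean <- colMeans(null)
  null_sd <- apply(null, 2, sd)
  # a null that is constant up to floating-point noise has no defined SES
  degenerate <- is.na(null_sd) |
    null_sd <= 1e-10 * pmax(1, abs(null_mean))
  null_sd[!is.na(null_sd) & degenerate] <- 0
  ses <- ifelse(degenerate, NA_real_, (obs - null_mean) / null_sd)
  out <- data.frame(n_species = rowSums(W > 0),
                    mpd_obs = obs, null_mean = null_mean,
                    null_sd = null_sd, ses = ses, n_rand = n_rand)
  sites <- attr(asm, "sites")
  if (!is.null(sites)) out <- cbind(sites, out)
  class(out) <- c("ses_result", "data.frame")
  out
}
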