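# Shared engine: SES of MPD under a given distance, then the Gaussian
# trend model of SES over exposure year; returns its adjusted R-squared.
ses_trend_r2 <- function(asm, distance, perms, k_year = 10, spatial = TRUE) {
  ses <- ses_mpd(asm, distance, perms = perms)
  d <- ses[!is.na(ses$ses), , drop = FALSE]
  stop_if_not(nrow(d) >= 3, "fewer than 3 valid SES rows")
  fit <- fit_trend_gam(as.data.frame(d), response = "ses",
                       family = "gaussian", k_year = k_year,
                       spatial = spatial)
  list(r2 = fit$adj_r2, fit = fit, ses = ses)
}

draw_perms <- function(n_rand, n_pool, seed) {
  with_seed(seed, t(replicate(n_rand, sample.int(n_pool))))
}

#' Scan the functional-phylogenetic blend weight
#'
#' For every `a` on a grid over [0, 1]: blend the functional and
#' phylogenetic distance matrices, compute SES of mean pairwise distance
#' under the tip-shuffling null, fit the Gaussian trend model of SES over
#' exposure year, and record its adjusted R-squared. The selected `a`
#' maximises adjusted R-squared (ties broken toward smaller `a`, the
#' parsimonious functional-only end).
#'
#' One master seed drives the scan. By default a single set of label
#' permutations is drawn once and reused across the whole grid, which
#' removes null-sampling noise from the comparison between `a` values;
#' with `reuse_permutations = FALSE` each grid point draws its own null
#' from a counter-derived sub-seed.
#'
#' @param asm Site-by-species matrix (with `"sites"` metadata) restricted
#'   to assemblages with at least two species.
#' @param func_matrix,phylo_matrix Source distance matrices over the pool.
#' @param grid_step Grid spacing; must divide 1 evenly (default 0.025,
#'   i.e. 41 grid points including 0 and 1).
#' @param p Blend exponent.
#' @param n_rand Randomizations per SES computation.
#' @param seed Master seed.
#' @param reuse_permutations Share one null across the grid (default TRUE).
#' @param k_year,spatial Passed to the trend model.
#' @return Object of class `a_scan`: list with `curve` (data frame `a`,
#'   `adj_r2`), `selected_a`, `selected_r2`, and the scan parameters.
#' @export
scan_a <- function(asm, func_matrix, phylo_matrix, grid_step = 0.025,
                   p = 2, n_rand = 999, seed = 1,
                   reuse_permutations = TRUE, k_year = 10, spatial = TRUE) {
  stop_if_not(abs(1 / grid_step - round(1 / grid_step)) < 1e-9,
              "grid_step must divide 1 evenly")
  grid <- seq(0, 1, by = grid_step)
  S <- nrow(func_matrix)
  base_perms <- if (reuse_permutations) {
    draw_perms(n_rand, S, derive_seed(seed, 1))
  } else NULL
  r2 <- vapply(seq_along(grid), function(i) {
    dist_a <- blend_distances(func_matrix, phylo_matrix, grid[i], p = p)
    perms <- base_perms %||% draw_perms(n_rand, S, derive_seed(seed, 1 + i))
    ses_trend_r2(asm, dist_a, perms, k_year = k_year, spatial = spatial)$r2
  }, numeric(1))
  sel <- which.max(r2)  # first maximum = smallest a on ties
  structure(list(curve = data.frame(a = grid, adj_r2 = r2),
                 selected_a = grid[sel], selected_r2 = r2[sel],
                 grid_step = grid_step, p = p, n_rand = n_rand,
                 seed = seed, reuse_permutations = reuse_permutations),
            class = "a_scan")
}

#' @export
print.a_scan <- function(x, ...) {
  cat(sprintf(
    "Blend-weight scan: %d grid points (step %.3f), %d randomizations\n",
    nrow(x$curve), x$grid_step, x$n_rand))
  cat(sprintf("Selected a = %.3f (adjusted R-squared = %.3f)\n",
              x$selected_a, x$selected_r2))
  invisible(x)
}

#' Flag substantial losses in explanatory power
#'
#' A reduction in adjusted R-squared of at least `threshold` (i.e.
#' `delta_r2 <= -threshold`) marks a trait whose removal substantially
#' degrades the model.
#'
#' @param delta_r2 Vector of (reduced - full) adjusted R-squared changes.
#' @param threshold Reduction threshold (default 0.03).
#' @return Logical vector.
#' @export
substantial_loss <- function(delta_r2, threshold = 0.03) {
  delta_r2 <= -threshold
}

#' Leave-one-trait-out ablation of the SES trend model
#'
#' Quantifies each trait's contribution to the functional-diversity
#' pattern: for every trait, the Gower matrix is recomputed without it
#' (the phylogenetic matrix is untouched), blended at the fixed `a`, the
#' SES trend model refitted, and the change in adjusted R-squared
#' relative to the full model recorded. Reductions of at least
#' `threshold` are flagged as substantial. The full model and every
#' reduced model share the same null permutations (drawn once from the
#' master seed), so differences reflect the trait removal alone.
#'
#' @param asm Site-by-species matrix with `"sites"` metadata.
#' @param traits,schema Trait table and schema (full species pool).
#' @param phylo_matrix Cophenetic distance matrix.
#' @param a Blend weight at which distances are recomputed.
#' @param p Blend exponent.
#' @param n_rand,seed Null-model settings.
#' @param threshold Substantial-loss threshold on the R-squared reduction.
#' @param traits_to_test Traits to ablate (default: all schema traits
#'   present in the table).
#' @param k_year,spatial Passed to the trend model.
#' @return Object of class `trait_ablation`: data frame with `trait`,
#'   `adj_r2`, `delta_r2`, `substantial`; the full-model R-squared is in
#'   attribute `"full_r2"`.
#' @export
ablate_traits <- function(asm, traits, schema, phylo_matrix, a = 0.35,
                          p = 2, n_rand = 999, seed = 1, threshold = 0.03,
                          traits_to_test = NULL, k_year = 10,
                          spatial = TRUE) {
  all_traits <- intersect(schema$trait, names(traits))
  stop_if_not(length(all_traits) >= 2, "need at least two traits to ablate")
  traits_to_test <- traits_to_test %||% all_traits
  S <- nrow(phylo_matrix)
  pool <- rownames(phylo_matrix)
  perms <- draw_perms(n_rand, S, derive_seed(seed, 1))
  run <- function(exclude) {
    g <- gower_distance(traits, schema, exclude_traits = exclude,
                        species = pool)
    dist_a <- blend_distances(g, phylo_matrix, a, p = p)
    ses_trend_r2(asm, dist_a, perms, k_year = k_year, spatial = spatial)$r2
  }
  full_r2 <- run(NULL)
  red <- vapply(traits_to_test, function(tr) run(tr), numeric(1))
  out <- data.frame(trait = traits_to_test, adj_r2 = as.numeric(red),
                    delta_r2 = as.numeric(red) - full_r2)
  out$substantial <- substantial_loss(out$delta_r2, threshold)
  out <- out[order(out$delta_r2), ]
  rownames(out) <- NULL
  structure(out, full_r2 = full_r2, a = a, threshold = threshold,
            class = c("trait_ablation", "data.frame"))
}

#' @export
print.trait_ablation <- function(x, ...) {
  cat(sprintf("Trait ablation at a = %.3f; full-model adjusted R2 = %.3f\n",
              attr(x, "a"), attr(x, "full_r2")))
  df <- as.data.frame(x)
  df$adj_r2 <- round(df$adj_r2, 3)
  df$delta_r2 <- round(df$delta_r2, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
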