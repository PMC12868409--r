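#' Temporal niche position and breadth per species
#'
#' For each species, yearly individual totals (pooled over logs) define an
#' abundance-weighted mean year of emergence
#' `mean = sum(n_y * y) / sum(n_y)` and a weighted standard deviation
#' around it, `sd = sqrt(sum(n_y * (y - mean)^2) / sum(n_y))`, used as a
#' proxy for temporal niche breadth. The SD is population-weighted (no
#' `n - 1` correction): it describes the dispersion of the observed
#' individuals over years, not a sampling-distribution estimate. A display
#' flag marks species with at least `min_individuals_per_year` individuals
#' in some year (the conventional plotting filter); summaries are computed
#' for every species regardless.
#'
#' @param community A `community_table`.
#' @param min_individuals_per_year Display-filter threshold (default 3).
#' @return Data frame of class `niche_summary`, ordered by weighted mean
#'   year: `species_id`, `mean_year`, `sd_year`, `total_individuals`,
#'   `associations` (sorted initials of the tree species the species
#'   emerged from, e.g. `"BFS"`), `display`.
#' @export
niche_summary <- function(community, min_individuals_per_year = 3) {
  stop_if_not(nrow(community) > 0, "empty community table")
  by_sp <- split(community[c("exposure_year", "count", "tree_species")],
                 community$species_id)
  rows <- lapply(names(by_sp), function(sp) {
    d <- by_sp[[sp]]
    ny <- tapply(d$count, d$exposure_year, sum)
    yrs <- as.numeric(names(ny))
    tot <- sum(ny)
    m <- sum(ny * yrs) / tot
    s <- sqrt(sum(ny * (yrs - m)^2) / tot)
    init <- c(beech = "B", fir = "F", spruce = "S")
    data.frame(species_id = sp, mean_year = m, sd_year = s,
               total_individuals = as.numeric(tot),
               associations = paste(sort(unique(
                 init[as.character(d$tree_species)])), collapse = ""),
               display = any(ny >= min_individuals_per_year))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_year, out$species_id), ]
  rownames(out) <- NULL
  class(out) <- c("niche_summary", "data.frame")
  out
}
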