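#' Survey design of a deadwood exposure experiment
#'
#' Describes the experimental layout: one row per deadwood log (identity,
#' tree species, plot membership, projected E/N coordinates in metres, and
#' the calendar year used as exposure origin), plus the calendar years that
#' were sampled and any years in which sampling was skipped. Years since
#' exposure are computed as `calendar_year - exposure_start`, so a
#' tree-species-specific origin (e.g. spruce logs whose first sampling year
#' counts as year 0) is plain data rather than a code path.
#'
#' @param logs Data frame with columns `log_id`, `tree_species` (one of
#'   `"spruce"`, `"fir"`, `"beech"`), `plot_id`, `E`, `N`, `exposure_start`.
#' @param sampling_years Integer vector of calendar years that were sampled.
#' @param missing_years Integer vector of calendar years inside the span of
#'   `sampling_years` in which no sampling took place.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(logs, sampling_years, missing_years = integer()) {
  needed <- c("log_id", "tree_species", "plot_id", "E", "N", "exposure_start")
  stop_if_not(all(needed %in% names(logs)),
              paste("design is missing columns:",
                    paste(setdiff(needed, names(logs)), collapse = ", ")))
  logs$log_id <- as.character(logs$log_id)
  stop_if_not(!anyDuplicated(logs$log_id), "duplicated log_id in design")
  stop_if_not(all(logs$tree_species %in% c("spruce", "fir", "beech")),
              "tree_species must be one of spruce, fir, beech")
  stop_if_not(all(is.finite(logs$E)) && all(is.finite(logs$N)),
              "log coordinates must be finite")
  sampling_years <- sort(unique(as.integer(sampling_years)))
  missing_years <- sort(unique(as.integer(missing_years)))
  if (length(missing_years)) {
    stop_if_not(all(missing_years > min(sampling_years) &
                    missing_years < max(sampling_years)),
                "missing_years must lie within the span of sampling_years")
    stop_if_not(!any(missing_years %in% sampling_years),
                "missing_years cannot also be sampling_years")
  }
  structure(
    list(logs = logs, sampling_years = sampling_years,
         missing_years = missing_years),
    class = "survey_design"
  )
}

#' @export
print.survey_design <- function(x, ...) {
  tab <- table(x$logs$tree_species)
  cat("Survey design:", nrow(x$logs), "logs (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n")
  cat("Sampling years:", min(x$sampling_years), "-", max(x$sampling_years))
  if (length(x$missing_years)) {
    cat(" (no sampling in", paste(x$missing_years, collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}

#' Construct a community table of emergence records
#'
#' Validates and normalises long-format emergence records. Zero counts are
#' dropped, duplicate `(log, year, species)` rows are summed, and each
#' record is annotated with the tree species of its log.
#'
#' @param records Data frame with columns `log_id`, `exposure_year` (integer
#'   years since exposure, >= 0), `species_id`, `count` (positive integer).
#' @param design A [survey_design()]; used to validate log ids and attach
#'   tree species.
#' @return A data frame of class `community_table` with columns `log_id`,
#'   `tree_species`, `exposure_year`, `species_id`, `count`.
#' @export
community_table <- function(records, design) {
  needed <- c("log_id", "exposure_year", "species_id", "count")
  stop_if_not(all(needed %in% names(records)),
              paste("records are missing columns:",
                    paste(setdiff(needed, names(records)), collapse = ", ")))
  records$log_id <- as.character(records$log_id)
  records$species_id <- as.character(records$species_id)
  unknown <- setdiff(records$log_id, design$logs$log_id)
  stop_if_not(length(unknown) == 0,
              paste("unknown log_id:", paste(unknown, collapse = ", ")))
  stop_if_not(all(records$count >= 0), "negative counts are not allowed")
  stop_if_not(all(records$exposure_year >= 0),
              "exposure_year must be >= 0; check exposure_start in the design")
  records <- records[records$count > 0, , drop = FALSE]
  agg <- aggregate(count ~ log_id + exposure_year + species_id,
                   data = records, FUN = sum)
  agg$tree_species <- design$logs$tree_species[
    match(agg$log_id, design$logs$log_id)]
  agg <- agg[order(agg$log_id, agg$exposure_year, agg$species_id),
             c("log_id", "tree_species", "exposure_year", "species_id",
               "count")]
  rownames(agg) <- NULL
  class(agg) <- c("community_table", "data.frame")
  agg
}

#' Read a survey design from CSV
#'
#' @param path CSV with columns `log_id`, `tree_species`, `plot_id`, `E`,
#'   `N`, `exposure_start` and two header-only metadata columns
#'   `sampling_years` / `missing_years` are not expected; sampling years are
#'   supplied separately or inferred from the records.
#' @param sampling_years,missing_years Passed to [survey_design()].
#' @return A `survey_design`.
#' @export
read_design <- function(path, sampling_years, missing_years = integer()) {
  survey_design(read.csv(path), sampling_years, missing_years)
}

#' Read emergence records and a survey design from CSV
#'
#' The records file holds calendar years; years since exposure are derived
#' per log as `calendar_year - exposure_start`. Rows with zero count are
#' dropped and duplicates summed. Rows dated in a year the design marks as
#' unsampled are kept but flagged with a warning, since they indicate a
#' bookkeeping inconsistency rather than impossible data.
#'
#' @param records_path CSV with columns `log_id`, `tree_species` (optional,
#'   checked against the design when present), `calendar_year`,
#'   `species_id`, `count`.
#' @param design_path CSV as in [read_design()].
#' @param sampling_years,missing_years Calendar years; see [survey_design()].
#'   When `sampling_years` is missing it is inferred from the records.
#' @return A list with elements `design` and `community`.
#' @export
read_community <- function(records_path, design_path,
                           sampling_years = NULL,
                           missing_years = integer()) {
  raw <- read.csv(records_path)
  needed <- c("log_id", "calendar_year", "species_id", "count")
  stop_if_not(all(needed %in% names(raw)),
              paste("records are missing columns:",
                    paste(setdiff(needed, names(raw)), collapse = ", ")))
  if (is.null(sampling_years)) {
    sampling_years <- sort(unique(raw$calendar_year))
  }
  design <- read_design(design_path, sampling_years, missing_years)
  raw$log_id <- as.character(raw$log_id)
  unknown <- setdiff(raw$log_id, design$logs$log_id)
  stop_if_not(length(unknown) == 0,
              paste("unknown log_id:", paste(unknown, collapse = ", ")))
  if ("tree_species" %in% names(raw)) {
    expect_sp <- design$logs$tree_species[match(raw$log_id,
                                                design$logs$log_id)]
    stop_if_not(all(raw$tree_species == expect_sp),
                "tree_species in records disagrees with the design")
  }
  if (length(design$missing_years)) {
    bad <- raw$calendar_year %in% design$missing_years & raw$count > 0
    if (any(bad)) {
      warning(sum(bad), " record(s) dated in an unsampled year (",
              paste(intersect(raw$calendar_year[bad], design$missing_years),
                    collapse = ", "), "); kept")
    }
  }
  start <- design$logs$exposure_start[match(raw$log_id, design$logs$log_id)]
  raw$exposure_year <- raw$calendar_year - start
  list(design = design,
       community = community_table(raw, design))
}

#' Write a community table to CSV (calendar-year records)
#'
#' Inverse of [read_community()]: exposure years are mapped back to
#' calendar years using the design, so a write/read round trip is the
#' identity on records.
#'
#' @param community A `community_table`.
#' @param design The matching `survey_design`.
#' @param path Output CSV path.
#' @export
write_community <- function(community, design, path) {
  start <- design$logs$exposure_start[match(community$log_id,
                                            design$logs$log_id)]
  out <- data.frame(log_id = community$log_id,
                    tree_species = community$tree_species,
                    calendar_year = community$exposure_year + start,
                    species_id = community$species_id,
                    count = community$count)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a survey design's log table to CSV
#' @param design A `survey_design`.
#' @param path Output CSV path.
#' @export
write_design <- function(design, path) {
  write.csv(design$logs, path, row.names = FALSE)
  invisible(path)
}

#' Species overlap among tree species
#'
#' Set algebra over the species observed per tree species: per-tree-species
#' species and individual totals, pairwise shared-species counts and the
#' three-way intersection.
#'
#' @param community A `community_table`.
#' @return An object of class `overlap_summary`: list with `per_species`
#'   (data frame of species and individual totals per tree species),
#'   `shared_pairs` (named vector), `shared_all`, `total_species`,
#'   `total_individuals`.
#' @export
summarize_overlap <- function(community) {
  stop_if_not(nrow(community) > 0, "empty community table")
  pools <- split(community$species_id, community$tree_species)
  pools <- lapply(pools, unique)
  inds <- vapply(split(community$count, community$tree_species), sum,
                 numeric(1))
  per <- data.frame(tree_species = names(pools),
                    n_species = vapply(pools, length, integer(1)),
                    n_individuals = as.numeric(inds[names(pools)]),
                    row.names = NULL)
  nm <- names(pools)
  pairs <- utils::combn(nm, min(2L, length(nm)), simplify = FALSE)
  shared_pairs <- numeric(0)
  if (length(nm) >= 2) {
    shared_pairs <- vapply(pairs, function(p) {
      length(intersect(pools[[p[1]]], pools[[p[2]]]))
    }, numeric(1))
    names(shared_pairs) <- vapply(pairs, paste, character(1), collapse = "-")
  }
  shared_all <- length(Reduce(intersect, pools))
  structure(
    list(per_species = per,
         shared_pairs = shared_pairs,
         shared_all = shared_all,
         total_species = length(unique(community$species_id)),
         total_individuals = sum(community$count)),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Species overlap summary\n")
  print(x$per_species, row.names = FALSE)
  if (length(x$shared_pairs)) {
    cat("Shared:", paste(names(x$shared_pairs), x$shared_pairs, sep = " = ",
                         collapse = ", "), "\n")
  }
  cat("Shared by all:", x$shared_all,
      "| total:", x$total_species, "species,",
      x$total_individuals, "individuals\n")
  invisible(x)
}

#' Serialise an overlap summary to JSON
#' @param x An `overlap_summary`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @export
overlap_to_json <- function(x, path = NULL) {
  obj <- list(per_species = x$per_species,
              shared_pairs = as.list(x$shared_pairs),
              shared_all = x$shared_all,
              total_species = x$total_species,
              total_individuals = x$total_individuals)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Site-by-species count matrix of assemblages
#'
#' One row per `(log, exposure_year)` assemblage, filtered to assemblages
#' with at least `min_species` species and with specific
#' `(tree_species, exposure_year)` combinations excluded (e.g. the
#' conifer logs whose first sampling season preceded full exposure).
#'
#' @param community A `community_table`.
#' @param design The matching `survey_design` (supplies coordinates for the
#'   site metadata).
#' @param min_species Minimum species count per assemblage (default 0).
#' @param exclusions Optional data frame with columns `tree_species` and
#'   `exposure_year`; matching assemblages are removed.
#' @return Numeric matrix (sites x species) with row names
#'   `"log_id|exposure_year"` and an attribute `"sites"` holding a data
#'   frame of per-row metadata (`log_id`, `tree_species`, `exposure_year`,
#'   `E`, `N`). A zero-row matrix (with a warning) signals an empty result.
#' @export
assemblage_matrix <- function(community, design, min_species = 0,
                              exclusions = NULL) {
  stop_if_not(min_species >= 0, "min_species must be >= 0")
  key <- paste(community$log_id, community$exposure_year, sep = "|")
  species <- sort(unique(community$species_id))
  sites <- unique(data.frame(key = key,
                             log_id = community$log_id,
                             tree_species = community$tree_species,
                             exposure_year = community$exposure_year,
                             stringsAsFactors = FALSE))
  tab <- stats::xtabs(count ~ key + species_id,
                      data = data.frame(key = key,
                                        species_id = community$species_id,
                                        count = community$count))
  m <- matrix(0, nrow = nrow(sites), ncol = length(species),
              dimnames = list(sites$key, species))
  m[rownames(tab), colnames(tab)] <- as.numeric(tab)
  keep <- rowSums(m > 0) >= min_species
  if (!is.null(exclusions) && nrow(exclusions)) {
    excl_key <- paste(exclusions$tree_species, exclusions$exposure_year)
    keep <- keep & !(paste(sites$tree_species, sites$exposure_year) %in%
                       excl_key)
  }
  m <- m[keep, , drop = FALSE]
  sites <- sites[keep, , drop = FALSE]
  sites$E <- design$logs$E[match(sites$log_id, design$logs$log_id)]
  sites$N <- design$logs$N[match(sites$log_id, design$logs$log_id)]
  rownames(sites) <- NULL
  if (nrow(m) == 0) warning("assemblage_matrix: no assemblage passed the filters")
  attr(m, "sites") <- sites[, c("log_id", "tree_species", "exposure_year",
                                "E", "N")]
  m
}

#' Per-(log, year) abundance and species-number table for trend models
#'
#' Builds the modelling frame for the temporal trend models: one row for
#' every sampled `(log, exposure_year)` combination implied by the design
#' (missing sampling years are absent, not zero-filled), with total
#' abundance and observed species number. Sampled log-years in which no
#' beetle emerged contribute genuine zeros.
#'
#' @param community A `community_table`.
#' @param design The matching `survey_design`.
#' @return Data frame with columns `log_id`, `tree_species` (factor),
#'   `exposure_year`, `E`, `N`, `abundance`, `n_species`.
#' @export
trend_data <- function(community, design) {
  years_ok <- setdiff(design$sampling_years, design$missing_years)
  grid <- do.call(rbind, lapply(seq_len(nrow(design$logs)), function(i) {
    l <- design$logs[i, ]
    data.frame(log_id = l$log_id, tree_species = l$tree_species,
               exposure_year = years_ok - l$exposure_start,
               E = l$E, N = l$N)
  }))
  grid <- grid[grid$exposure_year >= 0, , drop = FALSE]
  key <- paste(grid$log_id, grid$exposure_year, sep = "|")
  ab <- tapply(community$count,
               paste(community$log_id, community$exposure_year, sep = "|"),
               sum)
  ns <- tapply(community$species_id,
               paste(community$log_id, community$exposure_year, sep = "|"),
               function(s) length(unique(s)))
  grid$abundance <- as.numeric(ab[key])
  grid$n_species <- as.numeric(ns[key])
  grid$abundance[is.na(grid$abundance)] <- 0
  grid$n_species[is.na(grid$n_species)] <- 0
  grid$tree_species <- factor(grid$tree_species)
  rownames(grid) <- NULL
  grid
}
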