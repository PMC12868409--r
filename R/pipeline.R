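#' Run the full succession analysis pipeline
#'
#' Orchestrates every stage in analysis order: ingest (or simulate) the
#' community, preprocess traits, build the Gower and cophenetic distance
#' matrices, fit the four temporal trend models (abundance, species
#' number, species richness controlled for abundance, and SES of mean
#' functional-phylogenetic distance) with residual Moran's I checks, scan
#' the blend weight `a`, run the leave-one-trait-out ablation at the
#' selected `a`, analyse composition (assemblage filter, Bray-Curtis,
#' NMDS, conditional inference tree on the first axis, PERMANOVA), and
#' summarise temporal niches. All artifacts can be written as CSV/JSON to
#' `out_dir`, together with a run log recording seeds and parameters.
#'
#' @param input Either a [simulation_config()] (synthetic study) or a list
#'   of paths: `records`, `design`, `traits`, `schema`, `newick`, and
#'   optionally `grafts` (CSV with `species_id`, `relative_id`).
#' @param a_grid_step Grid spacing of the blend-weight scan.
#' @param p Blend exponent.
#' @param n_rand Null-model randomizations per SES computation.
#' @param n_perm PERMANOVA permutations.
#' @param n_starts NMDS random starts.
#' @param seed Master seed for every stochastic stage.
#' @param alpha Split significance level of the inference tree.
#' @param min_species Assemblage filter for the composition and SES stages
#'   (default 4, applied to composition; SES uses >= 2 species).
#' @param min_individuals_per_year Temporal-niche display filter.
#' @param ablation_threshold Substantial-loss threshold on delta R-squared.
#' @param exclude_year0_spruce Exclude spruce year-0 assemblages from the
#'   composition analysis (their first sampling season preceded a full
#'   exposure year; default TRUE).
#' @param k_year,k_space Smooth basis sizes of the trend models.
#' @param out_dir Optional output directory for artifacts.
#' @return List of class `deadwood_pipeline` with elements `design`,
#'   `community`, `overlap`, `trends` (named list of `trend_gam`),
#'   `moran` (named list), `scan`, `ses_trend`, `ablation`, `composition`
#'   (list: `nmds`, `tree`, `permanova`, `sites`), `niche`, `params`.
#' @export
run_pipeline <- function(input,
                         a_grid_step = 0.025, p = 2, n_rand = 999,
                         n_perm = 999, n_starts = 20, seed = 1,
                         alpha = 0.05, min_species = 4,
                         min_individuals_per_year = 3,
                         ablation_threshold = 0.03,
                         exclude_year0_spruce = TRUE,
                         k_year = 10, k_space = 30, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ingest -----------------------------------------------------------------
  ing <- stage("ingest", {
    if (inherits(input, "simulation_config")) {
      simulate_community(input)
    } else {
      rc <- read_community(input$records, input$design)
      tr <- read_traits(input$traits, input$schema)
      phylo <- read_phylogeny(input$newick)
      if (!is.null(input$grafts)) {
        phylo <- graft_all(phylo, read.csv(input$grafts))
      }
      list(design = rc$design, community = rc$community,
           traits = tr$traits, schema = tr$schema, phylo = phylo,
           truth = NULL, config = NULL)
    }
  })
  design <- ing$design; community <- ing$community
  schema <- ing$schema %||% attr(ing$traits, "schema")

  overlap <- stage("overlap", summarize_overlap(community))

  ## distances --------------------------------------------------------------
  traits_pp <- stage("preprocess_traits",
                     preprocess_traits(ing$traits, schema))
  pool <- sort(unique(community$species_id))
  func_d <- stage("gower", {
    g <- gower_distance(traits_pp, schema)
    g[pool, pool]
  })
  phylo_d <- stage("cophenetic", cophenetic_distance(ing$phylo, pool))

  ## trend models -----------------------------------------------------------
  td <- stage("trend_data", trend_data(community, design))
  trends <- list()
  trends$abundance <- stage("abundance_model",
    fit_trend_gam(td, "abundance", family = "nb", k_year = k_year,
                  k_space = k_space))
  trends$n_species <- stage("species_number_model",
    fit_trend_gam(td, "n_species", family = "nb", k_year = k_year,
                  k_space = k_space))
  trends$richness <- stage("richness_model",
    fit_richness_model(td, k_year = k_year, k_space = k_space))
  moran <- lapply(trends, function(f) {
    stage("morans_i", morans_i_residuals(f))
  })

  ## SES + blend-weight scan + ablation ------------------------------------
  asm_ses <- stage("assemblages_ses",
    assemblage_matrix(community, design, min_species = 2))
  scan <- stage("a_scan",
    scan_a(asm_ses, func_d, phylo_d, grid_step = a_grid_step, p = p,
           n_rand = n_rand, seed = derive_seed(seed, 10),
           k_year = k_year))
  ses_final <- stage("ses_trend", {
    dist_a <- blend_distances(func_d, phylo_d, scan$selected_a, p = p)
    perms <- draw_perms(n_rand, nrow(func_d),
                        derive_seed(derive_seed(seed, 10), 1))
    ses_trend_r2(asm_ses, dist_a, perms, k_year = k_year)
  })
  trends$ses <- ses_final$fit
  moran$ses <- stage("morans_i", morans_i_residuals(ses_final$fit))
  ablation <- stage("trait_ablation",
    ablate_traits(asm_ses, traits_pp, schema, phylo_d, a = scan$selected_a,
                  p = p, n_rand = n_rand, seed = derive_seed(seed, 11),
                  threshold = ablation_threshold, k_year = k_year))

  ## composition ------------------------------------------------------------
  composition <- stage("composition", {
    excl <- if (exclude_year0_spruce) {
      data.frame(tree_species = "spruce", exposure_year = 0)
    } else NULL
    asm <- assemblage_matrix(community, design, min_species = min_species,
                             exclusions = excl)
    sites <- attr(asm, "sites")
    d <- bray_curtis(asm)
    ord <- nmds(d, k = 2, n_starts = n_starts,
                seed = derive_seed(seed, 20))
    tree <- inference_tree(ord$scores[, 1], sites$exposure_year,
                           alpha = alpha)
    pmv <- permanova(d, sites[c("tree_species", "exposure_year")],
                     n_perm = n_perm, seed = derive_seed(seed, 21))
    list(sites = sites, nmds = ord, tree = tree, permanova = pmv)
  })

  niche <- stage("temporal_niche",
    niche_summary(community, min_individuals_per_year))

  params <- list(a_grid_step = a_grid_step, p = p, n_rand = n_rand,
                 n_perm = n_perm, n_starts = n_starts, seed = seed,
                 alpha = alpha, min_species = min_species,
                 min_individuals_per_year = min_individuals_per_year,
                 ablation_threshold = ablation_threshold,
                 exclude_year0_spruce = exclude_year0_spruce,
                 k_year = k_year, k_space = k_space)
  res <- structure(
    list(design = design, community = community, overlap = overlap,
         trends = trends, moran = moran, scan = scan,
         ses = ses_final$ses, ablation = ablation,
         composition = composition, niche = niche, truth = ing$truth,
         params = params),
    class = "deadwood_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' Write pipeline artifacts to a directory
#'
#' CSV artifacts: trend predictions, SES table, scan curve, ablation
#' table, ordination scores, PERMANOVA table, niche summary. JSON: overlap
#' summary, split tree, and a run log with parameters and seeds.
#'
#' @param x A `deadwood_pipeline`.
#' @param out_dir Directory (created if needed).
#' @export
write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wp <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  for (nm in names(x$trends)) {
    wp(predict_trend(x$trends[[nm]], years = sort(unique(
      x$trends[[nm]]$data$exposure_year))), paste0("trend_", nm, ".csv"))
  }
  wp(as.data.frame(x$ses), "ses_mfpd.csv")
  wp(x$scan$curve, "a_scan.csv")
  wp(as.data.frame(x$ablation), "trait_ablation.csv")
  wp(cbind(x$composition$sites,
           as.data.frame(x$composition$nmds$scores)), "nmds_scores.csv")
  wp(as.data.frame(x$composition$permanova), "permanova.csv")
  wp(as.data.frame(x$niche), "temporal_niche.csv")
  overlap_to_json(x$overlap, file.path(out_dir, "overlap.json"))
  split_tree_to_json(x$composition$tree, file.path(out_dir, "split_tree.json"))
  log <- list(params = x$params,
              selected_a = x$scan$selected_a,
              nmds_stress = x$composition$nmds$stress,
              r_version = as.character(getRversion()),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.deadwood_pipeline <- function(x, ...) {
  cat("Deadwood succession pipeline\n")
  print(x$design)
  print(x$overlap)
  cat("\nSelected blend weight a =", x$scan$selected_a,
      "(adjusted R2 =", round(x$scan$selected_r2, 3), ")\n")
  cat("Strongest trait (most negative delta R2):", x$ablation$trait[1], "\n")
  cat("NMDS stress:", round(x$composition$nmds$stress, 4), "\n")
  cat("Leaf year groups:",
      paste(vapply(leaf_groups(x$composition$tree), function(g) {
        paste0("{", paste(range(g), collapse = "-"), "}")
      }, character(1)), collapse = " "), "\n")
  invisible(x)
}
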