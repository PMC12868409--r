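#' Configuration of the synthetic community generator
#'
#' Bundles every knob of the generator. Defaults emulate the study
#' conditions of a 12-year deadwood exposure experiment: 10 beech, 10 fir
#' and 10 mixed beech-fir plots plus 12 uprooted spruce logs (52 logs in
#' total), 12 sampling years starting 2013 with no sampling in 2020, a
#' ~300-species pool with a phylogeny and mixed-type traits, an early
#' abundance pulse that decays over exposure time, narrow early temporal
#' niches, host-tree filtering, and a trait-based colonization penalty in
#' the first years after exposure.
#'
#' @param n_species Species-pool size (>= 3).
#' @param seed Master seed; sub-seeds for phylogeny, traits and emergence
#'   are derived deterministically from it.
#' @param n_beech_plots,n_fir_plots,n_mixed_plots,n_spruce_logs Design
#'   constants. Mixed plots carry one beech and one fir log; all other
#'   plots carry a single log.
#' @param start_year First sampled calendar year. Beech and fir logs were
#'   exposed the previous autumn, so their exposure origin is
#'   `start_year - 1` (first sampled year = exposure year 1); spruce logs
#'   were exposed in `start_year` itself (first sampled year = exposure
#'   year 0).
#' @param n_years Number of sampling seasons (calendar span).
#' @param missing_year Calendar year with no sampling (dropped when it
#'   falls outside the interior of the sampled span).
#' @param decay_rate Per-year decline of log expected abundance (the
#'   resource-pulse decay delta).
#' @param gamma Strength of the early trait-based colonization penalty;
#'   `gamma = 0` makes colonization independent of traits.
#' @param early_years Exposure years (<=) in which the penalty acts.
#' @param beta0 Baseline log expected count per species, log and year.
#' @param beta_host Log abundance bonus for species whose host-tree
#'   association matches the log's tree species.
#' @param theta Negative binomial dispersion of the observation noise.
#' @param trait_model `"BM"` (Brownian motion / Markov evolution on the
#'   tree, giving phylogenetic signal) or `"white"` (iid traits).
#' @param bm_rate Brownian rate (variance per unit branch length) of the
#'   continuous traits; 0 collapses every species to the root value.
#' @param trait_factor_loading Loading of tree-free (`"white"`) continuous
#'   traits on a shared latent species axis, reproducing the correlated
#'   size/shape syndromes of real morphology (0 gives iid traits).
#' @param cat_rate Transition rate of the Markov model for categorical
#'   traits; very large rates decouple states from the tree.
#' @param filter_basis `"traits"` (penalty from Gower distance to an
#'   early-specialist optimum in trait space) or `"phylogeny"` (penalty
#'   from rescaled cophenetic distance to an anchor tip).
#' @param filter_traits Traits the penalty distance is computed over
#'   (default: all traits).
#' @param flat_niche If `TRUE` the Gaussian temporal niche kernel is
#'   replaced by a constant (species emerge uniformly over years).
#' @param niche_mean_range Range of species temporal niche centres
#'   (exposure years).
#' @param niche_breadth_base,niche_breadth_slope Species niche breadth
#'   `sigma_s = base + slope * (mu_s - min)`: early species have narrow
#'   temporal niches, late species broad ones.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 300, seed = 1,
                              n_beech_plots = 10, n_fir_plots = 10,
                              n_mixed_plots = 10, n_spruce_logs = 12,
                              start_year = 2013, n_years = 12,
                              missing_year = 2020,
                              decay_rate = 0.35, gamma = 12,
                              early_years = 3, beta0 = -2, beta_host = 2.5,
                              theta = 1,
                              trait_model = c("BM", "white"), bm_rate = 1,
                              trait_factor_loading = 0.6, cat_rate = 0.3,
                              filter_basis = c("traits", "phylogeny"),
                              filter_traits = NULL,
                              flat_niche = FALSE,
                              niche_mean_range = c(1, 12),
                              niche_breadth_base = 0.5,
                              niche_breadth_slope = 0.15) {
  stop_if_not(n_species >= 3, "n_species must be >= 3")
  stop_if_not(gamma >= 0, "gamma must be >= 0")
  stop_if_not(all(is.finite(c(decay_rate, beta0, beta_host, theta))),
              "rates must be finite")
  cfg <- list(n_species = n_species, seed = as.integer(seed),
              n_beech_plots = n_beech_plots, n_fir_plots = n_fir_plots,
              n_mixed_plots = n_mixed_plots, n_spruce_logs = n_spruce_logs,
              start_year = start_year, n_years = n_years,
              missing_year = missing_year,
              decay_rate = decay_rate, gamma = gamma,
              early_years = early_years, beta0 = beta0,
              beta_host = beta_host, theta = theta,
              trait_model = match.arg(trait_model), bm_rate = bm_rate,
              trait_factor_loading = trait_factor_loading,
              cat_rate = cat_rate,
              filter_basis = match.arg(filter_basis),
              filter_traits = filter_traits,
              flat_niche = flat_niche,
              niche_mean_range = niche_mean_range,
              niche_breadth_base = niche_breadth_base,
              niche_breadth_slope = niche_breadth_slope)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a species-pool phylogeny
#'
#' Random rooted binary tree with positive branch lengths and uniquely
#' labelled tips (`sp001`, `sp002`, ...), via [ape::rtree()].
#'
#' @param n_species Number of tips (>= 3).
#' @param seed Integer seed; the same seed reproduces the same tree.
#' @return A `phylo` object.
#' @export
simulate_phylogeny <- function(n_species, seed = 1) {
  stop_if_not(n_species >= 3, "n_species must be >= 3")
  with_seed(seed, {
    tr <- ape::rtree(n_species,
                     tip.label = sprintf("sp%03d", seq_len(n_species)))
    # guard against zero-length branches from the uniform draw
    tr$edge.length <- pmax(tr$edge.length, 1e-6)
    tr
  })
}

# One continuous trait: Brownian motion on the tree (phylogenetic signal
# scales with bm_rate) or tree-free noise sharing a latent species axis.
# Under the tree-free model each trait loads on a common factor `u`
# (loading `trait_factor_loading`), mimicking the correlated size/shape
# syndromes of real beetle morphology; under BM the shared tree plays
# that role.
sim_cont_trait <- function(phylo, config, u = NULL) {
  if (config$trait_model == "BM") {
    ape::rTraitCont(phylo, model = "BM", sigma = sqrt(config$bm_rate))
  } else {
    w <- config$trait_factor_loading %||% 0.6
    n <- length(phylo$tip.label)
    if (is.null(u)) u <- rep(0, n)
    setNames(w * u + sqrt(1 - w^2) * rnorm(n), phylo$tip.label)
  }
}

# One categorical trait: Markov (ER) evolution on the tree or iid states.
sim_cat_trait <- function(phylo, config, states) {
  if (config$trait_model == "BM" && config$cat_rate > 0) {
    x <- ape::rTraitDisc(phylo, model = "ER", k = length(states),
                         rate = config$cat_rate, states = states)
    factor(as.character(x), levels = states)
  } else {
    factor(sample(states, length(phylo$tip.label), replace = TRUE),
           levels = states)
  }
}

# Ordinal class trait derived from a latent continuous trait.
cut_ordinal <- function(z, levels) {
  if (sd(z) == 0) {
    return(ordered(rep(levels[1], length(z)), levels = levels))
  }
  br <- unique(quantile(z, probs = seq(0, 1, length.out = length(levels) + 1)))
  if (length(br) < 3) {
    return(ordered(rep(levels[1], length(z)), levels = levels))
  }
  cls <- cut(z, breaks = br, include.lowest = TRUE, labels = FALSE)
  ordered(levels[cls], levels = levels)
}

#' Simulate a mixed-type trait table on a phylogeny
#'
#' Generates the 13 morphological + 4 ecological traits of the default
#' schema. Continuous traits evolve by Brownian motion on the tree (or are
#' iid under `trait_model = "white"`); size traits are positive
#' (log-normal on the BM scale) and appendage lengths co-vary with body
#' length, so realistic body-size correlations arise. Categorical traits
#' follow a symmetric Markov model on the tree.
#'
#' @param phylo Species-pool phylogeny; tips define the species ids.
#' @param config A [simulation_config()].
#' @return Data frame with `species_id` plus the trait columns of
#'   [default_trait_schema()]; the schema is attached as attribute
#'   `"schema"`.
#' @export
simulate_traits <- function(phylo, config) {
  with_seed(derive_seed(config$seed, 2), {
    n <- length(phylo$tip.label)
    u <- rnorm(n)  # latent axis shared by tree-free continuous traits
    z <- replicate(12, sim_cont_trait(phylo, config, u), simplify = FALSE)
    body_length <- exp(1 + 0.5 * z[[1]])
    traits <- data.frame(
      species_id = phylo$tip.label,
      body_length = body_length,
      body_width = exp(0.2 + 0.4 * z[[2]]),
      body_roundness = z[[3]],
      head_length = 0.2 * body_length^0.9 * exp(0.15 * z[[4]]),
      wing_length = 0.8 * body_length * exp(0.2 * z[[5]]),
      wing_aspect = z[[6]],
      wing_load = exp(0.3 * z[[7]]),
      leg_length = 0.5 * body_length^0.8 * exp(0.2 * z[[8]]),
      antenna_length = 0.4 * body_length^0.7 * exp(0.25 * z[[9]]),
      eye_length = 0.1 * body_length^0.5 * exp(0.2 * z[[10]]),
      mandibular_aspect = z[[11]],
      hairiness = cut_ordinal(z[[12]],
                              c("glabrous", "sparse", "moderate", "dense")),
      colour = sim_cat_trait(phylo, config,
                             c("dark", "brown", "red", "patterned")),
      decay_niche = ordered(
        sim_cat_trait(phylo, config, c("early", "mid", "late")),
        levels = c("early", "mid", "late")),
      wood_diameter_niche = ordered(
        sim_cat_trait(phylo, config, c("small", "medium", "large")),
        levels = c("small", "medium", "large")),
      feeding_type = sim_cat_trait(
        phylo, config, c("xylophagous", "mycetophagous", "predatory")),
      host_tree = sim_cat_trait(phylo, config,
                                c("conifer", "broadleaf", "both")),
      row.names = NULL
    )
    attr(traits, "schema") <- default_trait_schema()
    traits
  })
}

# Build the experimental layout implied by the design constants.
build_design <- function(config) {
  plots <- c(sprintf("B%02d", seq_len(config$n_beech_plots)),
             sprintf("F%02d", seq_len(config$n_fir_plots)),
             sprintf("M%02d", seq_len(config$n_mixed_plots)),
             sprintf("S%02d", seq_len(config$n_spruce_logs)))
  ncol_grid <- ceiling(sqrt(length(plots)))
  px <- 150 * ((seq_along(plots) - 1) %% ncol_grid) + runif(length(plots), 0, 40)
  py <- 150 * ((seq_along(plots) - 1) %/% ncol_grid) + runif(length(plots), 0, 40)
  names(px) <- names(py) <- plots
  one <- function(plot, sp, start) {
    data.frame(log_id = paste(plot, sp, sep = "_"), tree_species = sp,
               plot_id = plot, E = px[plot], N = py[plot],
               exposure_start = start)
  }
  b_start <- config$start_year - 1  # beech/fir exposed the previous autumn
  s_start <- config$start_year
  logs <- rbind(
    do.call(rbind, lapply(sprintf("B%02d", seq_len(config$n_beech_plots)),
                          one, sp = "beech", start = b_start)),
    do.call(rbind, lapply(sprintf("F%02d", seq_len(config$n_fir_plots)),
                          one, sp = "fir", start = b_start)),
    do.call(rbind, lapply(sprintf("M%02d", seq_len(config$n_mixed_plots)),
                          function(p) rbind(one(p, "beech", b_start),
                                            one(p, "fir", b_start)))),
    do.call(rbind, lapply(sprintf("S%02d", seq_len(config$n_spruce_logs)),
                          one, sp = "spruce", start = s_start))
  )
  years <- config$start_year:(config$start_year + config$n_years - 1)
  missing <- intersect(config$missing_year,
                       years[-c(1, length(years))])
  survey_design(logs, setdiff(years, missing), missing)
}

# The early-specialist optimum: peripheral in the distance space (extreme
# phenotype or isolated lineage, as real early-decay specialists are) but
# sitting at the edge of a populated region, so that a guild of similar
# species exists to be filtered in. Among the quartile of species with
# the largest mean distance to the pool, pick the one whose nearest
# neighbours are closest.
pick_optimum <- function(D, k = 10) {
  per <- rowMeans(D)
  cand <- which(per >= quantile(per, 0.75))
  k <- min(k, nrow(D) - 1)
  knn <- vapply(cand, function(i) mean(sort(D[i, -i])[seq_len(k)]),
                numeric(1))
  rownames(D)[cand[which.min(knn)]]
}

# Early-specialist penalty distance per species: Gower distance in trait
# space, or max-rescaled cophenetic distance to the anchor tip.
filter_distance <- function(phylo, traits, config, mu) {
  if (config$filter_basis == "traits") {
    schema <- attr(traits, "schema") %||% default_trait_schema()
    excl <- if (is.null(config$filter_traits)) NULL else
      setdiff(intersect(schema$trait, names(traits)), config$filter_traits)
    g <- gower_distance(traits, schema, exclude_traits = excl)
    opt <- pick_optimum(g)
    d <- g[traits$species_id, opt]
  } else {
    cp <- cophenetic_distance(phylo, traits$species_id)
    opt <- pick_optimum(cp)
    d <- cp[traits$species_id, opt] / max(cp)
  }
  list(d = setNames(as.numeric(d), traits$species_id), optimum = opt)
}

#' Simulate emergence records with known ground truth
#'
#' Expected count of species s on log l in exposure year t:
#' \deqn{\lambda = \exp(\beta_0 + \beta_h \,\mathrm{match}(s,l) - \delta t)
#'   \; K_s(t) \; f_s(t)}
#' where `match` indicates host-tree compatibility, `K_s(t) =
#' exp(-(t - mu_s)^2 / (2 sigma_s^2))` is the Gaussian temporal niche
#' kernel (so the generator's abundance-weighted niche mean and SD are
#' analytically known), and `f_s(t) = exp(-gamma d_s^2)` for
#' `t <= early_years` down-weights species far from the early-specialist
#' optimum. Counts are negative binomial with dispersion `theta`.
#'
#' @param phylo Species-pool phylogeny.
#' @param traits Trait table from [simulate_traits()].
#' @param config A [simulation_config()].
#' @return List with `design` (a `survey_design`), `community` (a
#'   `community_table`) and `truth` (all generating parameters: `mu`,
#'   `sigma`, `filter_distance`, `optimum_species`, and the scalar rates).
#' @export
simulate_emergence <- function(phylo, traits, config) {
  with_seed(derive_seed(config$seed, 3), {
    design <- build_design(config)
    sp <- traits$species_id
    n <- length(sp)
    mu <- setNames(runif(n, config$niche_mean_range[1],
                         config$niche_mean_range[2]), sp)
    sigma <- config$niche_breadth_base +
      config$niche_breadth_slope * (mu - config$niche_mean_range[1])
    fd <- if (config$gamma > 0) {
      filter_distance(phylo, traits, config, mu)
    } else {
      list(d = setNames(rep(0, n), sp), optimum = NA_character_)
    }

    # species x log host-match bonus
    host <- as.character(traits$host_tree)
    logsp <- design$logs$tree_species
    match_m <- outer(host, logsp, function(h, l) {
      as.numeric(h == "both" | (h == "conifer" & l %in% c("spruce", "fir")) |
                   (h == "broadleaf" & l == "beech"))
    })

    # sampled (log, year) combinations
    years_ok <- setdiff(design$sampling_years, design$missing_years)
    ly <- do.call(rbind, lapply(seq_len(nrow(design$logs)), function(i) {
      t <- years_ok - design$logs$exposure_start[i]
      t <- t[t >= 0]
      data.frame(log = i, t = t)
    }))

    tmax <- max(ly$t)
    tgrid <- 0:tmax
    K <- if (config$flat_niche) {
      matrix(1, n, length(tgrid))
    } else {
      exp(-outer(mu, tgrid, "-")^2 / (2 * sigma^2))
    }
    Fm <- matrix(1, n, length(tgrid))
    early <- tgrid <= config$early_years
    Fm[, early] <- exp(-config$gamma * fd$d^2)

    lam <- exp(config$beta0) *
      exp(config$beta_host * match_m[, ly$log, drop = FALSE]) *
      K[, ly$t + 1, drop = FALSE] * Fm[, ly$t + 1, drop = FALSE] *
      matrix(exp(-config$decay_rate * ly$t), nrow = n, ncol = nrow(ly),
             byrow = TRUE)
    cnt <- matrix(rnbinom(length(lam), mu = lam, size = config$theta),
                  nrow = n)
    idx <- which(cnt > 0, arr.ind = TRUE)
    records <- data.frame(
      log_id = design$logs$log_id[ly$log[idx[, 2]]],
      exposure_year = ly$t[idx[, 2]],
      species_id = sp[idx[, 1]],
      count = cnt[idx]
    )
    truth <- list(mu = mu, sigma = sigma,
                  decay_rate = config$decay_rate, gamma = config$gamma,
                  early_years = config$early_years,
                  beta0 = config$beta0, beta_host = config$beta_host,
                  theta = config$theta,
                  filter_distance = fd$d, optimum_species = fd$optimum,
                  filter_basis = config$filter_basis)
    list(design = design,
         community = community_table(records, design),
         truth = truth)
  })
}

#' Simulate a full synthetic study (phylogeny, traits, emergence)
#'
#' @param config A [simulation_config()].
#' @return List with `phylo`, `traits`, `schema`, `design`, `community`,
#'   `truth`, `config`.
#' @export
simulate_community <- function(config = simulation_config()) {
  phylo <- simulate_phylogeny(config$n_species, seed = config$seed)
  traits <- simulate_traits(phylo, config)
  em <- simulate_emergence(phylo, traits, config)
  c(list(phylo = phylo, traits = traits,
         schema = attr(traits, "schema"), config = config), em)
}
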