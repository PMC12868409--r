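test_that("simulated phylogeny has the right shape and is reproducible", {
  tr <- simulate_phylogeny(3, seed = 1)
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(simulate_phylogeny(20, seed = 9)),
                   ape::write.tree(simulate_phylogeny(20, seed = 9)))
  expect_false(identical(ape::write.tree(simulate_phylogeny(20, seed = 9)),
                         ape::write.tree(simulate_phylogeny(20, seed = 10))))
  expect_error(simulate_phylogeny(2), "n_species")
})

test_that("cophenetic distances on a simulated tree form a metric", {
  tr <- simulate_phylogeny(50, seed = 3)
  d <- cophenetic_distance(tr)
  expect_true(all(d >= 0))
  expect_equal(d, t(d))
  set.seed(1)
  for (k in 1:2000) {
    ijk <- sample(50, 3)
    expect_lte(d[ijk[1], ijk[2]],
               d[ijk[1], ijk[3]] + d[ijk[3], ijk[2]] + 1e-12)
  }
})

test_that("zero Brownian rate collapses continuous traits to the root value", {
  tr <- simulate_phylogeny(10, seed = 2)
  cfg <- simulation_config(n_species = 10, seed = 2, bm_rate = 0,
                           cat_rate = 0)
  tt <- simulate_traits(tr, cfg)
  expect_equal(sd(tt$body_length), 0)
  expect_equal(sd(tt$wing_aspect), 0)
})

test_that("Brownian traits diverge more across deep splits than shallow ones", {
  # two cherries at the tips of a deep split: (A,B) vs (C,D)
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):5,(C:0.1,D:0.1):5);")
  cfg <- simulation_config(n_species = 4, seed = 1, trait_model = "BM",
                           bm_rate = 1)
  d_sis <- d_far <- numeric(500)
  for (r in 1:500) {
    cfg$seed <- r
    tt <- simulate_traits(tr, cfg)
    z <- tt$wing_aspect  # raw Brownian trait
    d_sis[r] <- (z[tt$species_id == "A"] - z[tt$species_id == "B"])^2
    d_far[r] <- (z[tt$species_id == "A"] - z[tt$species_id == "C"])^2
  }
  # E[(zA-zB)^2] = 0.2 vs E[(zA-zC)^2] = 10.2
  expect_gt(mean(d_far), 5 * mean(d_sis))
})

test_that("fast Markov evolution decouples categorical states from the tree", {
  tr <- simulate_phylogeny(120, seed = 5)
  cfg <- simulation_config(n_species = 120, seed = 5, cat_rate = 500)
  tt <- simulate_traits(tr, cfg)
  # split tips into the two basal clades; state frequencies should agree
  root_children <- tr$edge[tr$edge[, 1] == 121, 2]
  clade1 <- ape::extract.clade(tr, root_children[root_children > 120][1])$tip.label
  grp <- tt$species_id %in% clade1
  suppressWarnings(p <- stats::chisq.test(table(grp, tt$host_tree))$p.value)
  expect_gt(p, 0.001)
})

test_that("default design constants yield 52 logs and skip one interior year", {
  cfg <- simulation_config(n_species = 10, seed = 1)
  sim <- simulate_emergence(simulate_phylogeny(10, 1),
                            simulate_traits(simulate_phylogeny(10, 1), cfg),
                            cfg)
  expect_equal(nrow(sim$design$logs), 52)
  expect_equal(sim$design$missing_years, 2020)
  expect_false(2020 %in% sim$design$sampling_years)
  # spruce first sampled season is exposure year 0; beech/fir year 1
  td <- trend_data(sim$community, sim$design)
  expect_equal(min(td$exposure_year[td$tree_species == "spruce"]), 0)
  expect_equal(min(td$exposure_year[td$tree_species == "beech"]), 1)
})

test_that("emergence is deterministic under a fixed seed and integer-valued", {
  cfg <- simulation_config(n_species = 30, seed = 11, n_beech_plots = 2,
                           n_fir_plots = 2, n_mixed_plots = 2,
                           n_spruce_logs = 2, n_years = 6)
  a <- simulate_community(cfg)
  b <- simulate_community(cfg)
  expect_identical(as.data.frame(a$community), as.data.frame(b$community))
  expect_true(all(a$community$count == round(a$community$count)))
  expect_true(all(a$community$count >= 1))
})

test_that("the generator recovers its own abundance decay rate", {
  cfg <- simulation_config(n_species = 150, seed = 21, decay_rate = 0.3,
                           gamma = 0, flat_niche = TRUE, beta0 = -1.5)
  sim <- simulate_community(cfg)
  td <- trend_data(sim$community, sim$design)
  tot <- aggregate(abundance ~ exposure_year, td[td$exposure_year >= 1, ], sum)
  fit <- lm(log(abundance) ~ exposure_year, tot)
  est <- coef(summary(fit))["exposure_year", ]
  expect_lt(abs(est["Estimate"] + 0.3), 2 * est["Std. Error"])
})

test_that("strong early filtering lowers early trait dispersion", {
  base <- list(n_species = 60, seed = 31, n_beech_plots = 3, n_fir_plots = 3,
               n_mixed_plots = 3, n_spruce_logs = 4, n_years = 6,
               trait_model = "white", flat_niche = TRUE, decay_rate = 0)
  cfg0 <- do.call(simulation_config, c(base, gamma = 0))
  cfg1 <- do.call(simulation_config, c(base, gamma = 10))
  mean_early_mpd <- function(cfg) {
    sim <- simulate_community(cfg)
    g <- gower_distance(preprocess_traits(sim$traits, sim$schema),
                        sim$schema)
    asm <- assemblage_matrix(sim$community, sim$design, min_species = 2)
    sites <- attr(asm, "sites")
    early <- sites$exposure_year <= 1
    mean(vapply(which(early), function(i) {
      mean_pairwise_distance(colnames(asm)[asm[i, ] > 0], g)
    }, numeric(1)))
  }
  expect_lt(mean_early_mpd(cfg1), mean_early_mpd(cfg0))
})
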