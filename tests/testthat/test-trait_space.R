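schema2 <- function(traits, types = NULL) {
  # minimal schema for ad-hoc trait tables
  tr <- setdiff(names(traits), "species_id")
  data.frame(trait = tr,
             type = types %||% rep("continuous", length(tr)),
             standardize_by_body_length = FALSE, log_transform = FALSE,
             levels = NA_character_)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("preprocessing standardizes by body length, then logs", {
  sch <- data.frame(
    trait = c("body_length", "wing_length", "wing_load"),
    type = "continuous",
    standardize_by_body_length = c(FALSE, TRUE, TRUE),
    log_transform = c(FALSE, FALSE, TRUE),
    levels = NA_character_)
  tt <- data.frame(species_id = c("a", "b"),
                   body_length = c(2, 4),
                   wing_length = c(4, 4),
                   wing_load = c(2, 1))
  out <- preprocess_traits(tt, sch)
  expect_equal(out$wing_length, c(2, 1))        # simple division
  # both flags: standardize first, then natural log
  expect_equal(out$wing_load, log(c(2, 1) / c(2, 4)))
  expect_equal(preprocess_traits(
    data.frame(species_id = "a", body_length = 1, wing_length = 1,
               wing_load = 1), sch)$wing_load, 0)  # log(1) = 0
  bad <- data.frame(species_id = "a", body_length = 2, wing_length = 1,
                    wing_load = -1)
  expect_error(preprocess_traits(bad, sch), "non-positive")
})

test_that("VIF matches its closed form and flags perfect collinearity", {
  set.seed(1)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)            # orthogonal pair
  tt <- data.frame(species_id = paste0("s", 1:n), t1 = x1, t2 = x2)
  rep1 <- trait_correlations(tt, schema2(tt))
  expect_true(all(abs(rep1$vif - 1) < 0.1))
  expect_true(all(rep1$vif >= 1))

  # population correlation 0.8 -> VIF = 1 / (1 - 0.64) = 2.78
  y <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)
  tt2 <- data.frame(species_id = paste0("s", 1:n), t1 = x1, t2 = y)
  rep2 <- trait_correlations(tt2, schema2(tt2))
  expect_true(all(abs(rep2$vif - 1 / (1 - 0.64)) < 0.4))

  # duplicated trait -> infinite VIF, flagged above threshold
  tt3 <- data.frame(species_id = paste0("s", 1:n), t1 = x1, t2 = x1,
                    t3 = x2)
  rep3 <- trait_correlations(tt3, schema2(tt3))
  expect_true(all(c("t1", "t2") %in% rep3$flagged))

  # constant trait excluded with a flag, r symmetric with unit diagonal
  tt4 <- data.frame(species_id = paste0("s", 1:n), t1 = x1, t2 = x2,
                    t3 = 1)
  rep4 <- trait_correlations(tt4, schema2(tt4))
  expect_equal(rep4$excluded, "t3")
  expect_equal(rep4$r, t(rep4$r))
  expect_equal(unname(diag(rep4$r)), c(1, 1))
})

test_that("VIF equals the correlation-matrix inverse diagonal", {
  set.seed(7)
  x <- matrix(rnorm(200 * 5), 200, 5) %*% matrix(runif(25, -1, 1), 5)
  tt <- cbind(data.frame(species_id = paste0("s", 1:200)),
              as.data.frame(x))
  names(tt)[-1] <- paste0("t", 1:5)
  rep <- trait_correlations(tt, schema2(tt))
  expect_equal(unname(rep$vif), unname(diag(solve(rep$r))),
               tolerance = 1e-8)
})

test_that("Gower distance handles degenerate and hand-worked cases", {
  types <- c(c1 = "continuous", c2 = "continuous", k = "categorical")
  tt <- data.frame(species_id = c("A", "B", "C", "D"),
                   c1 = c(0, 1, 2, 4),
                   c2 = c(10, 10, 20, 20),
                   k = c("x", "x", "y", "x"))
  sch <- schema2(tt, types = unname(types[c("c1", "c2", "k")]))
  d <- gower_distance(tt, sch)
  # per-trait contributions: |dx|/4, |dy|/10, and 0/1 matching, averaged
  expect_equal(d["A", "B"], (0.25 + 0 + 0) / 3)
  expect_equal(d["A", "C"], (0.5 + 1 + 1) / 3)
  expect_equal(d["A", "D"], (1 + 1 + 0) / 3)
  expect_equal(d["B", "C"], (0.25 + 1 + 1) / 3)
  expect_equal(d["B", "D"], (0.75 + 1 + 0) / 3)
  expect_equal(d["C", "D"], (0.5 + 0 + 1) / 3)
  expect_equal(unname(diag(d)), rep(0, 4))

  # identical trait vectors -> 0; one categorical of two differing -> 0.5
  t2 <- data.frame(species_id = c("a", "b"), k1 = c("x", "x"),
                   k2 = c("u", "v"))
  d2 <- gower_distance(t2, schema2(t2, types = c("categorical",
                                                 "categorical")))
  expect_equal(d2["a", "b"], 0.5)
  t3 <- data.frame(species_id = c("a", "b"), k1 = c("x", "x"),
                   k2 = c("u", "u"))
  expect_equal(gower_distance(t3, schema2(t3, c("categorical",
                                                "categorical")))["a", "b"], 0)
})

test_that("Gower agrees with an independent oracle on random mixed tables", {
  set.seed(3)
  for (r in 1:5) {
    n <- 8
    tt <- data.frame(species_id = paste0("s", 1:n),
                     c1 = rnorm(n), c2 = runif(n),
                     o1 = sample(c("lo", "mid", "hi"), n, replace = TRUE),
                     k1 = sample(c("p", "q"), n, replace = TRUE))
    sch <- schema2(tt, types = c("continuous", "continuous", "ordinal",
                                 "categorical"))
    sch$levels[sch$trait == "o1"] <- "lo|mid|hi"
    d <- gower_distance(tt, sch)
    types <- c(c1 = "continuous", c2 = "continuous", o1 = "ordinal",
               k1 = "categorical")
    df <- tt[-1]
    df$o1 <- ordered(df$o1, levels = c("lo", "mid", "hi"))
    rownames(df) <- tt$species_id
    expect_equal(d, gower_oracle(df, types), tolerance = 1e-10)
  }
})

test_that("Gower invariances: bounds, affine rescaling, trait-removal bound", {
  sim <- small_sim()
  sch <- sim$schema
  tt <- preprocess_traits(sim$traits, sch)
  d <- gower_distance(tt, sch)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  # affine rescaling of a continuous trait leaves distances unchanged
  tt2 <- tt
  tt2$wing_aspect <- -3 * tt2$wing_aspect + 7
  expect_equal(gower_distance(tt2, sch), d, tolerance = 1e-12)
  # dropping one of k traits moves the mean-over-traits distance by at
  # most 1/(k - 1)
  k <- sum(sch$trait %in% names(tt))
  d_red <- gower_distance(tt, sch, exclude_traits = "host_tree")
  expect_lte(max(abs(d_red - d)), 1 / (k - 1) + 1e-12)
})
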