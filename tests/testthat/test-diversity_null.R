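rand_dist <- function(n, seed = 1, prefix = "s") {
  set.seed(seed)
  d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  dimnames(d) <- list(paste0(prefix, seq_len(n)), paste0(prefix, seq_len(n)))
  d
}

test_that("blend endpoints reproduce the rescaled source matrices exactly", {
  Fm <- rand_dist(6, 1)
  Pm <- rand_dist(6, 2)
  b0 <- blend_distances(Fm, Pm, a = 0)
  b1 <- blend_distances(Fm, Pm, a = 1)
  expect_equal(unclass(b0), Fm / max(Fm), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unclass(b1), Pm / max(Pm), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(b0 >= 0 & b0 <= 1) && all(b1 >= 0 & b1 <= 1))
})

test_that("intermediate blends follow the p-norm closed form", {
  Fm <- matrix(c(0, 0.8, 0.8, 0), 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  Pm <- matrix(c(0, 0.6, 0.6, 0), 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  b <- blend_distances(Fm, Pm, a = 0.5, p = 2, rescale = FALSE)
  expect_equal(b["x", "y"], sqrt(0.5 * 0.36 + 0.5 * 0.64))  # ~0.7071
  # monotone in a when P > F and vice versa
  Fm6 <- rand_dist(6, 3); Pm6 <- rand_dist(6, 4)
  grid <- seq(0, 1, 0.1)
  vals <- sapply(grid, function(a) {
    blend_distances(Fm6, Pm6, a)[2, 5]
  })
  Pr <- (Pm6 / max(Pm6))[2, 5]; Fr <- (Fm6 / max(Fm6))[2, 5]
  expect_true(all(diff(vals) > 0) == (Pr > Fr) ||
                all(diff(vals) < 0) == (Pr < Fr))
  expect_error(blend_distances(Fm, rand_dist(3, 1), 0.5), "same species")
  expect_error(blend_distances(Fm * 0, Pm, 0.5), "all-zero")
})

test_that("mean pairwise distance equals explicit pair enumeration", {
  D <- rand_dist(8, 5)
  expect_equal(mean_pairwise_distance(c("s1", "s2"), D), D["s1", "s2"])
  D3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  D3["a", "b"] <- D3["b", "a"] <- 0.2
  D3["a", "c"] <- D3["c", "a"] <- 0.4
  D3["b", "c"] <- D3["c", "b"] <- 0.6
  expect_equal(mean_pairwise_distance(letters[1:3], D3), 0.4)
  sp <- paste0("s", c(1, 3, 4, 6, 8))
  expect_equal(mean_pairwise_distance(sp, D), mpd_oracle(sp, D))
  expect_true(is.na(mean_pairwise_distance("s1", D)))
})

test_that("SES matches the exhaustive label-permutation null on a 4-species pool", {
  D <- rand_dist(4, 9)
  asm <- matrix(c(1, 1, 1, 0), 1, 4, dimnames = list("a1", rownames(D)))
  all_perms <- perms_all(4)
  got <- ses_mpd(asm, D, perms = all_perms)
  # oracle: relabel the pool under every permutation, recompute MPD
  null <- apply(all_perms, 1, function(idx) {
    relabel <- setNames(rownames(D)[idx], rownames(D))
    # assemblage {s1,s2,s3} under permuted labels
    mpd_oracle(names(relabel)[relabel %in% c("s1", "s2", "s3")], D)
  })
  expect_equal(got$mpd_obs, mpd_oracle(c("s1", "s2", "s3"), D))
  expect_equal(got$null_mean, mean(null))
  expect_equal(got$null_sd, sd(null))
  expect_equal(got$ses, (got$mpd_obs - mean(null)) / sd(null))
})

test_that("an assemblage equal to the whole pool has a degenerate null", {
  D <- rand_dist(5, 2)
  asm <- matrix(1, 1, 5, dimnames = list("all", rownames(D)))
  got <- ses_mpd(asm, D, n_rand = 50, seed = 1)
  expect_equal(got$null_sd, 0)
  expect_true(is.na(got$ses))
  # fewer than two species: missing SES, flagged not dropped
  asm2 <- rbind(asm, one = c(1, 0, 0, 0, 0))
  got2 <- ses_mpd(asm2, D, n_rand = 20, seed = 1)
  expect_true(is.na(got2$ses[2]) && is.na(got2$mpd_obs[2]))
})

test_that("SES is invariant under global rescaling of the distance matrix", {
  D <- rand_dist(10, 4)
  set.seed(8)
  asm <- matrix(rbinom(50, 1, 0.5), 5, 10,
                dimnames = list(paste0("a", 1:5), rownames(D)))
  s1 <- ses_mpd(asm, D, n_rand = 99, seed = 7)
  s2 <- ses_mpd(asm, D * 37.5, n_rand = 99, seed = 7)
  expect_equal(s1$ses, s2$ses, tolerance = 1e-10)
  # tip shuffling preserves the distance multiset
  idx <- sample(10)
  expect_equal(sort(D[idx, idx][lower.tri(D)]), sort(D[lower.tri(D)]))
})

test_that("observed MPD and null moments agree with picante's ses.mpd", {
  skip_if_not_installed("picante")
  D <- rand_dist(20, 11)
  set.seed(12)
  comm <- matrix(rbinom(120, 1, 0.4), 6, 20,
                 dimnames = list(paste0("a", 1:6), rownames(D)))
  comm <- comm[rowSums(comm) >= 2, ]
  mine <- ses_mpd(comm, D, n_rand = 1500, seed = 3)
  ref <- picante::ses.mpd(comm, stats::as.dist(D),
                          null.model = "taxa.labels", runs = 1500)
  expect_equal(mine$mpd_obs, ref$mpd.obs, tolerance = 1e-10)
  expect_equal(mine$null_mean, ref$mpd.rand.mean, tolerance = 0.03)
  expect_equal(mine$ses, ref$mpd.obs.z, tolerance = 0.15)
})

test_that("abundance-weighted MPD weights pairs by abundance products", {
  D <- rand_dist(3, 6)
  asm <- matrix(c(2, 1, 1), 1, 3, dimnames = list("a", rownames(D)))
  got <- ses_mpd(asm, D, n_rand = 5, seed = 1, abundance_weighted = TRUE)
  w_manual <- (2 * 1 * D["s1", "s2"] + 2 * 1 * D["s1", "s3"] +
                 1 * 1 * D["s2", "s3"]) / (2 * 1 + 2 * 1 + 1 * 1)
  expect_equal(got$mpd_obs, w_manual)
})
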