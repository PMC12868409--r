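# Independent oracles and small fixtures used across the suite.

# All permutations of 1..n (n small), one per row.
perms_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Hand-rolled Gower distance, independent of cluster::daisy.
# types: named character vector "continuous" / "ordinal" / "categorical".
gower_oracle <- function(df, types) {
  n <- nrow(df)
  cols <- names(types)
  vals <- lapply(cols, function(cl) {
    x <- df[[cl]]
    if (types[[cl]] == "continuous") as.numeric(x)
    else if (types[[cl]] == "ordinal") {
      r <- as.numeric(ordered(x))
      if (max(r, na.rm = TRUE) > 1) (r - 1) / (max(r, na.rm = TRUE) - 1) else r * 0
    } else x
  })
  names(vals) <- cols
  d <- matrix(0, n, n, dimnames = list(rownames(df), rownames(df)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; den <- 0
    for (cl in cols) {
      xi <- vals[[cl]][i]; xj <- vals[[cl]][j]
      if (is.na(xi) || is.na(xj)) next
      den <- den + 1
      if (types[[cl]] == "categorical") {
        num <- num + as.numeric(xi != xj)
      } else {
        rg <- diff(range(vals[[cl]], na.rm = TRUE))
        num <- num + if (rg > 0) abs(xi - xj) / rg else 0
      }
    }
    d[i, j] <- num / den
  }
  d
}

# Brute-force mean pairwise distance by explicit pair enumeration.
mpd_oracle <- function(species, D) {
  pairs <- utils::combn(unique(species), 2)
  mean(apply(pairs, 2, function(p) D[p[1], p[2]]))
}

# Path-length oracle via ape::nodepath (independent of stats::cophenetic).
patristic_oracle <- function(tree, a, b) {
  ia <- which(tree$tip.label == a)
  ib <- which(tree$tip.label == b)
  np <- ape::nodepath(tree, ia, ib)
  sum(vapply(seq_len(length(np) - 1), function(k) {
    e <- which((tree$edge[, 1] == np[k] & tree$edge[, 2] == np[k + 1]) |
                 (tree$edge[, 2] == np[k] & tree$edge[, 1] == np[k + 1]))
    tree$edge.length[e]
  }, numeric(1)))
}

# Minimal three-log design for data-model tests.
toy_design <- function() {
  survey_design(
    data.frame(log_id = c("L1", "L2", "L3"),
               tree_species = c("spruce", "beech", "fir"),
               plot_id = c("P1", "P2", "P3"),
               E = c(0, 100, 200), N = c(0, 50, 100),
               exposure_start = c(2013, 2012, 2012)),
    sampling_years = c(2013:2019, 2021:2024),
    missing_years = 2020
  )
}

toy_community <- function(design = toy_design()) {
  community_table(
    data.frame(
      log_id = c("L1", "L1", "L2", "L2", "L2", "L3", "L3", "L3", "L3"),
      exposure_year = c(0, 1, 1, 1, 2, 1, 1, 2, 3),
      species_id = c("sA", "sB", "sA", "sC", "sD", "sB", "sC", "sC", "sE"),
      count = c(3, 1, 2, 5, 1, 4, 2, 2, 6)),
    design)
}

# Small simulated study reused by several files (built once per test run).
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_community(simulation_config(
      n_species = 50, seed = 42, n_beech_plots = 3, n_fir_plots = 3,
      n_mixed_plots = 3, n_spruce_logs = 4, n_years = 9))
  }
  .sim_cache$sim
}
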