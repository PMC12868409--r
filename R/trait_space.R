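#' Default trait schema for saproxylic beetle trait tables
#'
#' Declares, for each trait, its measurement type and preprocessing flags:
#' 13 morphological traits (11 continuous, hairiness as ordered classes,
#' colour as categories) and 4 ecological traits (decay niche and wood
#' diameter niche as ordered classes, feeding type and host-tree
#' association as categories). Appendage measurements are standardized by
#' body length; strongly right-skewed size traits are log-transformed.
#' The assignments are configurable: the schema is data, not code.
#'
#' @return Data frame with columns `trait`, `type`
#'   (`"continuous"|"ordinal"|"categorical"`), `standardize_by_body_length`,
#'   `log_transform`, `levels` (pipe-separated level order for ordinal
#'   traits, `NA` otherwise).
#' @export
default_trait_schema <- function() {
  sch <- data.frame(
    trait = c("body_length", "body_width", "body_roundness", "head_length",
              "wing_length", "wing_aspect", "wing_load", "leg_length",
              "antenna_length", "eye_length", "mandibular_aspect",
              "hairiness", "colour",
              "decay_niche", "wood_diameter_niche", "feeding_type",
              "host_tree"),
    type = c(rep("continuous", 11), "ordinal", "categorical",
             "ordinal", "ordinal", "categorical", "categorical"),
    standardize_by_body_length = FALSE,
    log_transform = FALSE,
    levels = NA_character_
  )
  sch$standardize_by_body_length[sch$trait %in%
    c("head_length", "wing_length", "leg_length", "antenna_length",
      "eye_length")] <- TRUE
  sch$log_transform[sch$trait %in%
    c("body_length", "body_width", "wing_load")] <- TRUE
  sch$levels[sch$trait == "hairiness"] <- "glabrous|sparse|moderate|dense"
  sch$levels[sch$trait == "decay_niche"] <- "early|mid|late"
  sch$levels[sch$trait == "wood_diameter_niche"] <- "small|medium|large"
  sch
}

#' Read a trait table and its sidecar schema
#'
#' @param traits_path CSV with a `species_id` column plus one column per
#'   trait.
#' @param schema_path CSV with the columns of [default_trait_schema()].
#' @return List with elements `traits` (data frame, ordinal/categorical
#'   columns converted to (ordered) factors per the schema) and `schema`.
#' @export
read_traits <- function(traits_path, schema_path) {
  traits <- read.csv(traits_path)
  schema <- read.csv(schema_path)
  stop_if_not("species_id" %in% names(traits),
              "trait table needs a species_id column")
  list(traits = apply_schema_types(traits, schema), schema = schema)
}

# Coerce trait columns to the classes their declared types imply.
apply_schema_types <- function(traits, schema) {
  for (i in seq_len(nrow(schema))) {
    tr <- schema$trait[i]
    if (!tr %in% names(traits)) next
    if (schema$type[i] == "continuous") {
      traits[[tr]] <- as.numeric(traits[[tr]])
    } else if (schema$type[i] == "ordinal") {
      lev <- if (!is.na(schema$levels[i])) {
        strsplit(schema$levels[i], "|", fixed = TRUE)[[1]]
      } else {
        sort(unique(stats::na.omit(traits[[tr]])))
      }
      traits[[tr]] <- factor(traits[[tr]], levels = lev, ordered = TRUE)
    } else {
      traits[[tr]] <- factor(traits[[tr]])
    }
  }
  traits
}

#' Preprocess a raw trait table
#'
#' Applies the schema's preprocessing flags: traits flagged
#' `standardize_by_body_length` are divided by the (raw) body length, then
#' traits flagged `log_transform` are natural-log transformed.
#' Standardization precedes the log so that size-corrected ratios are the
#' quantities being log-transformed. Transformations applied are recorded
#' in the `"provenance"` attribute.
#'
#' @param traits Trait data frame with `species_id` and raw trait columns.
#' @param schema Schema as in [default_trait_schema()].
#' @return The transformed trait data frame.
#' @export
preprocess_traits <- function(traits, schema) {
  prov <- character(0)
  raw_body <- NULL
  if (any(schema$standardize_by_body_length)) {
    stop_if_not("body_length" %in% names(traits),
                "standardization requested but body_length is absent")
    raw_body <- traits$body_length
    stop_if_not(all(raw_body > 0),
                "body_length must be positive for standardization")
  }
  for (i in seq_len(nrow(schema))) {
    tr <- schema$trait[i]
    if (!tr %in% names(traits)) next
    if (isTRUE(schema$standardize_by_body_length[i])) {
      traits[[tr]] <- traits[[tr]] / raw_body
      prov <- c(prov, paste0(tr, ": / body_length"))
    }
    if (isTRUE(schema$log_transform[i])) {
      if (any(traits[[tr]] <= 0, na.rm = TRUE)) {
        stop("non-positive value in '", tr, "' under log_transform flag",
             call. = FALSE)
      }
      traits[[tr]] <- log(traits[[tr]])
      prov <- c(prov, paste0(tr, ": log"))
    }
  }
  attr(traits, "provenance") <- prov
  traits
}

#' Collinearity diagnostics for continuous traits
#'
#' Pairwise-complete Pearson correlations among the continuous traits and
#' a variance inflation factor per trait, `VIF_j = 1 / (1 - R^2_j)` from
#' regressing trait j on all other continuous traits (complete cases).
#' Constant traits have no defined correlation and are excluded from the
#' VIF computation (flagged in `excluded`).
#'
#' @param traits (Preprocessed) trait data frame.
#' @param schema Trait schema; only `type == "continuous"` traits enter.
#' @param threshold VIF threshold above which a trait is flagged (default
#'   5, the conventional cut-off for problematic multicollinearity).
#' @return Object of class `collinearity_report`: list with `r` (correlation
#'   matrix), `vif` (named vector), `threshold`, `flagged` (traits with
#'   VIF >= threshold), `excluded` (constant traits).
#' @export
trait_correlations <- function(traits, schema, threshold = 5) {
  cont <- intersect(schema$trait[schema$type == "continuous"], names(traits))
  stop_if_not(length(cont) >= 2, "need at least two continuous traits")
  x <- as.data.frame(lapply(traits[cont], as.numeric))
  stop_if_not(nrow(x) >= 3, "need at least three species")
  sds <- vapply(x, function(v) sd(v, na.rm = TRUE), numeric(1))
  excluded <- names(sds)[!is.finite(sds) | sds == 0]
  use <- setdiff(cont, excluded)
  r <- cor(x[use], use = "pairwise.complete.obs")
  vif <- vapply(use, function(j) {
    fit <- lm(stats::reformulate(setdiff(use, j), response = j), data = x)
    r2 <- 1 - sum(residuals(fit)^2) /
      sum((x[[j]][!is.na(x[[j]])] - mean(x[[j]], na.rm = TRUE))^2)
    r2 <- min(r2, 1)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  structure(list(r = r, vif = vif, threshold = threshold,
                 flagged = names(vif)[vif >= threshold],
                 excluded = excluded),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Collinearity report (", length(x$vif), "continuous traits )\n")
  print(round(x$vif, 2))
  if (length(x$flagged)) {
    cat("VIF >=", x$threshold, ":", paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("All VIF values below", x$threshold, "\n")
  }
  invisible(x)
}

#' Gower distance over mixed-type traits
#'
#' Per-trait contributions: continuous and ordinal (rank-scaled to [0, 1])
#' traits contribute `|x_i - x_j| / range`, categorical traits contribute
#' 0/1 simple matching; the distance is the mean contribution over traits
#' non-missing in both species (pairwise deletion). Ranges are taken over
#' all species in `traits` -- pass the full species pool and subset the
#' result, so distances are comparable across assemblages. Computed with
#' [cluster::daisy()].
#'
#' @param traits Trait data frame (columns typed per the schema).
#' @param schema Trait schema.
#' @param exclude_traits Optional character vector of traits to drop before
#'   computing distances (used by the trait-ablation analysis).
#' @param species Optional subset (and ordering) of species for the
#'   returned matrix; ranges are still computed over the full table.
#' @return Symmetric matrix in [0, 1] with species ids as dimnames.
#' @export
gower_distance <- function(traits, schema, exclude_traits = NULL,
                           species = NULL) {
  stop_if_not("species_id" %in% names(traits),
              "trait table needs a species_id column")
  use <- intersect(schema$trait, names(traits))
  use <- setdiff(use, exclude_traits)
  stop_if_not(length(use) >= 1, "no traits left after exclusion")
  x <- apply_schema_types(traits[use], schema)
  rownames(x) <- traits$species_id
  d <- as.matrix(cluster::daisy(x, metric = "gower"))
  if (any(!is.finite(d))) {
    stop("undefined Gower distance: some species pair shares no ",
         "non-missing trait", call. = FALSE)
  }
  if (!is.null(species)) {
    unknown <- setdiff(species, rownames(d))
    stop_if_not(length(unknown) == 0,
                paste("unknown species:", paste(unknown, collapse = ", ")))
    d <- d[species, species, drop = FALSE]
  }
  d
}
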