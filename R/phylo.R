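#' Read / write a species phylogeny in Newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]. Branch
#' lengths are required downstream; internal node labels are ignored and
#' polytomies are allowed (path-length computations do not assume a binary
#' tree).
#'
#' @param path Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(path) {
  tr <- ape::read.tree(path)
  stop_if_not(!is.null(tr$edge.length), "phylogeny must carry branch lengths")
  stop_if_not(!anyDuplicated(tr$tip.label), "duplicated tip labels")
  tr
}

#' @rdname read_phylogeny
#' @param phylo A `phylo` object.
#' @export
write_phylogeny <- function(phylo, path) {
  ape::write.tree(phylo, file = path)
  invisible(path)
}

#' Graft a species missing from the phylogeny next to a known relative
#'
#' Attaches `species_id` as sister to the tip `relative_id`. The new tip
#' gets a pendant branch of length `epsilon`, and the attachment point sits
#' `epsilon` below the relative's tip, so tip depths -- and therefore all
#' pairwise distances among pre-existing tips -- are preserved exactly.
#' With `epsilon = 0` (the default) the grafted species inherits its
#' relative's position: their cophenetic distance is 0 and distances to all
#' other tips equal the relative's.
#'
#' @param phylo A `phylo` object.
#' @param species_id Label of the new tip; must not already be present.
#' @param relative_id Label of an existing tip.
#' @param epsilon Pendant branch length for the new tip (>= 0). Must not
#'   exceed the relative's pendant branch length.
#' @return The augmented `phylo`.
#' @export
graft_missing <- function(phylo, species_id, relative_id, epsilon = 0) {
  stop_if_not(relative_id %in% phylo$tip.label,
              paste("relative tip not found:", relative_id))
  stop_if_not(!(species_id %in% phylo$tip.label),
              paste("species already present:", species_id))
  stop_if_not(epsilon >= 0, "epsilon must be >= 0")
  tip <- which(phylo$tip.label == relative_id)
  pend <- phylo$edge.length[phylo$edge[, 2] == tip]
  stop_if_not(pend >= epsilon,
              "relative's pendant branch is shorter than epsilon")
  phytools::bind.tip(phylo, species_id, edge.length = epsilon,
                     where = tip, position = epsilon)
}

#' Apply a graft list to a phylogeny
#'
#' @param phylo A `phylo`.
#' @param grafts Data frame with columns `species_id` and `relative_id`
#'   (e.g. read from CSV); grafted in row order so a grafted species may in
#'   turn serve as a later relative.
#' @param epsilon Pendant length used for every graft.
#' @return The augmented `phylo`.
#' @export
graft_all <- function(phylo, grafts, epsilon = 0) {
  for (i in seq_len(nrow(grafts))) {
    phylo <- graft_missing(phylo, grafts$species_id[i],
                           grafts$relative_id[i], epsilon)
  }
  phylo
}

#' Cophenetic (patristic) distances between tips
#'
#' Entry (i, j) is the sum of branch lengths along the tree path between
#' tips i and j; the diagonal is zero.
#'
#' @param phylo A `phylo` with branch lengths.
#' @param species Optional character vector restricting (and ordering) the
#'   returned matrix; must be a subset of the tip labels.
#' @return Symmetric numeric matrix.
#' @export
cophenetic_distance <- function(phylo, species = NULL) {
  d <- stats::cophenetic(phylo)
  if (!is.null(species)) {
    unknown <- setdiff(species, rownames(d))
    stop_if_not(length(unknown) == 0,
                paste("unknown species:", paste(unknown, collapse = ", ")))
    d <- d[species, species, drop = FALSE]
  }
  d
}
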