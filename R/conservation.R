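#' Equal-split phylogenetic leaf weights
#'
#' Computes per-species weights that control for phylogenetic relatedness
#' when summarizing an alignment column: each branch's length is divided
#' equally among the leaves descending from it, a leaf's raw weight is the
#' sum of its shares over all ancestral branches, and weights are normalized
#' to sum to one. Clusters of closely related species are down-weighted so
#' that a nucleotide shared only by near-identical orthologs does not count
#' as independent evidence of conservation.
#'
#' @param tree an [ape::phylo] tree with branch lengths, or a path to / text
#'   of a Newick file.
#' @return A `weighted_tree`: list with `tree` (the `phylo` object) and
#'   `weights` (named numeric vector over leaf labels, summing to 1).
#' @examples
#' wt <- leaf_weights(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' wt$weights  # A = B = 0.3, C = 0.4
#' @export
leaf_weights <- function(tree) {
  tree <- .as_phylo(tree)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  if (all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; falling back to uniform weights")
    w <- rep(1 / n_tip, n_tip)
    names(w) <- tree$tip.label
    return(structure(list(tree = tree, weights = w), class = "weighted_tree"))
  }
  # leaves under each edge, by one postorder sweep
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  raw <- numeric(n_tip)
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2]
    parent <- po$edge[e, 1]
    if (is.null(desc[[parent]])) desc[[parent]] <- integer(0)
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  for (e in seq_len(nrow(tree$edge))) {
    leaves <- desc[[tree$edge[e, 2]]]
    raw[leaves] <- raw[leaves] + tree$edge.length[e] / length(leaves)
  }
  w <- raw / sum(raw)
  names(w) <- tree$tip.label
  structure(list(tree = tree, weights = w), class = "weighted_tree")
}

.as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (inherits(tree, "weighted_tree")) return(tree$tree)
  if (is.character(tree) && length(tree) == 1) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("cannot interpret 'tree' as a phylogeny")
}

#' Weighted entropy of an alignment column
#'
#' The per-site conservation score: Shannon entropy (base 2) of the column's
#' nucleotide composition, with each sequence contributing its phylogenetic
#' weight instead of 1/n. `E_w = 0` means no variation in the column; the
#' maximum is 2 bits (four equiprobable nucleotides). Gap and `N` characters
#' are excluded and the remaining weights renormalized; a column consisting
#' entirely of gaps yields `NA` and is dropped downstream.
#'
#' @param column character vector, one nucleotide (or `-`/`N`) per leaf, in
#'   `weights` order.
#' @param weights named or plain numeric vector of leaf weights summing to 1,
#'   or a `weighted_tree` from [leaf_weights()].
#' @return list with `E_w` (bits; `NA` if the column is all gaps),
#'   `n_effective` (total weight of non-gap rows) and `fractions` (weighted
#'   nucleotide fractions `p_i`).
#' @examples
#' weighted_entropy(c("A", "A", "C"), c(0.3, 0.3, 0.4))$E_w  # ~0.971
#' @export
weighted_entropy <- function(column, weights) {
  if (inherits(weights, "weighted_tree")) weights <- weights$weights
  column <- toupper(column)
  column[column == "U"] <- "T"
  if (length(column) != length(weights))
    stop("column and weights have different lengths")
  ok <- column %in% c("A", "C", "G", "T", "-", "N")
  if (!all(ok))
    stop("invalid character(s) in column: ",
         paste(unique(column[!ok]), collapse = ", "))
  keep <- column %in% c("A", "C", "G", "T")
  n_eff <- sum(weights[keep])
  if (n_eff <= 0)
    return(list(E_w = NA_real_, n_effective = 0, fractions = numeric(0)))
  p <- tapply(weights[keep], factor(column[keep]), sum) / n_eff
  p <- as.numeric(p[p > 0])
  ew <- -sum(p * log2(p)) + 0  # + 0 normalizes IEEE negative zero
  list(E_w = ew, n_effective = n_eff,
       fractions = sort(p, decreasing = TRUE))
}

#' Classify a site as conserved
#'
#' A site counts as conserved when its weighted entropy is strictly below
#' the cutoff (default 0.5 bits); a site exactly at the cutoff is
#' non-conserved.
#'
#' @param e_w weighted entropy in bits (vectorized).
#' @param cutoff conservation cutoff in bits.
#' @return Logical vector; `NA` where `e_w` is `NA`.
#' @export
classify_conserved <- function(e_w, cutoff = 0.5) {
  e_w < cutoff
}

#' Weighted entropy for many alignment columns at once
#'
#' Vectorized version of [weighted_entropy()] used by the pipeline: takes
#' the alignment as a character matrix (rows = leaves in weight order) and
#' returns one `E_w` per requested column. Gap/`N` rows are excluded per
#' column and weights renormalized, as in the scalar function.
#'
#' @param chars character matrix (leaves x columns).
#' @param weights numeric leaf weights summing to 1, or a `weighted_tree`.
#' @param cols columns to score (default all).
#' @return Numeric vector of entropies in bits (`NA` for all-gap columns).
#' @export
column_entropies <- function(chars, weights, cols = seq_len(ncol(chars))) {
  if (inherits(weights, "weighted_tree")) weights <- weights$weights
  stopifnot(nrow(chars) == length(weights))
  M <- chars[, cols, drop = FALSE]
  M[M == "U"] <- "T"
  wsum <- matrix(0, nrow = 4, ncol = ncol(M))
  for (k in seq_along(c("A", "C", "G", "T"))) {
    nt <- c("A", "C", "G", "T")[k]
    wsum[k, ] <- as.numeric(weights %*% (M == nt))
  }
  tot <- colSums(wsum)
  p <- sweep(wsum, 2, tot, "/")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ew <- -colSums(plogp) + 0
  ew[tot <= 0] <- NA_real_
  ew
}

#' Per-site records for one gene: entropy joined with sensitivity
#'
#' Computes the weighted entropy of each 4-fold site's alignment column
#' and joins it with the site's structural sensitivity, yielding the
#' per-site record rows that every downstream statistic consumes.
#'
#' @param alignment an `ortholog_alignment`.
#' @param sites data.frame from [fourfold_sites()].
#' @param weights leaf weights in the alignment's species order (named
#'   vector or `weighted_tree`; names are matched to species when present).
#' @param sensitivity optional numeric vector of per-site sensitivities
#'   aligned with `sites` rows.
#' @return `sites` with added columns `E_w` (and `sensitivity` if given).
#' @export
site_entropies <- function(alignment, sites, weights, sensitivity = NULL) {
  if (inherits(weights, "weighted_tree")) weights <- weights$weights
  chars <- .aln_matrix(alignment)
  if (!is.null(names(weights))) {
    miss <- setdiff(alignment$species, names(weights))
    if (length(miss))
      stop("no weight for species: ", paste(miss, collapse = ", "))
    weights <- weights[alignment$species]
  }
  sites$E_w <- column_entropies(chars, weights, sites$aln_col)
  if (!is.null(sensitivity)) sites$sensitivity <- sensitivity
  sites
}
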