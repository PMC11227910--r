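#' Read a community phylogeny from Newick text or a file
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree must have
#' uniquely labeled tips and a branch length on every edge; polytomies and
#' zero-length branches (common after polytomy resolution) are allowed.
#' Tip labels must byte-match the species fields of the census tables.
#'
#' @param x a Newick string (containing `";"`) or a file path.
#' @return an [ape] `phylo` object.
#' @export
read_newick <- function(x) {
  tr <- if (grepl(";", x, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = x),
             error = function(e) NULL, warning = function(w) NULL)
  } else {
    if (!file.exists(x)) stop("file not found: ", x)
    tryCatch(ape::read.tree(x),
             error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(tr)) stop("Newick parse error")
  if (is.null(tr$tip.label) || anyDuplicated(tr$tip.label))
    stop("tips must be uniquely labeled")
  if (any(tr$tip.label == "")) stop("unlabeled tip in Newick input")
  if (is.null(tr$edge.length))
    stop("Newick input has no branch lengths")
  if (length(tr$edge.length) != nrow(tr$edge) || anyNA(tr$edge.length))
    stop("missing branch length on one or more edges")
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr
}

#' Patristic distance matrix of a phylogeny
#'
#' d[i, j] is the sum of branch lengths along the tip-to-tip path between
#' species i and j, in the units of the tree's branch lengths (Myr for a
#' dated tree).
#'
#' @param phy a `phylo` object with >= 2 tips and branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(phy) {
  if (ape::Ntip(phy) < 2) stop("need at least 2 tips")
  d <- ape::cophenetic.phylo(phy)
  d[phy$tip.label, phy$tip.label]
}

#' Permute the label-to-row assignment of a distance matrix
#'
#' Implements the taxa-shuffle null model: shuffling species labels on the
#' phylogeny is equivalent to permuting which label owns which row/column of
#' the patristic matrix. The multiset of off-diagonal distances is
#' unchanged.
#'
#' @param dmat labeled symmetric distance matrix.
#' @param perm integer permutation of `seq_len(nrow(dmat))`; when `NULL` a
#'   uniform random permutation is drawn from the current RNG stream.
#' @return the permuted distance matrix (same labels, reassigned).
#' @export
permute_labels <- function(dmat, perm = NULL) {
  n <- nrow(dmat)
  if (is.null(perm)) perm <- sample.int(n)
  stopifnot(length(perm) == n, !anyDuplicated(perm))
  out <- dmat[perm, perm, drop = FALSE]
  dimnames(out) <- dimnames(dmat)
  out
}
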