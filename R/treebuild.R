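# Desk-scale tree inference: neighbor joining, bootstrap resampling,
# majority-rule consensus, outgroup rooting, external ML adapter.

#' Neighbor-joining tree from a distance matrix
#'
#' Wraps `ape::nj`. On additive matrices the path-length distances of the
#' result reproduce the input exactly. Negative branch lengths (a known NJ
#' artifact on noisy matrices) are clamped to zero and recorded in the
#' `clamped` attribute.
#'
#' @param d square symmetric distance matrix with id dimnames, n >= 3.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    tr$edge.length[neg] <- 0
    attr(tr, "clamped") <- sum(neg)
  }
  tr
}

#' Bootstrap column resampling of an alignment
#'
#' Each replicate draws `ncols` columns uniformly with replacement; a fixed
#' seed reproduces the exact replicate set.
#'
#' @param aln an [mt_alignment].
#' @param n number of replicates (default 100).
#' @param seed integer seed.
#' @return list of [mt_alignment] replicates (colmaps dropped: resampled
#'   columns are no longer reference-ordered).
#' @export
bootstrap_replicates <- function(aln, n = 100L, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  m <- .aln_matrix(aln)
  lapply(seq_len(n), function(i) {
    idx <- sample.int(aln$ncols, aln$ncols, replace = TRUE)
    mt_alignment(aln$ids, apply(m[, idx, drop = FALSE], 1L, paste,
                                collapse = ""))
  })
}

# canonical bipartition key of a clade: the side not containing the first
# leaf label (alphabetically), as a sorted, collapsed string
.bipartitions <- function(tree, all_leaves) {
  anchor <- min(all_leaves)
  ntip <- length(tree$tip.label)
  keys <- character(0)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    tips <- tree$tip.label[unlist(.clade_tips(tree, node))]
    side <- if (anchor %in% tips) setdiff(all_leaves, tips) else tips
    if (length(side) <= 1L || length(side) >= length(all_leaves) - 1L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

.clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .clade_tips, tree = tree))
}

#' Majority-rule consensus tree
#'
#' Retains the bipartitions whose frequency across the input trees exceeds
#' `threshold` (default 0.5), collapsing the rest into polytomies; each
#' retained internal node carries its frequency as support (node label and
#' `support` attribute).
#'
#' @param trees list (or `multiPhylo`) of trees on identical leaf sets.
#' @param threshold retention threshold in `[0.5, 1)`.
#' @return an `ape::phylo` consensus tree with `node.label` supports.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(threshold >= 0.5, threshold < 1)
  trees <- unclass(trees)
  leaves <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), leaves))
      stop("consensus requires identical leaf sets")
  counts <- table(unlist(lapply(trees, .bipartitions, all_leaves = leaves)))
  freq <- as.numeric(counts) / length(trees)
  names(freq) <- names(counts)
  cons <- ape::consensus(trees, p = threshold + 1e-9, check.labels = TRUE)
  # attach supports: frequency of each retained clade's bipartition
  ntip <- length(cons$tip.label)
  labs <- character(cons$Nnode)
  sup <- numeric(cons$Nnode)
  anchor <- min(leaves)
  for (node in (ntip + 1L):(ntip + cons$Nnode)) {
    tips <- cons$tip.label[unlist(.clade_tips(cons, node))]
    side <- if (anchor %in% tips) setdiff(leaves, tips) else tips
    key <- paste(sort(side), collapse = "|")
    f <- if (length(side) <= 1L || length(side) >= length(leaves) - 1L) 1
    else if (!is.na(freq[key])) freq[key] else 0
    sup[node - ntip] <- f
    labs[node - ntip] <- format(round(f, 3))
  }
  cons$node.label <- labs
  attr(cons, "support") <- sup
  attr(cons, "bipartition_freq") <- freq
  cons
}

#' Root a tree on an outgroup
#'
#' The outgroup ids must form a clade of the unrooted tree; the root is
#' placed on the edge separating outgroup from ingroup.
#'
#' @param tree an `ape::phylo` tree.
#' @param outgroup_ids tip labels of the outgroup.
#' @return a rooted `ape::phylo` tree with the same leaf set.
#' @export
root_by_outgroup <- function(tree, outgroup_ids) {
  missing <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing)) stop("outgroup ids not in tree: ",
                            paste(missing, collapse = ", "))
  if (length(outgroup_ids) < length(tree$tip.label) - 1L &&
      !ape::is.monophyletic(tree, outgroup_ids)) {
    mrca_tips <- tree$tip.label[unlist(.clade_tips(
      ape::unroot(tree), ape::getMRCA(tree, outgroup_ids)))]
    stop("outgroup is not monophyletic; smallest containing clade adds: ",
         paste(setdiff(mrca_tips, outgroup_ids), collapse = ", "))
  }
  ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE)
}

#' External maximum-likelihood engine adapter
#'
#' Thin subprocess adapter (no internal ML): writes the alignment as FASTA,
#' invokes the configured engine and parses the newick it produces.
#'
#' @param aln an [mt_alignment].
#' @param config list with `cmd` (binary name, e.g. `"fasttree"`) and
#'   optional `args` (character vector; default `c("-nt", "-gtr")`).
#' @return an `ape::phylo` tree with the alignment's leaf set.
#' @export
run_external_ml <- function(aln, config = list(cmd = "fasttree",
                                               args = c("-nt", "-gtr"))) {
  if (Sys.which(config$cmd) == "")
    stop("external ML engine '", config$cmd, "' not found on PATH; ",
         "use neighbor_joining() on a distance_matrix() instead")
  td <- tempfile("ml"); dir.create(td); on.exit(unlink(td, recursive = TRUE))
  infa <- file.path(td, "aln.fasta"); outnwk <- file.path(td, "tree.nwk")
  write_fasta(aln, infa)
  args <- c(if (!is.null(config$args)) config$args else character(), infa)
  res <- suppressWarnings(system2(config$cmd, args, stdout = outnwk,
                                  stderr = FALSE))
  if (res != 0L || !file.size(outnwk))
    stop("external ML engine '", config$cmd, "' failed (exit ", res, ")")
  tr <- ape::read.tree(outnwk)
  if (!setequal(tr$tip.label, aln$ids))
    stop("engine output leaf set does not match the alignment")
  tr
}
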