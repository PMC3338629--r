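# Neighbor-joining trees on Jukes-Cantor distance matrices, Felsenstein
# column bootstrap, majority-rule consensus, Newick output.
#
# The agglomeration itself is the standard Saitou-Nei algorithm (ape::nj);
# negative branch-length estimates are clamped to zero (MEGA-compatible).
# Bootstrap support is the percentage of column-resampled replicates whose
# NJ tree contains each internal bipartition of the point-estimate tree.

#' Neighbor-joining tree from a JC distance matrix
#'
#' @param dm a `jc_dist` from [build_distance_matrix()] (>= 3 sequences, no
#'   undefined cells), or a plain symmetric numeric matrix.
#' @return an [ape::phylo] unrooted tree; negative branch lengths clamped
#'   to 0.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "jc_dist")) dm$d else as.matrix(dm)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 sequences")
  if (anyNA(d)) {
    bad <- which(is.na(d), arr.ind = TRUE)[1L, ]
    stop(sprintf("undefined distance between '%s' and '%s'",
                 rownames(d)[bad[1L]], colnames(d)[bad[2L]]))
  }
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length <= 0] <- 0
  tr
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement (Felsenstein bootstrap),
#' rebuilds the JC distance matrix and NJ tree per replicate, and reports
#' for each internal edge of the point-estimate tree the percentage of
#' replicates containing that bipartition. A replicate whose resampled
#' distance matrix has an undefined cell is dropped and counted; more than
#' 10% dropped is an error. A majority-rule consensus of the replicate
#' trees is also returned.
#'
#' @param aligned character matrix of aligned rows (e.g. from
#'   [star_align()]), rows named by sequence id.
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed integer seed; identical seeds give identical supports.
#' @return object of class `nj_boot`: list with `tree` (point estimate,
#'   `node.label` = support percent, root label empty), `consensus`
#'   (majority-rule, >=50%), `supports` (data.frame node/support),
#'   `n_reps`, `n_dropped`.
#' @export
bootstrap_support <- function(aligned, n_reps = 1000L, seed = 1L) {
  stopifnot(is.matrix(aligned), ncol(aligned) >= 2L, nrow(aligned) >= 3L)
  point <- nj_tree(dm_from_aligned(aligned))
  trees <- vector("list", n_reps)
  dropped <- 0L
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(aligned), ncol(aligned), replace = TRUE)
      dm <- dm_from_aligned(aligned[, cols, drop = FALSE])
      if (anyNA(dm$d)) {
        dropped <- dropped + 1L
        next
      }
      trees[[r]] <- nj_tree(dm)
    }
  })
  if (dropped > 0.1 * n_reps)
    stop(sprintf("%d of %d bootstrap replicates had undefined distances",
                 dropped, n_reps))
  trees <- trees[!vapply(trees, is.null, logical(1))]
  class(trees) <- "multiPhylo"
  n_used <- length(trees)
  counts <- ape::prop.clades(point, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_used
  tree <- point
  tree$node.label <- c("", formatC(support[-1L], format = "fg"))
  tree$node.label[1L] <- ""  # root of the unrooted representation
  cons <- ape::consensus(trees, p = 0.5)
  structure(list(tree = tree, consensus = cons,
                 supports = data.frame(node = seq_along(support) +
                                         length(point$tip.label),
                                       support = support),
                 n_reps = n_reps, n_dropped = dropped),
            class = "nj_boot")
}

dm_from_aligned <- function(aligned) {
  build_distance_matrix(NULL, aligned_rows = aligned)
}

#' @export
print.nj_boot <- function(x, ...) {
  s <- x$supports$support[-1L]
  cat(sprintf("<nj_boot> %d tips, %d replicates (%d dropped); support %s-%s%%\n",
              length(x$tree$tip.label), x$n_reps, x$n_dropped,
              if (length(s)) round(min(s)) else NA,
              if (length(s)) round(max(s)) else NA))
  invisible(x)
}

#' Bootstrap support for a specific bipartition
#'
#' Percentage of replicate trees containing the bipartition that separates
#' `tips` from the rest; useful for interrogating one split of interest.
#'
#' @param x an `nj_boot`.
#' @param tips character vector of tip labels on one side of the split.
#' @return support percent, or `NA` if the split is not an internal edge of
#'   the point-estimate tree.
#' @export
split_support <- function(x, tips) {
  tr <- x$tree
  for (node in (length(tr$tip.label) + 1L):(length(tr$tip.label) + tr$Nnode)) {
    below <- ape::extract.clade(tr, node)$tip.label
    if (setequal(below, tips) ||
        setequal(setdiff(tr$tip.label, below), tips))
      return(x$supports$support[x$supports$node == node])
  }
  NA_real_
}

#' Write a tree as Newick with support labels
#'
#' Internal-node supports strictly greater than `min_support_display` are
#' written as node labels; others are omitted (all values are retained in
#' the optional sidecar TSV). The output round-trips through a standard
#' Newick parser.
#'
#' @param tree an [ape::phylo], or an `nj_boot` (its point-estimate tree is
#'   written).
#' @param path output path.
#' @param min_support_display hide supports at or below this percent
#'   (default 50).
#' @param sidecar_path optional TSV path for the full node/support table.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, min_support_display = 50,
                         sidecar_path = NULL) {
  supports <- NULL
  if (inherits(tree, "nj_boot")) {
    supports <- tree$supports
    tree <- tree$tree
  }
  if (!is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    tree$node.label <- ifelse(!is.na(lab) & lab > min_support_display,
                              formatC(lab, format = "fg"), "")
  }
  ape::write.tree(tree, file = path)
  if (!is.null(sidecar_path) && !is.null(supports))
    write_tsv(supports, sidecar_path)
  invisible(path)
}
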