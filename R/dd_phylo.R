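# Distance-based phylogeny of classified sequences: p-distances on a
# gapped alignment, neighbor joining, seeded column-resampling bootstrap
# supports, outgroup rooting and clade-coherence checks. Tree handling is
# built on ape's "phylo" machinery.

.check_aligned <- function(aligned) {
  if (is.null(names(aligned)) || any(!nzchar(names(aligned))))
    stop("aligned sequences must be named")
  if (length(aligned) < 3) stop("need at least 3 sequences")
  if (length(unique(nchar(aligned))) != 1)
    stop("aligned sequences must have equal gapped length")
  invisible(aligned)
}

#' Pairwise p-distance matrix from a gapped alignment
#'
#' d(i, j) = mismatches / comparable columns, where columns holding a gap
#' (`-`) in either sequence are excluded from the comparison.
#'
#' @param aligned Named character vector of equal-length gapped sequences.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
pdistance_matrix <- function(aligned) {
  .check_aligned(aligned)
  n <- length(aligned)
  m <- do.call(rbind, strsplit(aligned, ""))
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok))
        stop("no comparable columns between '", names(aligned)[i],
             "' and '", names(aligned)[j], "'")
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch lengths
#' are clamped to zero with the deficit moved to the sibling edge so that
#' path lengths between leaves are preserved where possible.
#'
#' @param d Symmetric distance matrix with taxa as dimnames (>= 3 taxa,
#'   finite entries).
#' @return An unrooted `phylo` tree over the taxa.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) < 3) stop("need a matrix over >= 3 taxa")
  if (any(!is.finite(d))) stop("non-finite distances")
  tr <- ape::nj(d)
  .clamp_negative_edges(tr)
}

.clamp_negative_edges <- function(tr, max_iter = 20L) {
  for (k in seq_len(max_iter)) {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0) return(tr)
    e <- neg[1]
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs) > 0)
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Column-resampling bootstrap supports for the NJ tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds a
#' p-distance NJ tree per replicate, and reports for every internal edge of
#' the full-data tree the fraction of replicates containing the same
#' bipartition. Each replicate draws from its own seeded substream
#' (`seed + replicate index`), so supports are reproducible and independent
#' of evaluation order.
#'
#' @param aligned Named character vector of equal-length gapped sequences.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed governing all replicates.
#' @return The full-data `phylo` tree with `node.label` holding support
#'   fractions in `[0, 1]` (the root label is empty).
#' @export
bootstrap_supports <- function(aligned, n_reps, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  .check_aligned(aligned)
  main <- nj_tree(pdistance_matrix(aligned))
  ncol <- nchar(aligned[[1]])
  mat <- do.call(rbind, strsplit(aligned, ""))
  rownames(mat) <- names(aligned)
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(as.integer(seed) + r)
    idx <- sample.int(ncol, ncol, replace = TRUE)
    rep_aln <- apply(mat[, idx, drop = FALSE], 1, paste, collapse = "")
    boots[[r]] <- tryCatch(nj_tree(pdistance_matrix(rep_aln)),
                           error = function(e) NULL)
  }
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- counts / n_reps
  main$node.label[1] <- NA  # root of the unrooted representation
  main
}

#' Root a tree on the edge separating an outgroup clade
#'
#' @param tree An unrooted `phylo`.
#' @param outgroup Character vector of outgroup taxa; must be a proper,
#'   monophyletic subset of the leaves.
#' @return A rooted `phylo`; the unrooted bipartition set is unchanged.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!all(outgroup %in% tree$tip.label))
    stop("outgroup taxa missing from the tree")
  if (length(outgroup) >= length(tree$tip.label))
    stop("outgroup cannot contain every taxon")
  if (!ape::is.monophyletic(tree, outgroup))
    stop("outgroup is not monophyletic in the unrooted tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Test monophyly of each class of labelled leaves
#'
#' A class is monophyletic iff some edge bipartition isolates exactly its
#' leaves; singleton classes are monophyletic by convention.
#'
#' @param tree A `phylo`.
#' @param labels Named character vector mapping every leaf to a class.
#' @return Named logical vector, one entry per class.
#' @export
check_monophyly <- function(tree, labels) {
  missing <- setdiff(tree$tip.label, names(labels))
  if (length(missing) > 0)
    stop("unlabeled leaves: ", paste(missing, collapse = ", "))
  classes <- unique(unname(labels[tree$tip.label]))
  out <- vapply(classes, function(cl) {
    tips <- tree$tip.label[labels[tree$tip.label] == cl]
    if (length(tips) <= 1) return(TRUE)
    ape::is.monophyletic(tree, tips)
  }, logical(1))
  names(out) <- classes
  out
}

#' Unrooted bipartition set of a tree
#'
#' Each non-trivial bipartition is represented canonically as the
#' lexicographically sorted side not containing the first taxon (sorted
#' taxon order), serialised as a single string.
#'
#' @param tree A `phylo`.
#' @return Character vector of canonical bipartition keys.
#' @export
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  taxa <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- vapply(parts, function(p) {
    side <- sort(labs[p])
    if (taxa[1] %in% side) side <- sort(setdiff(taxa, side))
    paste(side, collapse = "|")
  }, character(1))
  unique(keys[vapply(parts, function(p)
    length(p) > 1 && length(p) < length(taxa) - 1, logical(1))])
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d Distance matrix with taxa as dimnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  ")),
               con)
  }
  invisible(path)
}
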