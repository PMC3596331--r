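# Neighbour-joining phylogenies from protein alignments: p-distance with
# complete deletion, bootstrap support, Newick output.  Mirrors the classic
# MEGA-style settings for protein family trees.

#' Read an aligned FASTA file into an alignment matrix
#'
#' @param path Aligned FASTA (all rows the same length; gaps as \code{-}).
#' @return Character matrix, one row per taxon (rownames are the taxa),
#'   one column per alignment site.
#' @export
read_alignment <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate taxa labels in ", path)
  seqs <- toupper(as.character(aas))
  as_alignment(setNames(seqs, ids))
}

#' Build an alignment matrix from named sequences
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return Character matrix with taxa as rownames.
#' @export
as_alignment <- function(seqs) {
  if (length(seqs) < 2) stop("an alignment needs at least 2 taxa")
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned rows must all have the same length")
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' Remove every alignment column containing a gap in any row
#'
#' The "complete deletion" option of distance phylogenetics: a column is kept
#' only if it is gap-free in all taxa.  Idempotent; taxa order preserved.
#'
#' @param aln Alignment matrix (see \code{\link{as_alignment}}).
#' @return The reduced alignment matrix.
#' @export
complete_deletion <- function(aln) {
  stopifnot(is.matrix(aln))
  keep <- colSums(aln == "-") == 0
  if (!any(keep))
    stop("complete deletion removed every column; ",
         "pairwise deletion is not supported")
  aln[, keep, drop = FALSE]
}

#' p-distance matrix of a gap-free alignment
#'
#' Entry (i, j) is the fraction of sites at which taxa i and j differ.
#'
#' @param aln Gap-free alignment matrix (run \code{\link{complete_deletion}}
#'   first).
#' @return Symmetric numeric matrix with zero diagonal, entries in [0, 1],
#'   and attribute \code{sites_used} (number of columns).
#' @export
p_distance <- function(aln) {
  stopifnot(is.matrix(aln), ncol(aln) >= 1)
  if (any(aln == "-"))
    stop("alignment contains gaps; apply complete_deletion() first")
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- mean(aln[i, ] != aln[j, ])
  }
  attr(d, "sites_used") <- ncol(aln)
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion.  Ties in the Q
#' minimum go to the lowest index pair (row-major), making the procedure
#' deterministic.  Negative branch lengths are clamped to zero with the
#' absorbed amount added to the sibling edge (the usual MEGA-style
#' convention).  On additive matrices the returned topology and branch
#' lengths reproduce the generating tree exactly.
#'
#' @param d Symmetric distance matrix with zero diagonal, non-negative
#'   entries and at least 3 labelled taxa.
#' @return An unrooted \code{ape::phylo} tree with branch lengths.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d))
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 3) stop("neighbour joining needs at least 3 taxa")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  fmt <- function(x) sprintf("%.17g", x)
  # active nodes carried as Newick fragments
  sub <- rownames(d)
  D <- d
  while (length(sub) > 3) {
    m <- length(sub)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest-index pair among the minima (row-major)
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    new_sub <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":", fmt(lj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    sub <- c(sub[keep], new_sub)
    D <- D2
  }
  # final three-point formulas
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(0, la); lb <- max(0, lb); lc <- max(0, lc)
  nwk <- paste0("(", sub[1], ":", fmt(la), ",", sub[2], ":", fmt(lb), ",",
                sub[3], ":", fmt(lc), ");")
  ape::read.tree(text = nwk)
}

# One full pipeline pass: complete deletion -> p-distance -> NJ.
infer_nj <- function(aln) nj_tree(p_distance(complete_deletion(aln)))

#' Bootstrap support for a neighbour-joining tree
#'
#' Builds the full-data NJ tree (complete deletion, p-distance), then
#' resamples alignment columns with replacement \code{replicates} times,
#' reruns the whole pipeline per replicate, and reports, for every internal
#' edge of the full tree, the percentage of replicate trees containing the
#' same bipartition.  Deterministic given \code{seed}.
#'
#' @param aln Alignment matrix.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the column resampling.
#' @return The full-data \code{phylo} tree with supports (percentages) in
#'   \code{node.label} and in attribute \code{support}.
#' @export
nj_bootstrap <- function(aln, replicates = 1000, seed = 1) {
  stopifnot(is.matrix(aln))
  if (replicates < 1) stop("replicates must be >= 1")
  full <- infer_nj(aln)
  reps <- with_seed(seed, lapply(seq_len(replicates), function(i) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    infer_nj(aln[, cols, drop = FALSE])
  }))
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / replicates
  full$node.label <- as.character(round(support, 1))
  attr(full, "support") <- support
  full
}

#' Fraction of true bipartitions recovered by an inferred tree
#'
#' Robinson-Foulds-style agreement between two unrooted trees on the same
#' taxa: 1 minus the RF distance over its maximum \code{2(n-3)}, i.e. 1.0 for
#' identical topologies, about 0 for unrelated ones.
#'
#' @param inferred,true \code{phylo} trees over the same tip labels.
#' @return Agreement fraction in [0, 1].
#' @export
topology_recovery <- function(inferred, true) {
  inferred <- ape::unroot(inferred)
  true <- ape::unroot(true)
  n <- length(true$tip.label)
  if (n <= 3) return(1)
  rf <- phangorn::RF.dist(inferred, true, check.labels = TRUE)
  1 - rf / (2 * (n - 3))
}

#' Write a tree as Newick
#'
#' Bootstrap supports (if present) are written as internal node labels and
#' branch lengths with 6 decimals.
#'
#' @param tree A \code{phylo} tree.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Write a distance matrix as a PHYLIP-style square TSV
#' @param d Distance matrix from \code{\link{p_distance}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_distance_tsv <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(d)), con)
  write.table(format(d, digits = 10), con, sep = "\t", quote = FALSE,
              col.names = FALSE)
  invisible(path)
}
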