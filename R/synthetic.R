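# Ground-truthed synthetic data generators.  Every generator is a pure
# function of its spec and seed, and validates its own truth record against
# the emitted object before returning (scanner/generator consistency is
# checked at the source).
#
# Design notes: filler residues INSIDE the RING region exclude C and H so the
# embedded ligand set is unambiguous; flanks and linkers draw from all 20
# residues (uniformly; stray flank Cys are legitimate hard cases).  ANK
# repeats are emitted in tandem.

ring_group_window <- function(group) {
  sig <- ring_signatures()
  row <- sig[sig$group == group, ]
  if (nrow(row) != 1) stop("unknown group: ", group)
  row
}

# Build a RING region for a group: returns the region string plus 1-based
# ligand offsets within it.  Sub-spacings fixed at the canonical
# L3-x1-H-x2-C-x2-C arrangement.
build_ring_region <- function(group, d67 = NULL, c3h2c3 = FALSE) {
  sig <- ring_group_window(group)
  if (is.null(d67))
    d67 <- if (sig$d67_min == sig$d67_max) sig$d67_min else
      sample(sig$d67_min:sig$d67_max, 1)
  if (d67 < sig$d67_min || d67 > sig$d67_max)
    stop(sprintf("d67=%d outside group %s window [%d,%d]",
                 d67, group, sig$d67_min, sig$d67_max))
  filler <- function(n) if (n > 0)
    paste(sample(setdiff(AA_ALPHABET, c("C", "H")), n, replace = TRUE),
          collapse = "") else ""
  before_L2 <- sample(c("V", "I"), 1)
  before_L4 <- if (sig$before_L4 == "G") "G" else filler(1)
  before_L8 <- sample(strsplit(sig$before_L8, ",")[[1]], 1)
  region <- paste0(
    "C", filler(1), before_L2,                 # L1 . x . V/I
    "C", filler(11),                           # L2 . x11
    "C", before_L4, "H",                       # L3 . x1 . L4(H)
    filler(2), if (c3h2c3) "H" else "C",       # x2 . L5 (His in C3H2C3)
    filler(2), "C",                            # x2 . L6
    filler(d67), "C",                          # x(d67) . L7
    "P", before_L8, "C", "R")                  # P . b8 . L8 . R
  lig <- c(1L, 4L, 16L, 18L, 21L, 24L, 24L + d67 + 1L, 24L + d67 + 4L)
  list(region = region, ligands = lig, d67 = d67)
}

# One ANK repeat instance: the consensus with n_mut random point mutations.
mutated_repeat <- function(n_mut) {
  ch <- seq_chars(ank_consensus())
  if (n_mut > 0) {
    pos <- sample(length(ch), n_mut)
    for (p in pos) ch[p] <- sample(setdiff(AA_ALPHABET, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic XB3-like family member with ground truth
#'
#' Emits a protein built as: N-flank, \code{n_ank} tandem 33-residue ANK
#' repeats (each carrying \code{n_mut} point mutations of the packaged
#' consensus), a linker, and a group-consistent C3HC4 RING region (filler
#' inside the RING excludes C and H), plus a C-flank.  Flanks and linker are
#' uniform over all 20 residues.  Before returning, the generator re-scans
#' its own output and verifies that the scanners recover exactly the recorded
#' truth.
#'
#' @param group \code{"I"}, \code{"II"} or \code{"III"}.
#' @param n_ank Number of ANK repeats (2..7 for classes A-F).
#' @param d67 Ligand 6-7 spacing; default: uniform over the group's window.
#' @param n_mut Point mutations per ANK repeat (keep <= 4 so repeats stay
#'   comfortably above the default score threshold).
#' @param flank Lengths of the N- and C-terminal random flanks.
#' @param linker_len Length of the ANK-to-RING linker.
#' @param seed Integer seed (\code{NULL} = use the current RNG stream).
#' @return A \code{synthetic_truth}: list with \code{record} (data frame row
#'   \code{id, species, seq}), \code{ank_intervals} (matrix of start/end),
#'   \code{ligand_pos}, \code{group}, \code{d67}, \code{is_member = TRUE}.
#' @export
make_member <- function(group = c("I", "II", "III"), n_ank = 5, d67 = NULL,
                        n_mut = 2, flank = c(30, 30), linker_len = 25,
                        seed = NULL) {
  group <- match.arg(group)
  stopifnot(n_ank >= 2, n_ank <= 7, n_mut >= 0, n_mut <= 33)
  with_seed(seed, {
    nflank <- random_protein(flank[1])
    reps <- vapply(seq_len(n_ank), function(i) mutated_repeat(n_mut), "")
    linker <- random_protein(linker_len)
    ring <- build_ring_region(group, d67)
    cflank <- random_protein(flank[2])
    seq <- paste0(nflank, paste(reps, collapse = ""), linker,
                  ring$region, cflank)
    ank_start <- flank[1] + 1L + (seq_len(n_ank) - 1L) * 33L
    ring_off <- flank[1] + n_ank * 33L + linker_len
    truth <- structure(list(
      record = data.frame(id = sprintf("syn_%s_%dank", group, n_ank),
                          species = "synthetic", seq = seq,
                          stringsAsFactors = FALSE),
      ank_intervals = cbind(start = ank_start, end = ank_start + 32L),
      ligand_pos = ring$ligands + ring_off,
      group = group, d67 = ring$d67, is_member = TRUE
    ), class = "synthetic_truth")
    validate_truth(truth)
    truth
  })
}

# Self-check at source: the scanners must recover exactly the recorded truth.
validate_truth <- function(truth) {
  seq <- truth$record$seq
  ank <- scan_ank(seq)
  if (ank$count != nrow(truth$ank_intervals) ||
      !all(ank$repeats$start == truth$ank_intervals[, "start"]))
    stop("generation self-check failed: ANK intervals not recovered")
  rings <- scan_ring(seq, strictness = "strict")
  if (length(rings) != 1 ||
      !all(rings[[1]]$ligand_pos == truth$ligand_pos))
    stop("generation self-check failed: RING ligands not recovered")
  if (classify_group(rings[[1]])$group != truth$group)
    stop("generation self-check failed: group not recovered")
  invisible(truth)
}

#' Generate a synthetic non-member decoy
#'
#' Decoy kinds: \code{"ring_only"} (valid RING, no ANK repeats),
#' \code{"single_ank"} (one ANK repeat plus a valid RING),
#' \code{"c3h2c3"} (two ANK repeats plus a C3H2C3-arranged zinc finger: His
#' at the ligand-5 slot, so it is not a C3HC4 RING), and \code{"shuffled"}
#' (a member's sequence randomly permuted).
#'
#' @param kind Decoy kind.
#' @param seed Integer seed (\code{NULL} = current RNG stream).
#' @return A \code{synthetic_truth} with \code{is_member = FALSE} and a
#'   \code{kind} field.  A shuffled decoy that happens to remain a member
#'   (never observed in practice) would carry \code{spurious = TRUE}.
#' @export
make_decoy <- function(kind = c("ring_only", "single_ank", "c3h2c3",
                                "shuffled"), seed = NULL) {
  kind <- match.arg(kind)
  with_seed(seed, {
    seq <- switch(kind,
      ring_only = paste0(random_protein(60),
                         build_ring_region(sample(c("I", "II", "III"), 1))$region,
                         random_protein(30)),
      single_ank = paste0(random_protein(30), mutated_repeat(2),
                          random_protein(25),
                          build_ring_region("III")$region,
                          random_protein(30)),
      c3h2c3 = paste0(random_protein(30), mutated_repeat(2),
                      mutated_repeat(2), random_protein(25),
                      build_ring_region("III", c3h2c3 = TRUE)$region,
                      random_protein(30)),
      shuffled = {
        m <- make_member(group = "III", n_ank = 3, seed = NULL)
        paste(sample(seq_chars(m$record$seq)), collapse = "")
      })
    ank <- scan_ank(seq)
    rings <- scan_ring(seq)
    member <- ank$count >= 2 && length(rings) >= 1
    structure(list(
      record = data.frame(id = paste0("decoy_", kind), species = "synthetic",
                          seq = seq, stringsAsFactors = FALSE),
      kind = kind, is_member = FALSE, spurious = member
    ), class = "synthetic_truth")
  })
}

#' Evolve an aligned protein family down a known tree
#'
#' Starting from a root sequence, substitutes sites independently along every
#' branch with probability \code{1 - exp(-rate * branch_length)} per site
#' (substitutions uniform over the 19 alternative residues); no indels, so
#' the tip sequences are trivially aligned and the generating tree is exact
#' ground truth for \code{\link{topology_recovery}}.
#'
#' @param tree An \code{ape::phylo} tree with branch lengths.
#' @param root_seq Root amino-acid sequence (default: a synthetic group III
#'   member).
#' @param rate Substitution rate per site per unit branch length.
#' @param seed Integer seed.
#' @return List with \code{alignment} (character matrix, taxa as rownames)
#'   and \code{tree} (the generating tree).
#' @export
make_family <- function(tree, root_seq = NULL, rate = 0.1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  with_seed(seed, {
    if (is.null(root_seq))
      root_seq <- make_member(group = "III", n_ank = 3, seed = NULL)$record$seq
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", max(tree$edge))
    seqs[[root]] <- seq_chars(root_seq)
    tr <- stats::reorder(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      s <- seqs[[par]]
      p <- 1 - exp(-rate * tr$edge.length[e])
      hit <- which(runif(length(s)) < p)
      for (h in hit) s[h] <- sample(setdiff(AA_ALPHABET, s[h]), 1)
      seqs[[child]] <- s
    }
    aln <- do.call(rbind, seqs[seq_len(ntip)])
    rownames(aln) <- tree$tip.label
    list(alignment = aln, tree = tree)
  })
}

#' Generate a synthetic qPCR Ct table with programmed effects
#'
#' The reference gene sits at 20 cycles plus Gaussian noise; each target gene
#' at \code{20 + baseline - effect + noise}, where \code{effect} is the
#' programmed log2 expression effect for that gene x condition.  With this
#' construction \code{\link{fold_change}} between a condition and a
#' zero-effect control estimates \code{2^effect} exactly in the noise-free
#' limit.
#'
#' @param genes Character vector of target gene names.
#' @param conditions Character vector of condition (tissue/treatment) labels.
#' @param replicates Replicates per gene x condition (>= 2).
#' @param log2_effects Numeric matrix (genes x conditions) of programmed
#'   log2 effects; default all zero.
#' @param noise_sd Gaussian replicate noise, in cycles (default 0.1).
#' @param baseline Baseline Ct offset of targets above the reference.
#' @param seed Integer seed.
#' @return A \code{ct_table} with reference gene \code{"REF"}; the programmed
#'   effects are kept in \code{attr(, "log2_effects")}.
#' @export
make_ct_table <- function(genes, conditions, replicates = 3,
                          log2_effects = NULL, noise_sd = 0.1,
                          baseline = 5, seed = NULL) {
  stopifnot(replicates >= 2)
  if (is.null(log2_effects))
    log2_effects <- matrix(0, length(genes), length(conditions))
  log2_effects <- as.matrix(log2_effects)
  stopifnot(nrow(log2_effects) == length(genes),
            ncol(log2_effects) == length(conditions))
  dimnames(log2_effects) <- list(genes, conditions)
  with_seed(seed, {
    grid <- expand.grid(gene = c("REF", genes), condition = conditions,
                        replicate = seq_len(replicates),
                        stringsAsFactors = FALSE)
    eff <- numeric(nrow(grid))
    tg <- grid$gene != "REF"
    eff[tg] <- log2_effects[cbind(grid$gene[tg], grid$condition[tg])]
    base <- ifelse(grid$gene == "REF", 0, baseline)
    grid$ct <- 20 + base - eff + rnorm(nrow(grid), sd = noise_sd)
    tab <- ct_table(grid, reference_genes = "REF")
    attr(tab, "log2_effects") <- log2_effects
    tab
  })
}
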