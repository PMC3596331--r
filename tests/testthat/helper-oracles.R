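# Independent oracles and fixture builders shared across tests.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(n, pool = AA20) paste(sample(pool, n, replace = TRUE),
                                           collapse = "")

# Minimal group III RING exemplar: ligands at 1,4,16,18,21,24,36,39 with the
# family spacing constants d12=2, d23=11, d36=7, d67=11, d78=2 and all
# conserved flanking residues in place.
ring_exemplar <- function() {
  paste0("CAVC", strrep("A", 11), "CAHAACAAC", strrep("A", 11), "CPVCR")
}

# Brute-force RING candidate enumeration via the regex engine (overlapping
# matches through a lookahead), independent of the package's index-walking
# scanner.  Enumerates every (a, b, d67) sub-spacing combination allowed by
# the cross-brace definition and records the implied ligand tuples.
ring_oracle <- function(seq) {
  out <- list()
  for (a in 1:3) for (b in 2:3) {
    cc <- 5 - a - b
    if (cc < 0) next
    for (d67 in 11:24) {
      pat <- sprintf("(?=(C.{2}C.{11}C.{%d}H.{%d}C.{%d}C.{%d}C.{2}C))",
                     a, b, cc, d67)
      m <- gregexpr(pat, seq, perl = TRUE)[[1]]
      if (m[1] == -1) next
      for (s in as.integer(m)) {
        L3 <- s + 15L; L4 <- L3 + a + 1L; L5 <- L4 + b + 1L
        L6 <- L5 + cc + 1L; L7 <- L6 + d67 + 1L
        out[[length(out) + 1L]] <- c(s, s + 3L, L3, L4, L5, L6, L7, L7 + 3L)
      }
    }
  }
  m <- if (length(out)) unique(do.call(rbind, out)) else matrix(integer(), 0, 8)
  m[order(m[, 1], m[, 8], m[, 4]), , drop = FALSE]
}

tuple_keys <- function(m) if (nrow(m)) apply(m, 1, paste, collapse = ",") else character()

# Alignment with unambiguous signal for both internal edges of the 5-taxon
# tree ((A,B),C,(D,E)): every bootstrap resample supports both splits.
perfect_alignment <- function() {
  pat1 <- c(A = "W", B = "W", C = "G", D = "G", E = "G")
  pat2 <- c(A = "G", B = "G", C = "G", D = "W", E = "W")
  cons <- c(A = "A", B = "A", C = "A", D = "A", E = "A")
  cols <- cbind(matrix(rep(pat1, 20), 5), matrix(rep(pat2, 20), 5),
                matrix(rep(cons, 10), 5))
  rownames(cols) <- names(pat1)
  cols
}

# Full inference pass through the exported pipeline surface.
infer_nj_test <- function(aln) nj_tree(p_distance(complete_deletion(aln)))

# Random additive distance matrix with its generating tree.
random_additive <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.2, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
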