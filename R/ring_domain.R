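# C3HC4 RING finger detection and group I/II/III classification.
#
# The XB3-like C3HC4 RING carries eight metal ligands (C,C,C,H,C,C,C,C) in a
# cross-brace arrangement: ligand pairs 1&3 bind one zinc, 2&4 the other.
# Family-wide spacing constants (residues strictly BETWEEN the named ligands;
# intervening ligands count, so the 7 residues between L3 and L6 include L4
# and L5): d12 = 2, d23 = 11, d36 = 7, d78 = 2.  d67 varies by group:
# 19-23 (I), 21-24 (II), 11 (III).  Conserved flanking residues: Pro right
# after L7 and Arg right after L8 in all groups; Val/Ile right before L2;
# Gly before L4 in group II; the residue before L8 is L (I), F (II), or
# V/I (III).

# d67 window accepted by the scanner (union of the three group windows).
D67_MIN <- 11L
D67_MAX <- 24L

ring_signatures <- function() read_extdata("ring_group_signatures.tsv")

# Enumerate every 8-tuple of ligand positions satisfying the C3HC4
# cross-brace constraints, in left-to-right order of (L1, L8, L4).
# Sub-spacings within the fixed L3..L6 stretch: L3-L4 in {1,2,3},
# L4-L5 in {2,3}, totals constrained so exactly 7 residues lie strictly
# between L3 and L6 (hence L6 = L3 + 8).
ring_candidates <- function(seq) {
  ch <- seq_chars(seq)
  n <- length(ch)
  out <- list()
  for (L1 in which(ch == "C")) {
    L2 <- L1 + 3L
    if (L2 > n || ch[L2] != "C") next
    L3 <- L2 + 12L
    if (L3 > n || ch[L3] != "C") next
    L6 <- L3 + 8L
    if (L6 > n || ch[L6] != "C") next
    for (a in 1:3) {                      # residues between L3 and L4
      L4 <- L3 + a + 1L
      if (ch[L4] != "H") next
      for (b in 2:3) {                    # residues between L4 and L5
        cc <- 5L - a - b                  # residues between L5 and L6
        if (cc < 0L) next
        L5 <- L4 + b + 1L
        if (ch[L5] != "C") next
        for (d67 in D67_MIN:D67_MAX) {
          L7 <- L6 + d67 + 1L
          L8 <- L7 + 3L
          if (L8 > n) break
          if (ch[L7] != "C" || ch[L8] != "C") next
          out[[length(out) + 1L]] <- c(L1, L2, L3, L4, L5, L6, L7, L8)
        }
      }
    }
  }
  m <- if (length(out)) do.call(rbind, out) else
    matrix(integer(), 0, 8)
  colnames(m) <- paste0("L", 1:8)
  m[order(m[, 1], m[, 8], m[, 4]), , drop = FALSE]
}

new_ring_domain <- function(seq, lig) {
  lig <- as.integer(unname(lig))
  ch <- seq_chars(seq)
  n <- length(ch)
  d <- function(i, j) lig[j] - lig[i] - 1L
  dom <- structure(list(
    start = lig[1], end = lig[8],
    ligand_pos = unname(lig),
    ligand_res = ch[lig],
    d12 = d(1, 2), d23 = d(2, 3), d36 = d(3, 6), d67 = d(6, 7), d78 = d(7, 8),
    before_L2 = ch[lig[2] - 1L],
    before_L4 = ch[lig[4] - 1L],
    before_L8 = ch[lig[8] - 1L],
    after_L7  = ch[lig[7] + 1L],
    after_L8  = if (lig[8] + 1L <= n) ch[lig[8] + 1L] else NA_character_,
    # region spans L1 .. one past L8 when available, for consensus reports
    region = paste(ch[lig[1]:min(lig[8] + 1L, n)], collapse = ""),
    group = "unassigned"
  ), class = "ring_domain")
  validate_ring_domain(dom)
  dom
}

validate_ring_domain <- function(dom) {
  stopifnot(
    all(diff(dom$ligand_pos) > 0),
    identical(dom$ligand_res, c("C", "C", "C", "H", "C", "C", "C", "C")),
    dom$d12 == 2L, dom$d78 == 2L, dom$d23 == 11L, dom$d36 == 7L,
    dom$d67 >= D67_MIN, dom$d67 <= D67_MAX,
    # spacing self-consistency: d36 decomposes over the internal ligands
    dom$d36 == (dom$ligand_pos[4] - dom$ligand_pos[3] - 1L) + 1L +
      (dom$ligand_pos[5] - dom$ligand_pos[4] - 1L) + 1L +
      (dom$ligand_pos[6] - dom$ligand_pos[5] - 1L)
  )
  invisible(dom)
}

ring_signature_flags <- function(dom) {
  c(after_L7_P   = identical(dom$after_L7, "P"),
    after_L8_R   = identical(dom$after_L8, "R"),
    before_L2_VI = dom$before_L2 %in% c("V", "I"))
}

#' Scan a protein for C3HC4-type RING finger domains
#'
#' Finds every maximal non-overlapping match of the XB3-like C3HC4 pattern
#' \code{C-x2-C-x11-C-x(1-3)-H-x(2-3)-C-x2-C-x(11-24)-C-x2-C} with exactly 7
#' residues strictly between ligands 3 and 6 (the intervening ligands 4 and 5
#' count among the 7).  Overlapping candidates are resolved left to right:
#' the leftmost start wins, ties broken by the smaller end.
#'
#' In \code{"strict"} mode the conserved signature residues (Pro right after
#' ligand 7, Arg right after ligand 8, Val/Ile right before ligand 2) are
#' required; in \code{"tolerant"} mode they are recorded as flags but do not
#' veto a match, accommodating rare natural deviants.
#'
#' @param seq Amino-acid string over the canonical alphabet.
#' @param strictness \code{"strict"} (default) or \code{"tolerant"}.
#' @return A list of \code{ring_domain} objects (empty if no match), each
#'   carrying 1-based ligand positions, the inter-ligand spacings
#'   \code{d12, d23, d36, d67, d78}, the flanking residues and signature
#'   flags, and a \code{group} slot (filled by \code{\link{classify_group}}).
#' @examples
#' ex <- paste0("CAVC", strrep("A", 11), "CAHAACAAC", strrep("A", 11), "CPVCR")
#' scan_ring(ex)[[1]]$ligand_pos
#' @export
scan_ring <- function(seq, strictness = c("strict", "tolerant")) {
  strictness <- match.arg(strictness)
  check_canonical(seq)
  cand <- ring_candidates(seq)
  doms <- list()
  last_end <- 0L
  for (i in seq_len(nrow(cand))) {
    lig <- cand[i, ]
    if (lig[1] <= last_end) next
    dom <- new_ring_domain(seq, lig)
    if (strictness == "strict" && !all(ring_signature_flags(dom))) next
    doms[[length(doms) + 1L]] <- dom
    last_end <- dom$end
  }
  doms
}

#' @export
print.ring_domain <- function(x, ...) {
  cat(sprintf("C3HC4 RING at %d-%d (group %s)\n", x$start, x$end, x$group))
  cat("  ligands:", paste(x$ligand_res, x$ligand_pos, sep = "", collapse = " "), "\n")
  cat(sprintf("  spacings: d12=%d d23=%d d36=%d d67=%d d78=%d\n",
              x$d12, x$d23, x$d36, x$d67, x$d78))
  invisible(x)
}

#' Assign a RING domain to phylogenetic group I, II or III
#'
#' Classification follows the ligand 6-7 spacing first: 11 is diagnostic for
#' group III; 19-20 can only be group I; 24 can only be group II.  In the
#' 21-23 window, where the group I and II ranges overlap, the residue
#' immediately before ligand 8 decides (Leu = I, Phe = II).  Anything else is
#' \code{"unassigned"}, with the trace recording which tests passed or
#' failed.  The conserved-residue signature flags are evaluated and reported
#' regardless of the outcome.
#'
#' @param domain A \code{ring_domain} from \code{\link{scan_ring}}.
#' @return A list with \code{group} (\code{"I"}, \code{"II"}, \code{"III"} or
#'   \code{"unassigned"}), \code{trace} (character vector of applied rules)
#'   and \code{signatures} (named logical flags plus the flanking residues).
#' @export
classify_group <- function(domain) {
  stopifnot(inherits(domain, "ring_domain"))
  d67 <- domain$d67
  b8 <- domain$before_L8
  trace <- character()
  note <- function(x) trace <<- c(trace, x)
  group <- "unassigned"
  if (d67 < D67_MIN || d67 > D67_MAX) {
    note(sprintf("d67=%d outside accepted window [%d,%d]", d67, D67_MIN, D67_MAX))
  } else if (d67 == 11L) {
    group <- "III"; note("d67=11: diagnostic for group III")
  } else if (d67 %in% 19:20) {
    group <- "I"; note(sprintf("d67=%d: only group I window covers it", d67))
  } else if (d67 == 24L) {
    group <- "II"; note("d67=24: only group II window covers it")
  } else if (d67 %in% 21:23) {
    note(sprintf("d67=%d: group I and II windows overlap", d67))
    if (b8 == "L") {
      group <- "I"; note("before_L8=L: group I")
    } else if (b8 == "F") {
      group <- "II"; note("before_L8=F: group II")
    } else {
      note(sprintf("before_L8=%s matches neither L nor F: unassigned", b8))
    }
  } else {
    note(sprintf("d67=%d falls in no group window: unassigned", d67))
  }
  sigs <- ring_signature_flags(domain)
  sig_detail <- c(sigs,
                  before_L4_G = identical(domain$before_L4, "G"),
                  before_L8_consistent = switch(group,
                    I = b8 == "L", II = b8 == "F", III = b8 %in% c("V", "I"),
                    NA))
  list(group = group, trace = trace, signatures = sig_detail,
       residues = c(before_L2 = domain$before_L2, before_L4 = domain$before_L4,
                    before_L8 = b8, after_L7 = domain$after_L7,
                    after_L8 = domain$after_L8))
}

# Pad a stretch to `width` columns, right-justified with '-' gaps on the left
# (mirrors how the variable L6-L7 stretch is gapped in RING alignments).
pad_stretch <- function(s, width) {
  paste0(strrep("-", width - nchar(s)), s)
}

# Lay the RING region out on a fixed column grid anchored at the eight
# ligand positions; variable stretches are right-justified.
ring_region_columns <- function(dom) {
  p <- dom$ligand_pos - dom$start + 1L
  ch <- seq_chars(dom$region)
  piece <- function(i, j) paste(ch[(p[i] + 1L):(p[j] - 1L)], collapse = "")
  paste0(
    ch[p[1]], piece(1, 2), ch[p[2]], piece(2, 3), ch[p[3]],
    pad_stretch(piece(3, 4), 3L), ch[p[4]],
    pad_stretch(piece(4, 5), 3L), ch[p[5]],
    pad_stretch(piece(5, 6), 2L), ch[p[6]],
    pad_stretch(piece(6, 7), D67_MAX), ch[p[7]],
    piece(7, 8), ch[p[8]],
    if (length(ch) > p[8]) ch[p[8] + 1L] else "-"
  )
}

#' Per-group consensus of a cohort of RING domains
#'
#' Aligns the RING regions of classified domains on a fixed column grid
#' anchored at the eight metal-ligand positions (variable stretches gapped
#' right-justified) and reports, per group, the member count and the majority
#' residue with its frequency at every column.
#'
#' @param domains List of \code{ring_domain} objects whose \code{group} slot
#'   has been filled (see \code{\link{annotate_proteome}}), or with groups
#'   supplied via \code{groups}.
#' @param groups Optional character vector of group labels overriding the
#'   domains' \code{group} slots.
#' @return Named list, one element per group present, each a list with
#'   \code{n}, \code{consensus} (string) and \code{frequency} (numeric vector,
#'   one entry per column).
#' @export
signature_report <- function(domains, groups = NULL) {
  if (length(domains) == 0) stop("empty cohort")
  groups <- groups %||% vapply(domains, function(d) d$group, "")
  stopifnot(length(groups) == length(domains))
  rows <- vapply(domains, ring_region_columns, "")
  out <- list()
  for (g in unique(groups)) {
    mat <- do.call(rbind, strsplit(rows[groups == g], ""))
    maj <- vapply(seq_len(ncol(mat)), function(j) {
      tb <- table(mat[, j])          # majority residue; ties to the
      names(which.max(tb))           # alphabetically first (deterministic)
    }, "")
    freq <- vapply(seq_len(ncol(mat)), function(j)
      max(table(mat[, j])) / nrow(mat), 0)
    out[[g]] <- list(n = sum(groups == g),
                     consensus = paste(maj, collapse = ""),
                     frequency = freq)
  }
  out
}
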