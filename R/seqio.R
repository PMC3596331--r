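# Sequence input/output and physicochemical annotation.

#' Read protein sequences from a FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file into a data frame of
#' protein records.  Sequences are uppercased and a single trailing \code{*}
#' stop character is stripped.  Records containing non-canonical residue
#' letters (anything outside the 20 standard amino acids, e.g. B, J, O, U, X,
#' Z, or internal stops) are rejected: dropped with a warning under the
#' default policy, or a hard error with \code{on_invalid = "error"}.
#'
#' The first whitespace-separated token of the header is the record id; the
#' second token, when present, is kept as a species tag.
#'
#' @param path Path to a FASTA file.
#' @param on_invalid One of \code{"warn"} (drop invalid records with a
#'   warning) or \code{"error"} (fail on the first invalid record).
#' @return A data frame with columns \code{id}, \code{species}, \code{seq},
#'   one row per retained record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 Ath", "MKV", ">p2", "MK", "VA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, on_invalid = c("warn", "error")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1)
  species <- vapply(strsplit(headers, "\\s+"), function(x)
    if (length(x) >= 2) x[2] else "", "")
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate identifiers in ", path, ": ", paste(dups, collapse = ", "))
  }
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*$", "", seqs)
  ok <- !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs) &
    nzchar(seqs)
  if (any(!ok)) {
    msg <- paste0("non-canonical residues or empty sequence in: ",
                  paste(ids[!ok], collapse = ", "))
    if (on_invalid == "error") stop(msg)
    warning(msg, "; record(s) excluded")
  }
  data.frame(id = ids[ok], species = species[ok], seq = unname(seqs[ok]),
             stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' Round-trip property: \code{read_fasta()} applied to the written file
#' returns the input records unchanged.
#'
#' @param records Data frame with columns \code{id}, \code{seq} and
#'   optionally \code{species} (as returned by \code{\link{read_fasta}}).
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    sp <- if ("species" %in% names(records) && nzchar(records$species[i]))
      paste0(" ", records$species[i]) else ""
    writeLines(paste0(">", records$id[i], sp), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

residue_masses <- function() {
  x <- read_extdata("residue_masses_average.tsv")
  setNames(x$mass, x$residue)
}

pk_table <- function() read_extdata("bjellqvist_pk.tsv")

# Mass of one water molecule (Da), added once per chain.
WATER_MASS <- 18.0153

#' Average molecular weight of a protein
#'
#' Sum of packaged average residue masses plus one water mass (18.0153 Da),
#' matching the average (not monoisotopic) molecular weights reported by the
#' ExPASy tools.
#'
#' @param seq Amino-acid string over the 20 canonical residues.
#' @return Mass in Daltons.
#' @examples
#' molecular_weight("G")  # 75.0672
#' @export
molecular_weight <- function(seq) {
  check_canonical(seq)
  m <- residue_masses()
  sum(m[seq_chars(seq)]) + WATER_MASS
}

check_canonical <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq))
    stop("seq must be a non-empty character scalar")
  bad <- setdiff(unique(seq_chars(seq)), AA_ALPHABET)
  if (length(bad))
    stop("non-canonical residues: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the free N- and C-termini and the ionisable
#' side chains (D, E, C, Y, H, K, R) using the packaged Bjellqvist pK set.
#' Strictly decreasing in pH, so its root (the isoelectric point) is unique.
#'
#' @param seq Amino-acid string over the canonical alphabet.
#' @param pH pH value (vectorised).
#' @return Net charge in elementary charge units.
#' @export
protein_charge <- function(seq, pH) {
  check_canonical(seq)
  pk <- pk_table()
  counts <- table(factor(seq_chars(seq), levels = AA_ALPHABET))
  q <- numeric(length(pH))
  for (i in seq_len(nrow(pk))) {
    g <- pk$group[i]
    n <- if (g %in% c("nterm", "cterm")) 1 else as.numeric(counts[[g]])
    if (n == 0) next
    if (pk$type[i] == "base") {
      q <- q + n / (1 + 10^(pH - pk$pk[i]))
    } else {
      q <- q - n / (1 + 10^(pk$pk[i] - pH))
    }
  }
  q
}

#' Isoelectric point of a protein
#'
#' The unique pH in (0, 14) at which \code{\link{protein_charge}} is zero,
#' found by bisection to a bracket width below \code{tol} (default 1e-4 pH
#' units, well inside the 2-decimal precision customary for reported pI
#' values).  The returned point always satisfies |charge(pI)| < 1e-3.
#'
#' @param seq Amino-acid string over the canonical alphabet.
#' @param tol Bisection tolerance in pH units.
#' @return pI in pH units.
#' @examples
#' isoelectric_point("GG")   # (pK_Nterm + pK_Cterm) / 2 = 5.525
#' @export
isoelectric_point <- function(seq, tol = 1e-4) {
  check_canonical(seq)
  lo <- 0; hi <- 14
  if (protein_charge(seq, lo) < 0 || protein_charge(seq, hi) > 0)
    stop("net charge does not change sign on [0, 14]")
  # bisect well past `tol` so the charge at the midpoint is < 1e-3
  while (hi - lo > min(tol, 1e-6)) {
    mid <- (lo + hi) / 2
    if (protein_charge(seq, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
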