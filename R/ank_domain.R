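# Ankyrin (ANK) repeat detection by consensus-window scoring, and the
# repeat-count classes A-F (2..7 repeats).

#' The packaged 33-residue ANK consensus
#'
#' @return Character scalar of length 33.
#' @export
ank_consensus <- function() {
  if (is.null(.xb3_cache$ank_consensus)) {
    path <- system.file("extdata", "ank_consensus.txt",
                        package = "xb3scan", mustWork = TRUE)
    lines <- readLines(path)
    cons <- lines[!grepl("^#", lines) & nzchar(lines)][1]
    stopifnot(nchar(cons) == 33L)
    .xb3_cache$ank_consensus <- cons
  }
  .xb3_cache$ank_consensus
}

# BLOSUM62 restricted to the 20 canonical residues.  Its diagonal dominates
# every row, so the consensus' self-score is the maximum achievable window
# score.
blosum62 <- function() {
  if (is.null(.xb3_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .xb3_cache$blosum62 <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  .xb3_cache$blosum62
}

# Default acceptance threshold in BLOSUM62 score units.  Fixed once by
# calibrate_threshold() at target_fpr = 0 against uniform-random background:
# the consensus self-scores 164, repeats carrying up to 4 point mutations
# cannot score below 121, while the best window of 1000 random length-200
# sequences scored 24.  80 sits near the centre of that gap.
ANK_DEFAULT_THRESHOLD <- 80

#' Default ANK window score threshold
#' @return Score threshold in BLOSUM62 units (see \code{\link{scan_ank}}).
#' @export
ank_default_threshold <- function() ANK_DEFAULT_THRESHOLD

# Score every 33-residue window of `seq` against the consensus; returns a
# numeric vector indexed by window start.
ank_window_scores <- function(seq) {
  ch <- seq_chars(seq)
  n <- length(ch)
  if (n < 33L) return(numeric())
  B <- blosum62()
  cons <- seq_chars(ank_consensus())
  starts <- seq_len(n - 32L)
  sc <- numeric(length(starts))
  for (k in 0:32) sc <- sc + B[cbind(ch[starts + k], cons[k + 1L])]
  sc
}

ank_class_of <- function(count) {
  if (count >= 2L && count <= 7L) LETTERS[count - 1L] else "unclassified"
}

#' Scan a protein for tandem 33-residue ankyrin repeats
#'
#' Slides a 33-column window along the sequence, scoring each position
#' against the packaged ANK consensus with BLOSUM62.  Windows scoring at
#' least \code{threshold} are accepted greedily in order of descending score
#' (ties to the leftmost), discarding any window overlapping an accepted one.
#' The repeat count maps to class A-F (2, 3, 4, 5, 6, 7 repeats); counts of
#' 0, 1 or more than 7 are \code{"unclassified"}.
#'
#' @param seq Amino-acid string over the canonical alphabet.
#' @param threshold Minimum window score; see
#'   \code{\link{calibrate_threshold}} for how the default was fixed.
#' @return An \code{ank_annotation}: list with \code{repeats} (data frame of
#'   \code{start}, \code{end}, \code{score}, sorted by position,
#'   non-overlapping, every interval exactly 33 residues), \code{count} and
#'   \code{ank_class}.
#' @examples
#' scan_ank(strrep(ank_consensus(), 3))$count  # 3
#' @export
scan_ank <- function(seq, threshold = ank_default_threshold()) {
  check_canonical(seq)
  sc <- ank_window_scores(seq)
  keep <- which(sc >= threshold)
  keep <- keep[order(-sc[keep], keep)]
  taken <- integer()
  for (s in keep) {
    if (!any(abs(taken - s) < 33L)) taken <- c(taken, s)
  }
  taken <- sort(taken)
  repeats <- data.frame(start = taken, end = taken + 32L,
                        score = sc[taken])
  count <- nrow(repeats)
  structure(list(repeats = repeats, count = count,
                 ank_class = ank_class_of(count)),
            class = "ank_annotation")
}

#' @export
print.ank_annotation <- function(x, ...) {
  cat(sprintf("%d ANK repeat(s), class %s\n", x$count, x$ank_class))
  if (x$count) print(x$repeats)
  invisible(x)
}

#' Calibrate the ANK acceptance threshold
#'
#' Returns the smallest score threshold whose empirical false-positive rate
#' on the negative set does not exceed \code{target_fpr}, together with the
#' sensitivity on the positive set at that threshold.  Positives are scored
#' directly as 33-mers against the consensus; negatives by their best
#' 33-residue window.
#'
#' @param positives Character vector of 33-residue repeat instances (e.g. the
#'   consensus carrying k point mutations).
#' @param negatives Character vector of background sequences (length >= 33).
#' @param target_fpr Tolerated fraction of negatives at or above the
#'   threshold.
#' @return List with \code{threshold}, \code{sensitivity}, \code{fpr}.
#' @export
calibrate_threshold <- function(positives, negatives, target_fpr = 0) {
  if (!length(positives) || !length(negatives))
    stop("positives and negatives must both be non-empty")
  if (target_fpr < 0 || target_fpr > 1)
    stop("target_fpr must lie in [0, 1]; achievable minimum is 0")
  stopifnot(all(nchar(positives) == 33L))
  B <- blosum62()
  cons <- seq_chars(ank_consensus())
  pos_scores <- vapply(positives, function(p)
    sum(B[cbind(seq_chars(p), cons)]), 0)
  neg_scores <- vapply(negatives, function(s) max(ank_window_scores(s)), 0)
  # smallest integer threshold with FPR <= target (scores are integers)
  allowed <- floor(target_fpr * length(neg_scores))
  srt <- sort(neg_scores, decreasing = TRUE)
  threshold <- unname(if (allowed >= length(srt)) min(srt) else
    srt[allowed + 1L] + 1)
  list(threshold = threshold,
       sensitivity = mean(pos_scores >= threshold),
       fpr = mean(neg_scores >= threshold))
}
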