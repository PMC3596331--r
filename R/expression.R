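# qPCR expression analysis: delta-Ct normalisation against reference genes,
# fold changes (assuming 100% amplification efficiency, factor 2 per cycle),
# classic two-sample Student t tests on replicate delta-Ct values, and the
# family's decision rules: preferential expression (> 2-fold against EVERY
# other tissue, P < 0.05) and treatment response (> 1.2-fold vs control,
# P < 0.05).

#' Construct and validate a Ct table
#'
#' @param df Data frame with columns \code{gene}, \code{condition},
#'   \code{replicate}, \code{ct} (threshold cycles).
#' @param reference_genes Character vector naming the normalisation
#'   controls; must be measured in every condition.
#' @return The validated data frame, classed \code{ct_table}, with the
#'   reference genes recorded in \code{attr(, "reference_genes")}.
#' @export
ct_table <- function(df, reference_genes) {
  stopifnot(is.data.frame(df),
            all(c("gene", "condition", "replicate", "ct") %in% names(df)))
  if (!length(reference_genes) || !all(reference_genes %in% df$gene))
    stop("reference genes missing from the table")
  if (any(df$ct <= 0 | df$ct >= 45))
    stop("Ct values must lie in (0, 45) cycles")
  nrep <- table(df$gene, df$condition)
  if (length(unique(as.vector(nrep))) != 1)
    stop("every gene x condition must have the same replicate count")
  if (as.vector(nrep)[1] < 2) stop("at least 2 replicates are required")
  for (cond in unique(df$condition)) {
    present <- unique(df$gene[df$condition == cond])
    if (!all(reference_genes %in% present))
      stop("reference gene missing in condition: ", cond)
  }
  structure(df, class = c("ct_table", "data.frame"),
            reference_genes = reference_genes)
}

#' Read a Ct table from TSV
#'
#' @param path TSV with columns \code{gene}, \code{condition},
#'   \code{replicate}, \code{ct}.
#' @param reference_genes Names of the normalisation control genes.
#' @return A \code{ct_table}.
#' @export
read_ct_table <- function(path, reference_genes) {
  ct_table(read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
           reference_genes)
}

#' Delta-Ct normalisation
#'
#' Per replicate, delta-Ct = Ct(gene) - Ct(reference), where the reference Ct
#' is the mean over the reference genes measured in the same condition and
#' replicate.  Relative expression is \code{2^(-delta Ct)}.
#'
#' @param tab A \code{ct_table}.
#' @return Data frame \code{gene, condition, replicate, delta_ct, rel_expr}
#'   for the non-reference genes.
#' @export
delta_ct <- function(tab) {
  stopifnot(inherits(tab, "ct_table"))
  refs <- attr(tab, "reference_genes")
  rtab <- tab[tab$gene %in% refs, ]
  key <- paste(rtab$condition, rtab$replicate)
  ref_ct <- tapply(rtab$ct, key, mean)
  gt <- tab[!tab$gene %in% refs, ]
  gkey <- paste(gt$condition, gt$replicate)
  if (any(!gkey %in% names(ref_ct)))
    stop("missing reference Ct for some condition x replicate")
  dct <- gt$ct - as.numeric(ref_ct[gkey])
  data.frame(gene = gt$gene, condition = gt$condition,
             replicate = gt$replicate, delta_ct = dct,
             rel_expr = 2^(-dct), stringsAsFactors = FALSE)
}

# Classic (equal-variance) two-sided two-sample Student t on replicate
# delta-Ct values, with a limit-value guard for zero-variance groups, which
# synthetic noise-free data can produce.
student_p <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  t.test(x, y, var.equal = TRUE)$p.value
}

fc_between <- function(dct, gene, test, control) {
  x <- dct$delta_ct[dct$gene == gene & dct$condition == test]
  y <- dct$delta_ct[dct$gene == gene & dct$condition == control]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 replicates per condition for gene ", gene)
  list(fc = 2^(mean(y) - mean(x)), p = student_p(x, y))
}

#' Fold change and differential-expression calls between two conditions
#'
#' Fold change for each gene is \code{2^(mean dCt(control) - mean dCt(test))}
#' (so FC > 1 means higher expression under \code{test}); the P value is a
#' two-sided classic Student t test on the replicate delta-Ct values.  A gene
#' is called \code{up} when FC > \code{fold} and P < \code{alpha},
#' \code{down} when FC < 1/\code{fold} and P < \code{alpha}, otherwise
#' \code{unchanged}.  The default 1.2-fold / 0.05 rule is the customary
#' treatment-response criterion for qPCR panels.
#'
#' @param tab A \code{ct_table}.
#' @param test,control Condition labels (test vs control).
#' @param fold Fold-change cutoff (default 1.2).
#' @param alpha P-value cutoff (default 0.05).
#' @param adjust Add a Benjamini-Hochberg adjusted-P column (off by default;
#'   calls are always made on the raw P values).
#' @return Data frame \code{gene, condition, fold_change, p_value, call}
#'   (plus \code{p_adj} when \code{adjust = TRUE}).
#' @export
fold_change <- function(tab, test, control, fold = 1.2, alpha = 0.05,
                        adjust = FALSE) {
  stopifnot(inherits(tab, "ct_table"))
  if (!all(c(test, control) %in% tab$condition))
    stop("test/control condition not present in the table")
  dct <- delta_ct(tab)
  genes <- unique(dct$gene)
  res <- do.call(rbind, lapply(genes, function(g) {
    z <- fc_between(dct, g, test, control)
    data.frame(gene = g, condition = test, fold_change = z$fc,
               p_value = z$p, stringsAsFactors = FALSE)
  }))
  res$call <- ifelse(res$fold_change > fold & res$p_value < alpha, "up",
              ifelse(res$fold_change < 1 / fold & res$p_value < alpha,
                     "down", "unchanged"))
  if (adjust) res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Preferential-expression call for one gene across tissues
#'
#' A tissue is called preferential iff, against EVERY other tissue, the gene
#' is more than \code{fold}-fold higher (default 2) with Student-t P <
#' \code{alpha}.  The all-pairs requirement means at most one tissue can ever
#' satisfy it.
#'
#' @param tab A \code{ct_table} whose conditions are tissue labels.
#' @param gene Gene to test.
#' @param fold Fold cutoff against each other tissue (default 2).
#' @param alpha P-value cutoff (default 0.05).
#' @return List with \code{tissue} (the preferential tissue, or
#'   \code{NA_character_} if none) and \code{pairs}, the full pairwise
#'   fold-change / P table.
#' @export
preferential_call <- function(tab, gene, fold = 2, alpha = 0.05) {
  stopifnot(inherits(tab, "ct_table"))
  dct <- delta_ct(tab)
  tissues <- unique(tab$condition)
  if (length(tissues) < 2) stop("need at least 2 tissues")
  pairs <- do.call(rbind, lapply(tissues, function(t1) {
    others <- setdiff(tissues, t1)
    do.call(rbind, lapply(others, function(t2) {
      z <- fc_between(dct, gene, t1, t2)
      data.frame(tissue = t1, versus = t2, fold_change = z$fc,
                 p_value = z$p, stringsAsFactors = FALSE)
    }))
  }))
  pass <- vapply(tissues, function(t1) {
    sel <- pairs$tissue == t1
    all(pairs$fold_change[sel] > fold & pairs$p_value[sel] < alpha)
  }, TRUE)
  list(tissue = if (any(pass)) tissues[which(pass)[1]] else NA_character_,
       pairs = pairs)
}

#' Write expression calls as TSV
#' @param calls Data frame from \code{\link{fold_change}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_expression_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# xb3scan %s expression calls",
                     as.character(utils::packageVersion("xb3scan"))), con)
  write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
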