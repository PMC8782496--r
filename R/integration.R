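# Gene-level cross-omics integration: Spearman rank correlation of
# expression with copy number or methylation, and a concordance screen for
# genes altered in the same direction across nearly all samples.

correlate_layers <- function(expr, layer, min_samples = 5) {
  stopifnot(identical(dim(expr), dim(layer)))
  genes <- rownames(expr)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(expr)))
  res <- lapply(seq_len(nrow(expr)), function(i) {
    x <- expr[i, ]
    y <- layer[i, ]
    ok <- complete.cases(x, y)
    if (sum(ok) < min_samples)
      return(data.frame(gene = genes[i], rho = NA_real_, p_value = NA_real_,
                        note = "insufficient samples",
                        stringsAsFactors = FALSE))
    if (length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2)
      return(data.frame(gene = genes[i], rho = NA_real_, p_value = NA_real_,
                        note = "constant layer", stringsAsFactors = FALSE))
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(gene = genes[i], rho = unname(ct$estimate),
               p_value = ct$p.value, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out
}

#' Correlate gene expression with copy number across samples
#'
#' Per-gene Spearman rank correlation between expression (log2 fold change
#' vs matched normal) and the copy-number layer (discrete states in
#' \{-1, 0, 1\} or continuous values), with Benjamini-Hochberg adjustment
#' across genes. Genes with a constant layer or fewer than `min_samples`
#' complete pairs are skipped with a note.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param cnv Genes-by-samples copy-number matrix, aligned to `expr`.
#' @param min_samples Minimum complete sample pairs per gene (default 5).
#' @return Data.frame `gene`, `rho`, `p_value`, `q_value`, `note`.
#' @export
correlate_expression_cnv <- function(expr, cnv, min_samples = 5) {
  correlate_layers(expr, cnv, min_samples)
}

#' Correlate gene expression with methylation across samples
#'
#' Same procedure as [correlate_expression_cnv()] with the methylation
#' layer (states in \{-1, 0, 1\} or continuous enrichment values).
#'
#' @inheritParams correlate_expression_cnv
#' @param methylation Genes-by-samples methylation matrix.
#' @return Data.frame `gene`, `rho`, `p_value`, `q_value`, `note`.
#' @export
correlate_expression_methylation <- function(expr, methylation,
                                             min_samples = 5) {
  correlate_layers(expr, methylation, min_samples)
}

#' Screen for cohort-wide concordant alterations
#'
#' Flags genes whose per-sample values satisfy the stated direction
#' (`"down"`: value < 0, `"up"`: value > 0) in all but at most `tolerance`
#' samples — the pattern of a biomarker consistently lost (expression down,
#' or copy-number state -1) across a cohort with at most one deviating
#' lesion.
#'
#' @param values Genes-by-samples numeric matrix (log2 fold changes or
#'   discrete states).
#' @param direction `"down"` or `"up"`.
#' @param tolerance Number of samples allowed to deviate (default 1).
#' @return Data.frame `gene`, `n_concordant`, `n_samples`, `flagged`.
#' @export
screen_concordant_genes <- function(values, direction = c("down", "up"),
                                    tolerance = 1) {
  direction <- match.arg(direction)
  genes <- rownames(values)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(values)))
  hit <- if (direction == "down") values < 0 else values > 0
  n_conc <- rowSums(hit, na.rm = TRUE)
  n_samp <- rowSums(!is.na(values))
  data.frame(gene = genes, n_concordant = n_conc, n_samples = n_samp,
             flagged = n_conc >= n_samp - tolerance,
             stringsAsFactors = FALSE, row.names = NULL)
}
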