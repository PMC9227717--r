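# Gene-group logic on the four standard contrasts.
#
# Group 1 "toxicity":    significant in exposed vs unexposed siblings.
# Group 2 "sensitivity": significant in exposed mutants vs unexposed
#                        siblings AND NOT significant in either single
#                        comparison. Split into synergistic (significant,
#                        sign-concordant interaction) and additive.
# Group 3 "mutant":      significant in unexposed mutants vs unexposed
#                        siblings. Split into rescued (no longer different
#                        in exposed mutants) and persistent.
# Groups are deliberately not mutually exclusive.

results_by_gene <- function(results) {
  need <- c("toxicity", "mutant_exposed", "mutant", "interaction")
  miss <- setdiff(need, names(results))
  if (length(miss) > 0L)
    mntox_error(sprintf("missing contrast table(s): %s",
                        paste(miss, collapse = ", ")), "mntox_data_error")
  universe <- results[[need[1L]]]$gene_id
  for (nm in need) {
    if (!identical(results[[nm]]$gene_id, universe))
      mntox_error("contrast tables cover different gene universes",
                  "mntox_data_error")
  }
  results[need]
}

sig_at <- function(padj, q) !is.na(padj) & padj <= q

#' Classify genes into the three factorial groups
#'
#' @param results Named list of the four contrast result tables
#'   (`toxicity`, `mutant_exposed`, `mutant`, `interaction`), all over the
#'   same gene universe.
#' @param q Adjusted-p significance threshold (default 0.05).
#' @return data.frame per gene with logical group memberships
#'   `in_group1_toxicity`, `in_group2_sensitivity`, `in_group3_mutant`,
#'   plus `sensitivity_mode` and `mutant_fate` initialised to `"n/a"` and
#'   `most_sensitive_target` to `FALSE` (filled by [split_sensitivity()]
#'   and [rescue_report()]).
#' @export
classify_genes <- function(results, q = 0.05) {
  res <- results_by_gene(results)
  s1 <- sig_at(res$toxicity$padj, q)
  s2 <- sig_at(res$mutant_exposed$padj, q)
  s3 <- sig_at(res$mutant$padj, q)
  data.frame(
    gene_id = res$toxicity$gene_id,
    in_group1_toxicity = s1,
    in_group2_sensitivity = s2 & !s1 & !s3,
    in_group3_mutant = s3,
    sensitivity_mode = "n/a",
    mutant_fate = "n/a",
    antagonistic_interaction = FALSE,
    most_sensitive_target = FALSE,
    stringsAsFactors = FALSE)
}

#' Split increased-sensitivity genes into synergistic vs additive
#'
#' A group-2 gene is synergistic when the interaction term is itself
#' significant and has the same sign as the total exposed-mutant effect
#' (the combined single effects fall significantly short of the observed
#' change); otherwise the change is consistent with adding the two
#' sub-threshold single effects. Significant opposite-sign interactions
#' are additionally flagged in `antagonistic_interaction`.
#'
#' @param classification Output of [classify_genes()].
#' @param results The same contrast list.
#' @param q Significance threshold.
#' @return The classification with `sensitivity_mode` filled for group-2
#'   genes.
#' @export
split_sensitivity <- function(classification, results, q = 0.05) {
  res <- results_by_gene(results)
  if (!identical(classification$gene_id, res$toxicity$gene_id))
    mntox_error("classification and results cover different genes",
                "mntox_data_error")
  g2 <- classification$in_group2_sensitivity
  int_sig <- sig_at(res$interaction$padj, q)
  concord <- sign(res$interaction$lfc) == sign(res$mutant_exposed$lfc)
  concord[is.na(concord)] <- FALSE
  syn <- g2 & int_sig & concord
  classification$sensitivity_mode <- ifelse(
    g2, ifelse(syn, "synergistic", "additive"), "n/a")
  classification$antagonistic_interaction <- g2 & int_sig & !concord
  classification
}

#' Identify rescued vs persistent mutant-effect genes
#'
#' A group-3 gene is `rescued` when it is no longer significantly
#' different between exposed mutants and unexposed siblings (evidence that
#' exogenous metal normalises its expression), `persistent` otherwise.
#' Persistent genes that are also in the toxicity group are marked as the
#' most sensitive toxicity targets.
#'
#' @inheritParams split_sensitivity
#' @return List with `classification` (mutant_fate and
#'   most_sensitive_target filled) and `summary` (set sizes, fractions and
#'   intersections).
#' @export
rescue_report <- function(classification, results, q = 0.05) {
  res <- results_by_gene(results)
  if (!identical(classification$gene_id, res$toxicity$gene_id))
    mntox_error("classification and results cover different genes",
                "mntox_data_error")
  g3 <- classification$in_group3_mutant
  c2_sig <- sig_at(res$mutant_exposed$padj, q)
  classification$mutant_fate <- ifelse(
    g3, ifelse(c2_sig, "persistent", "rescued"), "n/a")
  classification$most_sensitive_target <-
    classification$mutant_fate == "persistent" &
    classification$in_group1_toxicity
  cl <- classification
  n3 <- sum(g3)
  summary <- list(
    n_genes = nrow(cl),
    n_group1_toxicity = sum(cl$in_group1_toxicity),
    n_group2_sensitivity = sum(cl$in_group2_sensitivity),
    n_group3_mutant = n3,
    n_synergistic = sum(cl$sensitivity_mode == "synergistic"),
    n_additive = sum(cl$sensitivity_mode == "additive"),
    n_rescued = sum(cl$mutant_fate == "rescued"),
    n_persistent = sum(cl$mutant_fate == "persistent"),
    n_most_sensitive_target = sum(cl$most_sensitive_target),
    frac_rescued = if (n3 > 0) sum(cl$mutant_fate == "rescued") / n3 else NA,
    n_group1_and_group3 = sum(cl$in_group1_toxicity & g3),
    n_group1_and_group2 = sum(cl$in_group1_toxicity &
                                cl$in_group2_sensitivity),
    n_group2_and_group3 = sum(cl$in_group2_sensitivity & g3))
  list(classification = classification, summary = summary)
}

#' Full classification in one call
#'
#' Runs [classify_genes()], [split_sensitivity()] and [rescue_report()].
#'
#' @inheritParams classify_genes
#' @return As [rescue_report()].
#' @export
classify_all <- function(results, q = 0.05) {
  cl <- classify_genes(results, q)
  cl <- split_sensitivity(cl, results, q)
  rescue_report(cl, results, q)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = Ct_target - Ct_reference` per sample; `ddCt` subtracts the mean
#' `dCt` of the control condition; the fold change is `2^-ddCt`.
#'
#' @param ct_table data.frame with columns `sample`, `condition`, `gene`,
#'   `ct`.
#' @param target_gene,reference_gene Gene labels to use.
#' @param control_condition Condition defining the baseline.
#' @return data.frame per sample with `dct`, `ddct` and `fold`.
#' @export
delta_delta_ct <- function(ct_table, target_gene, reference_gene,
                           control_condition) {
  t_rows <- ct_table[ct_table$gene == target_gene, ]
  r_rows <- ct_table[ct_table$gene == reference_gene, ]
  if (nrow(t_rows) == 0L || nrow(r_rows) == 0L)
    mntox_error("target or reference gene absent from Ct table",
                "mntox_data_error")
  m <- merge(t_rows[, c("sample", "condition", "ct")],
             r_rows[, c("sample", "ct")],
             by = "sample", suffixes = c("_target", "_reference"),
             all.x = TRUE)
  if (any(is.na(m$ct_reference)) || any(is.na(m$ct_target))) {
    bad <- m$sample[is.na(m$ct_reference) | is.na(m$ct_target)][1L]
    mntox_error(sprintf("missing Ct for sample '%s'", bad),
                "mntox_data_error")
  }
  if (!any(m$condition == control_condition))
    mntox_error("control condition has no samples", "mntox_data_error")
  m$dct <- m$ct_target - m$ct_reference
  m$ddct <- m$dct - mean(m$dct[m$condition == control_condition])
  m$fold <- 2^(-m$ddct)
  m[order(m$condition, m$sample),
    c("sample", "condition", "dct", "ddct", "fold")]
}

#' Concordance of sequencing and qPCR fold changes
#'
#' @param seq_lfc Named numeric, log2 fold changes from sequencing.
#' @param qpcr_folds Named positive numeric, qPCR fold changes (linear).
#' @return List with per-gene table (`seq_lfc`, `qpcr_lfc`, `log2_ratio`,
#'   `sign_concordant`) and the summary fraction of sign-concordant genes.
#' @export
compare_qpcr <- function(seq_lfc, qpcr_folds) {
  genes <- intersect(names(seq_lfc), names(qpcr_folds))
  if (length(genes) == 0L)
    mntox_error("no genes shared between sequencing and qPCR inputs",
                "mntox_data_error")
  qp <- log2(qpcr_folds[genes])
  sq <- seq_lfc[genes]
  tab <- data.frame(gene_id = genes, seq_lfc = unname(sq),
                    qpcr_lfc = unname(qp),
                    log2_ratio = unname(sq - qp),
                    sign_concordant = unname(sign(sq) == sign(qp)),
                    stringsAsFactors = FALSE)
  list(table = tab,
       fraction_concordant = mean(tab$sign_concordant))
}

#' Write a gene classification table
#' @param classification Classification data.frame.
#' @param path TSV path.
#' @export
write_classification <- function(classification, path) {
  utils::write.table(classification, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
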