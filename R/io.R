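#' @keywords internal
"_PACKAGE"

GENOTYPE_LEVELS  <- c("wt", "het", "hom")
TREATMENT_LEVELS <- c("unexposed", "exposed")
GROUP_LEVELS     <- c("sibling", "mutant")

mntox_error <- function(msg, class) {
  stop(structure(class = c(class, "mntox_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Derive the analysis group from genotypes
#'
#' Homozygous mutants form the `mutant` group; wild-type and heterozygous
#' individuals are pooled as unaffected `sibling`s, the reference group of
#' the factorial design.
#'
#' @param genotype Character vector with values `wt`, `het` or `hom`.
#' @return Factor with levels `sibling`, `mutant`.
#' @export
analysis_group <- function(genotype) {
  bad <- setdiff(unique(genotype), GENOTYPE_LEVELS)
  if (length(bad) > 0L)
    mntox_error(sprintf("unknown genotype token(s): %s",
                        paste(bad, collapse = ", ")), "mntox_vocab_error")
  factor(ifelse(genotype == "hom", "mutant", "sibling"), levels = GROUP_LEVELS)
}

#' Build and validate a sample table
#'
#' @param sample_id Unique sample identifiers.
#' @param genotype `wt`, `het` or `hom`.
#' @param treatment `unexposed` or `exposed`.
#' @return A `data.frame` with columns `sample_id`, `genotype`, `treatment`
#'   and the derived `analysis_group`.
#' @export
make_samples <- function(sample_id, genotype, treatment) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    mntox_error("duplicate sample_id values", "mntox_duplicate_id_error")
  bad <- setdiff(unique(as.character(treatment)), TREATMENT_LEVELS)
  if (length(bad) > 0L)
    mntox_error(sprintf("unknown treatment token(s): %s",
                        paste(bad, collapse = ", ")), "mntox_vocab_error")
  data.frame(
    sample_id = sample_id,
    genotype = factor(as.character(genotype), levels = GENOTYPE_LEVELS),
    treatment = factor(as.character(treatment), levels = TREATMENT_LEVELS),
    analysis_group = analysis_group(as.character(genotype)),
    stringsAsFactors = FALSE
  )
}

#' Read a sample sheet
#'
#' @param path CSV file with columns `sample_id`, `genotype`, `treatment`.
#' @return Sample table as from [make_samples()].
#' @export
read_samples <- function(path) {
  if (!file.exists(path))
    mntox_error(sprintf("sample sheet not found: %s", path), "mntox_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    mntox_error(sprintf("sample sheet missing column(s): %s",
                        paste(miss, collapse = ", ")), "mntox_format_error")
  make_samples(df$sample_id, df$genotype, df$treatment)
}

#' Write a sample sheet
#' @param samples Sample table.
#' @param path Output CSV path.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(
    samples[, c("sample_id", "genotype", "treatment")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (!is.matrix(counts))
    mntox_error("counts must be a matrix", "mntox_format_error")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    mntox_error("count matrix needs gene row names and sample column names",
                "mntox_format_error")
  if (anyDuplicated(rownames(counts)))
    mntox_error("duplicate gene ids in count matrix", "mntox_duplicate_id_error")
  if (anyDuplicated(colnames(counts)))
    mntox_error("duplicate sample ids in count matrix",
                "mntox_duplicate_id_error")
  bad <- which(counts < 0 | counts != round(counts) | !is.finite(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    mntox_error(sprintf(
      "non-integer or negative count at gene '%s', sample '%s'",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]),
      "mntox_format_error")
  storage.mode(counts) <- "integer"
  counts
}

#' Read a gene-by-sample count table
#'
#' Tab-separated, first column gene ids, header row sample ids. Gzipped
#' files are accepted by extension. Row and column order are preserved.
#'
#' @param path Count table path (`.tsv` or `.tsv.gz`).
#' @return Integer matrix, genes in rows, with dimnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path))
    mntox_error(sprintf("count table not found: %s", path), "mntox_io_error")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    mntox_error("count table needs a gene id column plus >=1 sample column",
                "mntox_format_error")
  gene_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    cell <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                    !is.na(m), arr.ind = TRUE)
    loc <- if (nrow(cell) > 0L)
      sprintf(" at gene '%s', sample '%s'", gene_ids[cell[1L, 1L]],
              colnames(m)[cell[1L, 2L]]) else ""
    mntox_error(paste0("non-numeric count value", loc), "mntox_format_error")
  }
  rownames(m) <- gene_ids
  validate_counts(m)
}

#' Write a count table
#' @param counts Integer matrix, genes in rows.
#' @param path Output TSV path (gzipped if ending in `.gz`).
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression result table
#' @param path TSV with columns `gene_id`, `contrast`, `lfc`, `se`, `stat`,
#'   `pvalue`, `padj`.
#' @return data.frame of per-gene Wald results.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "contrast", "lfc", "se", "stat", "pvalue", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    mntox_error(sprintf("result table missing column(s): %s",
                        paste(miss, collapse = ", ")), "mntox_format_error")
  ok <- !is.na(df$pvalue)
  if (any(df$pvalue[ok] < 0 | df$pvalue[ok] > 1) ||
      any(df$padj[!is.na(df$padj)] < 0 | df$padj[!is.na(df$padj)] > 1))
    mntox_error("pvalue/padj outside [0, 1]", "mntox_format_error")
  df
}

#' Write a differential-expression result table
#' @param results data.frame as produced by [wald_contrast()].
#' @param path Output TSV path.
#' @export
write_results <- function(results, path) {
  cols <- c("gene_id", "contrast", "lfc", "se", "stat", "pvalue", "padj")
  out <- results[, cols]
  for (col in c("lfc", "se", "stat"))
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  for (col in c("pvalue", "padj"))
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

condition_of <- function(samples) {
  interaction(samples$analysis_group, samples$treatment, sep = "_",
              drop = FALSE)
}

#' PCA-based sample outlier QC
#'
#' Formalises visual PCA inspection as a distance rule: samples are
#' projected onto the first two principal components of
#' `log2(normalised count + 1)` (size-factor normalised), and a sample is
#' flagged when its Euclidean distance from its condition centroid in
#' (PC1, PC2) exceeds `k_mad` times the median absolute deviation of all
#' within-condition distances. Each PC's sign is fixed so that its
#' largest-magnitude gene loading is positive, making the projection
#' deterministic.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param samples Sample table matching the columns of `counts`.
#' @param k_mad Flagging multiplier (default 5).
#' @return Object of class `pca_qc`: list with `flagged` (sample ids),
#'   `scores` (sample x PC matrix), `distance`, `threshold`, `condition`.
#' @export
pca_outlier_qc <- function(counts, samples, k_mad = 5) {
  counts <- validate_counts(counts)
  if (!identical(colnames(counts), samples$sample_id))
    mntox_error("count matrix columns do not match sample sheet",
                "mntox_data_error")
  cond <- condition_of(samples)
  if (any(table(cond) < 3L))
    mntox_error("each condition needs >=3 samples for PCA QC",
                "mntox_insufficient_replicates_error")
  sf <- size_factors(counts)
  x <- log2(sweep(counts, 2L, sf, "/") + 1)
  keep <- apply(x, 1L, stats::var) > 0
  if (!any(keep)) {
    # no between-sample variation at all: nothing can be an outlier
    scores <- matrix(0, ncol(counts), 2L,
                     dimnames = list(samples$sample_id, c("PC1", "PC2")))
    return(structure(list(flagged = character(0), scores = scores,
                          distance = rep(0, ncol(counts)), threshold = 0,
                          condition = cond, k_mad = k_mad),
                     class = "pca_qc"))
  }
  pc <- stats::prcomp(t(x[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  # deterministic sign: largest-|loading| gene positive in each PC
  for (i in seq_len(ncol(scores))) {
    load <- pc$rotation[, i]
    s <- sign(load[which.max(abs(load))])
    if (s < 0) scores[, i] <- -scores[, i]
  }
  # robust (median) condition centroid so one outlier cannot drag it
  cent <- apply(scores, 2L, function(v)
    stats::ave(v, cond, FUN = stats::median))
  d <- sqrt(rowSums((scores - cent)^2))
  mad_d <- stats::mad(d, center = stats::median(d))
  thr <- stats::median(d) + k_mad * mad_d
  flagged <- samples$sample_id[mad_d > 0 & d > thr]
  structure(list(flagged = flagged, scores = scores, distance = d,
                 threshold = thr, condition = cond, k_mad = k_mad),
            class = "pca_qc")
}

#' Write a QC report as JSON
#' @param qc A `pca_qc` object.
#' @param path Output JSON path.
#' @export
write_qc_json <- function(qc, path) {
  jsonlite::write_json(list(
    flagged = qc$flagged,
    k_mad = qc$k_mad,
    threshold = qc$threshold,
    distance = as.list(stats::setNames(qc$distance, rownames(qc$scores)))
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
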