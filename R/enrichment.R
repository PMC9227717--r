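# Ontology enrichment: OBO DAG handling, true-path annotation propagation,
# term-for-term hypergeometric testing with Holm-Bonferroni, and the
# parent-child-union method with Bonferroni. Only is_a relations are used
# (zebrafish anatomy / GO style); enrichment is right-sided only.

#' Load an OBO ontology as a DAG
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file, keeping `id`, `name`
#' and `is_a` child-to-parent edges. Obsolete terms are skipped and
#' counted. The graph must be acyclic; every non-root term must reach a
#' root.
#'
#' @param path OBO file path.
#' @return Object of class `ontology_dag`: `terms` (data.frame `id`,
#'   `name`), `parents` (named list, term -> is_a parents), `roots`,
#'   `n_obsolete`.
#' @export
load_obo <- function(path) {
  if (!file.exists(path))
    mntox_error(sprintf("OBO file not found: %s", path), "mntox_io_error")
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  term_ids <- character(0)
  term_names <- character(0)
  parents <- list()
  n_obsolete <- 0L
  for (k in seq_along(stanza_starts)) {
    from <- stanza_starts[k]
    if (lines[from] != "[Term]") next
    to <- if (k < length(stanza_starts)) stanza_starts[k + 1L] - 1L
          else length(lines)
    block <- lines[(from + 1L):to]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "",
               grep(paste0("^", key, ":"), block, value = TRUE))
      if (length(v) > 0L) v else character(0)
    }
    id <- get1("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    if (any(grepl("^is_obsolete: *true", block))) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    isa <- sub(" *!.*$", "", get1("is_a"))
    term_ids <- c(term_ids, id)
    nm <- get1("name")
    term_names <- c(term_names, if (length(nm) > 0L) nm[1L] else id)
    parents[[id]] <- trimws(isa)
  }
  if (length(term_ids) == 0L)
    mntox_error("no [Term] stanzas found", "mntox_format_error")
  # drop is_a references to terms absent from the file (e.g. obsolete)
  parents <- lapply(parents, function(p) intersect(p, term_ids))
  edges <- do.call(rbind, lapply(term_ids, function(id) {
    p <- parents[[id]]
    if (length(p) > 0L) cbind(id, p) else NULL
  }))
  if (!is.null(edges) && nrow(edges) > 0L) {
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      big <- which(comp$csize > 1L)[1L]
      cyc <- names(comp$membership)[comp$membership == big]
      mntox_error(sprintf("cyclic is_a relation involving: %s",
                          paste(utils::head(cyc, 5L), collapse = ", ")),
                  "mntox_cycle_error")
    }
  }
  roots <- term_ids[vapply(parents[term_ids], length, 1L) == 0L]
  structure(list(
    terms = data.frame(id = term_ids, name = term_names,
                       stringsAsFactors = FALSE),
    parents = parents[term_ids], roots = roots,
    n_obsolete = n_obsolete), class = "ontology_dag")
}

#' Ancestor sets of every term
#'
#' @param dag An `ontology_dag`.
#' @return Named list: term -> character vector of all ancestors
#'   (excluding the term itself).
#' @export
term_ancestors <- function(dag) {
  ids <- dag$terms$id
  anc <- stats::setNames(vector("list", length(ids)), ids)
  done <- stats::setNames(rep(FALSE, length(ids)), ids)
  walk <- function(id) {
    if (done[[id]]) return(anc[[id]])
    ps <- dag$parents[[id]]
    out <- ps
    for (p in ps) out <- union(out, walk(p))
    anc[[id]] <<- out
    done[[id]] <<- TRUE
    out
  }
  for (id in ids) walk(id)
  anc
}

#' Propagate gene annotations up the DAG (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor
#' of that term. Propagation is idempotent.
#'
#' @param dag An `ontology_dag`.
#' @param annotations data.frame with columns `gene_id`, `term_id`
#'   (direct annotations).
#' @return Object of class `annotation_set`: `direct` and `propagated`
#'   (named lists gene -> terms), `genes_by_term` (term -> genes,
#'   propagated), `population` (all annotated genes).
#' @export
propagate_annotations <- function(dag, annotations) {
  unknown <- setdiff(unique(annotations$term_id), dag$terms$id)
  if (length(unknown) > 0L)
    mntox_error(sprintf("annotation to unknown term(s): %s",
                        paste(unknown, collapse = ", ")),
                "mntox_data_error")
  anc <- term_ancestors(dag)
  direct <- split(annotations$term_id, annotations$gene_id)
  direct <- lapply(direct, unique)
  propagated <- lapply(direct, function(ts)
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE)))))
  pairs <- data.frame(
    gene_id = rep(names(propagated), lengths(propagated)),
    term_id = unlist(propagated, use.names = FALSE),
    stringsAsFactors = FALSE)
  genes_by_term <- lapply(split(pairs$gene_id, pairs$term_id), unique)
  structure(list(direct = direct, propagated = propagated,
                 genes_by_term = genes_by_term,
                 population = sort(names(direct))),
            class = "annotation_set")
}

holm_correct <- function(p, ids) {
  o <- order(p, ids)
  m <- length(p)
  adj <- pmin(cummax((m - seq_len(m) + 1L) * p[o]), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

finish_enrichment <- function(df, method, correction, alpha) {
  df$method <- method
  df$p_corrected <- switch(correction,
    holm = holm_correct(df$pvalue, df$term_id),
    bonferroni = pmin(df$pvalue * nrow(df), 1))
  df$discarded <- df$p_corrected > alpha
  df[order(df$p_corrected, df$pvalue, df$term_id), ]
}

#' Term-for-term hypergeometric enrichment
#'
#' Right-sided (enrichment-only) hypergeometric test of each term against
#' the whole population, with Holm-Bonferroni (step-down) correction.
#' Terms with no study gene annotated are not tested. Terms whose
#' corrected p exceeds `alpha` are kept in the output but flagged
#' `discarded`.
#'
#' @param annset An `annotation_set`.
#' @param study_genes Character vector, a subset of the population.
#' @param population Optional explicit population (default: all annotated
#'   genes in `annset`).
#' @param alpha Corrected-p cut-off used for the `discarded` flag.
#' @return data.frame with `term_id`, `k` (study genes with term), `n`
#'   (study size), `K` (population genes with term), `N` (population
#'   size), `pvalue`, `p_corrected`, `method`, `discarded`.
#' @export
term_for_term <- function(annset, study_genes, population = NULL,
                          alpha = 0.05) {
  if (is.null(population)) population <- annset$population
  outside <- setdiff(study_genes, population)
  if (length(outside) > 0L)
    mntox_error(sprintf("study gene(s) outside population: %s",
                        paste(utils::head(outside, 5L), collapse = ", ")),
                "mntox_data_error")
  study_genes <- unique(study_genes)
  n <- length(study_genes)
  N <- length(population)
  rows <- lapply(names(annset$genes_by_term), function(t) {
    tg <- intersect(annset$genes_by_term[[t]], population)
    K <- length(tg)
    k <- length(intersect(tg, study_genes))
    if (k == 0L || K == 0L) return(NULL)
    data.frame(term_id = t, k = k, n = n, K = K, N = N,
               pvalue = stats::phyper(k - 1L, K, N - K, n,
                                      lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    return(data.frame(term_id = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      pvalue = numeric(0), method = character(0),
                      p_corrected = numeric(0), discarded = logical(0)))
  finish_enrichment(df, "term_for_term", "holm", alpha)
}

#' Parent-child-union enrichment
#'
#' Each term is tested against the genes annotated (after propagation) to
#' the union of its is_a parents rather than against the whole
#' population, which removes the redundancy that true-path propagation
#' induces between a term and its ancestors. The draw is the study genes
#' falling in that parent union; successes are genes annotated to the
#' term itself. Root terms have no parents and are skipped. Bonferroni
#' correction over the tested terms.
#'
#' @inheritParams term_for_term
#' @param dag The `ontology_dag` providing the parent structure.
#' @return As [term_for_term()], where `N` is the parent-union size and
#'   `n` the study genes in the union.
#' @export
parent_child_union <- function(annset, study_genes, dag,
                               population = NULL, alpha = 0.05) {
  if (is.null(population)) population <- annset$population
  outside <- setdiff(study_genes, population)
  if (length(outside) > 0L)
    mntox_error(sprintf("study gene(s) outside population: %s",
                        paste(utils::head(outside, 5L), collapse = ", ")),
                "mntox_data_error")
  study_genes <- unique(study_genes)
  rows <- lapply(dag$terms$id, function(t) {
    ps <- dag$parents[[t]]
    if (length(ps) == 0L) return(NULL)           # root: skipped
    u <- unique(unlist(annset$genes_by_term[ps], use.names = FALSE))
    u <- intersect(u, population)
    N <- length(u)
    if (N == 0L) return(NULL)
    tg <- intersect(annset$genes_by_term[[t]], u)
    K <- length(tg)
    n <- length(intersect(study_genes, u))
    k <- length(intersect(study_genes, tg))
    if (k == 0L) return(NULL)                    # enrichment only
    data.frame(term_id = t, k = k, n = n, K = K, N = N,
               pvalue = stats::phyper(k - 1L, K, N - K, n,
                                      lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    return(data.frame(term_id = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      pvalue = numeric(0), method = character(0),
                      p_corrected = numeric(0), discarded = logical(0)))
  finish_enrichment(df, "parent_child_union", "bonferroni", alpha)
}

#' Read a gene-to-term annotation table
#' @param path TSV with columns `gene_id`, `term_id`.
#' @return data.frame of direct annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "term_id"), names(df))
  if (length(miss) > 0L)
    mntox_error(sprintf("annotation table missing column(s): %s",
                        paste(miss, collapse = ", ")), "mntox_format_error")
  df
}

#' Write an enrichment result table
#' @param results Enrichment data.frame.
#' @param path TSV path.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
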