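test_that("OBO parsing builds the DAG and skips obsolete terms", {
  path <- write_toy_obo()
  dag <- load_obo(path)
  expect_equal(nrow(dag$terms), 3L)
  expect_equal(dag$roots, "T:0001")
  expect_equal(dag$parents[["T:0003"]], "T:0002")
  expect_equal(sum(lengths(dag$parents)), 2L)   # two is_a edges

  # term count matches an independent text scan of non-obsolete stanzas
  big <- write_toy_obo(c(
    "format-version: 1.2", "",
    "[Term]", "id: X:1", "name: r", "",
    "[Term]", "id: X:2", "name: a", "is_a: X:1", "",
    "[Term]", "id: X:3", "name: gone", "is_obsolete: true", "",
    "[Term]", "id: X:4", "name: b", "is_a: X:1", "",
    "[Typedef]", "id: part_of"))
  lines <- readLines(big)
  starts <- which(lines == "[Term]")
  ends <- c(grep("^\\[", lines)[-1] - 1, length(lines))
  obsolete <- vapply(starts, function(s) {
    e <- min(ends[ends >= s])
    any(grepl("^is_obsolete: true", lines[s:e]))
  }, logical(1))
  dag2 <- load_obo(big)
  expect_equal(nrow(dag2$terms), sum(!obsolete))
  expect_equal(dag2$n_obsolete, sum(obsolete))

  cyc <- write_toy_obo(c(
    "[Term]", "id: C:1", "name: a", "is_a: C:2", "",
    "[Term]", "id: C:2", "name: b", "is_a: C:1"))
  expect_error(load_obo(cyc), "C:", class = "mntox_cycle_error")
})

test_that("annotation propagation obeys the true-path rule", {
  dag <- load_obo(write_toy_obo())
  ann <- data.frame(gene_id = "g1", term_id = "T:0003")
  aset <- propagate_annotations(dag, ann)
  expect_equal(aset$propagated[["g1"]], c("T:0001", "T:0002", "T:0003"))

  # idempotence: re-propagating the propagated pairs changes nothing
  pairs <- data.frame(
    gene_id = rep(names(aset$propagated), lengths(aset$propagated)),
    term_id = unlist(aset$propagated, use.names = FALSE))
  expect_identical(propagate_annotations(dag, pairs)$propagated,
                   aset$propagated)

  expect_error(propagate_annotations(
    dag, data.frame(gene_id = "g1", term_id = "T:9999")),
    "T:9999", class = "mntox_data_error")
})

test_that("propagation equals a brute-force ancestor walk on a random DAG", {
  set.seed(61)
  n_terms <- 50L
  ids <- sprintf("R:%03d", seq_len(n_terms))
  # random DAG: each non-root picks parents among lower-numbered terms
  lines <- c("format-version: 1.2", "")
  parents <- list()
  for (i in seq_len(n_terms)) {
    stanza <- c("[Term]", paste0("id: ", ids[i]), paste0("name: t", i))
    if (i > 1L) {
      np <- sample(1:min(3L, i - 1L), 1L)
      parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], np)
      stanza <- c(stanza, paste0("is_a: ", parents[[ids[i]]]))
    }
    lines <- c(lines, stanza, "")
  }
  dag <- load_obo(write_toy_obo(lines))
  # independent recursive oracle
  anc_oracle <- function(t) {
    ps <- parents[[t]]
    if (is.null(ps)) return(character(0))
    sort(unique(c(ps, unlist(lapply(ps, anc_oracle)))))
  }
  genes <- sprintf("g%02d", 1:20)
  ann <- data.frame(gene_id = sample(genes, 60, replace = TRUE),
                    term_id = sample(ids, 60, replace = TRUE))
  aset <- propagate_annotations(dag, ann)
  for (g in names(aset$direct)) {
    want <- sort(unique(c(aset$direct[[g]],
                          unlist(lapply(aset$direct[[g]], anc_oracle)))))
    expect_identical(aset$propagated[[g]], want)
  }
})

test_that("term-for-term matches enumeration and the Holm correction", {
  # N=10, K=5, n=4, k=4: closed form 5/210, verified by full enumeration
  expect_equal(hyper_tail_enum(10, 5, 4, 4), 5 / 210)
  expect_equal(phyper(3, 5, 5, 4, lower.tail = FALSE), 5 / 210,
               tolerance = 1e-12)
  # exhaustive instances with N <= 12
  for (N in c(8L, 11L)) for (K in c(3L, 5L)) for (n in c(4L, 6L)) {
    for (k in seq_len(min(K, n))) {
      expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   hyper_tail_enum(N, K, n, k), tolerance = 1e-12)
    }
  }
  # Holm on p = (0.01, 0.04): corrected (0.02, 0.04)
  expect_equal(holm_oracle(c(0.01, 0.04)), c(0.02, 0.04))

  dag <- load_obo(write_toy_obo())
  ann <- data.frame(
    gene_id = sprintf("g%d", 1:8),
    term_id = c("T:0003", "T:0003", "T:0002", "T:0002", "T:0001",
                "T:0001", "T:0001", "T:0001"))
  aset <- propagate_annotations(dag, ann)
  res <- term_for_term(aset, c("g1", "g2", "g3"))
  expect_equal(res$p_corrected,
               holm_oracle(res$pvalue)[order(res$p_corrected, res$pvalue,
                                             res$term_id)],
               tolerance = 1e-12)
  expect_true(all(res$p_corrected >= res$pvalue))
  expect_true(all(res$k <= pmin(res$n, res$K)))

  # study == population: every right tail is 1
  res_all <- term_for_term(aset, aset$population)
  expect_true(all(res_all$pvalue == 1))

  expect_error(term_for_term(aset, c("g1", "stranger")),
               class = "mntox_data_error")
})

test_that("parent-child-union conditions on the parent union", {
  dag <- load_obo(write_toy_obo(c(
    "[Term]", "id: P:1", "name: root", "",
    "[Term]", "id: P:2", "name: pa", "is_a: P:1", "",
    "[Term]", "id: P:3", "name: pb", "is_a: P:1", "",
    "[Term]", "id: P:4", "name: child", "is_a: P:2", "is_a: P:3")))
  ann <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g4", "g5", "g6", "g7"),
    term_id = c("P:4", "P:2", "P:4", "P:2", "P:3", "P:3", "P:2", "P:1"))
  aset <- propagate_annotations(dag, ann)
  study <- c("g1", "g2", "g3", "g6")
  res <- parent_child_union(aset, study, dag)

  # root is skipped
  expect_false("P:1" %in% res$term_id)

  # oracle agreement for the multi-parent child
  row <- res[res$term_id == "P:4", ]
  expect_equal(row$pvalue,
               pcu_oracle(aset$genes_by_term, dag$parents, "P:4", study),
               tolerance = 1e-12)

  # degenerate: term annotation equals its parent union -> p = 1
  expect_true(all(res$pvalue[res$K == res$N] == 1))

  # Bonferroni
  expect_equal(res$p_corrected, pmin(res$pvalue * nrow(res), 1))

  # k = 0 terms are not tested
  res2 <- parent_child_union(aset, "g6", dag)
  expect_false("P:4" %in% res2$term_id)
})

test_that("parent-child-union reduces to term-for-term under a flat root", {
  # every tested term's single parent is the root, annotated to everyone
  dag <- load_obo(write_toy_obo(c(
    "[Term]", "id: F:1", "name: root", "",
    "[Term]", "id: F:2", "name: a", "is_a: F:1", "",
    "[Term]", "id: F:3", "name: b", "is_a: F:1")))
  genes <- sprintf("g%d", 1:12)
  ann <- rbind(
    data.frame(gene_id = genes, term_id = "F:1"),
    data.frame(gene_id = genes[1:5], term_id = "F:2"),
    data.frame(gene_id = genes[4:10], term_id = "F:3"))
  aset <- propagate_annotations(dag, ann)
  study <- genes[c(1:4, 11)]
  tft <- term_for_term(aset, study)
  pcu <- parent_child_union(aset, study, dag)
  for (t in intersect(tft$term_id, pcu$term_id)) {
    if (t == "F:1") next
    expect_equal(pcu$pvalue[pcu$term_id == t],
                 tft$pvalue[tft$term_id == t], tolerance = 1e-12)
  }
})
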