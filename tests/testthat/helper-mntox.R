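# Shared fixtures and oracles, all built in code.

# small factorial sample sheet: n per condition
tiny_samples <- function(n = 4L) {
  sib <- rep(c("wt", "het"), length.out = n)
  make_samples(
    sprintf("s%02d", seq_len(4L * n)),
    c(sib, rep("hom", n), sib, rep("hom", n)),
    rep(c("unexposed", "exposed"), each = 2L * n))
}

# homogeneous NB counts for the given samples, no planted effects
tiny_counts <- function(samples, n_genes = 60L, mu = 100, alpha = 0.05,
                        seed = 1L) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * nrow(samples), mu = mu, size = 1 / alpha),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              samples$sample_id))
  storage.mode(m) <- "integer"
  m
}

# per-truth-class recovery of the classifier output
recall_by_class <- function(truth, cls) {
  vapply(split(seq_len(nrow(truth)), truth$class), function(ix) {
    switch(truth$class[ix[1L]],
      null = mean(!cls$in_group1_toxicity[ix] &
                    !cls$in_group2_sensitivity[ix] &
                    !cls$in_group3_mutant[ix]),
      toxicity = mean(cls$in_group1_toxicity[ix]),
      sensitivity_synergistic = mean(cls$in_group2_sensitivity[ix] &
                                       cls$sensitivity_mode[ix] == "synergistic"),
      sensitivity_additive = mean(cls$in_group2_sensitivity[ix] &
                                    cls$sensitivity_mode[ix] == "additive"),
      mutant_rescued = mean(cls$in_group3_mutant[ix] &
                              cls$mutant_fate[ix] == "rescued"),
      mutant_persistent = mean(cls$in_group3_mutant[ix] &
                                 cls$mutant_fate[ix] == "persistent"))
  }, numeric(1L))
}

# hand-built result table for classifier unit tests
fake_results <- function(padj, lfc = NULL) {
  # padj: named list contrast -> vector; lfc optional same shape
  genes <- sprintf("g%d", seq_along(padj[[1L]]))
  out <- lapply(names(padj), function(nm) {
    l <- if (is.null(lfc)) rep(1, length(genes)) else lfc[[nm]]
    p <- padj[[nm]]
    data.frame(gene_id = genes, contrast = nm, lfc = l, se = 0.1,
               stat = l / 0.1, pvalue = p, padj = p,
               stringsAsFactors = FALSE)
  })
  names(out) <- names(padj)
  out
}

# write a toy OBO file; returns its path
write_toy_obo <- function(lines = NULL) {
  path <- tempfile(fileext = ".obo")
  if (is.null(lines))
    lines <- c(
      "format-version: 1.2", "",
      "[Term]", "id: T:0001", "name: root", "",
      "[Term]", "id: T:0002", "name: mid", "is_a: T:0001 ! root", "",
      "[Term]", "id: T:0003", "name: leaf", "is_a: T:0002 ! mid", "")
  writeLines(lines, path)
  path
}

# independent brute-force BH step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1L):1L) adj[i] <- min(adj[i], adj[i + 1L])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# independent brute-force Holm step-down
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- (m - seq_len(m) + 1L) * p[o]
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# hypergeometric right tail by exhaustive subset enumeration:
# population of N genes, K annotated; draw all C(N, n) study sets and
# count those with >= k annotated members
hyper_tail_enum <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  hits <- colSums(sets <= K)   # genes 1..K are the annotated ones
  mean(hits >= k)
}

# independent naive parent-child-union p for one term
pcu_oracle <- function(genes_by_term, parents, term, study) {
  u <- unique(unlist(genes_by_term[parents[[term]]]))
  tg <- intersect(genes_by_term[[term]], u)
  n_draw <- length(intersect(study, u))
  k <- length(intersect(study, tg))
  stats::phyper(k - 1, length(tg), length(u) - length(tg), n_draw,
                lower.tail = FALSE)
}

# brute-force 3D median filter with reflected edges
median_filter_oracle <- function(x, r) {
  d <- dim(x)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    ifelse(j >= n, 2 * n - 1 - j, j) + 1
  }
  out <- array(0, dim = d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (xx in 1:d[3]) {
    vals <- numeric(0)
    for (dz in -r:r) for (dy in -r:r) for (dx in -r:r)
      vals <- c(vals, x[refl(z + dz, d[1]), refl(y + dy, d[2]),
                        refl(xx + dx, d[3])])
    out[z, y, xx] <- median(vals)
  }
  out
}

# full-enumeration two-sided permutation p for a single voxel
perm_p_oracle <- function(a, b) {
  vals <- c(a, b)
  nb <- length(b)
  obs <- mean(b) - mean(a)
  sets <- utils::combn(length(vals), nb)
  stats <- apply(sets, 2L, function(ix)
    mean(vals[ix]) - mean(vals[-ix]))
  mean(abs(stats) >= abs(obs) - 1e-12)
}
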