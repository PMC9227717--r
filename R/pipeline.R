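# Config-driven end-to-end runs. A run configuration is a plain list
# (or a YAML file); every stochastic stage must carry an explicit seed,
# and identical configurations produce byte-identical artefacts.

#' Read a run configuration
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    mntox_error(sprintf("config not found: %s", path), "mntox_config_error")
  yaml::read_yaml(path)
}

require_seed <- function(config, where) {
  s <- config$seed
  if (is.null(s) || !is.finite(s))
    mntox_error(sprintf("config requires an explicit integer seed (%s)",
                        where), "mntox_config_error")
  as.integer(s)
}

write_manifest <- function(out_dir, files) {
  paths <- file.path(out_dir, files)
  md5 <- unname(tools::md5sum(paths))
  mf <- data.frame(file = files, md5 = md5, stringsAsFactors = FALSE)
  utils::write.table(mf, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mf
}

pipeline_log <- function(verbose, stage, t0) {
  if (verbose)
    message(sprintf("[mntox] %-12s %.2fs", stage,
                    as.numeric(Sys.time()) - t0))
}

#' Run the differential-expression pipeline
#'
#' Simulates (or loads) a factorial count dataset, applies PCA sample QC,
#' fits the NB GLM engine, computes the four standard Wald contrasts,
#' classifies genes into the three groups and, when an ontology and
#' annotation table are configured, runs both enrichment methods on the
#' group gene sets. All artefacts are written under `output_dir` and
#' listed with MD5 checksums in `manifest.tsv`.
#'
#' Config fields: `seed` (required), `output_dir` (required); either
#' `counts` + `samples` paths or `simulate` (arguments for
#' [sim_config()]); optional `q_threshold` (default 0.05), `qc`
#' (`k_mad`, `exclude`), `enrichment` (`obo`, `annotations`).
#'
#' @param config List or YAML path.
#' @param verbose Log per-stage timing.
#' @return The manifest data.frame, invisibly.
#' @export
run_de_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- require_seed(config, "de pipeline")
  out_dir <- config$output_dir
  if (is.null(out_dir))
    mntox_error("config requires output_dir", "mntox_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  q_thr <- if (is.null(config$q_threshold)) 0.05 else config$q_threshold
  t0 <- as.numeric(Sys.time())
  files <- character(0)

  if (!is.null(config$counts)) {
    counts <- read_counts(config$counts)
    samples <- read_samples(config$samples)
    truth <- NULL
  } else {
    sim_args <- config$simulate
    if (is.null(sim_args))
      mntox_error("config needs either counts/samples paths or simulate",
                  "mntox_config_error")
    if (!is.null(sim_args$class_fractions))   # YAML maps arrive as lists
      sim_args$class_fractions <- unlist(sim_args$class_fractions)
    sim_args$seed <- seed
    sim <- do.call(sim_config, sim_args)
    sim <- simulate_counts(sim)
    counts <- sim$counts; samples <- sim$samples; truth <- sim$truth
    write_counts(counts, file.path(out_dir, "counts.tsv"))
    write_samples(samples, file.path(out_dir, "samples.csv"))
    write_truth(truth, file.path(out_dir, "truth.tsv"))
    files <- c(files, "counts.tsv", "samples.csv", "truth.tsv")
  }
  pipeline_log(verbose, "input", t0)

  qc_cfg <- config$qc
  k_mad <- if (is.null(qc_cfg$k_mad)) 5 else qc_cfg$k_mad
  exclude <- isTRUE(qc_cfg$exclude) || is.null(qc_cfg$exclude)
  qc <- pca_outlier_qc(counts, samples, k_mad = k_mad)
  write_qc_json(qc, file.path(out_dir, "qc.json"))
  files <- c(files, "qc.json")
  if (exclude && length(qc$flagged) > 0L) {
    keep <- !(samples$sample_id %in% qc$flagged)
    samples <- samples[keep, , drop = FALSE]
    counts <- counts[, keep, drop = FALSE]
  }
  pipeline_log(verbose, "qc", t0)

  de <- run_de(counts, samples)
  sf_df <- data.frame(sample_id = names(de$size_factors),
                      size_factor = formatC(de$size_factors, digits = 17,
                                            format = "g"))
  utils::write.table(sf_df, file.path(out_dir, "size_factors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, "size_factors.tsv")
  for (nm in names(de$results)) {
    f <- sprintf("results_%s.tsv", nm)
    write_results(de$results[[nm]], file.path(out_dir, f))
    files <- c(files, f)
  }
  pipeline_log(verbose, "de", t0)

  cls <- classify_all(de$results, q = q_thr)
  write_classification(cls$classification,
                       file.path(out_dir, "classification.tsv"))
  files <- c(files, "classification.tsv")

  enr_cfg <- config$enrichment
  if (!is.null(enr_cfg$obo) && !is.null(enr_cfg$annotations)) {
    dag <- load_obo(enr_cfg$obo)
    ann <- read_annotations(enr_cfg$annotations)
    annset <- propagate_annotations(dag, ann)
    cl <- cls$classification
    sets <- list(
      group1_toxicity = cl$gene_id[cl$in_group1_toxicity],
      group2_sensitivity = cl$gene_id[cl$in_group2_sensitivity],
      group3_mutant = cl$gene_id[cl$in_group3_mutant])
    for (set_nm in names(sets)) {
      study <- intersect(sets[[set_nm]], annset$population)
      if (length(study) == 0L) next
      tft <- term_for_term(annset, study)
      pcu <- parent_child_union(annset, study, dag)
      f1 <- sprintf("enrichment_%s_term_for_term.tsv", set_nm)
      f2 <- sprintf("enrichment_%s_parent_child_union.tsv", set_nm)
      write_enrichment(tft, file.path(out_dir, f1))
      write_enrichment(pcu, file.path(out_dir, f2))
      files <- c(files, f1, f2)
    }
  }
  pipeline_log(verbose, "classify", t0)

  summary <- c(list(seed = seed, q_threshold = q_thr,
                    n_samples_used = nrow(samples),
                    flagged_samples = qc$flagged), cls$summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "summary.json")
  mf <- write_manifest(out_dir, files)
  pipeline_log(verbose, "done", t0)
  invisible(mf)
}

#' Run the voxel-mapping pipeline
#'
#' Simulates (or loads) two groups of registered volumes, applies the 3D
#' median filter, the voxel-wise permutation test and FDR masking, and
#' summarises the masks over the region atlas.
#'
#' Config fields: `seed` (required), `output_dir` (required); either
#' `volumes_a`/`volumes_b` (TIFF paths) + `atlas_labels` (TIFF path), or
#' `simulate` (`shape`, `n_per_group`, `n_regions`, `effect_regions`,
#' `noise_sd`, `baseline`); optional `median_radius` (default 1),
#' `n_perm` (default `"exact"`), `q` (default 0.0005).
#'
#' @param config List or YAML path.
#' @param verbose Log per-stage timing.
#' @return The manifest data.frame, invisibly.
#' @export
run_voxel_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- require_seed(config, "voxel pipeline")
  out_dir <- config$output_dir
  if (is.null(out_dir))
    mntox_error("config requires output_dir", "mntox_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  radius <- if (is.null(config$median_radius)) 1L else config$median_radius
  n_perm <- if (is.null(config$n_perm)) "exact" else config$n_perm
  q <- if (is.null(config$q)) 0.0005 else config$q
  t0 <- as.numeric(Sys.time())
  files <- character(0)

  if (!is.null(config$volumes_a)) {
    ga <- volume_stack(lapply(config$volumes_a, read_volume_tiff))
    gb <- volume_stack(lapply(config$volumes_b, read_volume_tiff))
    atlas <- region_atlas(array(as.integer(round(
      read_volume_tiff(config$atlas_labels))), dim = ga$shape))
  } else {
    sim_cfg <- config$simulate
    if (is.null(sim_cfg))
      mntox_error("config needs volumes or simulate", "mntox_config_error")
    shape <- as.integer(unlist(sim_cfg$shape))
    atlas <- make_block_atlas(shape, sim_cfg$n_regions)
    eff <- unlist(sim_cfg$effect_regions)
    if (is.null(eff)) eff <- stats::setNames(numeric(0), character(0))
    sim <- simulate_volumes(
      shape, sim_cfg$n_per_group, atlas, eff,
      noise_sd = if (is.null(sim_cfg$noise_sd)) 1 else sim_cfg$noise_sd,
      baseline = if (is.null(sim_cfg$baseline)) 100 else sim_cfg$baseline,
      seed = seed)
    ga <- sim$group_a; gb <- sim$group_b
  }
  pipeline_log(verbose, "input", t0)

  ga <- median_filter3d(ga, radius)
  gb <- median_filter3d(gb, radius)
  pipeline_log(verbose, "filter", t0)
  pt <- permutation_test(ga, gb, n_perm = n_perm, seed = seed)
  masks <- fdr_mask(pt$p, pt$sign, q = q)
  pipeline_log(verbose, "permtest", t0)

  write_volume_tiff(pt$p, file.path(out_dir, "p_volume.tiff"))
  write_volume_tiff(masks$enhanced + 0, file.path(out_dir, "enhanced.tiff"))
  write_volume_tiff(masks$suppressed + 0,
                    file.path(out_dir, "suppressed.tiff"))
  files <- c(files, "p_volume.tiff", "p_volume.tiff.range.json",
             "enhanced.tiff", "enhanced.tiff.range.json",
             "suppressed.tiff", "suppressed.tiff.range.json")
  reg <- region_summary(masks$enhanced, masks$suppressed, atlas)
  utils::write.table(reg, file.path(out_dir, "region_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, "region_table.tsv")
  jsonlite::write_json(list(
    seed = seed, q = q, n_perm = pt$n_perm, exact = pt$exact,
    n_enhanced = sum(masks$enhanced), n_suppressed = sum(masks$suppressed),
    top_region = if (nrow(reg) > 0) reg$region[1L] else NA),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  files <- c(files, "summary.json")
  mf <- write_manifest(out_dir, files)
  pipeline_log(verbose, "done", t0)
  invisible(mf)
}
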