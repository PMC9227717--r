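# Synthetic-data generators with machine-readable ground truth.
#
# The count generator inverts the factorial NB model: per-gene coefficients
# (log2) are planted by truth class, counts are drawn as
# NB(mean = s_j * 2^(X beta), dispersion alpha_i) with variance
# mu + alpha * mu^2. All generators are pure functions of (config, seed).

GENE_CLASSES <- c("null", "toxicity", "sensitivity_additive",
                  "sensitivity_synergistic", "mutant_rescued",
                  "mutant_persistent")

#' Configuration for the factorial count simulator
#'
#' Defaults emulate a heterozygous-incross 2x2 exposure study profiled by
#' 3'-tag counting: four conditions with 8 individual larvae each, 5000
#' genes, moderate NB dispersion (median 0.05, log-normal spread) and
#' library-size factors log-uniform in `[0.5, 2]`.
#'
#' @param n_genes Number of genes.
#' @param n_per_condition Replicates in each of the four conditions (>= 2).
#' @param class_fractions Named fractions per truth class, summing to 1.
#' @param effect_lfc Planted log2 fold change for the strong classes.
#' @param base_log2_mean,base_log2_sd Normal distribution of baseline
#'   log2 expression.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal dispersion
#'   distribution.
#' @param size_factor_range Range of the log-uniform true size factors.
#' @param q_threshold Significance threshold used when calibrating the
#'   additive-class detection scale.
#' @param seed Mandatory integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000L, n_per_condition = 8L,
                       class_fractions = c(
                         null = 0.75, toxicity = 0.05,
                         sensitivity_additive = 0.05,
                         sensitivity_synergistic = 0.05,
                         mutant_rescued = 0.05, mutant_persistent = 0.05),
                       effect_lfc = 2,
                       base_log2_mean = 7, base_log2_sd = 1.5,
                       dispersion_meanlog = log(0.05),
                       dispersion_sdlog = 0.5,
                       size_factor_range = c(0.5, 2),
                       q_threshold = 0.05,
                       seed = NULL) {
  if (is.null(seed) || !is.finite(seed))
    mntox_error("sim_config requires an explicit seed", "mntox_config_error")
  miss <- setdiff(GENE_CLASSES, names(class_fractions))
  if (length(miss) > 0L)
    class_fractions[miss] <- 0
  class_fractions <- class_fractions[GENE_CLASSES]
  if (abs(sum(class_fractions) - 1) > 1e-8)
    mntox_error("class_fractions must sum to 1", "mntox_config_error")
  if (any(class_fractions < 0))
    mntox_error("class_fractions must be non-negative", "mntox_config_error")
  if (n_per_condition < 2L)
    mntox_error("need >=2 replicates per condition", "mntox_config_error")
  structure(list(
    n_genes = as.integer(n_genes),
    n_per_condition = as.integer(n_per_condition),
    class_fractions = class_fractions, effect_lfc = effect_lfc,
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    dispersion_meanlog = dispersion_meanlog,
    dispersion_sdlog = dispersion_sdlog,
    size_factor_range = size_factor_range,
    q_threshold = q_threshold,
    seed = as.integer(seed)), class = "sim_config")
}

sim_samples <- function(n_per_condition) {
  n <- n_per_condition
  sib_geno <- rep(c("wt", "het"), length.out = n)  # balanced incross pick
  make_samples(
    sample_id = sprintf("s%02d", seq_len(4L * n)),
    genotype = c(sib_geno, rep("hom", n), sib_geno, rep("hom", n)),
    treatment = rep(c("unexposed", "exposed"), each = 2L * n))
}

class_counts <- function(fractions, n_genes) {
  diff(c(0L, round(cumsum(fractions) * n_genes)))
}

# Analytic first guess of the LFC detectable at power 0.5: Wald SE of a
# single-factor coefficient for a typical gene at the configured n.
analytic_detection_scale <- function(config) {
  mu0 <- 2^config$base_log2_mean
  alpha <- exp(config$dispersion_meanlog)
  w <- 1 / (alpha + 1 / mu0)
  se_log2 <- sqrt(2 / (config$n_per_condition * w)) / log(2)
  stats::qnorm(0.975) * se_log2
}

#' Empirical detection scale of the configured design
#'
#' Calibrates, once per configuration, the log2 fold change that the
#' package's own engine detects with probability 0.5 for a typical gene
#' at the configured sample size, where detection means a BH-adjusted p
#' at or below the configured threshold. A pilot dataset is simulated
#' from the same configuration (additive-class slots replaced by nulls,
#' since their effects depend on the result) and run through the engine;
#' the realised BH significance threshold on the Wald statistic, `z*`,
#' is the true standardised effect size a gene needs for 50% detection
#' probability, so the scale is `z*` times the median coefficient
#' standard error.
#'
#' @param config A `sim_config`.
#' @return Positive scalar, log2 units.
#' @export
detection_scale <- function(config) {
  d0 <- analytic_detection_scale(config)
  frac <- config$class_fractions
  pilot_cfg <- config
  pilot_cfg$class_fractions["sensitivity_additive"] <- 0
  pilot_cfg$class_fractions["null"] <-
    pilot_cfg$class_fractions["null"] + frac["sensitivity_additive"]
  pilot_cfg$seed <- (config$seed %% 1000000000L) + 7L
  sim <- simulate_counts(pilot_cfg)
  de <- run_de(sim$counts, sim$samples)
  res <- de$results$toxicity
  q <- config$q_threshold
  sig_p <- res$pvalue[!is.na(res$padj) & res$padj <= q]
  p_star <- if (length(sig_p) > 0L) max(sig_p) else q / config$n_genes
  z_star <- stats::qnorm(p_star / 2, lower.tail = FALSE)
  se_med <- stats::median(res$se, na.rm = TRUE)
  d <- z_star * se_med
  if (!is.finite(d) || d <= 0) d0 else d
}

#' Simulate a factorial NB count matrix with planted truth classes
#'
#' Gene classes and their planted coefficients (log2):
#' * `null`: all effects 0.
#' * `toxicity`: treatment effect `+-effect_lfc`.
#' * `sensitivity_synergistic`: interaction `+-effect_lfc`, single effects
#'   0, so the interaction sign matches the total exposed-mutant effect.
#' * `sensitivity_additive`: single effects 0.6 and 0.8 times the
#'   calibrated detection scale (same sign, each below it), interaction 0,
#'   so the combined effect (1.4x) is detectable but neither single effect
#'   is.
#' * `mutant_rescued`: genotype effect `+-effect_lfc`, interaction equal
#'   and opposite, so the exposed-mutant total effect is 0.
#' * `mutant_persistent`: genotype effect `+-effect_lfc` only.
#'
#' @param config A `sim_config`.
#' @return List with `counts`, `samples`, `truth` (gene_id, class, beta0,
#'   beta_g, beta_t, beta_gt, dispersion), `size_factors_true` and
#'   `detection_scale` (NA when no additive genes are planted).
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config"))
    mntox_error("config must be a sim_config", "mntox_config_error")
  n_cls <- class_counts(config$class_fractions, config$n_genes)
  names(n_cls) <- GENE_CLASSES
  d <- NA_real_
  if (n_cls[["sensitivity_additive"]] > 0L)
    d <- detection_scale(config)

  set.seed(config$seed)
  samples <- sim_samples(config$n_per_condition)
  n_s <- nrow(samples)
  sf_true <- exp(stats::runif(n_s, log(config$size_factor_range[1L]),
                              log(config$size_factor_range[2L])))
  names(sf_true) <- samples$sample_id

  g_n <- config$n_genes
  cls <- rep(GENE_CLASSES, times = n_cls)
  cls <- sample(cls)                      # shuffle class positions
  beta0 <- stats::rnorm(g_n, config$base_log2_mean, config$base_log2_sd)
  alpha <- stats::rlnorm(g_n, config$dispersion_meanlog,
                         config$dispersion_sdlog)
  sgn <- sample(c(-1, 1), g_n, replace = TRUE)
  bg <- bt <- bgt <- numeric(g_n)
  e <- config$effect_lfc
  i <- cls == "toxicity";                bt[i] <- sgn[i] * e
  i <- cls == "sensitivity_synergistic"; bgt[i] <- sgn[i] * e
  i <- cls == "sensitivity_additive"
  bg[i] <- sgn[i] * 0.7 * d; bt[i] <- sgn[i] * 0.7 * d
  i <- cls == "mutant_rescued";  bg[i] <- sgn[i] * e; bgt[i] <- -bg[i]
  i <- cls == "mutant_persistent"; bg[i] <- sgn[i] * e

  X <- design_matrix(samples)
  log2q <- cbind(beta0, bg, bt, bgt) %*% t(X)
  mu <- sweep(2^log2q, 2L, sf_true, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = rep(1 / alpha, n_s)),
                   nrow = g_n,
                   dimnames = list(sprintf("g%05d", seq_len(g_n)),
                                   samples$sample_id))
  truth <- data.frame(gene_id = rownames(counts), class = cls,
                      beta0 = beta0, beta_g = bg, beta_t = bt,
                      beta_gt = bgt, dispersion = alpha,
                      stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, truth = truth,
       size_factors_true = sf_true, detection_scale = d)
}

#' Write / read a gene truth table
#' @param truth Truth table from [simulate_counts()].
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Simulate registered image volumes with planted regional effects
#'
#' Group A volumes are baseline plus Gaussian noise; group B volumes are
#' additionally shifted by a constant inside each effect region. This
#' emulates registered whole-brain stacks of an activity marker for two
#' groups; it does not emulate registration error or spatially correlated
#' noise.
#'
#' @param shape Integer vector (Z, Y, X).
#' @param n_per_group Subjects per group.
#' @param atlas A `region_atlas` covering `shape`.
#' @param effect_regions Named numeric: region name -> intensity shift of
#'   group B. May be empty (null simulation).
#' @param noise_sd Gaussian noise standard deviation.
#' @param baseline Baseline intensity (arbitrary units).
#' @param seed Mandatory integer seed.
#' @return List with `group_a`, `group_b` (volume stacks) and `truth`
#'   (integer array: sign of the planted shift per voxel).
#' @export
simulate_volumes <- function(shape, n_per_group, atlas, effect_regions,
                             noise_sd = 1, baseline = 100, seed = NULL) {
  if (is.null(seed)) mntox_error("seed is required", "mntox_config_error")
  stopifnot(inherits(atlas, "region_atlas"))
  if (!identical(dim(atlas$labels), as.integer(shape)))
    mntox_error("atlas shape does not match requested shape",
                "mntox_data_error")
  unknown <- setdiff(names(effect_regions), atlas$region_names)
  if (length(unknown) > 0L)
    mntox_error(sprintf("unknown region label(s): %s",
                        paste(unknown, collapse = ", ")), "mntox_data_error")
  set.seed(seed)
  shift <- array(0, dim = shape)
  for (rn in names(effect_regions)) {
    lbl <- as.integer(names(atlas$region_names)[atlas$region_names == rn])
    shift[atlas$labels == lbl] <- effect_regions[[rn]]
  }
  draw <- function(ids, add) {
    vols <- lapply(ids, function(id)
      array(baseline + add + stats::rnorm(prod(shape), 0, noise_sd),
            dim = shape))
    volume_stack(vols, ids)
  }
  ga <- draw(sprintf("A%02d", seq_len(n_per_group)), 0)
  gb <- draw(sprintf("B%02d", seq_len(n_per_group)), shift)
  list(group_a = ga, group_b = gb,
       truth = array(as.integer(sign(shift)), dim = shape))
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Ct values are constructed so that the noiseless 2^-ddCt computation
#' recovers the planted fold change (relative to the control condition)
#' exactly: the target Ct decreases by one cycle per planted doubling
#' while the reference gene Ct is constant.
#'
#' @param fold_changes Named positive numeric, one true fold change per
#'   condition (relative to `control`).
#' @param control Name of the control condition (default first).
#' @param n_replicates Samples per condition.
#' @param target_gene,reference_gene Gene labels in the output.
#' @param target_base_ct Ct of the target gene in the control condition.
#' @param reference_ct Ct of the reference gene.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed Seed, required when `noise_sd > 0`.
#' @return data.frame with columns `sample`, `condition`, `gene`, `ct`.
#' @export
simulate_ct <- function(fold_changes, control = names(fold_changes)[1L],
                        n_replicates = 3L, target_gene = "target",
                        reference_gene = "reference",
                        target_base_ct = 20, reference_ct = 15,
                        noise_sd = 0, seed = NULL) {
  if (any(fold_changes <= 0) || any(!is.finite(fold_changes)))
    mntox_error("fold changes must be positive", "mntox_config_error")
  if (noise_sd > 0 && is.null(seed))
    mntox_error("seed is required when noise_sd > 0", "mntox_config_error")
  if (!is.null(seed)) set.seed(seed)
  conds <- names(fold_changes)
  if (!(control %in% conds))
    mntox_error("control condition not in fold_changes", "mntox_config_error")
  rows <- do.call(rbind, lapply(conds, function(cd) {
    ids <- sprintf("%s_r%d", cd, seq_len(n_replicates))
    ct_t <- target_base_ct - log2(fold_changes[[cd]] / fold_changes[[control]]) +
      stats::rnorm(n_replicates, 0, noise_sd)
    ct_r <- reference_ct + stats::rnorm(n_replicates, 0, noise_sd)
    rbind(data.frame(sample = ids, condition = cd, gene = target_gene,
                     ct = ct_t, stringsAsFactors = FALSE),
          data.frame(sample = ids, condition = cd, gene = reference_gene,
                     ct = ct_r, stringsAsFactors = FALSE))
  }))
  rownames(rows) <- NULL
  rows
}
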