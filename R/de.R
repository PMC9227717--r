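# Negative-binomial GLM engine for the 2x2 factorial design.
#
# The design (~ genotype + treatment + genotype:treatment with intercept,
# reference levels sibling/unexposed) is saturated: the four coefficients
# are a linear map of the four condition means, so per-gene fitting reduces
# to four one-dimensional Fisher-scoring problems that are vectorised
# across genes. Coefficients are reported in log2 units.

# cells in fixed order: (sibling,unexposed) (mutant,unexposed)
#                       (sibling,exposed)   (mutant,exposed)
CELL_LEVELS <- c("sibling_unexposed", "mutant_unexposed",
                 "sibling_exposed", "mutant_exposed")

# rows: beta0, betaG, betaT, betaGT; columns: cell log-means
BETA_FROM_CELLS <- rbind(
  beta0  = c(1, 0, 0, 0),
  betaG  = c(-1, 1, 0, 0),
  betaT  = c(-1, 0, 1, 0),
  betaGT = c(1, -1, -1, 1))

COEF_NAMES <- rownames(BETA_FROM_CELLS)

cell_index <- function(samples) {
  g <- as.integer(samples$analysis_group == "mutant")
  t <- as.integer(samples$treatment == "exposed")
  factor(CELL_LEVELS[1L + g + 2L * t], levels = CELL_LEVELS)
}

#' Design matrix of the factorial model
#'
#' Intercept, genotype (mutant = 1), treatment (exposed = 1) and their
#' interaction, with reference levels sibling and unexposed.
#'
#' @param samples Sample table (see [make_samples()]).
#' @return Numeric matrix with columns `beta0`, `betaG`, `betaT`, `betaGT`.
#' @export
design_matrix <- function(samples) {
  g <- as.numeric(samples$analysis_group == "mutant")
  t <- as.numeric(samples$treatment == "exposed")
  m <- cbind(beta0 = 1, betaG = g, betaT = t, betaGT = g * t)
  rownames(m) <- samples$sample_id
  m
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across reference genes of
#' the ratio of its count to the gene's geometric mean over samples;
#' reference genes are those with positive counts in every sample. The
#' result is rescaled to geometric mean 1.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param pseudo_reference If no gene is positive in all samples, fall back
#'   to a pseudo-reference built from each gene's positive samples instead
#'   of failing.
#' @return Named positive vector, one size factor per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- validate_counts(counts)
  lc <- log(counts)
  log_geo <- rowMeans(lc)
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    if (!pseudo_reference)
      mntox_error(paste0(
        "no gene has positive counts in every sample; ",
        "set pseudo_reference = TRUE to use a pseudo-reference"),
        "mntox_data_error")
    lc[!is.finite(lc)] <- NA
    log_geo <- rowMeans(lc, na.rm = TRUE)
    usable <- is.finite(log_geo)
  }
  ratios <- exp(lc[usable, , drop = FALSE] - log_geo[usable])
  s <- apply(ratios, 2L, stats::median, na.rm = TRUE)
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(counts))
}

# Fisher scoring for the per-cell log-means of every gene at once.
# counts: G x n, sf: n, alpha: G, cells: factor n. Returns log-mean matrix
# q (G x 4, natural log), per-cell Fisher information (G x 4) and a
# convergence flag (FALSE when a cell is all-zero or scoring failed).
fit_cell_means <- function(counts, sf, alpha, cells,
                           maxit = 50L, tol = 1e-10, qmin = 1e-8) {
  g_n <- nrow(counts)
  logq <- matrix(0, g_n, 4L, dimnames = list(rownames(counts), CELL_LEVELS))
  info <- matrix(NA_real_, g_n, 4L, dimnames = dimnames(logq))
  converged <- rep(TRUE, g_n)
  for (c_i in seq_along(CELL_LEVELS)) {
    j <- which(cells == CELL_LEVELS[c_i])
    y <- counts[, j, drop = FALSE]
    s <- sf[j]
    zero_cell <- rowSums(y) == 0L
    q <- pmax(rowSums(y) / sum(s), qmin)
    lq <- log(q)
    ok <- rep(FALSE, g_n)
    for (it in seq_len(maxit)) {
      mu <- exp(lq) %o% s
      denom <- 1 + alpha * mu
      score <- rowSums((y - mu) / denom)
      fisher <- rowSums(mu / denom)
      step <- score / pmax(fisher, 1e-12)
      step <- pmin(pmax(step, -3), 3)
      lq <- pmax(lq + step, log(qmin))
      ok <- abs(step) < tol | (zero_cell & lq <= log(qmin) + 1e-12)
      if (all(ok)) break
    }
    mu <- exp(lq) %o% s
    info[, c_i] <- rowSums(mu / (1 + alpha * mu))
    logq[, c_i] <- lq
    converged <- converged & ok & !zero_cell
  }
  list(logq = logq, info = info, converged = converged)
}

# Cox-Reid adjusted NB profile log-likelihood of one gene for optimize().
cr_loglik_fun <- function(y, mu_of_cell, cells_int, sf) {
  mu <- mu_of_cell[cells_int] * sf
  function(log_alpha) {
    alpha <- exp(log_alpha)
    ll <- sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
    w <- mu / (1 + alpha * mu)
    cr <- -0.5 * sum(log(pmax(
      tapply(w, cells_int, sum), 1e-300)))
    ll + cr
  }
}

#' Estimate per-gene NB dispersions with trend and shrinkage
#'
#' Three stages, following common practice for count GLM engines:
#' per-gene Cox-Reid adjusted maximum-likelihood dispersion given fitted
#' condition means; a mean-dispersion trend `a0 + a1/mu` fitted by a
#' Gamma GLM over genes with usable estimates; and per-gene posterior
#' modes shrinking `log(alpha)` towards the trend under a normal prior
#' whose variance is estimated from the spread of the log residuals in
#' excess of the sampling variance.
#'
#' @param counts Integer count matrix.
#' @param sf Size factors (see [size_factors()]).
#' @param samples Sample table.
#' @param min_alpha,max_alpha Optimisation bounds for the dispersion.
#' @param min_prior_var Lower bound for the log-normal prior variance.
#' @return Object of class `dispersion_fit` with elements `alpha_raw`,
#'   `alpha_trend`, `alpha_final`, `trend` (a0, a1), `prior_var`,
#'   `mu_bar` and `flagged` (all-zero genes, excluded from testing).
#' @export
estimate_dispersions <- function(counts, sf, samples,
                                 min_alpha = 1e-8, max_alpha = 30,
                                 min_prior_var = 0.25) {
  counts <- validate_counts(counts)
  cells <- cell_index(samples)
  if (any(table(cells) < 2L) || ncol(counts) - 4L < 2L)
    mntox_error("dispersion estimation needs >=2 residual df and >=2 samples per condition",
                "mntox_data_error")
  g_n <- nrow(counts)
  cells_int <- as.integer(cells)
  flagged <- rowSums(counts) == 0L
  norm <- sweep(counts, 2L, sf, "/")
  mu_bar <- rowMeans(norm)

  alpha_cur <- rep(0.1, g_n)
  alpha_raw <- rep(NA_real_, g_n)
  bounds <- log(c(min_alpha, max_alpha))
  for (pass in 1:2) {
    fit <- fit_cell_means(counts, sf, alpha_cur, cells)
    q <- exp(fit$logq)
    for (i in which(!flagged)) {
      f <- cr_loglik_fun(counts[i, ], q[i, ], cells_int, sf)
      opt <- stats::optimize(f, interval = bounds, maximum = TRUE,
                             tol = 1e-6)
      alpha_raw[i] <- exp(opt$maximum)
    }
    alpha_cur <- ifelse(is.na(alpha_raw), 0.1, alpha_raw)
  }

  # mean-dispersion trend a0 + a1/mu over well-behaved genes
  use <- !flagged & is.finite(alpha_raw) &
    alpha_raw > min_alpha * 10 & alpha_raw < max_alpha / 3 & mu_bar >= 1
  trend <- c(a0 = stats::median(alpha_raw[!flagged], na.rm = TRUE), a1 = 0)
  if (sum(use) >= 20L) {
    fit_df <- data.frame(a = alpha_raw[use], im = 1 / mu_bar[use])
    gfit <- tryCatch(
      stats::glm(a ~ im, data = fit_df,
                 family = stats::Gamma(link = "identity"),
                 start = c(stats::median(fit_df$a), 1)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(gfit)) {
      co <- stats::coef(gfit)
      if (is.finite(co[1L]) && co[1L] > 0 && is.finite(co[2L]))
        trend <- c(a0 = unname(co[1L]), a1 = max(unname(co[2L]), 0))
    }
  }
  alpha_trend <- pmax(trend["a0"] + trend["a1"] / mu_bar, min_alpha)
  names(alpha_trend) <- rownames(counts)

  # prior variance of log(alpha) around the trend
  m <- ncol(counts)
  sampling_var <- trigamma((m - 4L) / 2)
  lr <- log(alpha_raw) - log(alpha_trend)
  s_lr <- stats::mad(lr[use], na.rm = TRUE)
  prior_var <- max(s_lr^2 - sampling_var, min_prior_var)

  # posterior mode of log(alpha)
  fit <- fit_cell_means(counts, sf, alpha_cur, cells)
  q <- exp(fit$logq)
  alpha_final <- alpha_trend
  for (i in which(!flagged)) {
    f <- cr_loglik_fun(counts[i, ], q[i, ], cells_int, sf)
    lt <- log(alpha_trend[i])
    post <- function(la) f(la) - (la - lt)^2 / (2 * prior_var)
    opt <- stats::optimize(post, interval = bounds, maximum = TRUE,
                           tol = 1e-6)
    alpha_final[i] <- exp(opt$maximum)
  }
  alpha_final[flagged] <- NA_real_
  alpha_raw[flagged] <- NA_real_

  structure(list(alpha_raw = stats::setNames(alpha_raw, rownames(counts)),
                 alpha_trend = alpha_trend,
                 alpha_final = stats::setNames(alpha_final, rownames(counts)),
                 trend = trend, prior_var = prior_var, mu_bar = mu_bar,
                 flagged = stats::setNames(flagged, rownames(counts))),
            class = "dispersion_fit")
}

#' Fit the factorial NB GLM for every gene
#'
#' Maximises the NB log-likelihood with log link and offset `log(sf)` by
#' Fisher scoring on the condition means (the design is saturated), then
#' maps to the coefficient scale. The covariance is the inverse observed
#' Fisher information. Genes with an all-zero condition or failed scoring
#' are flagged as non-converged, never dropped silently.
#'
#' @param counts Integer count matrix.
#' @param sf Size factors.
#' @param dispersions A `dispersion_fit` or a numeric vector of per-gene
#'   dispersions.
#' @param samples Sample table.
#' @return Object of class `nb_glm_fit`: `beta` (genes x 4, log2 units),
#'   `cell_info` (Fisher information per condition mean, natural-log
#'   scale), `converged`, `size_factors`, `dispersion`, `flagged`.
#' @export
fit_nb_glm <- function(counts, sf, dispersions, samples) {
  counts <- validate_counts(counts)
  if (inherits(dispersions, "dispersion_fit")) {
    alpha <- dispersions$alpha_final
    flagged <- dispersions$flagged
  } else {
    alpha <- rep_len(as.numeric(dispersions), nrow(counts))
    flagged <- rowSums(counts) == 0L
  }
  alpha_use <- ifelse(is.na(alpha), 0.1, alpha)
  cells <- cell_index(samples)
  fit <- fit_cell_means(counts, sf, alpha_use, cells)
  beta <- fit$logq %*% t(BETA_FROM_CELLS) / log(2)
  colnames(beta) <- COEF_NAMES
  converged <- fit$converged & !flagged
  structure(list(beta = beta, cell_info = fit$info,
                 converged = converged,
                 size_factors = sf, dispersion = alpha,
                 flagged = flagged, samples = samples),
            class = "nb_glm_fit")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; missing values are allowed and are excluded
#' from the number of tests.
#'
#' @param pvalues Numeric vector in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, `NA` where the input was `NA`.
#' @export
adjust_bh <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    mntox_error("p-values must lie in [0, 1]", "mntox_data_error")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Wald test of a contrast
#'
#' Tests `c' beta = 0` per gene: `stat = lfc / se` with
#' `se = sqrt(c' Sigma c)`, two-sided standard-normal p-value, and BH
#' adjustment across the converged genes of this contrast.
#'
#' @param fit An `nb_glm_fit`.
#' @param contrast Numeric length-4 contrast on
#'   (beta0, betaG, betaT, betaGT).
#' @param name Contrast label stored in the result.
#' @return data.frame with `gene_id`, `contrast`, `lfc` (log2), `se`,
#'   `stat`, `pvalue`, `padj`; non-converged genes have `NA` statistics
#'   and are excluded from the BH denominator.
#' @export
wald_contrast <- function(fit, contrast, name = "contrast") {
  if (length(contrast) != 4L)
    mntox_error("contrast must have length 4", "mntox_contract_error")
  if (all(contrast == 0))
    mntox_error("contrast must be non-zero", "mntox_contract_error")
  w <- as.numeric(contrast %*% BETA_FROM_CELLS)   # weights on cell log2-means
  lfc <- as.numeric(fit$beta %*% contrast)
  se <- sqrt(rowSums(sweep(1 / fit$cell_info, 2L, w^2, "*"))) / log(2)
  stat <- lfc / se
  pvalue <- 2 * stats::pnorm(-abs(stat))
  drop <- !fit$converged
  lfc[drop] <- NA_real_; se[drop] <- NA_real_
  stat[drop] <- NA_real_; pvalue[drop] <- NA_real_
  data.frame(gene_id = rownames(fit$beta), contrast = name,
             lfc = lfc, se = se, stat = stat, pvalue = pvalue,
             padj = adjust_bh(pvalue), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' The four standard contrasts of the factorial analysis
#'
#' * `toxicity`: exposed vs unexposed siblings (`betaT`)
#' * `mutant_exposed`: exposed mutants vs unexposed siblings
#'   (`betaG + betaT + betaGT`)
#' * `mutant`: unexposed mutants vs unexposed siblings (`betaG`)
#' * `interaction`: genotype x treatment interaction (`betaGT`)
#'
#' @return 4 x 4 numeric matrix, one contrast per row.
#' @export
standard_contrasts <- function() {
  rbind(toxicity       = c(0, 0, 1, 0),
        mutant_exposed = c(0, 1, 1, 1),
        mutant         = c(0, 1, 0, 0),
        interaction    = c(0, 0, 0, 1))
}

#' Run the full differential-expression engine
#'
#' Size factors, dispersion estimation, GLM fit and the four standard
#' Wald contrasts in one call.
#'
#' @param counts Integer count matrix.
#' @param samples Sample table.
#' @param sf Optional precomputed size factors.
#' @param dispersions Optional precomputed dispersions.
#' @return List with `size_factors`, `dispersions`, `fit` and `results`
#'   (named list of the four contrast tables).
#' @export
run_de <- function(counts, samples, sf = NULL, dispersions = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, sf, samples)
  fit <- fit_nb_glm(counts, sf, dispersions, samples)
  cm <- standard_contrasts()
  results <- lapply(rownames(cm), function(nm)
    wald_contrast(fit, cm[nm, ], nm))
  names(results) <- rownames(cm)
  list(size_factors = sf, dispersions = dispersions, fit = fit,
       results = results)
}
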