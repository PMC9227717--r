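# Voxel-wise group comparison of registered 3D image stacks: median
# filtering, label-permutation testing, FDR masks and per-region summary.

#' Construct a volume stack
#'
#' @param volumes List of numeric 3D arrays, all of identical shape, with
#'   no missing values.
#' @param subjects Subject identifiers (default `V1..Vn`).
#' @return Object of class `volume_stack`.
#' @export
volume_stack <- function(volumes, subjects = NULL) {
  if (length(volumes) == 0L)
    mntox_error("empty volume stack", "mntox_data_error")
  shp <- dim(volumes[[1L]])
  if (length(shp) != 3L)
    mntox_error("volumes must be 3D arrays", "mntox_data_error")
  for (v in volumes) {
    if (!identical(dim(v), shp))
      mntox_error("all volumes must share one shape", "mntox_data_error")
    if (anyNA(v))
      mntox_error("volumes must not contain missing values",
                  "mntox_data_error")
  }
  if (is.null(subjects)) subjects <- sprintf("V%d", seq_along(volumes))
  structure(list(subjects = as.character(subjects), volumes = volumes,
                 shape = shp), class = "volume_stack")
}

#' Construct a region atlas
#'
#' @param labels Integer 3D array; 0 is background, positive values are
#'   region labels.
#' @param region_names Named character vector mapping label (as name) to
#'   region name; defaults to `region_<label>`.
#' @return Object of class `region_atlas`.
#' @export
region_atlas <- function(labels, region_names = NULL) {
  if (any(labels < 0))
    mntox_error("atlas labels must be >= 0", "mntox_data_error")
  lbl <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (is.null(region_names))
    region_names <- stats::setNames(sprintf("region_%02d", lbl),
                                    as.character(lbl))
  if (anyDuplicated(region_names))
    mntox_error("region names must be unique", "mntox_data_error")
  miss <- setdiff(as.character(lbl), names(region_names))
  if (length(miss) > 0L)
    mntox_error(sprintf("labels without names: %s",
                        paste(miss, collapse = ", ")), "mntox_data_error")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, region_names = region_names),
            class = "region_atlas")
}

#' Toy block atlas
#'
#' Splits a volume into `n_regions` contiguous slabs along the last (X)
#' axis, a stand-in for an anatomical parcellation in simulations and
#' tests. Slabs are at least one plane thick; keep them thicker than the
#' median-filter radius when planting effects.
#'
#' @param shape Integer (Z, Y, X).
#' @param n_regions Number of regions (`<= shape[3]`).
#' @return A `region_atlas`.
#' @export
make_block_atlas <- function(shape, n_regions) {
  if (n_regions > shape[3L])
    mntox_error("more regions than X planes", "mntox_data_error")
  slab <- as.integer(cut(seq_len(shape[3L]), n_regions, labels = FALSE))
  lab <- array(rep(slab, each = shape[1L] * shape[2L]), dim = shape)
  region_atlas(lab)
}

reflect_index <- function(i, n) {
  # reflection padding: ... 2 1 | 1 2 ... n | n n-1 ...
  j <- ((i - 1L) %% (2L * n))
  j <- ifelse(j >= n, 2L * n - 1L - j, j)
  j + 1L
}

#' 3D median filter
#'
#' Per-voxel median over the `(2r+1)^3` cube neighbourhood with
#' reflection at the edges; the shape is preserved.
#'
#' @param x A 3D array or a `volume_stack`.
#' @param radius Neighbourhood radius (>= 1).
#' @return Filtered array or stack of the same shape.
#' @export
median_filter3d <- function(x, radius = 1L) {
  if (inherits(x, "volume_stack")) {
    return(volume_stack(lapply(x$volumes, median_filter3d, radius = radius),
                        x$subjects))
  }
  shp <- dim(x)
  if (length(shp) != 3L)
    mntox_error("median_filter3d expects a 3D array", "mntox_data_error")
  if (radius < 1L)
    mntox_error("radius must be >= 1", "mntox_contract_error")
  if (any(radius >= shp))
    mntox_error("radius larger than a volume dimension",
                "mntox_contract_error")
  offs <- expand.grid(dz = -radius:radius, dy = -radius:radius,
                      dx = -radius:radius)
  nv <- prod(shp)
  neigh <- matrix(NA_real_, nv, nrow(offs))
  iz <- slice.index(x, 1L); iy <- slice.index(x, 2L); ix <- slice.index(x, 3L)
  for (k in seq_len(nrow(offs))) {
    z <- reflect_index(as.vector(iz) + offs$dz[k], shp[1L])
    y <- reflect_index(as.vector(iy) + offs$dy[k], shp[2L])
    xx <- reflect_index(as.vector(ix) + offs$dx[k], shp[3L])
    neigh[, k] <- x[cbind(z, y, xx)]
  }
  array(apply(neigh, 1L, stats::median), dim = shp)
}

stack_matrix <- function(stack) {
  do.call(rbind, lapply(stack$volumes, as.vector))  # subjects x voxels
}

#' Voxel-wise permutation test between two groups
#'
#' Statistic per voxel: `mean(group B) - mean(group A)`. The p-value is
#' the proportion of group-label permutations, the observed labelling
#' included, whose absolute statistic is at least the observed one. With
#' `n_perm = "exact"` all label assignments are enumerated when there are
#' at most 10000; otherwise Monte-Carlo resampling with a mandatory seed
#' is used (the identity permutation is always included, so
#' `p >= 1/(n_perm + 1)`).
#'
#' @param group_a,group_b `volume_stack`s of identical shape, each with at
#'   least 2 subjects.
#' @param n_perm `"exact"` or the number of Monte-Carlo permutations.
#' @param seed Seed for Monte-Carlo mode.
#' @return List with `p` (p-value array), `sign` (sign of the observed
#'   statistic), `stat` (observed statistic array), `exact`, `n_perm`.
#' @export
permutation_test <- function(group_a, group_b, n_perm = "exact",
                             seed = NULL) {
  stopifnot(inherits(group_a, "volume_stack"),
            inherits(group_b, "volume_stack"))
  if (!identical(group_a$shape, group_b$shape))
    mntox_error("group shapes differ", "mntox_data_error")
  na <- length(group_a$volumes); nb <- length(group_b$volumes)
  if (na + nb < 4L)
    mntox_error("need at least 4 subjects in total", "mntox_data_error")
  if (na < 2L || nb < 2L)
    mntox_error("need >=2 subjects per group", "mntox_data_error")
  X <- rbind(stack_matrix(group_a), stack_matrix(group_b))
  n <- na + nb
  n_total <- choose(n, nb)
  exact <- identical(n_perm, "exact") && n_total <= 10000
  if (identical(n_perm, "exact") && !exact) n_perm <- 10000L
  if (exact) {
    assign_b <- utils::combn(n, nb)               # columns: indices in B
  } else {
    if (is.null(seed))
      mntox_error("Monte-Carlo permutation mode requires a seed",
                  "mntox_config_error")
    n_perm <- as.integer(n_perm)
    if (n_perm < 100L)
      warning("fewer than 100 Monte-Carlo permutations requested")
    set.seed(seed)
    assign_b <- cbind(
      (na + 1L):n,                                # identity labelling
      replicate(n_perm, sample.int(n, nb)))
  }
  # weight matrix: +1/nb on B members, -1/na elsewhere
  W <- matrix(-1 / na, ncol(assign_b), n)
  for (j in seq_len(ncol(assign_b)))
    W[j, assign_b[, j]] <- 1 / nb
  S <- W %*% X                                    # assignments x voxels
  id_row <- if (exact) which(colSums(assign_b == (na + 1L):n) == nb)[1L]
            else 1L
  obs <- S[id_row, ]
  # tolerance so that sign-flipped relabellings tie with the observed one
  tol <- 1e-9 * (1 + abs(obs))
  p <- colMeans(sweep(abs(S), 2L, abs(obs) - tol, ">="))
  shp <- group_a$shape
  list(p = array(pmin(p, 1), dim = shp),
       sign = array(as.integer(sign(obs)), dim = shp),
       stat = array(obs, dim = shp),
       exact = exact,
       n_perm = ncol(assign_b))
}

#' FDR masks of enhanced and suppressed voxels
#'
#' BH adjustment across all voxel p-values; passing voxels are split by
#' the sign of the observed statistic into enhanced (positive) and
#' suppressed (negative) masks.
#'
#' @param p P-value array from [permutation_test()].
#' @param sign_vol Sign array from [permutation_test()].
#' @param q FDR threshold in `(0, 1)`. Default 0.0005 (0.05%); the
#'   alternative reading 0.005 (a 99.5% voxel significance level) can be
#'   supplied instead.
#' @return List with logical arrays `enhanced` and `suppressed` and the
#'   adjusted p-value array `padj`.
#' @export
fdr_mask <- function(p, sign_vol, q = 0.0005) {
  if (q <= 0 || q >= 1)
    mntox_error("q must be in (0, 1)", "mntox_contract_error")
  padj <- array(stats::p.adjust(as.vector(p), method = "BH"), dim = dim(p))
  pass <- padj <= q
  list(enhanced = pass & sign_vol > 0L,
       suppressed = pass & sign_vol < 0L,
       padj = padj)
}

#' Summarise masks over an anatomical region atlas
#'
#' @param enhanced,suppressed Logical arrays (masks).
#' @param atlas A `region_atlas` of the same shape.
#' @return data.frame per region: `region`, `n_voxels`, `n_enhanced`,
#'   `n_suppressed`, `frac_enhanced`, `frac_suppressed`, sorted by the
#'   larger fraction descending, ties broken by region name.
#' @export
region_summary <- function(enhanced, suppressed, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (!identical(dim(enhanced), dim(atlas$labels)) ||
      !identical(dim(suppressed), dim(atlas$labels)))
    mntox_error("mask and atlas shapes differ", "mntox_data_error")
  lbl <- as.vector(atlas$labels)
  keep <- lbl > 0L
  f <- factor(lbl[keep], levels = sort(unique(as.integer(
    names(atlas$region_names)))))
  n_vox <- as.integer(table(f))
  n_enh <- as.integer(tapply(as.vector(enhanced)[keep], f, sum,
                             default = 0L))
  n_sup <- as.integer(tapply(as.vector(suppressed)[keep], f, sum,
                             default = 0L))
  df <- data.frame(
    region = unname(atlas$region_names[levels(f)]),
    n_voxels = n_vox, n_enhanced = n_enh, n_suppressed = n_sup,
    frac_enhanced = ifelse(n_vox > 0, n_enh / n_vox, 0),
    frac_suppressed = ifelse(n_vox > 0, n_sup / n_vox, 0),
    stringsAsFactors = FALSE)
  o <- order(-pmax(df$frac_enhanced, df$frac_suppressed), df$region)
  df <- df[o, ]
  rownames(df) <- NULL
  df
}

#' Read / write a volume as multi-page TIFF
#'
#' Pages are Z slices; intensities are stored as 32-bit floats. Values
#' are scaled into `[0, 1]` on write using a stored range, and restored
#' on read from the sidecar `<path>.range.json`.
#'
#' @param vol Numeric 3D array (Z, Y, X).
#' @param path TIFF path.
#' @return `read_volume_tiff` returns the array.
#' @export
write_volume_tiff <- function(vol, path) {
  rng <- range(vol)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(vol)[1L]), function(z)
    (vol[z, , ] - rng[1L]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(min = rng[1L], scale = scale,
                            shape = dim(vol)),
                       paste0(path, ".range.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".range.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  vol <- array(0, dim = meta$shape)
  for (z in seq_along(pages))
    vol[z, , ] <- pages[[z]] * meta$scale + meta$min
  vol
}
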