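# Inversion discovery: windowed principal-coordinate profiles of pairwise
# genetic distances, clustered genome-wide to flag windows whose
# relationship structure deviates from the background.

#' Window specification for windowed analyses
#'
#' @param size Window size in bp (default 1 Mbp).
#' @param step Step between window starts (default `size/2`, half overlap).
#' @param min_snps Minimum SNPs for a window to be used (default 25).
#' @param max_missing Maximum fraction of missing genotypes (default 0.5).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(size = 1e6, step = size / 2, min_snps = 25,
                        max_missing = 0.5) {
  if (step > size) stop("step must be <= size")
  if (min_snps < 2) stop("min_snps must be >= 2")
  structure(list(size = size, step = step, min_snps = min_snps,
                 max_missing = max_missing), class = "window_spec")
}

#' Pairwise genetic distance matrix
#'
#' Entry (i, j) is the mean per-site allelic difference `|d_i - d_j| / 2`
#' over SNPs non-missing in both samples (range 0..1); the diagonal is 0.
#' Computed from dosage-class indicator cross-products, so it is exact and
#' fast for large sample sets.
#'
#' @param dataset A [genotype_dataset()].
#' @param reg Optional [region()] restricting the SNPs.
#' @param idx Optional explicit SNP indices (overrides `reg`).
#' @return Symmetric numeric matrix samples x samples; `NA` where a pair
#'   shares no non-missing site.
#' @export
pairwise_distance_matrix <- function(dataset, reg = NULL, idx = NULL) {
  if (is.null(idx)) idx <- snps_in_region(dataset, reg)
  g <- dataset$geno[, idx, drop = FALSE]
  if (nrow(g) < 2) stop("need at least two samples")
  a0 <- (!is.na(g) & g == 0L) * 1
  a1 <- (!is.na(g) & g == 1L) * 1
  a2 <- (!is.na(g) & g == 2L) * 1
  p <- a0 + a1 + a2
  num <- 2 * (tcrossprod(a0, a2) + tcrossprod(a2, a0)) +
    tcrossprod(a1, a0 + a2) + tcrossprod(a0 + a2, a1)
  cc <- tcrossprod(p)
  d <- num / (2 * cc)
  d[cc == 0] <- NA
  diag(d) <- 0
  dimnames(d) <- list(dataset$samples, dataset$samples)
  d
}

window_starts <- function(chrom_len, spec) {
  s <- seq(1, max(1, chrom_len), by = spec$step)
  s[s <= chrom_len]
}

#' Per-window principal-coordinate profiles
#'
#' Slides windows along each chromosome and, per window, performs classical
#' multidimensional scaling (eigendecomposition of the double-centred
#' squared-distance matrix) of the pairwise genetic distances. Windows with
#' too few SNPs or too much missingness are skipped with a log message.
#'
#' @param dataset A [genotype_dataset()].
#' @param spec A [window_spec()].
#' @param n_pcs Number of principal coordinates (must be < number of
#'   samples).
#' @return A list of class `window_profiles`; each element holds `region`,
#'   `n_snps`, `coords` (samples x n_pcs, centred), `var_explained`.
#' @export
compute_window_profiles <- function(dataset, spec = window_spec(),
                                    n_pcs = 2) {
  n <- length(dataset$samples)
  if (n_pcs > n - 1) stop("n_pcs must be <= samples - 1")
  profiles <- list()
  skipped <- 0L
  for (ci in seq_len(nrow(dataset$chrom))) {
    cn <- dataset$chrom$name[ci]
    len <- dataset$chrom$length[ci]
    on_chr <- which(dataset$snps$chrom == cn)
    pos <- dataset$snps$pos[on_chr]
    for (ws in window_starts(len, spec)) {
      we <- min(ws + spec$size - 1, len)
      idx <- on_chr[pos >= ws & pos <= we]
      if (length(idx) < spec$min_snps) { skipped <- skipped + 1L; next }
      miss <- mean(is.na(dataset$geno[, idx]))
      if (miss > spec$max_missing) { skipped <- skipped + 1L; next }
      d <- pairwise_distance_matrix(dataset, idx = idx)
      profiles[[length(profiles) + 1L]] <-
        mds_profile(d, n_pcs, region(cn, ws, we), length(idx))
    }
  }
  if (skipped) inv_log(skipped, " window(s) skipped (SNP/missingness filter)")
  structure(profiles, class = "window_profiles",
            samples = dataset$samples)
}

mds_profile <- function(d, n_pcs, reg, nsnp) {
  n <- nrow(d)
  coords <- matrix(0, n, n_pcs)
  ve <- rep(0, n_pcs)
  if (any(d > 0, na.rm = TRUE)) {
    d0 <- d
    d0[is.na(d0)] <- mean(d, na.rm = TRUE)
    mds <- stats::cmdscale(d0, k = n_pcs, eig = TRUE)
    k_got <- ncol(mds$points)
    if (k_got > 0) coords[, seq_len(k_got)] <- mds$points
    pos_eig <- pmax(mds$eig, 0)
    if (sum(pos_eig) > 0)
      ve <- pos_eig[seq_len(n_pcs)] / sum(pos_eig)
  }
  rownames(coords) <- rownames(d)
  list(region = reg, n_snps = nsnp, coords = coords, var_explained = ve)
}

#' Genome-wide anchor profile
#'
#' Principal coordinates of the genome-wide distance matrix, used to align
#' per-window PC signs. At most `max_snps` evenly spaced SNPs are used.
#'
#' @inheritParams compute_window_profiles
#' @param max_snps Subsampling cap.
#' @return A single profile as in [compute_window_profiles()].
#' @export
anchor_profile <- function(dataset, n_pcs = 2, max_snps = 20000) {
  idx <- seq_len(n_snps(dataset))
  if (length(idx) > max_snps)
    idx <- idx[round(seq(1, length(idx), length.out = max_snps))]
  d <- pairwise_distance_matrix(dataset, idx = idx)
  mds_profile(d, n_pcs, NULL, length(idx))
}

#' Align per-window principal-coordinate signs to an anchor
#'
#' The sign of each principal coordinate is arbitrary per window; each
#' window PC k is negated iff its correlation with the anchor's PC k is
#' negative. Zero-variance or exactly orthogonal PCs are left unchanged
#' (with a log message for the latter). Idempotent.
#'
#' @param profiles A `window_profiles` list.
#' @param anchor An anchor profile ([anchor_profile()]).
#' @return The profiles with aligned signs.
#' @export
align_pc_signs <- function(profiles, anchor) {
  n_pcs <- ncol(anchor$coords)
  out <- lapply(profiles, function(pr) {
    for (k in seq_len(min(n_pcs, ncol(pr$coords)))) {
      x <- pr$coords[, k]
      if (stats::sd(x) == 0 || stats::sd(anchor$coords[, k]) == 0) next
      cc <- stats::cor(x, anchor$coords[, k])
      if (is.na(cc)) next
      if (cc < 0) pr$coords[, k] <- -x
      else if (cc == 0) inv_log("window PC", k, " orthogonal to anchor; ",
                                "sign left unchanged")
    }
    pr
  })
  attributes(out) <- attributes(profiles)
  out
}

feature_matrix <- function(profiles, n_pcs = 2) {
  t(vapply(profiles, function(pr) {
    v <- as.vector(pr$coords[, seq_len(min(n_pcs, ncol(pr$coords))),
                             drop = FALSE])
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }, numeric(length(attr(profiles, "samples")) * n_pcs)))
}

#' Detect outlier regions by k-means clustering of window profiles
#'
#' Clusters per-window feature vectors (concatenated, sign-aligned,
#' unit-normalised principal coordinates) with k-means; the largest cluster
#' is taken as the genome background, and maximal runs of at least
#' `min_run` consecutive non-background windows become region calls.
#' Adjacent runs separated by fewer than `min_run` background windows are
#' merged.
#'
#' @param profiles Sign-aligned `window_profiles`.
#' @param k_clusters Number of k-means clusters (default 2).
#' @param min_run Minimum run length in windows (default 3).
#' @param seed Seed for the k-means restarts.
#' @param n_pcs PCs per window entering the feature vector.
#' @return List of `region_call` objects: `region`, `window_idx`,
#'   `cluster`, `score` (fraction of member windows in the outlier
#'   cluster).
#' @export
detect_outlier_regions <- function(profiles, k_clusters = 2, min_run = 3,
                                   seed = 1, n_pcs = 2) {
  if (length(profiles) < 2 * min_run)
    stop("need at least 2 * min_run windows")
  fm <- feature_matrix(profiles, n_pcs)
  km <- with_local_seed(seed,
    stats::kmeans(fm, centers = k_clusters, nstart = 10, iter.max = 50))
  bg <- as.integer(which.max(table(km$cluster))[1])
  outlier <- km$cluster != bg
  if (!any(outlier)) return(list())

  chroms <- vapply(profiles, function(p) p$region$chrom, character(1))
  starts <- vapply(profiles, function(p) p$region$start, numeric(1))
  calls <- list()
  for (cn in unique(chroms)) {
    wi <- which(chroms == cn)
    wi <- wi[order(starts[wi])]
    flag <- outlier[wi]
    r <- rle(flag)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    runs <- data.frame(s = starts_i[r$values], e = ends_i[r$values],
                       len = r$lengths[r$values])
    runs <- runs[runs$len >= min_run, , drop = FALSE]
    if (!nrow(runs)) next
    # merge runs separated by short background gaps
    merged <- runs[1, , drop = FALSE]
    for (j in seq_len(nrow(runs))[-1]) {
      gap <- runs$s[j] - merged$e[nrow(merged)] - 1
      if (gap < min_run) merged$e[nrow(merged)] <- runs$e[j]
      else merged <- rbind(merged, runs[j, ])
    }
    for (j in seq_len(nrow(merged))) {
      memb <- wi[merged$s[j]:merged$e[j]]
      reg <- region(cn, profiles[[memb[1]]]$region$start,
                    profiles[[memb[length(memb)]]]$region$end)
      calls[[length(calls) + 1L]] <- structure(
        list(region = reg, window_idx = memb,
             cluster = setdiff(unique(km$cluster[memb]), bg),
             score = mean(outlier[memb])),
        class = "region_call")
    }
  }
  calls
}

#' Per-sample PC1 track along a chromosome
#'
#' Sign-aligned first principal coordinate per sample per window, as used
#' for plotting inversion-state clusters and for pedigree crossover
#' counting.
#'
#' @param dataset A [genotype_dataset()].
#' @param spec A [window_spec()].
#' @param samples Sample ids (default all).
#' @param chrom Optional chromosome name restriction.
#' @return `list(starts, chrom, pc1)` where `pc1` is windows x samples.
#' @export
windowed_pc1_track <- function(dataset, spec = window_spec(),
                               samples = NULL, chrom = NULL) {
  ds <- if (is.null(samples)) dataset else subset_dataset(dataset, samples)
  if (!is.null(chrom)) {
    keep <- which(ds$snps$chrom == chrom)
    ds <- subset_dataset(ds, snp_idx = keep)
    ds$chrom <- ds$chrom[ds$chrom$name == chrom, , drop = FALSE]
  }
  prof <- compute_window_profiles(ds, spec, n_pcs = 2)
  prof <- align_pc_signs(prof, anchor_profile(ds, n_pcs = 2))
  pc1 <- t(vapply(prof, function(p) p$coords[, 1],
                  numeric(length(ds$samples))))
  colnames(pc1) <- ds$samples
  list(starts = vapply(prof, function(p) p$region$start, numeric(1)),
       chrom = vapply(prof, function(p) p$region$chrom, character(1)),
       size = spec$size, pc1 = pc1)
}
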