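# Multi-step PC genotyping of inversion karyotypes: PCA of region dosages
# fit on a reference panel, 1-D k-means on PC1 with k chosen from {2, 3},
# projection of remaining samples, and polarity from the outgroup
# projection. The middle cluster (when present) must be the most
# heterozygous, as expected for heterokaryotypes of two divergent
# haplotypes.

#' Region heterozygosity per sample
#'
#' Number of heterozygous SNPs per 10 kbp of region length.
#'
#' @param dataset A [genotype_dataset()].
#' @param reg A [region()].
#' @param samples Sample ids (default all).
#' @return Named numeric vector; `NA` for samples missing at every region
#'   SNP.
#' @export
region_heterozygosity <- function(dataset, reg, samples = NULL) {
  samples <- samples %||% dataset$samples
  idx <- snps_in_region(dataset, reg)
  g <- dataset$geno[samples, idx, drop = FALSE]
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  all_missing <- rowSums(!is.na(g)) == 0
  out <- n_het / region_length(reg) * 1e4
  out[all_missing & length(idx) > 0] <- NA
  stats::setNames(out, samples)
}

# within-cluster sum of squares of a 1-D k-means solution
wss_1d <- function(x, centers) {
  d2 <- outer(x, centers, function(a, b) (a - b)^2)
  sum(apply(d2, 1, min))
}

kmeans_1d <- function(x, k, seed) {
  with_local_seed(seed, {
    if (length(unique(x)) < k) {
      # degenerate: fewer distinct values than clusters
      centers <- sort(unique(x))
      cl <- match(x, centers)
      list(centers = centers, cluster = cl, tot.withinss = 0)
    } else {
      km <- stats::kmeans(matrix(x), centers = k, nstart = 10, iter.max = 100)
      list(centers = as.vector(km$centers), cluster = km$cluster,
           tot.withinss = km$tot.withinss)
    }
  })
}

# gap statistic (uniform reference on the observed range) for k in {2, 3},
# with the one-standard-error rule: prefer the smaller k unless the extra
# cluster improves the gap by more than the reference spread
choose_k_gap <- function(x, seed, B = 20) {
  stat <- lapply(2:3, function(k) {
    km <- kmeans_1d(x, k, seed)
    if (length(km$centers) < k) return(list(gap = -Inf, s = 0))
    w <- max(km$tot.withinss, 1e-12)
    ref <- with_local_seed(seed + k, vapply(seq_len(B), function(b) {
      xr <- stats::runif(length(x), min(x), max(x))
      kr <- stats::kmeans(matrix(xr), centers = k, nstart = 5, iter.max = 50)
      log(max(kr$tot.withinss, 1e-12))
    }, numeric(1)))
    list(gap = mean(ref) - log(w), s = stats::sd(ref) * sqrt(1 + 1 / B))
  })
  if (stat[[1]]$gap >= stat[[2]]$gap - stat[[2]]$s) 2 else 3
}

#' Genotype an inversion region across samples
#'
#' Multi-step PC genotyping: (1) PCA of region ALT dosages fitted on the
#' reference panel (missing genotypes mean-imputed per SNP); (2) 1-D
#' k-means on PC1 with k chosen from {2, 3} by the larger gap statistic;
#' (3) non-panel samples projected and assigned to the nearest centre; (4)
#' clusters mapped to genotypes: with three clusters the middle one is the
#' heterokaryotype and the end cluster nearest the outgroup projection is
#' genotype 0 (homozygous ancestral orientation); with two clusters the
#' more heterozygous one is the heterokaryotype and the other is 0 or 2 by
#' outgroup polarity. Samples whose assignment confidence
#' (1 - nearest/second-nearest centre distance) falls below
#' `min_confidence` are left unassigned.
#'
#' @param dataset A [genotype_dataset()].
#' @param reg A [region()] with at least `min_snps` SNPs.
#' @param outgroup_samples Outgroup ids for polarity (may be `NULL`:
#'   genotypes are then reported up to a 0/2 label swap).
#' @param reference_panel Panel sample ids for the PCA fit (default: all
#'   ingroup samples).
#' @param seed Seed for k-means restarts and the gap-statistic reference.
#' @param min_snps Minimum region SNPs (default 50).
#' @param min_confidence Assignment confidence threshold (default 0.2).
#' @return An `inversion_call`: `region`, `genotype` (named 0/1/2/`NA`),
#'   `confidence`, `het` (het SNPs per 10 kbp), `polarity_source`, `k`,
#'   `valid` (heterozygosity ordering check).
#' @export
genotype_region <- function(dataset, reg, outgroup_samples = NULL,
                            reference_panel = NULL, seed = 1,
                            min_snps = 50, min_confidence = 0.2) {
  idx <- snps_in_region(dataset, reg)
  if (length(idx) < min_snps)
    stop("region has ", length(idx), " SNPs; need >= ", min_snps)
  ingroup <- setdiff(dataset$samples, outgroup_samples)
  if (length(ingroup) < 3) stop("need at least 3 ingroup samples")
  panel <- reference_panel %||% ingroup
  g <- dataset$geno[, idx, drop = FALSE]
  gp <- g[panel, , drop = FALSE]
  mu <- colMeans(gp, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  imp <- function(m) {
    for (j in which(colSums(is.na(m)) > 0)) m[is.na(m[, j]), j] <- mu[j]
    m
  }
  gp <- sweep(imp(gp), 2, mu)
  het <- region_heterozygosity(dataset, reg)

  # degenerate region: no variation in the panel
  if (all(abs(gp) < 1e-12)) {
    geno <- stats::setNames(rep(0L, length(ingroup)), ingroup)
    return(structure(list(region = reg, genotype = geno,
                          confidence = stats::setNames(rep(1, length(ingroup)), ingroup),
                          het = het[ingroup],
                          polarity_source = outgroup_samples, k = 1L,
                          centers = 0, valid = TRUE),
                     class = "inversion_call"))
  }

  sv <- svd(gp, nu = 0, nv = 1)
  rot <- sv$v[, 1]
  pc1_panel <- as.vector(gp %*% rot)
  names(pc1_panel) <- panel
  k <- choose_k_gap(pc1_panel, seed)
  km <- kmeans_1d(pc1_panel, k, seed)
  centers <- sort(km$centers)
  k <- length(centers)

  project <- function(ids) {
    gm <- sweep(imp(g[ids, , drop = FALSE]), 2, mu)
    stats::setNames(as.vector(gm %*% rot), ids)
  }
  pc1 <- c(pc1_panel, project(setdiff(ingroup, panel)))[ingroup]

  d2c <- abs(outer(pc1, centers, `-`))
  nearest <- apply(d2c, 1, which.min)
  conf <- if (k == 1) rep(1, length(pc1)) else {
    srt <- t(apply(d2c, 1, sort))
    1 - srt[, 1] / pmax(srt[, 2], 1e-300)
  }

  out_proj <- if (length(outgroup_samples))
    mean(project(outgroup_samples)) else NA_real_

  # map ordered clusters (by centre) to genotypes
  cluster_geno <- integer(k)
  if (k == 3) {
    cluster_geno[2] <- 1L
    lo_is_anc <- if (!is.na(out_proj))
      abs(centers[1] - out_proj) <= abs(centers[3] - out_proj) else TRUE
    cluster_geno[c(1, 3)] <- if (lo_is_anc) c(0L, 2L) else c(2L, 0L)
  } else if (k == 2) {
    mh <- vapply(1:2, function(cc)
      mean(het[ingroup][nearest == cc], na.rm = TRUE), numeric(1))
    hetc <- which.max(mh)
    homc <- 3 - hetc
    cluster_geno[hetc] <- 1L
    hom_is_anc <- if (!is.na(out_proj))
      abs(centers[homc] - out_proj) < abs(centers[hetc] - out_proj) else TRUE
    cluster_geno[homc] <- if (hom_is_anc) 0L else 2L
  } else cluster_geno[1] <- 0L

  geno <- cluster_geno[nearest]
  geno[conf < min_confidence] <- NA_integer_
  names(geno) <- ingroup

  mh_g <- vapply(0:2, function(gg) {
    s <- names(geno)[!is.na(geno) & geno == gg]
    if (!length(s)) NA_real_ else mean(het[s], na.rm = TRUE)
  }, numeric(1))
  valid <- TRUE
  if (!is.na(mh_g[2])) {
    if (!is.na(mh_g[1]) && mh_g[2] <= mh_g[1]) valid <- FALSE
    if (!is.na(mh_g[3]) && mh_g[2] <= mh_g[3]) valid <- FALSE
  }

  structure(list(region = reg, genotype = geno,
                 confidence = stats::setNames(conf, ingroup),
                 het = het[ingroup],
                 polarity_source = outgroup_samples,
                 k = k, centers = centers, valid = valid),
            class = "inversion_call")
}

#' @export
print.inversion_call <- function(x, ...) {
  cat(sprintf("inversion_call %s:%d-%d  k=%d  valid=%s\n", x$region$chrom,
              x$region$start, x$region$end, x$k, x$valid))
  print(table(genotype = x$genotype, useNA = "ifany"))
  invisible(x)
}

#' Export an inversion call as a data frame
#'
#' @param call An `inversion_call`.
#' @return Data frame with sample, genotype, confidence and heterozygosity.
#' @export
inversion_call_table <- function(call) {
  data.frame(sample = names(call$genotype),
             chrom = call$region$chrom, start = call$region$start,
             end = call$region$end,
             genotype = unname(call$genotype),
             confidence = unname(call$confidence[names(call$genotype)]),
             het_per_10kb = unname(call$het[names(call$genotype)]),
             stringsAsFactors = FALSE)
}
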