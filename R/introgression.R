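# Divergence times, Patterson's D with block jackknife, the
# inversion-state-conditioned D experiment, and the coalescent
# incomplete-lineage-sorting retention factor.

#' Pairwise divergence time between two samples
#'
#' Mean per-bp pairwise difference d over the accessible scope, translated
#' into generations as t = d / (2 mu). Sites missing in either sample are
#' excluded and the accessible length scaled accordingly (monomorphic
#' accessible sites count as zero difference).
#'
#' @param dataset A [genotype_dataset()].
#' @param pair Two sample ids.
#' @param scope `NULL` (whole genome) or a [region()].
#' @param exclude Optional list of [region()]s removed from the scope
#'   (e.g. called inversions).
#' @param mu Mutation rate per bp per generation (default `3e-9`).
#' @param min_sites Minimum accessible bp (default 1000).
#' @return `list(d, t, mu, accessible_bp, n_snps)`.
#' @export
pairwise_divergence_time <- function(dataset, pair, scope = NULL,
                                     exclude = list(), mu = 3e-9,
                                     min_sites = 1000) {
  stopifnot(length(pair) == 2)
  idx <- snps_in_region(dataset, scope)
  scope_len <- if (is.null(scope)) sum(dataset$chrom$length)
               else region_length(scope)
  for (ex in exclude) {
    drop <- which(dataset$snps$chrom[idx] == ex$chrom &
                  dataset$snps$pos[idx] >= ex$start &
                  dataset$snps$pos[idx] <= ex$end)
    if (length(drop)) idx <- idx[-drop]
    ov_lo <- max(ex$start, if (is.null(scope)) 1 else scope$start)
    ov_hi <- min(ex$end, if (is.null(scope)) Inf else scope$end)
    if (!is.null(scope) && ex$chrom != scope$chrom) next
    len <- dataset$chrom$length[dataset$chrom$name == ex$chrom]
    if (length(len)) scope_len <- scope_len -
        max(0, min(ov_hi, len) - ov_lo + 1)
  }
  g <- dataset$geno[pair, idx, drop = FALSE]
  complete <- colSums(is.na(g)) == 0
  cf <- if (length(idx)) mean(complete) else 1
  accessible <- scope_len * cf
  if (accessible < min_sites)
    stop("only ", round(accessible), " comparable site(s) in scope")
  diffs <- sum(abs(g[1, complete] - g[2, complete])) / 2
  d <- diffs / accessible
  list(d = d, t = d / (2 * mu), mu = mu, accessible_bp = accessible,
       n_snps = sum(complete))
}

#' Per-population derived-allele frequencies
#'
#' @param dataset A polarized [genotype_dataset()].
#' @param pops Named list of sample-id vectors.
#' @param idx Optional SNP indices.
#' @return `list(freq (SNPs x pops), chrom, pos)`; missing genotypes are
#'   ignored per population (complete-case).
#' @export
pop_allele_freqs <- function(dataset, pops, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(n_snps(dataset))
  dd <- derived_dosages(dataset, idx)
  fr <- vapply(pops, function(ss) {
    m <- dd[ss, , drop = FALSE]
    colSums(m, na.rm = TRUE) / (2 * colSums(!is.na(m)))
  }, numeric(length(idx)))
  if (length(idx) == 1) fr <- matrix(fr, nrow = 1)
  list(freq = fr, chrom = dataset$snps$chrom[idx],
       pos = dataset$snps$pos[idx])
}

#' Patterson's D (ABBA-BABA) with block jackknife
#'
#' Frequency-weighted site patterns for the quartet (P1, P2, P3, O):
#' ABBA = (1-p1) p2 p3 (1-pO), BABA = p1 (1-p2) p3 (1-pO), summed over
#' SNPs; D = (ABBA-BABA)/(ABBA+BABA). The standard error comes from a
#' delete-one jackknife over contiguous genomic blocks.
#'
#' @param freq SNPs x 4 matrix of derived-allele frequencies, columns
#'   (P1, P2, P3, O).
#' @param chrom,pos SNP coordinates for block assignment.
#' @param block_size Jackknife block size in bp (default 1 Mbp).
#' @return `list(D, ABBA, BABA, se, z, n_blocks, n_snps)`.
#' @export
d_statistic <- function(freq, chrom, pos, block_size = 1e6) {
  ok <- stats::complete.cases(freq)
  freq <- freq[ok, , drop = FALSE]
  chrom <- chrom[ok]; pos <- pos[ok]
  p1 <- freq[, 1]; p2 <- freq[, 2]; p3 <- freq[, 3]; po <- freq[, 4]
  abba <- (1 - p1) * p2 * p3 * (1 - po)
  baba <- p1 * (1 - p2) * p3 * (1 - po)
  block <- paste(chrom, floor((pos - 1) / block_size))
  keep_blocks <- unique(block)
  B <- length(keep_blocks)
  if (B < 20) stop("need >= 20 non-empty blocks for the jackknife, got ", B)
  A <- sum(abba); Bb <- sum(baba)
  if (A + Bb == 0) stop("no informative sites")
  D <- (A - Bb) / (A + Bb)
  a_blk <- tapply(abba, block, sum)[keep_blocks]
  b_blk <- tapply(baba, block, sum)[keep_blocks]
  d_jack <- ((A - a_blk) - (Bb - b_blk)) / ((A - a_blk) + (Bb - b_blk))
  d_jack <- d_jack[is.finite(d_jack)]
  m <- length(d_jack)
  se <- sqrt((m - 1) / m * sum((d_jack - mean(d_jack))^2))
  list(D = D, ABBA = A, BABA = Bb, se = se,
       z = if (se > 0) D / se else NA_real_,
       n_blocks = B, n_snps = nrow(freq))
}

#' Inversion-state-conditioned D experiment
#'
#' For each inversion call, species quartets (P1, P2, P3, O) are
#' enumerated such that P1 and P2 belong to the same clade, P3 to a
#' different (non-outgroup) clade, and exactly one of P1/P2 shares the
#' species-majority inversion state with P3 — ordered so that P2 is the
#' sharer. D is computed on SNPs *outside* all called inversion regions.
#' Under the null of no inversion introgression, the D distribution is
#' symmetric around zero.
#'
#' @param dataset A polarized [genotype_dataset()].
#' @param calls List of `inversion_call`s.
#' @param metadata [read_sample_metadata()] table covering the samples.
#' @param outgroup Species name used as O.
#' @param block_size Jackknife block size (default 1 Mbp).
#' @return `list(results, summary)`: per-quartet data frame (inversion,
#'   P1, P2, P3, D, se, z, p_holm) and a summary (mean D, fraction
#'   positive, two-sided sign-test p).
#' @export
conditioned_d_experiment <- function(dataset, calls, metadata, outgroup,
                                     block_size = 1e6) {
  md <- metadata[metadata$sample %in% dataset$samples, ]
  sp_samples <- split(md$sample, md$species)
  sp_clade <- vapply(split(md$clade, md$species), `[`, character(1), 1)
  outside <- seq_len(n_snps(dataset))
  for (cl in calls) {
    r <- cl$region
    outside <- setdiff(outside, snps_in_region(dataset, r))
  }
  if (!length(outside)) stop("no SNPs outside the called inversion regions")

  quartets <- list()
  for (ci in seq_along(calls)) {
    geno <- calls[[ci]]$genotype
    state <- vapply(sp_samples, function(ss) {
      gg <- geno[intersect(ss, names(geno))]
      gg <- gg[!is.na(gg)]
      if (!length(gg)) return(NA_real_)
      as.numeric(mean(gg) / 2 >= 0.5)
    }, numeric(1))
    ing <- setdiff(names(state)[!is.na(state)], outgroup)
    for (cl_name in unique(sp_clade[ing])) {
      members <- ing[sp_clade[ing] == cl_name]
      others <- ing[sp_clade[ing] != cl_name]
      if (length(members) < 2 || !length(others)) next
      prs <- utils::combn(members, 2, simplify = FALSE)
      for (pr in prs) for (p3 in others) {
        s <- state[c(pr, p3)]
        if (s[1] == s[2]) next  # need exactly one sharer among P1/P2
        p2 <- pr[which(s[1:2] == s[3])]
        p1 <- setdiff(pr, p2)
        quartets[[length(quartets) + 1L]] <-
          data.frame(inversion = ci, P1 = p1, P2 = p2, P3 = p3,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(quartets)) stop("no qualifying quartets")
  qt <- do.call(rbind, quartets)

  res <- lapply(seq_len(nrow(qt)), function(i) {
    pops <- sp_samples[c(qt$P1[i], qt$P2[i], qt$P3[i], outgroup)]
    fr <- pop_allele_freqs(dataset, pops, idx = outside)
    d <- d_statistic(fr$freq, fr$chrom, fr$pos, block_size)
    data.frame(qt[i, ], D = d$D, se = d$se, z = d$z,
               n_blocks = d$n_blocks, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p <- 2 * stats::pnorm(abs(res$z), lower.tail = FALSE)
  res$p_holm <- stats::p.adjust(res$p, "holm")
  nz <- res$D[res$D != 0]
  sign_p <- if (length(nz))
    stats::binom.test(sum(nz > 0), length(nz))$p.value else 1
  list(results = res,
       summary = list(mean_D = mean(res$D),
                      frac_positive = mean(res$D > 0),
                      sign_test_p = sign_p,
                      n_quartets = nrow(res)))
}

#' Incomplete-lineage-sorting retention factor
#'
#' The probability factor that a neutral polymorphism is retained over t
#' generations of independent sorting in a lineage of effective size Ne,
#' approximated by the heterozygosity-decay factor exp(-t / (2 Ne)); the
#' joint factor over `n_lineages` independent lineages and `k_inversions`
#' independent inversions is that factor to the power n x k.
#'
#' @param ne Effective population size (> 0).
#' @param t Generations of independent sorting (>= 0).
#' @param n_lineages,k_inversions Number of lineages and inversions.
#' @return `list(probability, percent)`.
#' @export
ils_retention_probability <- function(ne, t, n_lineages = 1,
                                      k_inversions = 1) {
  if (ne <= 0 || t < 0 || n_lineages <= 0 || k_inversions <= 0)
    stop("all parameters must be positive (t may be zero)")
  p <- exp(-t / (2 * ne))^(n_lineages * k_inversions)
  list(probability = p, percent = 100 * p)
}

#' Forward Wright-Fisher heterozygosity retention
#'
#' Monte-Carlo companion to [ils_retention_probability()]: simulates
#' neutral allele-frequency drift in a diploid Wright-Fisher population
#' and reports the fraction of initial heterozygosity retained after t
#' generations (and the fraction of replicates still polymorphic).
#'
#' @param ne Diploid effective size.
#' @param t Generations.
#' @param n_rep Replicates (default 10000).
#' @param p0 Initial allele frequency (default 0.5).
#' @param seed Integer seed.
#' @return `list(het_retained, se, frac_polymorphic)`.
#' @export
wf_heterozygosity_retention <- function(ne, t, n_rep = 10000, p0 = 0.5,
                                        seed = 17) {
  set.seed(seed)
  x <- rep(round(2 * ne * p0), n_rep)
  for (g in seq_len(t)) x <- stats::rbinom(n_rep, 2 * ne, x / (2 * ne))
  p <- x / (2 * ne)
  h <- 2 * p * (1 - p)
  h0 <- 2 * p0 * (1 - p0)
  list(het_retained = mean(h) / h0,
       se = stats::sd(h / h0) / sqrt(n_rep),
       frac_polymorphic = mean(x > 0 & x < 2 * ne))
}
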