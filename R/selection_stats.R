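# Inversion-correlated SNP (ICS) scan and selection statistics on
# inversion haplotypes.

#' Scan for inversion-correlated SNPs
#'
#' For every polarized SNP, the signed Pearson correlation `r` between
#' derived-allele dosage and inversion genotype across samples (complete
#' cases), with a significance score `-log10 p` from the t-distribution
#' with n-2 degrees of freedom. Positive `r` means the derived allele is
#' enriched on inverted haplotypes. Monomorphic SNPs and SNPs with fewer
#' than `min_obs` complete observations are skipped and counted in the
#' log.
#'
#' @param dataset A polarized [genotype_dataset()] (see [polarize()]).
#' @param inv_genotype Named inversion genotype vector (0/1/2), or an
#'   `inversion_call`.
#' @param samples Samples to use (default: those with a non-missing
#'   inversion genotype).
#' @param min_obs Minimum complete observations per SNP (default 10).
#' @param score_cap Cap for the score, applied where p underflows
#'   (default 320).
#' @param ics_score_min,ics_r_min Thresholds defining the `is_ics` flag
#'   (defaults: score >= 7 and |r| >= 0.9).
#' @param n_perm If positive, two-sided permutation p-values with this many
#'   seeded permutations replace the t-approximation.
#' @param perm_seed Seed for the permutations.
#' @return Data frame: `snp_idx`, `chrom`, `pos`, `r`, `score`, `p`,
#'   `effect`, `is_ics`, `n`.
#' @export
ics_scan <- function(dataset, inv_genotype, samples = NULL, min_obs = 10,
                     score_cap = 320, ics_score_min = 7, ics_r_min = 0.9,
                     n_perm = 0, perm_seed = 1) {
  if (all(is.na(dataset$snps$ancestral)))
    stop("dataset is not polarized; run polarize() first")
  if (inherits(inv_genotype, "inversion_call"))
    inv_genotype <- inv_genotype$genotype
  gt <- inv_genotype[!is.na(inv_genotype)]
  samples <- samples %||% names(gt)
  gt <- gt[samples]
  if (length(gt) < min_obs) stop("inversion genotypes known for too few samples")

  dd <- derived_dosages(dataset)[samples, , drop = FALSE]
  M <- !is.na(dd)
  x <- dd; x[!M] <- 0
  g <- as.numeric(gt)
  n <- colSums(M)
  sx <- colSums(x)
  sx2 <- colSums(x^2)
  sg <- as.vector(crossprod(M, g))
  sg2 <- as.vector(crossprod(M, g^2))
  sxg <- as.vector(crossprod(x, g))
  vx <- n * sx2 - sx^2
  vg <- n * sg2 - sg^2
  keep <- n >= min_obs & vx > 0 & vg > 0
  n_skip <- sum(!keep)
  if (n_skip) inv_log(n_skip, " SNP(s) skipped in ICS scan ",
                      "(monomorphic or insufficient observations)")
  r <- rep(NA_real_, length(n))
  r[keep] <- ((n * sxg - sx * sg) / sqrt(vx * vg))[keep]
  r <- pmin(pmax(r, -1), 1)
  p <- rep(NA_real_, length(n))
  tt <- abs(r) * sqrt(pmax(n - 2, 1) / pmax(1 - r^2, 1e-300))
  p[keep] <- 2 * stats::pt(tt[keep], n[keep] - 2, lower.tail = FALSE)
  p[keep & abs(r) >= 1] <- 0

  out <- data.frame(snp_idx = which(keep),
                    chrom = dataset$snps$chrom[keep],
                    pos = dataset$snps$pos[keep],
                    r = r[keep], p = p[keep],
                    effect = dataset$snps$effect[keep],
                    n = n[keep], stringsAsFactors = FALSE)
  if (n_perm > 0) {
    out$p <- with_local_seed(perm_seed, vapply(seq_len(nrow(out)), function(i) {
      j <- out$snp_idx[i]
      xv <- dd[, j]; ok <- !is.na(xv)
      obs <- abs(stats::cor(xv[ok], g[ok]))
      perm <- vapply(seq_len(n_perm), function(b)
        abs(stats::cor(xv[ok], sample(g[ok]))), numeric(1))
      (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
    }, numeric(1)))
  }
  out$score <- pmin(-log10(pmax(out$p, 10^(-score_cap - 1))), score_cap)
  out$is_ics <- out$score >= ics_score_min & abs(out$r) >= ics_r_min
  out
}

#' Exonic enrichment of inversion-correlated SNPs
#'
#' 2x2 contingency of (ICS vs non-ICS) x (exonic vs non-exonic), where
#' exonic means a synonymous or nonsynonymous effect class. Odds ratio is
#' the sample cross-product ratio; p is the two-sided Fisher exact test.
#'
#' @param records [ics_scan()] output with effect classes.
#' @return `list(table, odds_ratio, p)`.
#' @export
exonic_enrichment <- function(records) {
  if (!any(records$is_ics)) stop("no ICS in records")
  exonic <- records$effect %in% c("synonymous", "nonsynonymous")
  tab <- matrix(c(sum(records$is_ics & exonic),
                  sum(records$is_ics & !exonic),
                  sum(!records$is_ics & exonic),
                  sum(!records$is_ics & !exonic)),
                2, 2, byrow = TRUE,
                dimnames = list(c("ICS", "non-ICS"),
                                c("exonic", "non-exonic")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, odds_ratio = or, p = fisher_exact_2x2(tab)$p)
}

#' McDonald-Kreitman table between inversion haplotype classes
#'
#' Sites fixed for different alleles between the inverted and ancestral
#' haplotype classes count as divergence (Dn/Ds by effect class); sites
#' variable within either class count as polymorphism (Pn/Ps). Each site
#' counts at most once. NI = (Pn/Ps)/(Dn/Ds); DoS = Dn/(Dn+Ds) -
#' Pn/(Pn+Ps); p is the Fisher exact test on the 2x2 table.
#'
#' @param phased A `phased_region` ([rephase_by_inversion()]).
#' @param effect_class Character vector of effect classes aligned with
#'   `phased$snp_idx` (e.g. `dataset$snps$effect[phased$snp_idx]`).
#' @return `list(Dn, Ds, Pn, Ps, NI, DoS, p, ni_defined)`.
#' @export
mk_test <- function(phased, effect_class) {
  H <- rbind(phased$h1, phased$h2)
  cls <- c(phased$class1, phased$class2)
  if (sum(cls == "inverted") < 2 || sum(cls == "ancestral") < 2)
    stop("need >= 2 haplotypes per class")
  inv <- H[cls == "inverted", , drop = FALSE]
  anc <- H[cls == "ancestral", , drop = FALSE]
  stopifnot(length(effect_class) == ncol(H))

  cnt <- function(m) {
    ones <- colSums(m == 1L, na.rm = TRUE)
    tot <- colSums(!is.na(m))
    cbind(ones = ones, tot = tot)
  }
  ci <- cnt(inv); ca <- cnt(anc)
  informative <- ci[, "tot"] > 0 & ca[, "tot"] > 0
  poly <- (ci[, "ones"] > 0 & ci[, "ones"] < ci[, "tot"]) |
          (ca[, "ones"] > 0 & ca[, "ones"] < ca[, "tot"])
  fixed_i <- ci[, "ones"] == 0 | ci[, "ones"] == ci[, "tot"]
  fixed_a <- ca[, "ones"] == 0 | ca[, "ones"] == ca[, "tot"]
  fixed_diff <- informative & fixed_i & fixed_a &
    (ci[, "ones"] > 0) != (ca[, "ones"] > 0)
  is_n <- effect_class == "nonsynonymous"
  is_s <- effect_class == "synonymous"
  Dn <- sum(fixed_diff & is_n); Ds <- sum(fixed_diff & is_s)
  Pn <- sum(informative & poly & is_n); Ps <- sum(informative & poly & is_s)
  ni_defined <- Ps > 0 && Ds > 0 && Dn > 0
  NI <- if (ni_defined) (Pn / Ps) / (Dn / Ds) else NA_real_
  DoS <- if ((Dn + Ds) > 0 && (Pn + Ps) > 0)
    Dn / (Dn + Ds) - Pn / (Pn + Ps)
  else if ((Dn + Ds) > 0) Dn / (Dn + Ds) else NA_real_
  tab <- matrix(c(Dn, Ds, Pn, Ps), 2, 2, byrow = TRUE)
  list(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps, NI = NI, DoS = DoS,
       p = fisher_exact_2x2(tab)$p, ni_defined = ni_defined)
}

#' Fraction of ICS with shared polymorphism across haplotype classes
#'
#' Fraction of inversion-correlated SNPs at which both alleles occur on at
#' least one haplotype of each orientation class.
#'
#' @param phased A `phased_region`.
#' @param records [ics_scan()] output.
#' @return Fraction in `[0, 1]`.
#' @export
shared_polymorphism_fraction <- function(phased, records) {
  ics_idx <- records$snp_idx[records$is_ics]
  pos_in_phase <- match(ics_idx, phased$snp_idx)
  pos_in_phase <- pos_in_phase[!is.na(pos_in_phase)]
  if (!length(pos_in_phase)) stop("no ICS among phased SNPs")
  H <- rbind(phased$h1, phased$h2)
  cls <- c(phased$class1, phased$class2)
  inv <- H[cls == "inverted", pos_in_phase, drop = FALSE]
  anc <- H[cls == "ancestral", pos_in_phase, drop = FALSE]
  both <- function(m) colSums(m == 1L, na.rm = TRUE) > 0 &
                      colSums(m == 0L, na.rm = TRUE) > 0
  mean(both(inv) & both(anc))
}

#' Correlation-binned normalized dN/dS
#'
#' Coding SNPs are binned by their inversion-genotype correlation `r`
#' (bins of `bin_width` partitioning -1..1, top bin closed); per bin,
#' dN/dS = (n_nonsyn / L_n) / (n_syn / L_s) with the supplied
#' nonsynonymous / synonymous site counts (see [nei_gojobori_sites()]).
#'
#' @param records [ics_scan()] output.
#' @param L_n,L_s Nonsynonymous and synonymous site counts (global).
#' @param bin_width Bin width over -1..1 (default 0.1).
#' @return Data frame: `lo`, `hi`, `n_nonsyn`, `n_syn`, `dnds` (`NA`
#'   flagged where `n_syn` is 0).
#' @export
binned_dnds <- function(records, L_n, L_s, bin_width = 0.1) {
  if (is.null(L_n) || is.null(L_s)) stop("site counts L_n and L_s required")
  breaks <- seq(-1, 1, by = bin_width)
  coding <- records[records$effect %in% c("synonymous", "nonsynonymous"), ]
  bin <- findInterval(coding$r, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  n_n <- tabulate(bin[coding$effect == "nonsynonymous"], nb)
  n_s <- tabulate(bin[coding$effect == "synonymous"], nb)
  dnds <- ifelse(n_s > 0, (n_n / L_n) / (n_s / L_s), NA_real_)
  data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
             n_nonsyn = n_n, n_syn = n_s, dnds = dnds)
}

#' Nei-Gojobori synonymous/nonsynonymous site counts
#'
#' For each codon position, the three single-base changes are enumerated;
#' changes producing a stop codon are excluded and the position's one site
#' is split between nonsynonymous and synonymous in proportion to the
#' remaining changes. Stop codons contribute no sites. Standard nuclear
#' code.
#'
#' @param sequences Character vector of coding sequences (each a string,
#'   length a multiple of 3, in-frame).
#' @return `list(L_n, L_s)` summed over all input sequences.
#' @export
nei_gojobori_sites <- function(sequences) {
  bases <- c("a", "c", "g", "t")
  L_n <- 0; L_s <- 0
  for (s in sequences) {
    s <- tolower(s)
    v <- strsplit(s, "")[[1]]
    if (length(v) %% 3 != 0) stop("sequence length not a multiple of 3")
    for (i in seq(1, length(v), by = 3)) {
      cod <- v[i:(i + 2)]
      aa0 <- seqinr::translate(cod)
      if (aa0 == "*") next
      for (pp in 1:3) {
        nn <- 0L; vv <- 0L
        for (b in setdiff(bases, cod[pp])) {
          mut <- cod; mut[pp] <- b
          aa1 <- seqinr::translate(mut)
          if (aa1 == "*") next
          vv <- vv + 1L
          if (aa1 != aa0) nn <- nn + 1L
        }
        if (vv > 0) {
          L_n <- L_n + nn / vv
          L_s <- L_s + (vv - nn) / vv
        }
      }
    }
  }
  list(L_n = L_n, L_s = L_s)
}
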