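# Rephasing of heterozygous SNPs by inversion genotype: homokaryotypes
# contribute two haplotypes of their own class; in heterokaryotypes the
# allele matching the inverted-class consensus goes to the inverted
# haplotype.

# per-SNP consensus ALT-indicator of the inverted class from genotype-2
# homozygotes: 1 (ALT), 0 (REF), NA (tie / no data)
inverted_consensus <- function(g, geno) {
  g2 <- g[names(geno)[!is.na(geno) & geno == 2L], , drop = FALSE]
  if (!nrow(g2)) return(NULL)
  freq <- colMeans(g2, na.rm = TRUE) / 2
  out <- ifelse(is.nan(freq), NA, ifelse(freq > 0.5, 1L,
                                         ifelse(freq < 0.5, 0L, NA)))
  as.integer(out)
}

ancestral_consensus <- function(g, geno) {
  g0 <- g[names(geno)[!is.na(geno) & geno == 0L], , drop = FALSE]
  if (!nrow(g0)) return(NULL)
  freq <- colMeans(g0, na.rm = TRUE) / 2
  as.integer(ifelse(is.nan(freq), NA, ifelse(freq > 0.5, 1L,
                                             ifelse(freq < 0.5, 0L, NA))))
}

#' Rephase region SNPs by inversion genotype
#'
#' Homokaryotypes contribute two haplotypes of their own orientation class
#' (within-class heterozygous sites are split arbitrarily between the two).
#' For heterokaryotypes, at each heterozygous SNP the allele matching the
#' inverted-class consensus (majority allele among genotype-2 homozygotes)
#' is assigned to the inverted haplotype and the other allele to the
#' ancestral haplotype; consensus ties leave the site unassigned.
#'
#' @param dataset A [genotype_dataset()].
#' @param reg A [region()].
#' @param call An `inversion_call` for the region ([genotype_region()]).
#' @return A `phased_region`: `h1`, `h2` (samples x SNPs ALT indicators,
#'   `NA` where unassigned), `class1`, `class2` (haplotype orientation
#'   labels per sample), `snp_idx`.
#' @export
rephase_by_inversion <- function(dataset, reg, call) {
  idx <- snps_in_region(dataset, reg)
  geno <- call$genotype
  ids <- names(geno)[!is.na(geno)]
  g <- dataset$geno[ids, idx, drop = FALSE]
  geno <- geno[ids]

  cons_inv <- inverted_consensus(g, geno)
  cons_anc <- ancestral_consensus(g, geno)
  n_het <- sum(geno == 1L)
  if (is.null(cons_inv)) {
    # fall back: infer inverted consensus from heterozygotes given the
    # ancestral consensus (dosage minus ancestral allele)
    if (is.null(cons_anc) || n_het < 2)
      stop("no consensus source for class 'inverted'")
    gh <- g[geno == 1L, , drop = FALSE]
    freq <- colMeans(sweep(gh, 2, cons_anc), na.rm = TRUE)
    cons_inv <- as.integer(ifelse(is.nan(freq) | freq == 0.5, NA, freq > 0.5))
  }
  if (is.null(cons_anc) && n_het < 2 && !any(geno == 0L))
    stop("no consensus source for class 'ancestral'")

  S <- length(idx)
  h1 <- h2 <- matrix(NA_integer_, length(ids), S, dimnames = list(ids, NULL))
  class1 <- class2 <- stats::setNames(character(length(ids)), ids)
  for (i in seq_along(ids)) {
    gi <- g[i, ]
    if (geno[i] %in% c(0L, 2L)) {
      cl <- if (geno[i] == 0L) "ancestral" else "inverted"
      class1[i] <- class2[i] <- cl
      h1[i, ] <- ifelse(is.na(gi), NA, ifelse(gi == 2L, 1L, 0L))
      h2[i, ] <- ifelse(is.na(gi), NA, ifelse(gi >= 1L, 1L, 0L))
      # (dosage-1 sites split as 0 + 1: within-class polymorphism)
      tmp <- gi == 1L & !is.na(gi)
      h1[i, tmp] <- 0L; h2[i, tmp] <- 1L
    } else {
      class1[i] <- "inverted"; class2[i] <- "ancestral"
      hom0 <- !is.na(gi) & gi == 0L
      hom2 <- !is.na(gi) & gi == 2L
      h1[i, hom0] <- 0L; h2[i, hom0] <- 0L
      h1[i, hom2] <- 1L; h2[i, hom2] <- 1L
      hets <- which(!is.na(gi) & gi == 1L)
      ci <- cons_inv[hets]
      h1[i, hets] <- ifelse(is.na(ci), NA, ci)
      h2[i, hets] <- ifelse(is.na(ci), NA, 1L - ci)
    }
  }
  structure(list(h1 = h1, h2 = h2, class1 = class1, class2 = class2,
                 snp_idx = idx, region = reg),
            class = "phased_region")
}

#' Extract the consensus ancestral-orientation carrier haplotype
#'
#' For the configuration where the ancestral orientation exists only in
#' heterokaryotypes: at each SNP, subtract the inverted-class consensus
#' from each heterozygous carrier's genotype to recover the allele on its
#' ancestral-orientation haplotype, then take the majority across carriers.
#'
#' @param dataset A [genotype_dataset()].
#' @param reg A [region()].
#' @param call An `inversion_call` with at least one heterokaryotype and at
#'   least one genotype-2 homokaryotype.
#' @return Data frame per region SNP: `snp_idx`, `pos`, `allele` (ALT
#'   indicator, `NA` unresolved), `support` (fraction of informative
#'   carriers agreeing), `n_carriers`.
#' @export
extract_carrier_haplotype <- function(dataset, reg, call) {
  idx <- snps_in_region(dataset, reg)
  geno <- call$genotype
  hets <- names(geno)[!is.na(geno) & geno == 1L]
  if (!length(hets)) stop("no heterozygous carriers in region")
  if (!any(geno == 2L, na.rm = TRUE))
    stop("no genotype-2 homozygotes to derive the inverted consensus from")
  ids <- names(geno)[!is.na(geno)]
  g <- dataset$geno[ids, idx, drop = FALSE]
  cons_inv <- inverted_consensus(g, geno[ids])

  gh <- dataset$geno[hets, idx, drop = FALSE]
  # carrier's ancestral-orientation allele = dosage - inverted consensus,
  # valid when the result is 0 or 1
  anc <- sweep(gh, 2, cons_inv)
  anc[anc < 0 | anc > 1] <- NA
  votes1 <- colSums(anc == 1L, na.rm = TRUE)
  votes0 <- colSums(anc == 0L, na.rm = TRUE)
  nv <- votes1 + votes0
  allele <- ifelse(nv == 0, NA_integer_,
                   ifelse(votes1 > votes0, 1L, 0L))
  support <- ifelse(nv == 0, NA_real_, pmax(votes1, votes0) / nv)
  data.frame(snp_idx = idx, pos = dataset$snps$pos[idx],
             allele = allele, support = support, n_carriers = nv)
}
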