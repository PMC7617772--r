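#' SNP genotype dataset
#'
#' Container for a multi-sample biallelic-SNP callset: an ALT-allele dosage
#' matrix (samples x SNPs, values 0/1/2, `NA` = missing) together with the
#' SNP table (chromosome, 1-based position, REF/ALT alleles, coding-effect
#' class, and — after [polarize()] — the ancestral allele).
#'
#' @param samples Character vector of unique sample identifiers.
#' @param chrom Data frame with columns `name`, `length` (chromosome sizes
#'   in bp).
#' @param snps Data frame with columns `chrom`, `pos` (1-based, strictly
#'   increasing within chromosome), `ref`, `alt`, and optionally `effect`
#'   (one of `"synonymous"`, `"nonsynonymous"`, `"noncoding"`, `"unknown"`)
#'   and `ancestral` (`"ref"`, `"alt"` or `NA`).
#' @param geno Integer matrix, `length(samples)` rows x `nrow(snps)`
#'   columns, entries in `{0, 1, 2, NA}` counting ALT alleles.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, chrom, snps, geno) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  chrom <- as.data.frame(chrom)
  stopifnot(all(c("name", "length") %in% names(chrom)))
  snps <- as.data.frame(snps)
  stopifnot(all(c("chrom", "pos") %in% names(snps)))
  if (is.null(snps$ref)) snps$ref <- "A"
  if (is.null(snps$alt)) snps$alt <- "T"
  if (is.null(snps$effect)) snps$effect <- "unknown"
  if (is.null(snps$ancestral)) snps$ancestral <- NA_character_
  if (!all(snps$chrom %in% chrom$name))
    stop("SNP table references unknown chromosome(s)")
  for (cn in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == cn]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      bad <- p[which(diff(p) <= 0)[1] + 1]
      stop("positions not strictly increasing on ", cn, " at position ", bad)
    }
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(samples) || ncol(geno) != nrow(snps))
    stop("geno matrix dimensions do not match samples/snps")
  ok <- geno[!is.na(geno)]
  if (length(ok) && (min(ok) < 0L || max(ok) > 2L))
    stop("dosages must be in {0, 1, 2, NA}")
  rownames(geno) <- samples
  structure(list(samples = samples, chrom = chrom, snps = snps, geno = geno),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples, %d SNPs, %d chromosome(s)\n",
              length(x$samples), nrow(x$snps), nrow(x$chrom)))
  cat(sprintf("  polarized: %d/%d SNPs; effect classes: %s\n",
              sum(!is.na(x$snps$ancestral)), nrow(x$snps),
              paste(names(table(x$snps$effect)), collapse = "/")))
  invisible(x)
}

#' @export
n_snps <- function(dataset) nrow(dataset$snps)

#' Indices of SNPs falling inside a region
#'
#' @param dataset A [genotype_dataset()].
#' @param reg A [region()], or `NULL` for all SNPs.
#' @return Integer vector of SNP column indices.
#' @export
snps_in_region <- function(dataset, reg) {
  if (is.null(reg)) return(seq_len(n_snps(dataset)))
  which(dataset$snps$chrom == reg$chrom &
        dataset$snps$pos >= reg$start & dataset$snps$pos <= reg$end)
}

#' Derived-allele dosages
#'
#' Recodes ALT dosages as counts of the *derived* allele using the
#' ancestral-allele annotation set by [polarize()]: where the ancestral
#' allele is REF the derived dosage equals the ALT dosage; where it is ALT,
#' derived = 2 - ALT dosage. SNPs without a known ancestral state get `NA`
#' columns; missing genotypes stay missing.
#'
#' @param dataset A polarized [genotype_dataset()].
#' @param idx Optional SNP column indices.
#' @return Numeric matrix samples x SNPs of derived-allele counts.
#' @export
derived_dosages <- function(dataset, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(n_snps(dataset))
  g <- dataset$geno[, idx, drop = FALSE]
  anc <- dataset$snps$ancestral[idx]
  flip <- which(!is.na(anc) & anc == "alt")
  if (length(flip)) g[, flip] <- 2L - g[, flip, drop = FALSE]
  unknown <- which(is.na(anc))
  if (length(unknown)) g[, unknown] <- NA_integer_
  g
}

#' Subset a dataset by samples and/or SNPs
#'
#' @param dataset A [genotype_dataset()].
#' @param samples Sample ids to keep (default all). Unknown ids are an error.
#' @param snp_idx SNP column indices to keep (default all).
#' @return A [genotype_dataset()].
#' @export
subset_dataset <- function(dataset, samples = NULL, snp_idx = NULL) {
  if (is.null(samples)) samples <- dataset$samples
  missing <- setdiff(samples, dataset$samples)
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  if (is.null(snp_idx)) snp_idx <- seq_len(n_snps(dataset))
  genotype_dataset(samples, dataset$chrom,
                   dataset$snps[snp_idx, , drop = FALSE],
                   dataset$geno[samples, snp_idx, drop = FALSE])
}
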