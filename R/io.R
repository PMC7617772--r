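# VCF, metadata and BED input/output. Reading goes through vcfR; the VCF
# writer emits the minimal GT-only subset of VCFv4.2 that the reader (and
# any compliant tool) accepts.

#' Read a multi-sample VCF into a genotype dataset
#'
#' Only biallelic SNP records are retained; multi-allelic sites and indels
#' are dropped and counted in the log. Dosages encode ALT-allele counts;
#' `./.` becomes missing. Effect classes are taken from an `EFF=` INFO key
#' or a SnpEff-style `ANN=` field when present; an `AA=` INFO key matching
#' REF or ALT sets the ancestral allele.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param reg Optional [region()]; only SNPs inside are kept.
#' @param sample_subset Optional character vector of sample ids to keep.
#' @return A [genotype_dataset()].
#' @export
read_vcf <- function(path, reg = NULL, sample_subset = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom_col <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  for (cn in unique(chrom_col)) {
    p <- pos[chrom_col == cn]
    if (length(p) > 1 && any(diff(p) <= 0)) {
      bad <- p[which(diff(p) <= 0)[1] + 1]
      stop("VCF positions not sorted on ", cn, ": offending position ",
           format(bad, scientific = FALSE))
    }
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T", "a", "c", "g", "t")
  keep <- !is.na(alt) & ref %in% bases & alt %in% bases
  n_drop <- sum(!keep)
  if (n_drop) inv_log(n_drop, " non-biallelic-SNP record(s) dropped")
  info <- if ("INFO" %in% colnames(fix)) fix[, "INFO"] else rep(NA, nrow(fix))

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, samples)
    if (length(missing))
      stop("sample subset contains unknown id(s): ",
           paste(missing, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }

  idx <- which(keep)
  if (!is.null(reg))
    idx <- idx[chrom_col[idx] == reg$chrom & pos[idx] >= reg$start &
               pos[idx] <= reg$end]

  # "0/0" -> 0, "0/1"/"1/0" -> 1, "1/1" -> 2 (phased separators too)
  g <- gt[idx, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow = length(idx), ncol = length(samples))
  clean <- gsub("\\|", "/", g)
  dos[clean == "0/0"] <- 0L
  dos[clean == "0/1" | clean == "1/0"] <- 1L
  dos[clean == "1/1"] <- 2L

  eff <- rep("unknown", length(idx))
  anc <- rep(NA_character_, length(idx))
  ii <- info[idx]
  has_eff <- grepl("EFF=", ii)
  eff[has_eff] <- sub(".*EFF=([^;]+).*", "\\1", ii[has_eff])
  has_ann <- !has_eff & grepl("ANN=", ii)
  if (any(has_ann)) {
    ann <- sub(".*ANN=([^;]+).*", "\\1", ii[has_ann])
    eff[has_ann] <- ifelse(grepl("synonymous_variant", ann) &
                             !grepl("non", ann), "synonymous",
                    ifelse(grepl("missense_variant", ann), "nonsynonymous",
                           "noncoding"))
  }
  eff[!eff %in% c("synonymous", "nonsynonymous", "noncoding")] <- "unknown"
  has_aa <- grepl("AA=", ii)
  aa <- rep(NA_character_, length(idx))
  aa[has_aa] <- sub(".*AA=([^;]+).*", "\\1", ii[has_aa])
  anc[!is.na(aa) & aa == ref[idx]] <- "ref"
  anc[!is.na(aa) & aa == alt[idx]] <- "alt"

  contigs <- parse_contigs(v@meta)
  seen <- unique(chrom_col[idx])
  if (is.null(contigs)) {
    lens <- vapply(seen, function(cn) max(pos[idx][chrom_col[idx] == cn]),
                   numeric(1))
    contigs <- data.frame(name = seen, length = lens)
  } else {
    contigs <- contigs[contigs$name %in% union(seen, contigs$name), ,
                       drop = FALSE]
  }

  genotype_dataset(
    samples, contigs,
    data.frame(chrom = chrom_col[idx], pos = pos[idx], ref = ref[idx],
               alt = alt[idx], effect = eff, ancestral = anc,
               stringsAsFactors = FALSE),
    t(dos))
}

parse_contigs <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  nm <- sub(".*ID=([^,>]+).*", "\\1", ln)
  len <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ln)))
  data.frame(name = nm, length = len, stringsAsFactors = FALSE)
}

#' Write a genotype dataset as a minimal GT-only VCF
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output path (plain text).
#' @export
write_vcf <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%s>", dataset$chrom$name,
                       format(dataset$chrom$length, scientific = FALSE)),
               "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect class\">",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", dataset$samples), collapse = "\t"), con)
  s <- dataset$snps
  info <- ifelse(s$effect == "unknown", ".", paste0("EFF=", s$effect))
  aa <- ifelse(is.na(s$ancestral), NA,
               ifelse(s$ancestral == "ref", s$ref, s$alt))
  info <- ifelse(is.na(aa), info,
                 ifelse(info == ".", paste0("AA=", aa),
                        paste0(info, ";AA=", aa)))
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_snps(dataset), ncol = length(dataset$samples))
  gmat <- t(dataset$geno)
  ok <- !is.na(gmat)
  gt[ok] <- code[gmat[ok] + 1L]
  lines <- paste(s$chrom, format(s$pos, scientific = FALSE, trim = TRUE),
                 ".", s$ref, s$alt, ".", "PASS", info, "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Assign ancestral alleles from outgroup genotypes
#'
#' The ancestral state at a SNP is the allele whose frequency among
#' non-missing outgroup haplotypes is at least `min_outgroup_agreement`
#' (default 1: full outgroup agreement). SNPs with an all-missing or
#' disagreeing outgroup keep an unknown ancestral state. Applying the
#' function twice with the same outgroups is a no-op.
#'
#' @param dataset A [genotype_dataset()].
#' @param outgroup_samples Sample ids used as outgroup (must be non-empty).
#' @param min_outgroup_agreement Minimum outgroup allele frequency, in
#'   (0.5, 1].
#' @return The dataset with `snps$ancestral` filled in.
#' @export
polarize <- function(dataset, outgroup_samples, min_outgroup_agreement = 1.0) {
  if (length(outgroup_samples) == 0) stop("need at least one outgroup sample")
  missing <- setdiff(outgroup_samples, dataset$samples)
  if (length(missing))
    stop("unknown outgroup sample(s): ", paste(missing, collapse = ", "))
  if (min_outgroup_agreement <= 0.5 || min_outgroup_agreement > 1)
    stop("min_outgroup_agreement must be in (0.5, 1]")
  og <- dataset$geno[outgroup_samples, , drop = FALSE]
  alt_cnt <- colSums(og, na.rm = TRUE)
  n_hap <- 2 * colSums(!is.na(og))
  freq_alt <- ifelse(n_hap > 0, alt_cnt / n_hap, NA)
  anc <- rep(NA_character_, n_snps(dataset))
  anc[!is.na(freq_alt) & freq_alt >= min_outgroup_agreement] <- "alt"
  anc[!is.na(freq_alt) & (1 - freq_alt) >= min_outgroup_agreement] <- "ref"
  dataset$snps$ancestral <- anc
  attr(dataset, "outgroup_samples") <- outgroup_samples
  dataset
}

#' Write regions as BED3
#'
#' Converts internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention. Input order is preserved; no merging.
#'
#' @param regions A list of [region()] objects (may be empty).
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- vapply(regions, function(r)
    sprintf("%s\t%s\t%s", r$chrom,
            format(r$start - 1, scientific = FALSE),
            format(r$end, scientific = FALSE)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata from a tab-separated table
#'
#' Expected columns: `sample`, `species`, `clade`, `sex` (male/female/
#' unknown), and optionally `generation`, `parent1`, `parent2`, `depth_m`.
#' Pedigree parents, when given, must themselves appear in the table.
#'
#' @param path Path to a TSV with a header row.
#' @return A data frame of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  if (!"sample" %in% names(md)) stop("metadata needs a 'sample' column")
  if (anyDuplicated(md$sample)) stop("duplicate sample ids in metadata")
  for (col in c("species", "clade")) if (is.null(md[[col]])) md[[col]] <- NA
  if (is.null(md$sex)) md$sex <- "unknown"
  md$sex[is.na(md$sex)] <- "unknown"
  if (!all(md$sex %in% c("male", "female", "unknown")))
    stop("sex must be male/female/unknown")
  for (col in c("parent1", "parent2")) {
    if (!is.null(md[[col]])) {
      p <- md[[col]][!is.na(md[[col]]) & md[[col]] != ""]
      bad <- setdiff(p, md$sample)
      if (length(bad)) stop("pedigree parent(s) not in table: ",
                            paste(bad, collapse = ", "))
    }
  }
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' @rdname read_sample_metadata
#' @param md Metadata data frame.
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach coding-effect classes from a side table
#'
#' @param dataset A [genotype_dataset()].
#' @param effects Data frame with columns `chrom`, `pos`, `effect`.
#' @return The dataset with `snps$effect` updated where matched.
#' @export
set_effect_classes <- function(dataset, effects) {
  key <- paste(dataset$snps$chrom, dataset$snps$pos)
  m <- match(key, paste(effects$chrom, effects$pos))
  hit <- !is.na(m)
  dataset$snps$effect[hit] <- effects$effect[m[hit]]
  dataset
}
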