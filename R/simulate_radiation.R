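#' Define a radiation scenario with planted inversions
#'
#' Describes the simulated system: a set of clades (tip populations) on an
#' ultrametric species tree, one or more chromosomes split into
#' freely-recombining blocks, and planted polymorphic inversions. Inside an
#' inversion region the two orientation classes ("inverted" vs "ancestral")
#' form their own two-population genealogy that splits at the inversion
#' origin time — capturing both recombination suppression in
#' heterokaryotypes and elevated between-class divergence. Optional
#' introgression events and XY-like sex linkage (males heterozygous,
#' females homozygous inverted) can be planted.
#'
#' @param clades Data frame with columns `name`, `n` (diploid samples) and
#'   `ne` (diploid effective size), optionally `group` (clade label for
#'   metadata; defaults to `name`).
#' @param tree Newick string; tip labels must equal `clades$name`; branch
#'   lengths in generations; must be ultrametric.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param mu Mutation rate per bp per generation (default `3e-9`, a typical
#'   vertebrate rate).
#' @param block_bp Length of the independent-genealogy block approximating
#'   recombination (default 5e5 bp).
#' @param inversions List of `list(chrom, start, end, origin_time, freq,
#'   gene_flux = 0)`; `freq` is a named vector of inverted-haplotype
#'   frequencies per clade; `gene_flux` is the per-block probability that a
#'   haplotype's local genealogy swaps orientation class (mimicking rare
#'   double crossovers). Region bounds are snapped to block boundaries.
#' @param introgression List of `list(donor, recipient, time, fraction)`.
#' @param sex_linkage `NULL`, or `list(inversion = k, clades = <names>)`
#'   forcing males heterozygous and females homozygous-inverted at
#'   inversion `k` in the given clades.
#' @param outgroup Name of the clade used as outgroup (polarisation and
#'   inversion polarity), or `NULL`.
#' @param ancestral_ne Effective size of ancestral populations and of the
#'   orientation classes (default mean of clade sizes).
#' @param effect_probs Probabilities for assigning SNP coding-effect
#'   classes (noncoding / synonymous / nonsynonymous).
#' @param missing_rate Per-genotype missingness probability.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return An object of class `radiation_scenario`.
#' @export
radiation_scenario <- function(clades, tree, chrom_lengths,
                               mu = 3e-9, block_bp = 5e5,
                               inversions = list(), introgression = list(),
                               sex_linkage = NULL, outgroup = NULL,
                               ancestral_ne = NULL,
                               effect_probs = c(noncoding = 0.7,
                                                synonymous = 0.15,
                                                nonsynonymous = 0.15),
                               missing_rate = 0, seed = 1) {
  clades <- as.data.frame(clades)
  stopifnot(all(c("name", "n", "ne") %in% names(clades)))
  if (is.null(clades$group)) clades$group <- clades$name
  phy <- ape::read.tree(text = tree)
  if (!setequal(phy$tip.label, clades$name))
    stop("tree tip labels must match clade names")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (!is.null(outgroup) && !outgroup %in% clades$name)
    stop("unknown outgroup clade")
  ancestral_ne <- ancestral_ne %||% mean(clades$ne)
  inversions <- lapply(seq_along(inversions), function(k) {
    iv <- inversions[[k]]
    if (!iv$chrom %in% names(chrom_lengths))
      stop("inversion ", k, " on unknown chromosome")
    if (is.null(iv$origin_time) || iv$origin_time <= 0)
      stop("inversion ", k, ": origin_time must be positive")
    f <- iv$freq
    if (is.null(names(f)) || !all(names(f) %in% clades$name))
      stop("inversion ", k, ": freq must be named by clade")
    if (any(f < 0 | f > 1)) stop("inversion ", k, ": frequencies outside [0,1]")
    # snap to the block grid: blocks are the recombination unit
    iv$start <- floor((iv$start - 1) / block_bp) * block_bp + 1
    iv$end <- min(ceiling(iv$end / block_bp) * block_bp,
                  chrom_lengths[[iv$chrom]])
    iv$gene_flux <- iv$gene_flux %||% 0
    # derived inverted haplotype: founder-scale diversity; ancestral
    # orientation: radiation-scale diversity
    iv$inv_ne <- iv$inv_ne %||% (ancestral_ne / 10)
    iv$anc_ne <- iv$anc_ne %||% (2 * ancestral_ne)
    iv
  })
  for (ev in introgression)
    if (!all(c(ev$donor, ev$recipient) %in% clades$name) || ev$time <= 0 ||
        ev$fraction < 0 || ev$fraction > 1)
      stop("invalid introgression event")
  if (!is.null(sex_linkage)) {
    if (sex_linkage$inversion > length(inversions))
      stop("sex_linkage refers to a missing inversion")
    sex_linkage$clades <- sex_linkage$clades %||%
      names(which(inversions[[sex_linkage$inversion]]$freq > 0))
  }
  structure(list(clades = clades, tree = phy, chrom_lengths = chrom_lengths,
                 mu = mu, block_bp = block_bp, inversions = inversions,
                 introgression = introgression, sex_linkage = sex_linkage,
                 outgroup = outgroup, ancestral_ne = ancestral_ne,
                 effect_probs = effect_probs, missing_rate = missing_rate,
                 seed = seed),
            class = "radiation_scenario")
}

#' Simulate a species radiation with planted inversions
#'
#' Draws genotypes from a structured coalescent per block (see
#' [radiation_scenario()]). Inside inversion regions the genealogy is
#' conditioned on each haplotype's orientation class, so recombination
#' between classes is absent in heterokaryotypes and between-class
#' divergence reflects the inversion origin time. Returns the dataset, the
#' sample metadata, and truth tables for validation.
#'
#' @param scenario A [radiation_scenario()].
#' @return `list(dataset, metadata, truth)`; `truth` holds per-sample
#'   inversion genotypes, per-haplotype orientation classes, per-SNP
#'   ancestral alleles and derived-allele background classes, and the
#'   region haplotype matrices.
#' @export
simulate_radiation <- function(scenario) {
  stopifnot(inherits(scenario, "radiation_scenario"))
  set.seed(scenario$seed)
  cl <- scenario$clades
  n_total <- sum(cl$n)
  sample_ids <- unlist(lapply(seq_len(nrow(cl)), function(i)
    sprintf("%s_%02d", cl$name[i], seq_len(cl$n[i]))))
  sample_clade <- rep(cl$name, cl$n)
  sex <- unlist(lapply(cl$n, function(n) rep(c("female", "male"),
                                             length.out = n)))
  hap_sample <- rep(seq_len(n_total), each = 2)
  hap_clade <- sample_clade[hap_sample]
  n_hap <- 2 * n_total
  ne <- stats::setNames(cl$ne, cl$name)

  # orientation class per haplotype per inversion (TRUE = inverted)
  n_inv <- length(scenario$inversions)
  hap_inv <- matrix(FALSE, n_hap, max(1, n_inv))
  for (k in seq_len(n_inv)) {
    f <- scenario$inversions[[k]]$freq
    fr <- ifelse(hap_clade %in% names(f), f[hap_clade], 0)
    fr[is.na(fr)] <- 0
    hap_inv[, k] <- stats::runif(n_hap) < fr
    sl <- scenario$sex_linkage
    if (!is.null(sl) && sl$inversion == k) {
      sel <- which(sample_clade %in% sl$clades)
      for (i in sel) {
        h <- c(2 * i - 1, 2 * i)
        hap_inv[h, k] <- if (sex[i] == "female") c(TRUE, TRUE)
                         else c(TRUE, FALSE)
      }
    }
  }

  merge_ev <- tree_to_merge_events(scenario$tree, scenario$ancestral_ne)
  mig_ev <- if (length(scenario$introgression))
    do.call(rbind, lapply(scenario$introgression, function(ev)
      data.frame(time = ev$time, type = "migrate", from = ev$recipient,
                 to = ev$donor, prob = ev$fraction, ne = NA_real_))) else NULL
  bg_events <- rbind(merge_ev, mig_ev)
  bg_events <- bg_events[order(bg_events$time), , drop = FALSE]
  root_time <- max(merge_ev$time)

  snp_chunks <- list()
  geno_chunks <- list()
  truth_bg <- list()
  truth_haps <- vector("list", n_inv)
  region_snp_keys <- vector("list", n_inv)

  for (cn in names(scenario$chrom_lengths)) {
    L <- scenario$chrom_lengths[[cn]]
    starts <- seq(1, L, by = scenario$block_bp)
    for (bs in starts) {
      blen <- min(scenario$block_bp, L - bs + 1)
      inv_k <- 0L
      for (k in seq_len(n_inv)) {
        iv <- scenario$inversions[[k]]
        if (iv$chrom == cn && bs >= iv$start && bs <= iv$end) inv_k <- k
      }
      if (inv_k == 0L) {
        pops <- hap_clade
        evs <- bg_events
        nev <- ne
      } else {
        iv <- scenario$inversions[[inv_k]]
        cls <- hap_inv[, inv_k]
        if (iv$gene_flux > 0) {
          swap <- stats::runif(n_hap) < iv$gene_flux
          cls[swap] <- !cls[swap]
        }
        pops <- ifelse(cls, "INV", "ANC")
        if (!is.null(scenario$outgroup))
          pops[hap_clade == scenario$outgroup] <- "OUTG"
        evs <- data.frame(time = iv$origin_time, type = "merge",
                          from = "INV", to = "ANC", prob = NA_real_,
                          ne = scenario$ancestral_ne)
        if (!is.null(scenario$outgroup)) {
          tm <- max(root_time, iv$origin_time + 1)
          evs <- rbind(evs, data.frame(time = tm, type = "merge",
                                       from = "OUTG", to = "ANC",
                                       prob = NA_real_,
                                       ne = scenario$ancestral_ne))
        }
        evs <- evs[order(evs$time), , drop = FALSE]
        nev <- c(INV = iv$inv_ne, ANC = iv$anc_ne,
                 OUTG = scenario$ancestral_ne)
      }
      blk <- sim_block_snps(pops, nev, evs, scenario$mu * blen)
      if (!length(blk$pos_frac)) next
      pos <- bs + floor(blk$pos_frac * blen)
      keep <- !duplicated(pos)
      pos <- pos[keep]
      carriers <- blk$carriers[keep]
      S <- length(pos)
      H <- matrix(0L, n_hap, S)
      for (s in seq_len(S)) H[carriers[[s]], s] <- 1L
      dos_derived <- H[seq(1, n_hap, 2), , drop = FALSE] +
                     H[seq(2, n_hap, 2), , drop = FALSE]
      flip <- stats::runif(S) < 0.5  # whether ALT is the ancestral allele
      dos_alt <- dos_derived
      if (any(flip)) dos_alt[, flip] <- 2L - dos_alt[, flip, drop = FALSE]
      refs <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
      alts <- vapply(refs, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      eff <- sample(names(scenario$effect_probs), S, replace = TRUE,
                    prob = scenario$effect_probs)
      bgcls <- rep(NA_character_, S)
      if (inv_k > 0L) {
        inv_set <- which(pops == "INV")
        anc_set <- which(pops != "INV")
        bgcls <- vapply(carriers, function(cr) {
          if (all(cr %in% inv_set)) "inverted"
          else if (all(cr %in% anc_set)) "ancestral"
          else "shared"
        }, character(1))
        truth_haps[[inv_k]] <- c(truth_haps[[inv_k]], list(H))
        region_snp_keys[[inv_k]] <- c(region_snp_keys[[inv_k]],
                                      paste(cn, pos))
      }
      snp_chunks[[length(snp_chunks) + 1L]] <- data.frame(
        chrom = cn, pos = pos, ref = refs, alt = alts, effect = eff,
        ancestral = NA_character_,
        true_ancestral = ifelse(flip, "alt", "ref"),
        background = bgcls, stringsAsFactors = FALSE)
      geno_chunks[[length(geno_chunks) + 1L]] <- dos_alt
    }
  }

  snps <- do.call(rbind, snp_chunks)
  geno <- do.call(cbind, geno_chunks)
  if (scenario$missing_rate > 0) {
    drop <- stats::runif(length(geno)) < scenario$missing_rate
    geno[drop] <- NA_integer_
  }
  true_anc <- snps$true_ancestral
  background <- snps$background
  snps$true_ancestral <- NULL
  snps$background <- NULL

  dataset <- genotype_dataset(
    sample_ids,
    data.frame(name = names(scenario$chrom_lengths),
               length = as.numeric(scenario$chrom_lengths)),
    snps, geno)

  metadata <- validate_metadata(data.frame(
    sample = sample_ids, species = sample_clade,
    clade = rep(cl$group, cl$n), sex = sex, stringsAsFactors = FALSE))

  inv_geno <- matrix(0L, n_total, max(1, n_inv),
                     dimnames = list(sample_ids, NULL))
  hap_class <- vector("list", n_inv)
  regions <- vector("list", n_inv)
  haps <- vector("list", n_inv)
  for (k in seq_len(n_inv)) {
    iv <- scenario$inversions[[k]]
    inv_geno[, k] <- hap_inv[seq(1, n_hap, 2), k] + hap_inv[seq(2, n_hap, 2), k]
    hap_class[[k]] <- matrix(hap_inv[, k], ncol = 2, byrow = TRUE,
                             dimnames = list(sample_ids, NULL))
    regions[[k]] <- region(iv$chrom, iv$start, iv$end)
    if (length(truth_haps[[k]])) {
      Hk <- do.call(cbind, truth_haps[[k]])
      colnames(Hk) <- region_snp_keys[[k]]
      haps[[k]] <- Hk
    }
  }

  truth <- list(inv_genotypes = inv_geno[, seq_len(n_inv), drop = FALSE],
                hap_classes = hap_class, regions = regions,
                region_haplotypes = haps,
                ancestral_allele = true_anc, snp_background = background,
                sample_clade = sample_clade)
  list(dataset = dataset, metadata = metadata, truth = truth)
}
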