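#' Simulate an interspecific pedigree cross with a recombination-suppressed
#' region
#'
#' Crosses two founders that are homozygous for opposite inversion
#' orientations, producing F1, F2 and F3 generations. Meioses of parents
#' heterozygous for the region place zero crossovers inside
#' `suppressed_region`; elsewhere crossover counts are Poisson with the
#' configured map rate. Realized crossover (founder-origin switch)
#' positions are recorded as truth.
#'
#' @param founder_a,founder_b Haplotype allele vectors (0/1 ALT indicator)
#'   of the two homozygous founders, over the SNPs in `positions`.
#' @param positions Strictly increasing 1-based SNP positions (single
#'   chromosome).
#' @param chrom_length Chromosome length in bp.
#' @param n_f2,n_f3 Number of F2 and F3 individuals.
#' @param recomb_rate Crossovers per bp per meiosis (e.g. `1e-8`).
#' @param suppressed_region A [region()] inside the chromosome.
#' @param seed Integer seed.
#' @param chrom Chromosome name (default `"chr1"`).
#' @return `list(dataset, metadata, truth)`; `truth$crossovers` is a list
#'   per individual of realized crossover positions with an `in_region`
#'   flag, `truth$region_genotype` the count of founder-B haplotypes in the
#'   region (0/1/2).
#' @export
simulate_cross <- function(founder_a, founder_b, positions, chrom_length,
                           n_f2, n_f3, recomb_rate, suppressed_region,
                           seed = 1, chrom = "chr1") {
  stopifnot(length(founder_a) == length(positions),
            length(founder_b) == length(positions))
  if (suppressed_region$chrom != chrom ||
      suppressed_region$end > chrom_length)
    stop("suppressed_region outside the simulated chromosome")
  set.seed(seed)
  reg <- suppressed_region
  L <- chrom_length

  seg_founder <- function(origin)
    matrix(c(1, L, origin), nrow = 1,
           dimnames = list(NULL, c("start", "end", "origin")))

  # does a haplotype pair differ in founder origin anywhere inside reg?
  region_het <- function(h1, h2) {
    orig_at <- function(seg, p) seg[findInterval(p, seg[, "start"]), "origin"]
    probe <- unique(pmin(pmax(c(reg$start, (reg$start + reg$end) / 2,
                                reg$end,
                                sort(c(h1[, "start"], h2[, "start"]))), 1), L))
    probe <- probe[probe >= reg$start & probe <= reg$end]
    any(orig_at(h1, probe) != orig_at(h2, probe))
  }

  gamete <- function(parent) {
    het <- region_het(parent$h1, parent$h2)
    if (het) {
      lens <- c(reg$start - 1, L - reg$end)
      nx <- stats::rpois(1, recomb_rate * sum(lens))
      if (nx > 0) {
        u <- stats::runif(nx, 0, sum(lens))
        xpos <- ifelse(u < lens[1], u + 1, reg$end + (u - lens[1]))
      } else xpos <- numeric(0)
    } else {
      nx <- stats::rpois(1, recomb_rate * L)
      xpos <- if (nx > 0) stats::runif(nx, 1, L) else numeric(0)
    }
    xpos <- sort(xpos)
    haps <- if (stats::runif(1) < 0.5) list(parent$h1, parent$h2)
            else list(parent$h2, parent$h1)
    bounds <- c(1, xpos, L + 1)
    segs <- list()
    for (i in seq_len(length(bounds) - 1)) {
      a <- bounds[i]
      b <- if (i == length(bounds) - 1) L else bounds[i + 1]
      src <- haps[[(i - 1) %% 2 + 1]]
      sel <- src[, "end"] >= a & src[, "start"] <= b
      sub <- src[sel, , drop = FALSE]
      sub[1, "start"] <- a
      sub[nrow(sub), "end"] <- b
      segs[[i]] <- sub
    }
    segs <- do.call(rbind, segs)
    # realized crossovers = origin switches between adjacent segments
    sw <- which(diff(segs[, "origin"]) != 0)
    list(segs = segs, xover = segs[sw + 1, "start"])
  }

  mate <- function(mother, father) {
    gm <- gamete(mother); gf <- gamete(father)
    list(ind = list(h1 = gm$segs, h2 = gf$segs),
         xover = c(gm$xover, gf$xover))
  }

  alleles_at <- function(seg) {
    orig <- seg[findInterval(positions, seg[, "start"]), "origin"]
    ifelse(orig == 1, founder_a, founder_b)
  }

  fA <- list(h1 = seg_founder(1), h2 = seg_founder(1))
  fB <- list(h1 = seg_founder(2), h2 = seg_founder(2))
  inds <- list(FA = fA, FB = fB)
  gen <- c(FA = "founder", FB = "founder")
  parents <- list(FA = c(NA_character_, NA_character_),
                  FB = c(NA_character_, NA_character_))
  xovers <- list(FA = numeric(0), FB = numeric(0))

  for (i in 1:2) {
    m <- mate(fA, fB)
    id <- sprintf("F1_%02d", i)
    inds[[id]] <- m$ind; gen[id] <- "F1"
    parents[[id]] <- c("FA", "FB"); xovers[[id]] <- m$xover
  }
  f2_ids <- character(n_f2)
  for (i in seq_len(n_f2)) {
    m <- mate(inds$F1_01, inds$F1_02)
    id <- sprintf("F2_%03d", i)
    inds[[id]] <- m$ind; gen[id] <- "F2"
    parents[[id]] <- c("F1_01", "F1_02"); xovers[[id]] <- m$xover
    f2_ids[i] <- id
  }
  for (i in seq_len(n_f3)) {
    pr <- sample(f2_ids, 2)
    m <- mate(inds[[pr[1]]], inds[[pr[2]]])
    id <- sprintf("F3_%03d", i)
    inds[[id]] <- m$ind; gen[id] <- "F3"
    parents[[id]] <- pr; xovers[[id]] <- m$xover
  }

  ids <- names(inds)
  geno <- t(vapply(inds, function(ind)
    alleles_at(ind$h1) + alleles_at(ind$h2), numeric(length(positions))))
  rownames(geno) <- ids

  mid <- (reg$start + reg$end) / 2
  region_genotype <- vapply(inds, function(ind) {
    o1 <- ind$h1[findInterval(mid, ind$h1[, "start"]), "origin"]
    o2 <- ind$h2[findInterval(mid, ind$h2[, "start"]), "origin"]
    sum(c(o1, o2) == 2)
  }, numeric(1))

  dataset <- genotype_dataset(
    ids, data.frame(name = chrom, length = L),
    data.frame(chrom = chrom, pos = positions, ref = "A", alt = "C",
               effect = "unknown", ancestral = NA_character_,
               stringsAsFactors = FALSE),
    geno)
  metadata <- validate_metadata(data.frame(
    sample = ids, species = "cross", clade = "cross", sex = "unknown",
    generation = unname(gen),
    parent1 = vapply(parents, `[`, character(1) , 1),
    parent2 = vapply(parents, `[`, character(1), 2),
    stringsAsFactors = FALSE))

  truth <- list(
    crossovers = lapply(xovers, function(x)
      data.frame(pos = x,
                 in_region = x >= reg$start & x <= reg$end)),
    region_genotype = region_genotype,
    generation = gen)
  list(dataset = dataset, metadata = metadata, truth = truth)
}
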