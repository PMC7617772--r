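#' Configuration for the two-background forward selection simulator
#'
#' @param ne Diploid effective size (>= 2).
#' @param n_genes Number of genes.
#' @param gene_sites Coding sites per gene.
#' @param ns_ratio Nonsynonymous:synonymous site ratio (default 2.8, the
#'   typical value for vertebrate codon composition).
#' @param s_beneficial,s_deleterious Selection coefficients for beneficial
#'   and deleterious nonsynonymous mutations.
#' @param frac_beneficial Fraction of nonsynonymous mutations arising on
#'   the inverted background that are beneficial; all other nonsynonymous
#'   mutations take `s_deleterious`. Synonymous mutations are neutral.
#' @param generations Run length in generations.
#' @param inv_freq Inversion (inverted-background) frequency; the
#'   polymorphism is held at this frequency, modelling the balanced or
#'   sex-linked state in which the backgrounds coexist.
#' @param mu_per_site Mutation rate per site per generation.
#' @param noncoding_sites Number of neutral noncoding sites simulated
#'   alongside the genes (default 0).
#' @param seed Integer seed.
#' @return An object of class `forward_sim_config`.
#' @export
forward_sim_config <- function(ne = 1000, n_genes = 100, gene_sites = 1000,
                               ns_ratio = 2.8, s_beneficial = 0.05,
                               s_deleterious = -0.01, frac_beneficial = 0.1,
                               generations = 4 * ne, inv_freq = 0.5,
                               mu_per_site = 1e-7, noncoding_sites = 0,
                               seed = 1) {
  if (ne < 2) stop("ne must be >= 2")
  stopifnot(frac_beneficial >= 0, frac_beneficial <= 1,
            inv_freq > 0, inv_freq < 1, mu_per_site >= 0)
  L_total <- n_genes * gene_sites
  structure(list(ne = ne, n_genes = n_genes, gene_sites = gene_sites,
                 ns_ratio = ns_ratio, s_beneficial = s_beneficial,
                 s_deleterious = s_deleterious,
                 frac_beneficial = frac_beneficial,
                 generations = generations, inv_freq = inv_freq,
                 mu_per_site = mu_per_site,
                 noncoding_sites = noncoding_sites, seed = seed,
                 L_n = L_total * ns_ratio / (1 + ns_ratio),
                 L_s = L_total / (1 + ns_ratio)),
            class = "forward_sim_config")
}

#' Forward Wright-Fisher simulation of selection on two non-recombining
#' inversion backgrounds
#'
#' Discrete-generation Wright-Fisher dynamics. The inverted and ancestral
#' orientation classes are two non-recombining haploid backgrounds of fixed
#' size `2*ne*inv_freq` and `2*ne*(1-inv_freq)`. New mutations arise
#' Poisson-distributed, land on a background proportionally to its size,
#' are synonymous or nonsynonymous proportionally to the site ratio, and
#' drift within their background under their selection coefficient (free
#' recombination among sites within a background).
#'
#' @param config A [forward_sim_config()].
#' @return Data frame with one row per mutation: `effect`, `background`,
#'   `s`, `status` (`fixed`/`lost`/`polymorphic`), `freq_inv`, `freq_anc`
#'   (final within-background frequencies). The config (with site counts
#'   `L_n`, `L_s`) is attached as attribute `config`.
#' @export
simulate_selection_forward <- function(config) {
  stopifnot(inherits(config, "forward_sim_config"))
  set.seed(config$seed)
  K_inv <- max(1L, round(2 * config$ne * config$inv_freq))
  K_anc <- max(1L, 2 * config$ne - K_inv)
  L_all <- config$L_n + config$L_s + config$noncoding_sites
  lambda <- 2 * config$ne * config$mu_per_site * L_all
  p_noncoding <- config$noncoding_sites / L_all
  p_nonsyn <- config$L_n / L_all  # conditional assignment below

  cap <- max(64L, ceiling(lambda * config$generations * 1.4))
  eff <- character(cap); bg <- character(cap); sel <- numeric(cap)
  stat <- character(cap); fi <- numeric(cap); fa <- numeric(cap)
  n_rec <- 0L

  # active (segregating) mutations
  ax <- integer(0); aK <- integer(0); as_ <- numeric(0); aid <- integer(0)

  record <- function(i, status, x) {
    stat[i] <<- status
    p <- x / if (bg[i] == "inverted") K_inv else K_anc
    if (bg[i] == "inverted") { fi[i] <<- p; fa[i] <<- 0 }
    else { fi[i] <<- 0; fa[i] <<- p }
  }

  for (g in seq_len(config$generations)) {
    if (length(ax)) {
      w <- ax * (1 + as_)
      p <- w / (w + (aK - ax))
      ax <- stats::rbinom(length(ax), aK, p)
      done_fix <- ax == aK
      done_lost <- ax == 0L
      if (any(done_fix)) for (j in which(done_fix)) record(aid[j], "fixed", ax[j])
      if (any(done_lost)) for (j in which(done_lost)) record(aid[j], "lost", ax[j])
      keep <- !(done_fix | done_lost)
      ax <- ax[keep]; aK <- aK[keep]; as_ <- as_[keep]; aid <- aid[keep]
    }
    m <- stats::rpois(1, lambda)
    if (m > 0) {
      on_inv <- stats::runif(m) < K_inv / (K_inv + K_anc)
      u <- stats::runif(m)
      is_nc <- u < p_noncoding
      is_ns <- !is_nc & (u - p_noncoding) < p_nonsyn
      s_new <- numeric(m)
      ben <- is_ns & on_inv & stats::runif(m) < config$frac_beneficial
      s_new[is_ns] <- config$s_deleterious
      s_new[ben] <- config$s_beneficial
      idx <- n_rec + seq_len(m)
      if (max(idx) > cap) {
        grow <- max(idx) * 2L
        length(eff) <- grow; length(bg) <- grow; length(sel) <- grow
        length(stat) <- grow; length(fi) <- grow; length(fa) <- grow
        cap <- grow
      }
      eff[idx] <- ifelse(is_nc, "noncoding",
                         ifelse(is_ns, "nonsynonymous", "synonymous"))
      bg[idx] <- ifelse(on_inv, "inverted", "ancestral")
      sel[idx] <- s_new
      n_rec <- n_rec + m
      ax <- c(ax, rep(1L, m))
      aK <- c(aK, ifelse(on_inv, K_inv, K_anc))
      as_ <- c(as_, s_new)
      aid <- c(aid, idx)
    }
  }
  if (length(aid)) for (j in seq_along(aid)) record(aid[j], "polymorphic", ax[j])

  out <- data.frame(effect = eff[seq_len(n_rec)], background = bg[seq_len(n_rec)],
                    s = sel[seq_len(n_rec)], status = stat[seq_len(n_rec)],
                    freq_inv = fi[seq_len(n_rec)], freq_anc = fa[seq_len(n_rec)],
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  out
}

#' Sample a diploid cohort from forward-simulation output
#'
#' Draws `n_samples` diploid individuals whose inversion genotypes follow
#' Hardy-Weinberg proportions at the configured inversion frequency and
#' whose alleles at each surviving mutation are drawn from the final
#' within-background frequencies. The result is a polarized
#' [genotype_dataset()] (mutant allele = derived) plus the inversion
#' genotype vector, ready for [ics_scan()] and [binned_dnds()].
#'
#' @param mut_table Output of [simulate_selection_forward()].
#' @param n_samples Cohort size.
#' @param seed Integer seed.
#' @return `list(dataset, inv_genotype, L_n, L_s)`.
#' @export
forward_sim_cohort <- function(mut_table, n_samples = 200, seed = 1) {
  config <- attr(mut_table, "config")
  set.seed(seed)
  keep <- mut_table$status != "lost"
  mt <- mut_table[keep, , drop = FALSE]
  S <- nrow(mt)
  if (!S) stop("no surviving mutations in forward-simulation output")
  f <- config$inv_freq
  hap_inv <- matrix(stats::runif(2 * n_samples) < f, nrow = n_samples)
  inv_geno <- rowSums(hap_inv)
  geno <- matrix(0L, n_samples, S)
  for (h in 1:2) {
    p_hap <- outer(hap_inv[, h], rep(1, S)) * rep(mt$freq_inv, each = n_samples) +
             outer(!hap_inv[, h], rep(1, S)) * rep(mt$freq_anc, each = n_samples)
    geno <- geno + (matrix(stats::runif(n_samples * S), n_samples, S) < p_hap)
  }
  pos <- seq_len(S) * 100
  ds <- genotype_dataset(
    sprintf("S%03d", seq_len(n_samples)),
    data.frame(name = "chrSim", length = max(pos) + 100),
    data.frame(chrom = "chrSim", pos = pos, ref = "A", alt = "C",
               effect = mt$effect, ancestral = "ref",
               stringsAsFactors = FALSE),
    geno)
  list(dataset = ds, inv_genotype = stats::setNames(inv_geno, ds$samples),
       L_n = config$L_n, L_s = config$L_s)
}
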