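# Shared simulation fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

outgroup_ids <- function(ds) grep("^OUT", ds$samples, value = TRUE)
ingroup_ids <- function(ds) grep("^OUT", ds$samples, value = TRUE,
                                 invert = TRUE)

# standard planted-inversion radiation: 3 ingroup clades (20 each) +
# outgroup, one 10.5 Mbp inversion at frequency 0.5 on chr2
inversion_scenario <- function(seed = 1, gene_flux = 0,
                               sex_linkage = NULL, missing_rate = 0,
                               anc_ne = NULL) {
  inv <- list(chrom = "chr2", start = 5e6, end = 1.5e7,
              origin_time = 1e5, gene_flux = gene_flux,
              freq = c(A = 0.5, B = 0.5, C = 0.5, OUT = 0))
  inv$anc_ne <- anc_ne
  radiation_scenario(
    clades = data.frame(name = c("A", "B", "C", "OUT"),
                        n = c(20, 20, 20, 4), ne = c(5e3, 5e3, 5e3, 5e3)),
    tree = "(((A:20000,B:20000):10000,C:30000):170000,OUT:200000);",
    chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
    inversions = list(inv),
    sex_linkage = sex_linkage, outgroup = "OUT",
    missing_rate = missing_rate, seed = seed)
}

sim_inversion <- function(seed = 1)
  cached(paste0("inv", seed), simulate_radiation(inversion_scenario(seed)))

# chr9-like configuration: XY-linked inversion, so only heterozygous
# (males) and homozygous-inverted (females) karyotypes exist; the
# ancestral-orientation haplotype is a single re-introgressed lineage,
# hence founder-scale diversity (small anc_ne)
sim_sexlinked <- function(seed = 19)
  cached(paste0("sex", seed), simulate_radiation(
    inversion_scenario(seed, anc_ne = 500,
                       sex_linkage = list(inversion = 1,
                                          clades = c("A", "B", "C")))))

sim_null <- function(seed = 2)
  cached(paste0("null", seed), simulate_radiation(radiation_scenario(
    clades = data.frame(name = c("A", "B", "C", "OUT"),
                        n = c(20, 20, 20, 4), ne = c(5e3, 5e3, 5e3, 5e3)),
    tree = "(((A:20000,B:20000):10000,C:30000):170000,OUT:200000);",
    chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
    outgroup = "OUT", seed = seed)))

cross_fixture <- function(seed = 7, n_f2 = 100, n_f3 = 50) {
  cached(paste0("cross", seed, "_", n_f2, "_", n_f3), {
    set.seed(990)
    S <- 3000
    pos <- sort(sample(2e7, S))
    fa <- rbinom(S, 1, 0.1)
    fb <- rbinom(S, 1, 0.9)
    reg <- region("chr1", 6e6, 1.4e7)
    out <- simulate_cross(fa, fb, pos, 2e7, n_f2 = n_f2, n_f3 = n_f3,
                          recomb_rate = 2e-7, suppressed_region = reg,
                          seed = seed)
    out$region <- reg
    out
  })
}

forward_fixture <- function(seed, s_beneficial = 0.05, s_deleterious = -0.01,
                            frac_beneficial = 0.1, ne = 1000,
                            generations = 4 * ne, noncoding_sites = 0,
                            mu_per_site = 1e-7) {
  cfg <- forward_sim_config(ne = ne, n_genes = 100, gene_sites = 1000,
                            ns_ratio = 2.8, s_beneficial = s_beneficial,
                            s_deleterious = s_deleterious,
                            frac_beneficial = frac_beneficial,
                            generations = generations, inv_freq = 0.5,
                            noncoding_sites = noncoding_sites,
                            mu_per_site = mu_per_site, seed = seed)
  simulate_selection_forward(cfg)
}

forward_bins <- function(mt, seed = 1, n_samples = 200) {
  coh <- forward_sim_cohort(mt, n_samples = n_samples, seed = seed)
  rec <- suppressMessages(ics_scan(coh$dataset, coh$inv_genotype))
  list(records = rec, bins = binned_dnds(rec, coh$L_n, coh$L_s),
       cohort = coh)
}

# quartet scenario for D-statistic work: ((P1,P2),P3),OUT with optional
# P3 -> P2 introgression
quartet_dstat <- function(seed, introg = 0) {
  sc <- radiation_scenario(
    clades = data.frame(name = c("P1", "P2", "P3", "OUT"),
                        n = c(8, 8, 8, 3), ne = c(1e4, 1e4, 1e4, 1e4)),
    tree = "(((P1:20000,P2:20000):20000,P3:40000):60000,OUT:100000);",
    chrom_lengths = c(chr1 = 3e7, chr2 = 3e7), block_bp = 5e5,
    introgression = if (introg > 0)
      list(list(donor = "P3", recipient = "P2", time = 2000,
                fraction = introg)) else list(),
    outgroup = "OUT", seed = seed)
  sim <- simulate_radiation(sc)
  ds <- polarize(sim$dataset, outgroup_ids(sim$dataset))
  pops <- list(P1 = grep("^P1", ds$samples, value = TRUE),
               P2 = grep("^P2", ds$samples, value = TRUE),
               P3 = grep("^P3", ds$samples, value = TRUE),
               O = outgroup_ids(ds))
  fr <- pop_allele_freqs(ds, pops)
  list(freq = fr, dataset = ds,
       d = d_statistic(fr$freq, fr$chrom, fr$pos, block_size = 5e5))
}

# two species groups (3 species each) + outgroup, one inversion whose
# per-species states are either assigned "by drift" (null) or planted by a
# donor -> recipient transfer with a genome-wide admixture pulse
conditioned_fixture <- function(seed, transfer = FALSE) {
  cached(paste0("cond", seed, "_", transfer), {
    states_g1 <- if (transfer) c(0, 1, 0) else c(1, 0, 1)
    states_g2 <- if (transfer) c(1, 1, 1) else c(0, 1, 0)
    f <- c(stats::setNames(states_g1, paste0("g1s", 1:3)),
           stats::setNames(states_g2, paste0("g2s", 1:3)), OUT = 0)
    sc <- radiation_scenario(
      clades = data.frame(
        name = c(paste0("g1s", 1:3), paste0("g2s", 1:3), "OUT"),
        n = c(rep(8, 6), 3), ne = rep(1e4, 7),
        group = c(rep("G1", 3), rep("G2", 3), "outgroup")),
      tree = paste0("(((g1s1:10000,g1s2:10000,g1s3:10000):10000,",
                    "(g2s1:10000,g2s2:10000,g2s3:10000):10000):90000,",
                    "OUT:100000);"),
      chrom_lengths = c(chr1 = 2e7, chr2 = 2e7), block_bp = 5e5,
      inversions = list(list(chrom = "chr2", start = 4e6, end = 1e7,
                             origin_time = 1.2e5, freq = f)),
      introgression = if (transfer)
        list(list(donor = "g2s1", recipient = "g1s2", time = 1000,
                  fraction = 0.3)) else list(),
      outgroup = "OUT", seed = seed)
    sim <- simulate_radiation(sc)
    ds <- polarize(sim$dataset, outgroup_ids(sim$dataset))
    call <- truth_call(sim, 1)
    list(dataset = ds, metadata = sim$metadata, call = call, truth = sim$truth)
  })
}

# inversion_call built from the simulator's truth table (for tests that
# need genotypes but are not about the genotyper)
truth_call <- function(sim, k = 1) {
  structure(list(region = sim$truth$regions[[k]],
                 genotype = stats::setNames(sim$truth$inv_genotypes[, k],
                                            rownames(sim$truth$inv_genotypes)),
                 valid = TRUE),
            class = "inversion_call")
}

# single-chromosome dataset from a bare dosage matrix
make_ds <- function(geno, positions = NULL, chrom_len = NULL) {
  S <- ncol(geno)
  if (is.null(positions)) positions <- seq_len(S) * 10
  if (is.null(chrom_len)) chrom_len <- max(positions) + 10
  ids <- rownames(geno)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(geno)))
  genotype_dataset(ids,
                   data.frame(name = "chr1", length = chrom_len),
                   data.frame(chrom = "chr1", pos = positions), geno)
}

# minimal VCF text fixture
write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples, contigs = "##contig=<ID=chr1,length=1000000>") {
  c("##fileformat=VCFv4.2", contigs,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
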