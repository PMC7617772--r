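test_that("planted 0/1/2 karyotypes are recovered with correct polarity", {
  sim <- sim_inversion(1)
  reg <- sim$truth$regions[[1]]
  call <- genotype_region(sim$dataset, reg,
                          outgroup_samples = outgroup_ids(sim$dataset),
                          seed = 1)
  truth <- sim$truth$inv_genotypes[, 1]
  ids <- names(call$genotype)
  n_ok <- sum(call$genotype[ids] == truth[ids], na.rm = TRUE)
  expect_gte(n_ok, length(ids) - 1)
  expect_equal(call$k, 3)
  expect_true(call$valid)
  # genotype-1 samples are the most heterozygous (invariant)
  m <- tapply(call$het, call$genotype, mean)
  expect_true(m["1"] > m["0"] && m["1"] > m["2"])
})

test_that("genotyping is stable under sample-order permutation", {
  sim <- sim_inversion(1)
  reg <- sim$truth$regions[[1]]
  set.seed(21)
  perm <- sample(sim$dataset$samples)
  c1 <- genotype_region(sim$dataset, reg, outgroup_ids(sim$dataset), seed = 1)
  c2 <- genotype_region(subset_dataset(sim$dataset, perm), reg,
                        outgroup_ids(sim$dataset), seed = 1)
  ids <- names(c1$genotype)
  expect_equal(c1$genotype[ids], c2$genotype[ids])
})

test_that("an invariant region yields a single genotype-0 cluster", {
  g <- matrix(0L, 6, 60)
  ds <- make_ds(g, positions = seq_len(60) * 100)
  call <- genotype_region(ds, region("chr1", 1, 6100), min_snps = 50)
  expect_true(all(call$genotype == 0))
  expect_true(all(call$het[names(call$genotype)] < 1e-9))
})

test_that("a heterozygote/homozygote-only region selects k = 2 without genotype 0", {
  sim <- sim_sexlinked(19)
  reg <- sim$truth$regions[[1]]
  call <- genotype_region(sim$dataset, reg,
                          outgroup_samples = outgroup_ids(sim$dataset),
                          seed = 1)
  expect_equal(call$k, 2)
  expect_true(all(call$genotype %in% c(1L, 2L)))
  truth <- sim$truth$inv_genotypes[, 1]
  ids <- names(call$genotype)
  expect_gte(mean(call$genotype[ids] == truth[ids]), 0.98)
})

test_that("region heterozygosity is het SNPs per 10 kbp", {
  g <- matrix(0L, 2, 600)
  g[1, 1:500] <- 1L
  ds <- make_ds(g, positions = sort(sample(1e6, 600)), chrom_len = 1e6)
  h <- region_heterozygosity(ds, region("chr1", 1, 1e6))
  expect_equal(unname(h["s1"]), 5.0)
  expect_equal(unname(h["s2"]), 0.0)
  g[2, ] <- NA_integer_
  ds2 <- make_ds(g, positions = ds$snps$pos, chrom_len = 1e6)
  expect_true(is.na(region_heterozygosity(ds2, region("chr1", 1, 1e6))["s2"]))
})

test_that("rephasing follows the consensus rule and sums to dosage", {
  # 4 samples: two inverted homozygotes, one ancestral homozygote, one het
  geno <- rbind(i1 = c(2L, 2L, 0L, 1L),
                i2 = c(2L, 2L, 0L, 0L),
                a1 = c(0L, 0L, 2L, 0L),
                h1 = c(1L, 2L, 1L, 0L))
  ds <- make_ds(geno, positions = c(100, 200, 300, 400))
  call <- structure(list(region = region("chr1", 1, 500),
                         genotype = c(i1 = 2L, i2 = 2L, a1 = 0L, h1 = 1L)),
                    class = "inversion_call")
  ph <- rephase_by_inversion(ds, call$region, call)
  # het sample: site 1 consensus ALT -> inverted gets ALT
  expect_equal(unname(ph$h1["h1", 1]), 1L)
  expect_equal(unname(ph$h2["h1", 1]), 0L)
  # homozygous site in the het: both haplotypes carry that allele
  expect_equal(unname(ph$h1["h1", 2] + ph$h2["h1", 2]), 2L)
  # site 3: consensus of genotype-2 samples is REF -> ancestral hap gets ALT
  expect_equal(unname(ph$h1["h1", 3]), 0L)
  expect_equal(unname(ph$h2["h1", 3]), 1L)
  # pair sums to dosage wherever assigned
  tot <- ph$h1 + ph$h2
  ok <- !is.na(tot)
  expect_equal(tot[ok], geno[rownames(tot), ][ok])
  # heterokaryotypes carry one haplotype of each label
  expect_equal(unname(ph$class1["h1"]), "inverted")
  expect_equal(unname(ph$class2["h1"]), "ancestral")
})

test_that("rephased heterokaryotype haplotypes match the planted truth", {
  sim <- sim_inversion(1)
  reg <- sim$truth$regions[[1]]
  call <- truth_call(sim, 1)
  ph <- rephase_by_inversion(sim$dataset, reg, call)
  H <- sim$truth$region_haplotypes[[1]]
  key <- paste(sim$dataset$snps$chrom[ph$snp_idx],
               sim$dataset$snps$pos[ph$snp_idx])
  cols <- match(key, colnames(H))
  # truth haplotypes carry derived alleles; convert to ALT indicators
  anc <- sim$truth$ancestral_allele[ph$snp_idx]
  to_alt <- function(hap) ifelse(anc == "alt", 1L - hap, hap)
  hets <- names(call$genotype)[call$genotype == 1]
  n_match <- 0; n_tot <- 0
  for (s in hets) {
    si <- 2 * which(rownames(sim$truth$inv_genotypes) == s)
    cls <- sim$truth$hap_classes[[1]][s, ]
    truth_inv <- to_alt(H[si - 2 + which(cls), cols])
    het_sites <- which(!is.na(ph$h1[s, ]) &
                       sim$dataset$geno[s, ph$snp_idx] == 1L)
    n_match <- n_match + sum(ph$h1[s, het_sites] == truth_inv[het_sites])
    n_tot <- n_tot + length(het_sites)
  }
  expect_gt(n_tot, 100)
  expect_gte(n_match / n_tot, 0.95)
})

test_that("carrier-haplotype extraction recovers the ancestral-orientation allele", {
  geno <- rbind(i1 = c(2L, 2L, 0L), i2 = c(2L, 2L, 0L),
                h1 = c(1L, 2L, 1L))
  ds <- make_ds(geno, positions = c(100, 200, 300))
  call <- structure(list(region = region("chr1", 1, 400),
                         genotype = c(i1 = 2L, i2 = 2L, h1 = 1L)),
                    class = "inversion_call")
  hap <- extract_carrier_haplotype(ds, call$region, call)
  expect_equal(hap$allele, c(0L, 1L, 1L))  # inverted fixed ALT,ALT,REF
  expect_equal(hap$support, c(1, 1, 1))
  # two disagreeing carriers: majority undecided, support 0.5
  geno2 <- rbind(i1 = c(2L, 2L), i2 = c(2L, 2L),
                 h1 = c(1L, 1L), h2 = c(1L, 1L))
  geno2["h2", 1] <- 1L
  ds2 <- make_ds(rbind(i1 = c(2L, 0L), i2 = c(2L, 0L),
                       h1 = c(1L, 1L), h2 = c(1L, 0L)),
                 positions = c(100, 200))
  call2 <- structure(list(region = region("chr1", 1, 300),
                          genotype = c(i1 = 2L, i2 = 2L, h1 = 1L, h2 = 1L)),
                     class = "inversion_call")
  hap2 <- extract_carrier_haplotype(ds2, call2$region, call2)
  expect_equal(hap2$support[2], 0.5)
  expect_error(extract_carrier_haplotype(
    ds2, call2$region,
    structure(list(region = call2$region,
                   genotype = c(i1 = 2L, i2 = 2L, h1 = 2L, h2 = 2L)),
              class = "inversion_call")), "heterozygous")
})

test_that("an introgressed carrier haplotype clusters with the donor clade", {
  sim <- cached("carrier_donor", {
    # recipient clade R mostly inverted with het carriers; donor clade D
    # is the only source of ancestral-orientation haplotypes
    simulate_radiation(radiation_scenario(
      clades = data.frame(name = c("R", "D", "OUT"), n = c(20, 10, 4),
                          ne = c(5e3, 5e3, 5e3)),
      tree = "((R:30000,D:30000):170000,OUT:200000);",
      chrom_lengths = c(chr1 = 8e6),
      inversions = list(list(chrom = "chr1", start = 2e6, end = 6e6,
                             origin_time = 1e5,
                             freq = c(R = 0.8, D = 0, OUT = 0))),
      outgroup = "OUT", seed = 3))
  })
  reg <- sim$truth$regions[[1]]
  call <- truth_call(sim, 1)
  ing <- grep("^R", sim$dataset$samples, value = TRUE)
  call$genotype <- call$genotype[ing]
  if (!any(call$genotype == 1)) skip("no carriers drawn in this scenario")
  hap <- extract_carrier_haplotype(sim$dataset, reg, call)
  ok <- !is.na(hap$allele)
  # mismatch distance of extracted haplotype to each clade's consensus
  idx <- hap$snp_idx[ok]
  cons <- function(ids) {
    f <- colMeans(sim$dataset$geno[ids, idx, drop = FALSE],
                  na.rm = TRUE) / 2
    as.integer(f > 0.5)
  }
  d_donor <- mean(hap$allele[ok] != cons(grep("^D", sim$dataset$samples,
                                              value = TRUE)))
  inv_hom <- names(call$genotype)[call$genotype == 2]
  d_recip_inv <- mean(hap$allele[ok] != cons(inv_hom))
  expect_lt(d_donor, d_recip_inv)
})

test_that("crossover counting sees zero events in the suppressed region", {
  cx <- cross_fixture(7)
  track <- windowed_pc1_track(cx$dataset,
                              window_spec(size = 1e6, step = 1e6,
                                          min_snps = 10), chrom = "chr1")
  cent <- founder_state_centroids(track, hom_a = "FA", hom_b = "FB",
                                  het = c("F1_01", "F1_02"))
  prog <- grep("^F[23]", colnames(track$pc1), value = TRUE)
  cc <- count_crossovers(track, cx$region, cent, individuals = prog)
  expect_equal(sum(cc$n_in[!cc$flagged]), 0)
  expect_gt(sum(cc$n_out[!cc$flagged]), 0)
})

test_that("a planted state switch is counted once, near its true window", {
  starts <- seq(1, 20e6, 1e6)
  pc1 <- matrix(rep(c(rep(-1, 8), rep(0, 12)), 1), ncol = 1,
                dimnames = list(NULL, "ind"))
  track <- list(starts = starts, chrom = rep("chr1", 20), size = 1e6,
                pc1 = pc1)
  cent <- cbind(homA = rep(-1, 20), het = rep(0, 20), homB = rep(1, 20))
  cc <- count_crossovers(track, region("chr1", 1.8e7, 2e7), cent)
  expect_equal(cc$n_in + cc$n_out, 1)
  # constant individual: no events anywhere
  track$pc1[, 1] <- 1
  cc0 <- count_crossovers(track, region("chr1", 1.8e7, 2e7), cent)
  expect_equal(cc0$n_in + cc0$n_out, 0)
})
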