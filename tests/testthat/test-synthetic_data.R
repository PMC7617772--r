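test_that("radiation simulation is seed-deterministic", {
  a <- simulate_radiation(inversion_scenario(5))
  b <- simulate_radiation(inversion_scenario(5))
  expect_identical(a$dataset$geno, b$dataset$geno)
  expect_identical(a$truth$inv_genotypes, b$truth$inv_genotypes)
})

test_that("planted heterokaryotypes have the highest region heterozygosity", {
  sim <- sim_inversion(1)
  reg <- sim$truth$regions[[1]]
  het <- region_heterozygosity(sim$dataset, reg)
  g <- sim$truth$inv_genotypes[, 1]
  m <- tapply(het[rownames(sim$truth$inv_genotypes)], g, mean)
  expect_true(m["1"] > m["0"])
  expect_true(m["1"] > m["2"])
})

test_that("in-region FST between homokaryotype classes exceeds the genome background", {
  sim <- sim_inversion(1)
  g <- sim$truth$inv_genotypes[, 1]
  hom0 <- rownames(sim$truth$inv_genotypes)[g == 0]
  hom2 <- rownames(sim$truth$inv_genotypes)[g == 2]
  # Hudson-style FST from dosage frequencies (independent check code)
  fst <- function(ds, idx) {
    g0 <- ds$geno[hom0, idx, drop = FALSE]
    g2 <- ds$geno[hom2, idx, drop = FALSE]
    p1 <- colMeans(g0, na.rm = TRUE) / 2
    p2 <- colMeans(g2, na.rm = TRUE) / 2
    n1 <- colSums(!is.na(g0)); n2 <- colSums(!is.na(g2))
    num <- (p1 - p2)^2 - p1 * (1 - p1) / pmax(n1 - 1, 1) -
      p2 * (1 - p2) / pmax(n2 - 1, 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num[den > 0]) / sum(den[den > 0])
  }
  reg_idx <- snps_in_region(sim$dataset, sim$truth$regions[[1]])
  bg_idx <- which(sim$dataset$snps$chrom == "chr1")
  expect_gt(fst(sim$dataset, reg_idx), fst(sim$dataset, bg_idx) + 0.2)
})

test_that("pedigree cross: F1 heterozygous, suppression absolute, F2 Mendelian", {
  cx <- cross_fixture(7)
  tr <- cx$truth
  f1 <- names(tr$generation)[tr$generation == "F1"]
  expect_true(all(tr$region_genotype[f1] == 1))
  expect_equal(sum(vapply(tr$crossovers, function(d) sum(d$in_region),
                          numeric(1))), 0)
  f2 <- names(tr$generation)[tr$generation == "F2"]
  counts <- as.vector(table(factor(tr$region_genotype[f2], levels = 0:2)))
  expect_gt(mendelian_segregation_test(counts)$p, 0.01)
  # determinism
  cx2 <- simulate_cross(rep(0, 10), rep(1, 10), seq(1e6, 1e7, 1e6), 2e7,
                        10, 0, 1e-8, region("chr1", 1.2e7, 1.6e7), seed = 3)
  cx3 <- simulate_cross(rep(0, 10), rep(1, 10), seq(1e6, 1e7, 1e6), 2e7,
                        10, 0, 1e-8, region("chr1", 1.2e7, 1.6e7), seed = 3)
  expect_identical(cx2$dataset$geno, cx3$dataset$geno)
  expect_error(simulate_cross(rep(0, 10), rep(1, 10), seq(1e6, 1e7, 1e6),
                              2e7, 10, 0, 1e-8,
                              region("chr1", 1.9e7, 2.5e7), seed = 3),
               "outside")
})

test_that("realized crossover counts outside the region match the map length", {
  cx <- cross_fixture(7)
  tr <- cx$truth
  f2 <- names(tr$generation)[tr$generation == "F2"]
  # F2s are children of genome-wide heterozygous F1s: every crossover is an
  # origin switch, region suppressed in both parents
  per_ind <- vapply(tr$crossovers[f2], nrow, numeric(1))
  expected <- 2 * 2e-7 * (2e7 - (1.4e7 - 6e6 + 1))  # two meioses
  se <- sqrt(expected / length(f2))
  expect_lt(abs(mean(per_ind) - expected), 3 * se)
})

test_that("neutral forward simulation gives dN/dS near 1", {
  pooled_n <- 0; pooled_s <- 0
  above <- 0; below <- 0
  for (sd in 1:5) {
    mt <- forward_fixture(sd, s_beneficial = 0, s_deleterious = 0,
                          frac_beneficial = 0, ne = 200, generations = 800,
                          mu_per_site = 1e-6)
    fb <- forward_bins(mt, seed = sd)
    cfg <- attr(mt, "config")
    ok <- !is.na(fb$bins$dnds) & (fb$bins$n_nonsyn + fb$bins$n_syn) >= 20
    above <- above + sum(fb$bins$dnds[ok] > 1)
    below <- below + sum(fb$bins$dnds[ok] < 1)
    pooled_n <- pooled_n + sum(fb$bins$n_nonsyn)
    pooled_s <- pooled_s + sum(fb$bins$n_syn)
  }
  # overall ratio within Monte-Carlo error of 1
  cfg <- forward_sim_config(ne = 200)
  overall <- (pooled_n / cfg$L_n) / (pooled_s / cfg$L_s)
  expect_lt(abs(overall - 1), 0.1)
  # bins above vs below 1 balanced
  expect_gt(stats::binom.test(above, above + below)$p.value, 0.01)
})

test_that("purifying selection depresses, positive selection raises, top-bin dN/dS", {
  top_bin <- function(bins) bins$dnds[nrow(bins)]
  pur <- vapply(1:5, function(sd) {
    mt <- forward_fixture(sd, s_beneficial = 0, s_deleterious = -0.05,
                          frac_beneficial = 0, ne = 200, generations = 800,
                          mu_per_site = 1e-6)
    top_bin(forward_bins(mt, seed = sd)$bins)
  }, numeric(1))
  expect_true(all(!is.na(pur)))
  expect_true(all(pur < 1))
  pos <- vapply(1:3, function(sd) {
    mt <- forward_fixture(sd, ne = 500, generations = 2000)
    top_bin(forward_bins(mt, seed = sd)$bins)
  }, numeric(1))
  expect_true(all(pos >= 1))
})

test_that("forward simulator is deterministic and validates its config", {
  cfg <- forward_sim_config(ne = 100, generations = 200, seed = 4)
  expect_identical(simulate_selection_forward(cfg),
                   simulate_selection_forward(cfg))
  expect_error(forward_sim_config(ne = 1), "ne")
})

test_that("scenario validation rejects malformed inversions and events", {
  base <- function(...) radiation_scenario(
    clades = data.frame(name = c("A", "B"), n = c(2, 2), ne = c(1e3, 1e3)),
    tree = "(A:1000,B:1000);", chrom_lengths = c(chr1 = 1e6), ...)
  expect_error(base(inversions = list(list(chrom = "chrX", start = 1,
                                           end = 10, origin_time = 10,
                                           freq = c(A = 1, B = 0)))),
               "unknown chromosome")
  expect_error(base(inversions = list(list(chrom = "chr1", start = 1,
                                           end = 10, origin_time = -5,
                                           freq = c(A = 1, B = 0)))),
               "origin_time")
  expect_error(base(inversions = list(list(chrom = "chr1", start = 1,
                                           end = 10, origin_time = 10,
                                           freq = c(A = 2, B = 0)))),
               "frequencies")
  expect_error(base(introgression = list(list(donor = "A", recipient = "B",
                                              time = 10, fraction = 2))),
               "introgression")
})
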