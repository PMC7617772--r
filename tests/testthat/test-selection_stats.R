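polarized_ds <- function(geno, effect = NULL) {
  ds <- make_ds(geno)
  ds$snps$ancestral <- "ref"
  if (!is.null(effect)) ds$snps$effect <- effect
  ds
}

test_that("ICS correlation matches hand-computed Pearson values", {
  g <- c(s1 = 0L, s2 = 0L, s3 = 1L, s4 = 1L, s5 = 2L, s6 = 2L)
  geno <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 2L),
                c(2L, 1L), c(2L, 2L))
  ds <- polarized_ds(geno)
  rec <- suppressMessages(ics_scan(ds, g, min_obs = 6))
  # identity column: r = 1, score capped
  expect_equal(rec$r[1], 1)
  expect_equal(rec$score[1], 320)
  # swapped pair: hand-computed Pearson r = 3/4
  # (Sxg = 3, Sxx = Sgg = 4)
  expect_equal(rec$r[2], 0.75, tolerance = 1e-12)
  # the permutation p-value option matches an external permutation oracle
  set.seed(99)
  perm <- replicate(20000, abs(cor(sample(geno[, 2]), as.numeric(g))))
  p_perm <- mean(perm >= 0.75 - 1e-12)
  rec_p <- suppressMessages(ics_scan(ds, g, min_obs = 6, n_perm = 20000,
                                     perm_seed = 2))
  expect_lt(abs(rec_p$p[2] - p_perm),
            4 * sqrt(p_perm * (1 - p_perm) / 20000) + 0.005)
})

test_that("monomorphic SNPs are skipped with a log and unpolarized data errors", {
  g <- c(s1 = 0L, s2 = 1L, s3 = 2L, s4 = 0L, s5 = 1L, s6 = 2L,
         s7 = 0L, s8 = 1L, s9 = 2L, s10 = 0L)
  geno <- cbind(rep(1L, 10), c(0L, 0L, 1L, 0L, 1L, 2L, 0L, 1L, 2L, 0L))
  ds <- polarized_ds(geno)
  expect_message(rec <- ics_scan(ds, g), "skipped")
  expect_equal(rec$snp_idx, 2L)
  ds$snps$ancestral <- NA_character_
  expect_error(ics_scan(ds, g), "polarize")
})

test_that("re-polarizing a SNP negates its correlation exactly", {
  sim <- sim_inversion(1)
  ds <- polarize(sim$dataset, outgroup_ids(sim$dataset))
  call <- truth_call(sim, 1)
  idx <- snps_in_region(ds, sim$truth$regions[[1]])[1:200]
  sub <- subset_dataset(ds, snp_idx = idx)
  rec1 <- suppressMessages(ics_scan(sub, call))
  flipped <- sub
  flipped$snps$ancestral <- ifelse(is.na(sub$snps$ancestral), NA,
                                   ifelse(sub$snps$ancestral == "ref",
                                          "alt", "ref"))
  rec2 <- suppressMessages(ics_scan(flipped, call))
  expect_equal(rec2$r, -rec1$r, tolerance = 1e-12)
})

test_that("exonic enrichment arithmetic and forward-sim signal", {
  rec <- data.frame(
    snp_idx = 1:200,
    r = rep(c(0.95, 0.1), c(100, 100)),
    is_ics = rep(c(TRUE, FALSE), c(100, 100)),
    effect = c(rep("synonymous", 30), rep("noncoding", 70),
               rep("nonsynonymous", 10), rep("noncoding", 90)))
  en <- exonic_enrichment(rec)
  expect_equal(en$odds_ratio, (30 * 90) / (70 * 10), tolerance = 1e-12)
  # identical proportions: OR 1, p 1
  rec2 <- rec
  rec2$effect <- rep(c("synonymous", "noncoding"), 100)
  en2 <- exonic_enrichment(rec2)
  expect_equal(en2$odds_ratio, 1)
  expect_equal(en2$p, 1)
  expect_error(exonic_enrichment(rec[!rec$is_ics, ]), "ICS")
  # planted beneficial nonsynonymous ICS: coding enriched among ICS
  mt <- forward_fixture(2, ne = 500, generations = 2000,
                        noncoding_sites = 1e5)
  fb <- forward_bins(mt, seed = 2)
  en3 <- exonic_enrichment(fb$records)
  expect_gt(en3$odds_ratio, 1)
  expect_lt(en3$p, 0.05)
})

test_that("MK table arithmetic: NI, DoS and degenerate denominators", {
  # construct haplotype classes yielding the target counts directly
  phased_from <- function(inv_haps, anc_haps) {
    n <- nrow(inv_haps)
    structure(list(h1 = rbind(inv_haps), h2 = rbind(anc_haps),
                   class1 = rep("inverted", n),
                   class2 = rep("ancestral", n),
                   snp_idx = seq_len(ncol(inv_haps))),
              class = "phased_region")
  }
  # sites: Dn x10, Ds x5, Pn x2, Ps x8, plus invariant
  S <- 26
  inv <- matrix(0L, 2, S); anc <- matrix(0L, 2, S)
  eff <- character(S)
  inv[, 1:10] <- 1L; eff[1:10] <- "nonsynonymous"          # Dn
  inv[, 11:15] <- 1L; eff[11:15] <- "synonymous"           # Ds
  inv[1, 16:17] <- 1L; eff[16:17] <- "nonsynonymous"       # Pn
  anc[1, 18:25] <- 1L; eff[18:25] <- "synonymous"          # Ps
  eff[26] <- "nonsynonymous"                               # invariant
  mk <- mk_test(phased_from(inv, anc), eff)
  expect_equal(c(mk$Dn, mk$Ds, mk$Pn, mk$Ps), c(10, 5, 2, 8))
  expect_equal(mk$NI, (2 / 8) / (10 / 5))
  expect_equal(mk$DoS, 10 / 15 - 2 / 10, tolerance = 1e-12)
  expect_lte(mk$Dn + mk$Ds + mk$Pn + mk$Ps, S)
  # neutral identity
  inv2 <- matrix(0L, 2, 4); anc2 <- matrix(0L, 2, 4)
  inv2[, 1] <- 1L; inv2[, 2] <- 1L; inv2[1, 3] <- 1L; anc2[1, 4] <- 1L
  mk2 <- mk_test(phased_from(inv2, anc2),
                 c("nonsynonymous", "synonymous", "nonsynonymous",
                   "synonymous"))
  expect_equal(mk2$NI, 1)
  expect_equal(mk2$DoS, 0)
  # Ds = 0: NI undefined, DoS still available
  inv3 <- matrix(0L, 2, 2); anc3 <- matrix(0L, 2, 2)
  inv3[, 1] <- 1L; inv3[1, 2] <- 1L
  mk3 <- mk_test(phased_from(inv3, anc3), c("nonsynonymous", "synonymous"))
  expect_false(mk3$ni_defined)
  expect_true(is.na(mk3$NI))
  expect_error(mk_test(structure(list(h1 = matrix(0L, 1, 1),
                                      h2 = matrix(0L, 1, 1),
                                      class1 = "inverted",
                                      class2 = "inverted",
                                      snp_idx = 1),
                                 class = "phased_region"), "synonymous"),
               "class")
})

test_that("MK test on planted inversion haplotypes shows the divergence excess", {
  sim <- sim_inversion(1)
  ph <- rephase_by_inversion(sim$dataset, sim$truth$regions[[1]],
                             truth_call(sim, 1))
  mk <- mk_test(ph, sim$dataset$snps$effect[ph$snp_idx])
  expect_gt(mk$Dn + mk$Ds, 0)
  expect_gt(mk$Pn + mk$Ps, 0)
})

test_that("site counts by codon enumeration and bin arithmetic", {
  ng <- nei_gojobori_sites("atggaa")
  # one bin with equal counts and equal site totals
  rec <- data.frame(snp_idx = 1:4, r = c(0.95, 0.92, 0.97, 0.99),
                    effect = rep(c("synonymous", "nonsynonymous"), 2),
                    is_ics = TRUE)
  bins <- binned_dnds(rec, L_n = 10, L_s = 10)
  expect_equal(bins$dnds[20], 1.0)
  expect_equal(sum(bins$n_nonsyn), 2)
  expect_true(is.na(bins$dnds[1]))   # empty bin flagged
  expect_equal(nrow(bins), 20)
  expect_equal(bins$lo[1], -1)
  expect_equal(bins$hi[20], 1)
  expect_error(binned_dnds(rec, NULL, NULL), "site counts")
  expect_gt(ng$L_n, ng$L_s)  # coding sequences are mostly nonsynonymous
})

test_that("positive selection raises dN/dS with inversion correlation", {
  mt <- forward_fixture(1, ne = 500, generations = 2000)
  fb <- forward_bins(mt, seed = 1)
  bins <- fb$bins
  top <- bins$dnds[20]
  low_pos <- (sum(bins$n_nonsyn[11:15]) / attr(mt, "config")$L_n) /
             (sum(bins$n_syn[11:15]) / attr(mt, "config")$L_s)
  expect_gte(top, 1)
  expect_gt(top, low_pos)
})

test_that("shared polymorphism responds to gene flux between classes", {
  frac_for <- function(flux) {
    sim <- cached(paste0("flux", flux), simulate_radiation(
      inversion_scenario(31, gene_flux = flux)))
    ds <- polarize(sim$dataset, outgroup_ids(sim$dataset))
    call <- truth_call(sim, 1)
    rec <- suppressMessages(ics_scan(ds, call, ics_score_min = 5,
                                     ics_r_min = 0.8))
    ph <- rephase_by_inversion(ds, sim$truth$regions[[1]], call)
    shared_polymorphism_fraction(ph, rec)
  }
  f0 <- frac_for(0)
  f1 <- frac_for(0.1)
  expect_gt(f1, f0)
  # degenerate cases
  ph <- structure(list(h1 = rbind(c(1L, 1L)), h2 = rbind(c(0L, 0L)),
                       class1 = "inverted", class2 = "ancestral",
                       snp_idx = 1:2),
                  class = "phased_region")
  rec <- data.frame(snp_idx = 1:2, r = c(0.99, 0.99), is_ics = TRUE)
  expect_equal(shared_polymorphism_fraction(ph, rec), 0)  # fixed diffs
  ph2 <- structure(list(h1 = rbind(c(1L, 0L), c(0L, 1L)),
                        h2 = rbind(c(0L, 1L), c(1L, 0L)),
                        class1 = c("inverted", "inverted"),
                        class2 = c("ancestral", "ancestral"),
                        snp_idx = 1:2),
                   class = "phased_region")
  expect_equal(shared_polymorphism_fraction(ph2, rec), 1)
  expect_error(shared_polymorphism_fraction(ph, rec[FALSE, ]), "ICS")
})
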