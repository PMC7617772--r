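#!/usr/bin/env Rscript
# Step 6 — sex linkage and genotype-frequency tests: Hardy-Weinberg
# heterozygote-excess per species (with cross-species pooling) on the
# study dataset, and Fisher sex-association tests on an XY-linked
# simulation (males heterozygous, females homozygous-inverted).

suppressPackageStartupMessages(library(invrad))

ds <- read_vcf("results/data/callset.vcf")
md <- read_sample_metadata("results/data/metadata.tsv")
outg <- md$sample[md$clade == "outgroup"]
calls_tab <- read.delim("results/region_calls.tsv")
reg <- region(calls_tab$chrom[1], calls_tab$start[1], calls_tab$end[1])
call <- genotype_region(ds, reg, outgroup_samples = outg, seed = 1)

cnts <- genotype_counts_by_species(call, md)
cnts$hwe_excess_p <- vapply(seq_len(nrow(cnts)), function(i)
  hwe_excess_het_test(unlist(cnts[i, c("n0", "n1", "n2")]))$p, numeric(1))
write.table(cnts, "results/hwe_by_species.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
eligible <- cnts$n1 > 0
pooled <- pool_species_tests(cnts$hwe_excess_p[eligible])
message(sprintf(
  "HWE heterozygote excess: per-species p = %s; Fisher-combined p = %.3g",
  paste(signif(cnts$hwe_excess_p, 2), collapse = ", "), pooled$p))

# XY-linked inversion scenario: males heterozygous, females homozygous
sc <- radiation_scenario(
  clades = data.frame(name = c("A", "B", "C", "OUT"),
                      n = c(20, 20, 20, 4), ne = c(5e3, 5e3, 5e3, 5e3)),
  tree = "(((A:20000,B:20000):10000,C:30000):170000,OUT:200000);",
  chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
  inversions = list(list(chrom = "chr2", start = 5e6, end = 1.5e7,
                         origin_time = 1e5, anc_ne = 500,
                         freq = c(A = 0.5, B = 0.5, C = 0.5, OUT = 0))),
  sex_linkage = list(inversion = 1, clades = c("A", "B", "C")),
  outgroup = "OUT", seed = 19)
sim <- simulate_radiation(sc)
xcall <- genotype_region(sim$dataset, sim$truth$regions[[1]],
                         outgroup_samples = grep("^OUT",
                                                 sim$dataset$samples,
                                                 value = TRUE),
                         seed = 1)
tab <- sex_genotype_table(xcall, sim$metadata)
res <- fisher_sex_test(tab)
write.table(as.data.frame.matrix(tab), "results/sex_genotype_table.tsv",
            sep = "\t", quote = FALSE)
message("sex x genotype table (XY-linked scenario):")
print(tab)
message(sprintf(
  "Fisher sex association: p = %.3g, male-het odds ratio = %s (direction %s)",
  res$p, format(res$odds_ratio_male_het, digits = 3),
  if (res$direction_positive) "male-heterozygote, as expected for XY" else
    "reversed"))
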