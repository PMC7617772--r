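#!/usr/bin/env Rscript
# Step 1 — generate the study dataset: a three-clade radiation (20 diploids
# each) plus a 4-sample outgroup, two 20 Mbp chromosomes, and one planted
# polymorphic inversion (chr2:5-15 Mbp, origin 100k generations ago,
# frequency 0.5 in every ingroup clade). Writes the callset as VCF plus
# metadata and truth tables under results/data/.

suppressPackageStartupMessages(library(invrad))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scenario <- radiation_scenario(
  clades = data.frame(name = c("A", "B", "C", "OUT"),
                      n = c(20, 20, 20, 4), ne = c(5e3, 5e3, 5e3, 5e3),
                      group = c("deep_benthic", "shallow_benthic", "utaka",
                                "outgroup")),
  tree = "(((A:20000,B:20000):10000,C:30000):170000,OUT:200000);",
  chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
  inversions = list(list(chrom = "chr2", start = 5e6, end = 1.5e7,
                         origin_time = 1e5,
                         freq = c(A = 0.5, B = 0.5, C = 0.5, OUT = 0))),
  outgroup = "OUT", seed = 1)

sim <- simulate_radiation(scenario)

write_vcf(sim$dataset, file.path(out, "callset.vcf"))
write_sample_metadata(sim$metadata, file.path(out, "metadata.tsv"))
write_regions_bed(sim$truth$regions, file.path(out, "truth_regions.bed"))
write.table(data.frame(sample = rownames(sim$truth$inv_genotypes),
                       genotype = sim$truth$inv_genotypes[, 1]),
            file.path(out, "truth_genotypes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d samples, %d SNPs; planted inversion %s:%d-%d",
                length(sim$dataset$samples), n_snps(sim$dataset),
                sim$truth$regions[[1]]$chrom,
                sim$truth$regions[[1]]$start, sim$truth$regions[[1]]$end))
message("genotype truth: ",
        paste(names(table(sim$truth$inv_genotypes[, 1])),
              table(sim$truth$inv_genotypes[, 1]),
              sep = "=", collapse = ", "))
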