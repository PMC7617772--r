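#!/usr/bin/env Rscript
# Step 2 — inversion discovery from the callset written by 01_simulate.R:
# windowed principal-coordinate profiles of pairwise genetic distances
# (1 Mbp windows, half overlap), k-means outlier clustering, and region
# calls. Writes the calls (BED + TSV) and the per-sample windowed PC1
# track for the called chromosome.

suppressPackageStartupMessages(library(invrad))

ds <- read_vcf("results/data/callset.vcf")
md <- read_sample_metadata("results/data/metadata.tsv")
ingroup <- md$sample[md$clade != "outgroup"]
dsi <- subset_dataset(ds, ingroup)

prof <- compute_window_profiles(dsi, window_spec(size = 1e6, step = 5e5))
prof <- align_pc_signs(prof, anchor_profile(dsi))
calls <- detect_outlier_regions(prof, k_clusters = 2, min_run = 3, seed = 1)

dir.create("results", showWarnings = FALSE)
write_regions_bed(lapply(calls, `[[`, "region"), "results/region_calls.bed")
tab <- do.call(rbind, lapply(calls, function(x)
  data.frame(chrom = x$region$chrom, start = x$region$start,
             end = x$region$end, n_windows = length(x$window_idx),
             score = x$score)))
write.table(tab, "results/region_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (cl in calls) {
  track <- windowed_pc1_track(dsi, window_spec(size = 1e6, step = 5e5),
                              chrom = cl$region$chrom)
  write.table(data.frame(start = track$starts, track$pc1),
              sprintf("results/pc1_track_%s.tsv", cl$region$chrom),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

message(length(calls), " outlier region(s) called:")
for (cl in calls)
  message(sprintf("  %s:%d-%d (score %.2f)", cl$region$chrom,
                  cl$region$start, cl$region$end, cl$score))
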