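test_that("pairwise distances match a brute-force per-site tally", {
  g <- rbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L), c(2L, 0L, 1L, NA))
  ds <- make_ds(g)
  d <- pairwise_distance_matrix(ds)
  expect_equal(d[1, 2], 0)
  brute <- function(i, j) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    mean(abs(g[i, ok] - g[j, ok]) / 2)
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(d[i, j], if (i == j) 0 else brute(i, j))
  # maximal difference
  ds2 <- make_ds(rbind(rep(0L, 10), rep(2L, 10)))
  expect_equal(pairwise_distance_matrix(ds2)[1, 2], 1.0)
})

test_that("distance matrix is a semimetric on complete data", {
  set.seed(11)
  g <- matrix(sample(0:2, 15 * 40, replace = TRUE), 15)
  d <- pairwise_distance_matrix(make_ds(g))
  expect_equal(d, t(d))
  for (i in 1:15) for (j in 1:15) for (k in 1:15)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("window MDS coordinates match a dense eigendecomposition", {
  set.seed(2)
  g <- matrix(sample(0:2, 4 * 60, replace = TRUE), 4)
  ds <- make_ds(g)
  prof <- compute_window_profiles(ds, window_spec(size = 1000, step = 1000,
                                                  min_snps = 2), n_pcs = 2)
  d <- pairwise_distance_matrix(ds)
  # classical MDS by hand: double-centred squared distances
  d2 <- d^2
  J <- diag(4) - 1 / 4
  B <- -0.5 * J %*% d2 %*% J
  e <- eigen(B, symmetric = TRUE)
  expected <- e$vectors[, 1:2] %*% diag(sqrt(e$values[1:2]))
  got <- prof[[1]]$coords
  for (k in 1:2)
    expect_lt(min(max(abs(got[, k] - expected[, k])),
                  max(abs(got[, k] + expected[, k]))), 1e-9)
  expect_lt(max(abs(colSums(got))), 1e-9)  # centred
  expect_error(compute_window_profiles(ds, window_spec(1000, 1000, 2),
                                       n_pcs = 4), "n_pcs")
})

test_that("windows tile with half-overlap starts and degenerate windows are zero", {
  g <- matrix(0L, 3, 60)
  g[, 1:40] <- rep(c(0L, 1L, 2L), 40)[1:120]
  ds <- genotype_dataset(paste0("s", 1:3),
                         data.frame(name = "chr1", length = 2.2e6),
                         data.frame(chrom = "chr1",
                                    pos = seq(1000, 2.2e6, length.out = 60)),
                         g)
  prof <- compute_window_profiles(ds, window_spec(size = 1e6, step = 5e5,
                                                  min_snps = 2))
  starts <- vapply(prof, function(p) p$region$start, numeric(1))
  expect_true(all(starts %in% c(1, 500001, 1000001, 1500001, 2000001)))
  # identical samples -> zero coordinates and variance
  ds0 <- make_ds(matrix(1L, 4, 30))
  p0 <- compute_window_profiles(ds0, window_spec(1000, 1000, 2))
  expect_true(all(p0[[1]]$coords == 0))
  expect_true(all(p0[[1]]$var_explained == 0))
})

test_that("PC sign alignment is flip-correcting and idempotent", {
  set.seed(3)
  g <- matrix(sample(0:2, 8 * 80, replace = TRUE), 8)
  ds <- make_ds(g)
  anchor <- anchor_profile(ds)
  prof <- compute_window_profiles(ds, window_spec(400, 400, 2))
  flipped <- prof
  flipped[[1]]$coords[, 1] <- -flipped[[1]]$coords[, 1]
  realigned <- align_pc_signs(flipped, anchor)
  aligned <- align_pc_signs(prof, anchor)
  expect_equal(realigned[[1]]$coords, aligned[[1]]$coords)
  twice <- align_pc_signs(aligned, anchor)
  expect_identical(vapply(twice, function(p) p$coords[1, 1], numeric(1)),
                   vapply(aligned, function(p) p$coords[1, 1], numeric(1)))
})

test_that("a planted inversion is recovered as one call with >= 0.9 reciprocal overlap", {
  sim <- sim_inversion(1)
  ds <- subset_dataset(sim$dataset, ingroup_ids(sim$dataset))
  prof <- align_pc_signs(compute_window_profiles(ds, window_spec()),
                         anchor_profile(ds))
  calls <- detect_outlier_regions(prof, seed = 1)
  expect_length(calls, 1)
  expect_gte(reciprocal_overlap(calls[[1]]$region, sim$truth$regions[[1]]),
             0.9)
  expect_gt(calls[[1]]$score, 0)
  expect_lte(calls[[1]]$score, 1)
})

test_that("a null radiation yields no region calls", {
  sim <- sim_null(2)
  ds <- subset_dataset(sim$dataset, ingroup_ids(sim$dataset))
  prof <- align_pc_signs(compute_window_profiles(ds, window_spec()),
                         anchor_profile(ds))
  expect_length(detect_outlier_regions(prof, seed = 1), 0)
})

test_that("five planted inversions on five chromosomes give five calls", {
  sim <- cached("five_inv", {
    lens <- stats::setNames(rep(1.2e7, 5), paste0("chr", 1:5))
    invs <- lapply(paste0("chr", 1:5), function(cn)
      list(chrom = cn, start = 3e6, end = 9e6, origin_time = 1e5,
           freq = c(A = 0.5, B = 0.5, C = 0.5, OUT = 0)))
    simulate_radiation(radiation_scenario(
      clades = data.frame(name = c("A", "B", "C", "OUT"),
                          n = c(20, 20, 20, 4), ne = c(5e3, 5e3, 5e3, 5e3)),
      tree = "(((A:20000,B:20000):10000,C:30000):170000,OUT:200000);",
      chrom_lengths = lens, inversions = invs, outgroup = "OUT", seed = 4))
  })
  ds <- subset_dataset(sim$dataset, ingroup_ids(sim$dataset))
  prof <- align_pc_signs(compute_window_profiles(ds, window_spec()),
                         anchor_profile(ds))
  # each inversion has its own genotype composition, hence its own window
  # geometry: allow one cluster per candidate structure plus background
  calls <- detect_outlier_regions(prof, k_clusters = 6, seed = 1)
  expect_length(calls, 5)
  expect_setequal(vapply(calls, function(x) x$region$chrom, character(1)),
                  paste0("chr", 1:5))
  for (k in 1:5) {
    planted <- sim$truth$regions[[k]]
    hit <- Filter(function(x) x$region$chrom == planted$chrom, calls)[[1]]
    expect_gte(reciprocal_overlap(hit$region, planted), 0.75)
  }
})

test_that("permuting sample order changes no call boundaries", {
  sim <- sim_inversion(1)
  ids <- ingroup_ids(sim$dataset)
  run <- function(ord) {
    ds <- subset_dataset(sim$dataset, ord)
    prof <- align_pc_signs(compute_window_profiles(ds, window_spec()),
                           anchor_profile(ds))
    calls <- detect_outlier_regions(prof, seed = 1)
    lapply(calls, function(x) x$region)
  }
  set.seed(8)
  expect_equal(run(ids), run(sample(ids)))
})

test_that("windowed PC1 track separates founders and places F1 between them", {
  cx <- cross_fixture(7)
  track <- windowed_pc1_track(cx$dataset,
                              window_spec(size = 1e6, step = 1e6,
                                          min_snps = 10), chrom = "chr1")
  reg <- cx$region
  inw <- track$starts >= reg$start & (track$starts + 1e6 - 1) <= reg$end
  fa <- track$pc1[inw, "FA"]; fb <- track$pc1[inw, "FB"]
  f1 <- track$pc1[inw, "F1_01"]
  expect_true(all(sign(fa) != sign(fb)))
  expect_true(all(f1 > pmin(fa, fb) & f1 < pmax(fa, fb)))
  # identical samples give an all-zero track
  ds0 <- make_ds(matrix(1L, 4, 60), positions = seq(1e4, 6e5, 1e4),
                 chrom_len = 1e6)
  tr0 <- windowed_pc1_track(ds0, window_spec(size = 1e6, step = 1e6,
                                             min_snps = 2))
  expect_true(all(tr0$pc1 == 0))
})
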