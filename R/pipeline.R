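# End-to-end orchestration: simulate (or read) -> polarize -> detect ->
# genotype -> selection scan -> conditioned D -> association tests, with
# every stage's tables written to the output directory and a manifest
# recording config and seed. Rerunning with the same config reproduces
# identical tables.

#' Pipeline configuration
#'
#' Either a simulation `scenario` or real-input paths (`vcf`, `metadata`)
#' must be given, not neither.
#'
#' @param scenario A [radiation_scenario()], or `NULL`.
#' @param vcf,metadata Paths to a VCF and a metadata TSV, or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param seed Global seed governing all stochastic stages.
#' @param window A [window_spec()].
#' @param k_clusters,min_run Detection parameters
#'   ([detect_outlier_regions()]).
#' @param mu Mutation rate for divergence times.
#' @param block_size Jackknife block size (bp).
#' @param outgroup Outgroup clade/species label (defaults to the
#'   scenario's outgroup).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, vcf = NULL, metadata = NULL,
                            out_dir = "invrad_out", seed = 1,
                            window = window_spec(), k_clusters = 2,
                            min_run = 3, mu = 3e-9, block_size = 1e6,
                            outgroup = NULL) {
  if (is.null(scenario) && is.null(vcf))
    stop("config invalid: set either a scenario or input paths")
  if (!is.null(scenario) && !is.null(vcf))
    stop("config invalid: set a scenario or input paths, not both")
  structure(list(scenario = scenario, vcf = vcf, metadata = metadata,
                 out_dir = out_dir, seed = seed, window = window,
                 k_clusters = k_clusters, min_run = min_run, mu = mu,
                 block_size = block_size,
                 outgroup = outgroup %||% scenario$outgroup),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full inversion analysis pipeline
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a result bundle: dataset, metadata, region calls,
#'   inversion calls, ICS tables, association tables, conditioned-D
#'   results and the manifest. Tables are written as TSV/BED under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  bundle <- list()
  on_fail <- function(e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (!is.null(config$scenario)) {
      sim <- simulate_radiation(config$scenario)
      ds <- sim$dataset; md <- sim$metadata
      bundle$truth <- sim$truth
    } else {
      ds <- read_vcf(config$vcf)
      md <- read_sample_metadata(config$metadata)
    }
    inv_log("input: ", length(ds$samples), " samples, ", n_snps(ds), " SNPs")
    out_samples <- md$sample[md$species == config$outgroup |
                             md$clade == config$outgroup]
    out_samples <- intersect(out_samples, ds$samples)

    stage <- "polarize"
    if (length(out_samples)) ds <- polarize(ds, out_samples)
    ingroup <- setdiff(ds$samples, out_samples)

    stage <- "detect"
    prof <- compute_window_profiles(subset_dataset(ds, ingroup),
                                    config$window)
    prof <- align_pc_signs(prof, anchor_profile(subset_dataset(ds, ingroup)))
    calls_r <- detect_outlier_regions(prof, config$k_clusters,
                                      config$min_run, seed = config$seed)
    write_regions_bed(lapply(calls_r, `[[`, "region"),
                      file.path(config$out_dir, "region_calls.bed"))
    write_tsv(data.frame(
      chrom = vapply(calls_r, function(x) x$region$chrom, character(1)),
      start = vapply(calls_r, function(x) x$region$start, numeric(1)),
      end = vapply(calls_r, function(x) x$region$end, numeric(1)),
      score = vapply(calls_r, `[[`, numeric(1), "score")),
      file.path(config$out_dir, "region_calls.tsv"))
    inv_log("detect: ", length(calls_r), " outlier region(s)")

    stage <- "genotype"
    calls <- lapply(calls_r, function(rc)
      genotype_region(ds, rc$region, outgroup_samples = out_samples,
                      seed = config$seed))
    if (length(calls))
      write_tsv(do.call(rbind, lapply(calls, inversion_call_table)),
                file.path(config$out_dir, "inversion_genotypes.tsv"))

    stage <- "selection"
    ics <- list()
    if (length(calls) && any(!is.na(ds$snps$ancestral))) {
      ics <- lapply(calls, function(cl)
        ics_scan(ds, cl))
      write_tsv(do.call(rbind, Map(function(tb, i) cbind(inversion = i, tb),
                                   ics, seq_along(ics))),
                file.path(config$out_dir, "ics_scan.tsv"))
    }

    stage <- "dstat"
    dres <- NULL
    if (length(calls) && !is.null(config$outgroup) &&
        length(unique(md$species[md$sample %in% ingroup])) >= 3) {
      dres <- tryCatch(
        conditioned_d_experiment(ds, calls, md, config$outgroup,
                                 config$block_size),
        error = function(e) {
          inv_log("conditioned D skipped: ", conditionMessage(e)); NULL
        })
      if (!is.null(dres))
        write_tsv(dres$results,
                  file.path(config$out_dir, "conditioned_d.tsv"))
    }

    stage <- "assoc"
    assoc <- lapply(seq_along(calls), function(i) {
      cl <- calls[[i]]
      cnts <- genotype_counts_by_species(cl, md[md$sample %in% ingroup, ])
      cnts$hwe_p <- vapply(seq_len(nrow(cnts)), function(j)
        hwe_excess_het_test(unlist(cnts[j, c("n0", "n1", "n2")]))$p,
        numeric(1))
      eligible <- cnts$n1 > 0
      pooled <- if (any(eligible))
        pool_species_tests(pmax(cnts$hwe_p[eligible], 1e-300))$p else NA
      sex_tab <- sex_genotype_table(cl, md)
      sex <- fisher_sex_test(sex_tab)
      list(inversion = i, counts = cnts, pooled_hwe_p = pooled,
           sex_p = sex$p, sex_or = sex$odds_ratio_male_het)
    })
    if (length(assoc)) {
      write_tsv(do.call(rbind, lapply(assoc, function(a)
        cbind(inversion = a$inversion, a$counts))),
        file.path(config$out_dir, "hwe_by_species.tsv"))
      write_tsv(data.frame(
        inversion = vapply(assoc, `[[`, numeric(1), "inversion"),
        pooled_hwe_p = vapply(assoc, `[[`, numeric(1), "pooled_hwe_p"),
        sex_fisher_p = vapply(assoc, `[[`, numeric(1), "sex_p"),
        sex_or_male_het = vapply(assoc, `[[`, numeric(1), "sex_or")),
        file.path(config$out_dir, "association_summary.tsv"))
    }

    stage <- "manifest"
    manifest <- list(
      package = "invrad",
      version = as.character(utils::packageVersion("invrad")),
      seed = config$seed,
      n_samples = length(ds$samples), n_snps = n_snps(ds),
      n_region_calls = length(calls_r),
      outgroup = config$outgroup %||% NA)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    bundle$dataset <- ds; bundle$metadata <- md
    bundle$region_calls <- calls_r; bundle$inversion_calls <- calls
    bundle$ics <- ics; bundle$conditioned_d <- dres
    bundle$association <- assoc; bundle$manifest <- manifest
    invisible(bundle)
  }, error = on_fail)
}

#' Parse a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; numeric and
#' true/false values are converted.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
parse_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}
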