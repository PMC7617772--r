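#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genomic region
#'
#' A chromosome interval in 1-based inclusive coordinates (VCF convention).
#'
#' @param chrom Chromosome name.
#' @param start 1-based inclusive start (bp).
#' @param end 1-based inclusive end (bp); must be `>= start`.
#' @return An object of class `genomic_region`.
#' @export
region <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || end < start)
    stop("invalid region: need 1 <= start <= end, got [", start, ", ", end, "]")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("%s:%s-%s\n", x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE)))
  invisible(x)
}

#' Region length in bp
#' @param r A [region()].
#' @export
region_length <- function(r) r$end - r$start + 1

regions_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start <= b$end && b$start <= a$end
}

#' Reciprocal overlap between two regions
#'
#' The smaller of the two overlap fractions; 0 for disjoint regions.
#' @param a,b [region()] objects.
#' @export
reciprocal_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  ov <- min(a$end, b$end) - max(a$start, b$start) + 1
  if (ov <= 0) return(0)
  min(ov / region_length(a), ov / region_length(b))
}

# Run code with a private RNG stream; the caller's .Random.seed is restored.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

inv_log <- function(...) message("[invrad] ", ...)
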