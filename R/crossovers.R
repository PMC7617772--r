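# Crossover counting from windowed PC1 tracks of pedigree individuals.
# Each window of an individual is assigned to the nearest founder-state
# centroid (homozygous A / heterozygous / homozygous B); a crossover is a
# state change between consecutive windows after smoothing out short
# single-window islands.

#' Founder-state centroids per window
#'
#' Builds the per-window expected PC1 value of the three pedigree states
#' from reference individuals of known state.
#'
#' @param track Output of [windowed_pc1_track()].
#' @param hom_a,hom_b,het Sample ids homozygous for founder A, homozygous
#'   for founder B, and heterozygous (typically founders and F1s).
#' @return Matrix windows x 3 (`homA`, `het`, `homB`).
#' @export
founder_state_centroids <- function(track, hom_a, hom_b, het) {
  cbind(homA = rowMeans(track$pc1[, hom_a, drop = FALSE]),
        het = rowMeans(track$pc1[, het, drop = FALSE]),
        homB = rowMeans(track$pc1[, hom_b, drop = FALSE]))
}

smooth_states <- function(st, min_island = 2) {
  if (length(st) < 3) return(st)
  repeat {
    r <- rle(st)
    if (length(r$lengths) < 2) return(st)
    short <- which(r$lengths < min_island)
    short <- short[short != 1 & short != length(r$lengths)]
    # only absorb islands whose flanks agree (noise, not a double
    # crossover spanning >= min_island windows)
    short <- short[r$values[short - 1] == r$values[short + 1]]
    if (!length(short)) return(st)
    i <- short[1]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    st[starts[i]:ends[i]] <- r$values[i - 1]
  }
}

#' Count crossovers from a PC1 track
#'
#' @param track Output of [windowed_pc1_track()] for a single chromosome.
#' @param reg The recombination-suppressed [region()].
#' @param centroids Windows x 3 state centroids
#'   ([founder_state_centroids()]).
#' @param individuals Sample ids to count (default all columns of the
#'   track).
#' @param min_island Islands shorter than this many windows are smoothed
#'   away (default 2).
#' @param max_unassigned Individuals with a larger fraction of unassignable
#'   windows are flagged and excluded from totals (default 0.2).
#' @return Data frame per individual: `n_in` (crossovers inside `reg`),
#'   `n_out`, `flagged`.
#' @export
count_crossovers <- function(track, reg, centroids, individuals = NULL,
                             min_island = 2, max_unassigned = 0.2) {
  individuals <- individuals %||% colnames(track$pc1)
  n_w <- nrow(centroids)
  stopifnot(n_w == nrow(track$pc1))
  res <- lapply(individuals, function(id) {
    x <- track$pc1[, id]
    d <- abs(centroids - x)
    st <- apply(d, 1, which.min)
    unass <- rowSums(is.finite(d)) == 0
    st[unass] <- NA
    frac_un <- mean(is.na(st))
    if (frac_un > max_unassigned)
      return(data.frame(sample = id, n_in = NA, n_out = NA, flagged = TRUE))
    ok <- !is.na(st)
    sts <- smooth_states(st[ok], min_island)
    starts_ok <- track$starts[ok]
    chg <- which(diff(sts) != 0)
    wsize <- track$size %||% stats::median(diff(track$starts))
    # a crossover is inside the region only if both flanking windows lie
    # entirely within it (boundary events belong to the flanks)
    inside <- starts_ok[chg] >= reg$start &
      (starts_ok[chg + 1] + wsize - 1) <= reg$end
    data.frame(sample = id, n_in = sum(inside), n_out = sum(!inside),
               flagged = FALSE)
  })
  do.call(rbind, res)
}
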