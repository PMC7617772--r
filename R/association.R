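# Genotype-frequency and sex-association tests: exact Hardy-Weinberg
# heterozygote-excess (Levene conditional distribution), Fisher's exact
# 2x2 with explicit hypergeometric enumeration, Fisher's method for
# cross-species pooling, and the Mendelian segregation chi-square.

# Levene conditional distribution of heterozygote counts given allele
# counts: P(h | nA, n) = n! / (n0! h! n2!) * 2^h * nA! nB! / (2n)!
levene_het_distribution <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1
  nB <- 2 * n2 + n1
  h_max <- min(nA, nB)
  h_set <- seq(nA %% 2, h_max, by = 2)  # h shares parity with nA
  logp <- lgamma(n + 1) - lgamma((nA - h_set) / 2 + 1) -
    lgamma(h_set + 1) - lgamma((nB - h_set) / 2 + 1) +
    h_set * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  data.frame(h = h_set, p = p / sum(p))
}

#' Exact one-sided test for heterozygote excess
#'
#' Conditional exact test: given the observed allele counts, heterozygote
#' counts follow the Levene distribution; the one-sided p-value is the
#' probability of at least the observed number of heterozygotes. A
#' heterozygote excess at an inversion is the signature expected under
#' balancing processes or XY-like sex linkage.
#'
#' @param counts Genotype counts `c(n0, n1, n2)` (homozygous ancestral,
#'   heterozygous, homozygous inverted); total >= 2.
#' @return `list(p, observed_het, monomorphic)`; monomorphic input gives
#'   p = 1 with the flag set.
#' @export
hwe_excess_het_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n0 <- counts[1]; n1 <- counts[2]; n2 <- counts[3]
  if (n0 + n1 + n2 < 2) stop("need at least 2 individuals")
  nA <- 2 * n0 + n1; nB <- 2 * n2 + n1
  if (nA == 0 || nB == 0)
    return(list(p = 1, observed_het = n1, monomorphic = TRUE))
  dist <- levene_het_distribution(n0, n1, n2)
  list(p = sum(dist$p[dist$h >= n1]), observed_het = n1,
       monomorphic = FALSE)
}

#' Combine per-species p-values (Fisher's method)
#'
#' -2 * sum(log p) is chi-square distributed with 2k degrees of freedom
#' under the joint null.
#'
#' @param p Vector of per-species p-values (all in (0, 1]).
#' @param p_floor Optional floor applied to zero p-values; a zero p
#'   without a floor is an error.
#' @return `list(p, statistic, df, k)`.
#' @export
pool_species_tests <- function(p, p_floor = NULL) {
  if (!length(p)) stop("no eligible species")
  if (any(p <= 0)) {
    if (is.null(p_floor))
      stop("zero p-value supplied; set p_floor to combine")
    p <- pmax(p, p_floor)
  }
  stat <- -2 * sum(log(p))
  k <- length(p)
  list(p = stats::pchisq(stat, df = 2 * k, lower.tail = FALSE),
       statistic = stat, df = 2 * k, k = k)
}

# Two-sided Fisher exact by hypergeometric enumeration: sum of table
# probabilities <= observed (with the conventional 1e-7 relative tie
# tolerance). Returns the sample cross-product odds ratio.
fisher_exact_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n)
    return(list(p = 1, odds_ratio = NA_real_, flagged = TRUE))
  x <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(x, c1, n - c1, r1)
  p_obs <- probs[x == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p = min(p, 1), odds_ratio = or, flagged = FALSE)
}

#' Fisher's exact test of inversion genotype vs sex
#'
#' Collapses a (female, male) x (genotype 0, 1, 2) table to 2x2
#' (heterozygous vs homozygous) and runs a two-sided Fisher exact test
#' (hypergeometric enumeration; two-sided = sum of tables at most as
#' probable as the observed one). The direction is reported as the
#' male-heterozygote odds ratio: values > 1 match the XY-like expectation
#' of heterozygous males.
#'
#' @param tab Matrix with rows `female`, `male` and either three columns
#'   (genotypes 0/1/2) or two columns (`hom`, `het`).
#' @param collapse `"het_vs_hom"` pools both homozygote classes (default);
#'   `"het_vs_hom_inv"` drops genotype 0.
#' @return `list(p, odds_ratio_male_het, direction_positive, table,
#'   flagged)`; an empty margin gives p = 1 with the flag set.
#' @export
fisher_sex_test <- function(tab, collapse = c("het_vs_hom",
                                              "het_vs_hom_inv")) {
  collapse <- match.arg(collapse)
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2)
  if (ncol(tab) == 3) {
    hom <- if (collapse == "het_vs_hom") tab[, 1] + tab[, 3] else tab[, 3]
    t2 <- cbind(hom = hom, het = tab[, 2])
  } else t2 <- tab
  rownames(t2) <- rownames(tab) %||% c("female", "male")
  ft <- fisher_exact_2x2(t2)
  # male-het odds ratio: (male het * female hom) / (male hom * female het)
  or_mh <- unname((t2[2, 2] * t2[1, 1]) / (t2[2, 1] * t2[1, 2]))
  list(p = ft$p, odds_ratio_male_het = or_mh,
       direction_positive = is.finite(or_mh) && or_mh > 1 ||
         (t2[2, 1] == 0 && t2[2, 2] > 0 && t2[1, 1] > 0),
       table = t2, flagged = ft$flagged)
}

#' Mendelian segregation chi-square test
#'
#' Tests observed F2 genotype counts against the 1:2:1 expectation;
#' the p-value comes from the chi-square survival function with 2 df
#' (which equals exp(-X2/2)).
#'
#' @param counts Genotype counts `c(n0, n1, n2)`, total > 0.
#' @return `list(chisq, p, expected)`.
#' @export
mendelian_segregation_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("zero total count")
  e <- n * c(0.25, 0.5, 0.25)
  x2 <- sum((counts - e)^2 / e)
  list(chisq = x2, p = stats::pchisq(x2, df = 2, lower.tail = FALSE),
       expected = e)
}

#' Per-species genotype counts from an inversion call
#'
#' @param call An `inversion_call`.
#' @param metadata Sample metadata.
#' @return Data frame: species, n0, n1, n2.
#' @export
genotype_counts_by_species <- function(call, metadata) {
  g <- call$genotype[!is.na(call$genotype)]
  md <- metadata[match(names(g), metadata$sample), ]
  sp <- split(g, md$species)
  do.call(rbind, lapply(names(sp), function(s)
    data.frame(species = s,
               n0 = sum(sp[[s]] == 0), n1 = sum(sp[[s]] == 1),
               n2 = sum(sp[[s]] == 2), stringsAsFactors = FALSE)))
}

#' Sex-by-genotype table for an inversion call
#'
#' @param call An `inversion_call`.
#' @param metadata Sample metadata (sex column; `unknown` excluded and
#'   counted in the log).
#' @return 2x3 matrix rows female/male, columns genotypes 0/1/2.
#' @export
sex_genotype_table <- function(call, metadata) {
  g <- call$genotype[!is.na(call$genotype)]
  sex <- metadata$sex[match(names(g), metadata$sample)]
  drop <- sex == "unknown" | is.na(sex)
  if (any(drop)) inv_log(sum(drop), " sample(s) of unknown sex excluded")
  g <- g[!drop]; sex <- sex[!drop]
  tab <- matrix(0L, 2, 3, dimnames = list(c("female", "male"), 0:2))
  for (s in c("female", "male")) for (k in 0:2)
    tab[s, as.character(k)] <- sum(sex == s & g == k)
  tab
}
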