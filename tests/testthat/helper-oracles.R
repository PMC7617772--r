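# Independent oracles used by module and acceptance tests.

# Levene conditional heterozygote distribution via probability ratios
# (different route from the package's log-factorial implementation)
levene_oracle <- function(n0, n1, n2) {
  nA <- 2 * n0 + n1
  nB <- 2 * n2 + n1
  h_set <- seq(nA %% 2, min(nA, nB), by = 2)
  w <- numeric(length(h_set))
  w[1] <- 1
  if (length(h_set) > 1) for (i in 2:length(h_set)) {
    h <- h_set[i]
    n0p <- (nA - (h - 2)) / 2
    n2p <- (nB - (h - 2)) / 2
    w[i] <- w[i - 1] * 4 * n0p * n2p / (h * (h - 1))
  }
  p <- w / sum(w)
  sum(p[h_set >= n1])
}

# two-sided Fisher p by direct hypergeometric enumeration
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 %in% c(0, n) || c1 %in% c(0, n)) return(1)
  x <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(x, c1, n - c1, r1)
  min(1, sum(probs[probs <= probs[x == tab[1, 1]] * (1 + 1e-7)]))
}

# Nei-Gojobori site counts by exhaustive codon-mutation enumeration using
# the Biostrings genetic code (independent of the seqinr-based path)
ng_oracle <- function(seq) {
  code <- Biostrings::GENETIC_CODE
  s <- toupper(seq)
  v <- strsplit(s, "")[[1]]
  L_n <- 0; L_s <- 0
  for (i in seq(1, length(v), 3)) {
    cod <- paste(v[i:(i + 2)], collapse = "")
    aa0 <- code[[cod]]
    if (aa0 == "*") next
    for (pp in 1:3) for (b in c("A", "C", "G", "T")) {
      if (substr(cod, pp, pp) == b) next
      mut <- cod
      substr(mut, pp, pp) <- b
      aa1 <- code[[mut]]
      if (aa1 == "*") next
      # weight by the share of valid (non-stop) changes at this position
      valid <- sum(vapply(setdiff(c("A", "C", "G", "T"),
                                  substr(cod, pp, pp)), function(bb) {
        m2 <- cod; substr(m2, pp, pp) <- bb
        code[[m2]] != "*"
      }, logical(1)))
      if (aa1 != aa0) L_n <- L_n + 1 / valid else L_s <- L_s + 1 / valid
    }
  }
  list(L_n = L_n, L_s = L_s)
}
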