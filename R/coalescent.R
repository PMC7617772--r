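# Event-driven structured coalescent over discrete populations, used as the
# genealogy backbone of simulate_radiation(). Recombination along a
# chromosome is approximated by independent blocks, each with its own
# genealogy; within a block there is complete linkage. Mutations are
# dropped on branches under the infinite-sites model.

# pop_of_hap : character vector, population label per haploid lineage
# ne         : named numeric vector of diploid effective sizes per population
# events     : data.frame(time, type "merge"/"migrate", from, to, prob, ne)
#              sorted by time; "merge" moves all lineages of `from` into
#              `to` (optionally resetting `to`'s Ne); "migrate" moves each
#              lineage of `from` into `to` independently with prob `prob`
#              (backwards in time: models forward introgression to -> from).
# mu_len     : mutation rate per generation for the whole block (mu * bp)
# Returns list(pos_frac, carriers): derived-allele carrier index sets.
sim_block_snps <- function(pop_of_hap, ne, events, mu_len) {
  n <- length(pop_of_hap)
  lin_car <- as.list(seq_len(n))
  lin_pop <- as.character(pop_of_hap)
  lin_birth <- numeric(n)
  if (is.null(events)) events <- data.frame(time = numeric(0))
  ev_i <- 1L
  t <- 0
  br_car <- vector("list", 2 * n)
  br_len <- numeric(2 * n)
  nb <- 0L

  while (length(lin_car) > 1L) {
    cnt <- table(lin_pop)
    active <- names(cnt)[cnt >= 2]
    rates <- if (length(active))
      vapply(active, function(p) {
        k <- cnt[[p]]
        k * (k - 1) / 2 / (2 * ne[[p]])
      }, numeric(1)) else numeric(0)
    R <- sum(rates)
    t_ev <- if (ev_i <= nrow(events)) events$time[ev_i] else Inf
    t_coal <- if (R > 0) t + stats::rexp(1, R) else Inf
    if (t_coal < t_ev) {
      p <- if (length(active) == 1L) active else
        sample(active, 1L, prob = rates / R)
      pair <- sample(which(lin_pop == p), 2L)
      for (j in pair) {
        nb <- nb + 1L
        if (nb > length(br_len)) { br_len <- c(br_len, numeric(nb)); br_car <- c(br_car, vector("list", nb)) }
        br_car[[nb]] <- lin_car[[j]]
        br_len[nb] <- t_coal - lin_birth[j]
      }
      lin_car[[pair[1]]] <- c(lin_car[[pair[1]]], lin_car[[pair[2]]])
      lin_birth[pair[1]] <- t_coal
      lin_car <- lin_car[-pair[2]]
      lin_pop <- lin_pop[-pair[2]]
      lin_birth <- lin_birth[-pair[2]]
      t <- t_coal
    } else if (is.finite(t_ev)) {
      ev <- events[ev_i, ]
      if (ev$type == "merge") {
        lin_pop[lin_pop == ev$from] <- ev$to
        if (!is.null(ev$ne) && !is.na(ev$ne)) ne[[ev$to]] <- ev$ne
      } else if (ev$type == "migrate") {
        sel <- lin_pop == ev$from & stats::runif(length(lin_pop)) < ev$prob
        lin_pop[sel] <- ev$to
      }
      t <- t_ev
      ev_i <- ev_i + 1L
    } else {
      stop("coalescent stuck: disjoint populations never merge")
    }
  }

  br_car <- br_car[seq_len(nb)]
  br_len <- br_len[seq_len(nb)]
  total <- sum(br_len)
  n_mut <- stats::rpois(1, mu_len * total)
  if (n_mut == 0)
    return(list(pos_frac = numeric(0), carriers = list()))
  bi <- sample.int(nb, n_mut, replace = TRUE, prob = br_len)
  ord <- order(pos <- stats::runif(n_mut))
  list(pos_frac = pos[ord], carriers = br_car[bi][ord])
}

# Convert an ultrametric clade tree (ape::phylo, branch lengths in
# generations, tip labels = population names) into merge events.
tree_to_merge_events <- function(tree, ancestral_ne) {
  depth <- ape::node.depth.edgelength(tree)
  tmax <- max(depth)
  times <- tmax - depth  # time before present of each node
  ntip <- length(tree$tip.label)
  rep_of <- character(ntip + tree$Nnode)
  rep_of[seq_len(ntip)] <- tree$tip.label
  internal <- order(times[(ntip + 1):(ntip + tree$Nnode)]) + ntip
  ev <- list()
  for (nd in internal) {
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    reps <- rep_of[ch]
    for (k in seq_along(reps)[-1])
      ev[[length(ev) + 1L]] <- data.frame(
        time = times[nd], type = "merge", from = reps[k], to = reps[1],
        prob = NA_real_, ne = ancestral_ne, stringsAsFactors = FALSE)
    rep_of[nd] <- reps[1]
  }
  if (length(ev)) do.call(rbind, ev) else
    data.frame(time = numeric(0), type = character(0), from = character(0),
               to = character(0), prob = numeric(0), ne = numeric(0))
}
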